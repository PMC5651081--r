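# Infinium-style manifest construction: the SNP base plus 60 bp of flanking
# sequence either side, with the polymorphism encoded either as a bracket
# expression ("[A/G]") or as the single IUPAC two-base ambiguity character.

.IUPAC_PAIR <- c(
  "AC" = "M", "AG" = "R", "AT" = "W",
  "CG" = "S", "CT" = "Y", "GT" = "K"
)
.IUPAC_UNPAIR <- setNames(names(.IUPAC_PAIR), .IUPAC_PAIR)

#' IUPAC two-base ambiguity code for an allele pair
#'
#' @param allele_a,allele_b distinct characters from ACGT; order-insensitive.
#' @return single ambiguity character (R, Y, S, W, K or M).
#' @examples
#' iupac_code("A", "G") # "R"
#' iupac_code("G", "A") # "R"
#' @export
iupac_code <- function(allele_a, allele_b) {
  a <- toupper(allele_a); b <- toupper(allele_b)
  if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T"))
    stopf("alleles must be single bases in ACGT, got '%s'/'%s'", a, b)
  if (a == b) stopf("alleles must be distinct, got '%s'/'%s'", a, b)
  .IUPAC_PAIR[[paste(sort(c(a, b)), collapse = "")]]
}

#' Allele pair encoded by an IUPAC ambiguity character
#'
#' @param code one of R, Y, S, W, K, M.
#' @return character vector of the two bases, alphabetical.
#' @export
iupac_alleles <- function(code) {
  pair <- .IUPAC_UNPAIR[toupper(code)]
  if (is.na(pair)) stopf("'%s' is not a two-base IUPAC ambiguity code", code)
  strsplit(unname(pair), "", fixed = TRUE)[[1]]
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine (A/G) and pyrimidine-pyrimidine (C/T)
#' exchanges; everything else is a transversion.
#'
#' @param ref,alt distinct single bases in ACGT (vectorized).
#' @return character vector, "transition" or "transversion".
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) stopf("ref/alt must be distinct ACGT bases")
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  ifelse(pair %in% c("AG", "CT"), "transition", "transversion")
}

#' Construct a manifest record for one SNP
#'
#' Extracts `flank` reference bases either side of the variant position on
#' the forward strand and records the allele pair. The reference base at
#' `pos` must equal `ref`; SNPs closer than `flank` bases to a chromosome
#' end are rejected (a truncated probe context is not assayable).
#'
#' @param reference named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param chrom chromosome name.
#' @param pos 1-based position of the variant base.
#' @param ref,alt the two alleles, distinct ACGT characters.
#' @param marker_id optional marker identifier.
#' @param flank flanking length either side (default 60).
#' @return a `manifest_record`: list with `marker_id`, `chrom`, `pos`,
#'   `left_flank`, `right_flank`, `allele_a`, `allele_b` (alphabetical).
#' @export
build_manifest <- function(reference, chrom, pos, ref, alt,
                           marker_id = NULL, flank = 60) {
  seqs <- as_chrom_strings(reference)
  if (!chrom %in% names(seqs)) stopf("chromosome '%s' not in reference", chrom)
  chrom_seq <- seqs[[chrom]]
  len <- nchar(chrom_seq)
  if (pos - flank < 1 || pos + flank > len)
    stopf("insufficient flank: pos %d needs %d bases either side on '%s' (length %d)",
          pos, flank, chrom, len)
  at <- substr(chrom_seq, pos, pos)
  if (at != toupper(ref))
    stopf("reference allele mismatch at %s:%d: genome has '%s', ref given '%s'",
          chrom, pos, at, ref)
  alleles <- sort(c(toupper(ref), toupper(alt)))
  iupac_code(alleles[1], alleles[2]) # validates the pair
  structure(list(
    marker_id = marker_id %||% sprintf("%s_%d", chrom, pos),
    chrom = chrom, pos = as.integer(pos),
    left_flank = substr(chrom_seq, pos - flank, pos - 1),
    right_flank = substr(chrom_seq, pos + 1, pos + flank),
    allele_a = alleles[1], allele_b = alleles[2]
  ), class = "manifest_record")
}

#' Render a manifest record as a probe-design sequence
#'
#' @param record a `manifest_record`, or a data frame of them (columns
#'   `left_flank`, `right_flank`, `allele_a`, `allele_b`).
#' @param rendering "iupac" (121-character sequence, ambiguity code at
#'   position 61) or "bracket" (125 characters, "...[A/G]...").
#' @return character vector of rendered sequences.
#' @export
render_manifest <- function(record, rendering = c("iupac", "bracket")) {
  rendering <- match.arg(rendering)
  df <- if (inherits(record, "manifest_record")) {
    as.data.frame(unclass(record)[c("left_flank", "right_flank",
                                    "allele_a", "allele_b")])
  } else record
  mid <- if (rendering == "iupac") {
    mapply(iupac_code, df$allele_a, df$allele_b, USE.NAMES = FALSE)
  } else {
    sprintf("[%s/%s]", df$allele_a, df$allele_b)
  }
  paste0(df$left_flank, mid, df$right_flank)
}

#' Parse a rendered manifest sequence back into flanks and alleles
#'
#' Inverse of [render_manifest()]; the rendering is auto-detected from the
#' presence of a bracket expression.
#'
#' @param sequence rendered manifest sequence(s).
#' @return data frame with `left_flank`, `right_flank`, `allele_a`,
#'   `allele_b`.
#' @export
parse_manifest_sequence <- function(sequence) {
  out <- lapply(sequence, function(s) {
    if (grepl("\\[", s)) {
      m <- regmatches(s, regexec("^([ACGTN]*)\\[([ACGT])/([ACGT])\\]([ACGTN]*)$", s))[[1]]
      if (length(m) != 5) stopf("malformed bracket manifest sequence")
      al <- sort(c(m[3], m[4]))
      data.frame(left_flank = m[2], right_flank = m[5],
                 allele_a = al[1], allele_b = al[2])
    } else {
      n <- nchar(s)
      if (n < 3 || n %% 2 == 0) stopf("iupac manifest must have odd length >= 3")
      mid <- (n + 1) / 2
      al <- iupac_alleles(substr(s, mid, mid))
      data.frame(left_flank = substr(s, 1, mid - 1),
                 right_flank = substr(s, mid + 1, n),
                 allele_a = al[1], allele_b = al[2])
    }
  })
  do.call(rbind, out)
}
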