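# Domain types and readers/writers. Coordinates at every interface are
# 1-based inclusive (the VCF/GFF3 dialect).

#' Coerce a genome reference to a named character vector of chromosomes
#' @param reference named `DNAStringSet` or named character vector.
#' @return named character vector, uppercase.
#' @export
as_chrom_strings <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference)) {
    seqs <- reference
  } else {
    stopf("reference must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("reference chromosomes must have unique names")
  toupper(seqs)
}

#' Read a genome reference from FASTA
#' @param path FASTA file.
#' @return named uppercase character vector of chromosome sequences.
#' @export
read_reference <- function(path) {
  as_chrom_strings(Biostrings::readDNAStringSet(path))
}

#' Write a genome reference to FASTA
#' @param reference named character vector or DNAStringSet.
#' @param path output FASTA path.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(as_chrom_strings(reference)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Candidate variants: VCF + design-score sidecar

.GT_MAP <- c("0/0" = "RR", "0|0" = "RR",
             "1/1" = "AA", "1|1" = "AA",
             "0/1" = "RA", "1/0" = "RA", "0|1" = "RA", "1|0" = "RA")

#' Read candidate SNPs from a VCF plus a design-score sidecar
#'
#' Keeps biallelic SNPs only; multiallelic records and indels are skipped
#' (and counted). Genotypes are collapsed to RR/AA/RA/missing — phased
#' separators are treated as unphased, and any genotype containing "." is
#' missing. `missing_rate` is recomputed from the genotype fields. Variants
#' whose id is absent from the sidecar are kept but flagged scoreless
#' (`design_score` NA), which excludes them from all selection filters.
#'
#' @param vcf_path VCF 4.x file (plain or bgzipped).
#' @param score_sidecar TSV with columns `id` and `design_score`, or a data
#'   frame of the same; NULL leaves all scores NA.
#' @return a `candidate_set`: list with `variants` (data frame: id, chrom,
#'   pos, ref, alt, missing_rate, design_score, gene_id, effect), `calls`
#'   (markers x samples character matrix over RR/AA/RA/NA) and `skipped`
#'   (count of non-biallelic-SNP records dropped).
#' @export
read_candidates <- function(vcf_path, score_sidecar = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(candidate_set(empty_variants(), calls = NULL, skipped = 0L))
  }
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  is_snp[is.na(is_snp)] <- FALSE
  skipped <- sum(!is_snp)
  if (skipped > 0)
    message(sprintf("read_candidates: skipped %d non-biallelic-SNP record(s)",
                    skipped))
  fix <- fix[is_snp, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID)

  calls <- NULL
  missing_rate <- rep(NA_real_, nrow(fix))
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
    gt <- gsub("|", "/", gt, fixed = TRUE)
    calls <- matrix(.GT_MAP[gt], nrow = nrow(gt), dimnames = list(ids, colnames(gt)))
    missing_rate <- rowMeans(is.na(calls))
  }

  scores <- read_score_sidecar(score_sidecar)
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    missing_rate = missing_rate,
    design_score = unname(scores[ids]),
    gene_id = NA_character_, effect = NA_character_,
    stringsAsFactors = FALSE
  )
  candidate_set(variants, calls = calls, skipped = as.integer(skipped))
}

#' @noRd
read_score_sidecar <- function(score_sidecar) {
  if (is.null(score_sidecar)) return(character(0))
  df <- if (is.data.frame(score_sidecar)) score_sidecar else
    read.delim(score_sidecar, stringsAsFactors = FALSE)
  if (!all(c("id", "design_score") %in% names(df)))
    stopf("score sidecar needs columns 'id' and 'design_score'")
  bad <- !is.na(df$design_score) &
    (df$design_score < 0 | df$design_score > 1)
  if (any(bad)) stopf("design scores must lie in [0,1]")
  setNames(as.numeric(df$design_score), df$id)
}

#' @noRd
empty_variants <- function() {
  data.frame(id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(),
             missing_rate = numeric(), design_score = numeric(),
             gene_id = character(), effect = character(),
             stringsAsFactors = FALSE)
}

#' Construct a candidate set
#' @param variants data frame as returned by [read_candidates()].
#' @param calls optional markers x samples call matrix.
#' @param skipped count of skipped input records.
#' @return object of class `candidate_set`.
#' @export
candidate_set <- function(variants, calls = NULL, skipped = 0L) {
  structure(list(variants = variants, calls = calls,
                 skipped = as.integer(skipped)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d variant(s), %s, %d record(s) skipped\n",
              nrow(x$variants),
              if (is.null(x$calls)) "no calls" else
                sprintf("%d sample(s)", ncol(x$calls)),
              x$skipped))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gene models

#' Construct a gene model
#'
#' Exons and CDS segments are 1-based inclusive genomic intervals. UTRs are
#' derived as the exonic sequence outside the genomic CDS span, 5' and 3'
#' assigned by strand.
#'
#' @param gene_id,chrom,strand identifiers; strand "+" or "-".
#' @param exons two-column matrix/data frame of [start, end], non-overlapping.
#' @param cds optional CDS segments, same shape; must lie within exons.
#' @return object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons`, `cds`, `utr5`, `utr3`, `span`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  exons <- as_segment_matrix(exons)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stopf("exons of '%s' overlap or are unsorted", gene_id)
  if (!is.null(cds) && nrow(as_segment_matrix(cds)) == 0) cds <- NULL
  utr5 <- utr3 <- NULL
  if (!is.null(cds)) {
    cds <- as_segment_matrix(cds)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    if (!segments_within(cds, exons))
      stopf("CDS of '%s' extends outside its exons", gene_id)
    cds_span <- c(min(cds[, 1]), max(cds[, 2]))
    left <- clip_segments(exons, upper = cds_span[1] - 1)
    right <- clip_segments(exons, lower = cds_span[2] + 1)
    if (strand == "+") { utr5 <- left; utr3 <- right }
    else { utr5 <- right; utr3 <- left }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                 span = c(min(exons[, 1]), max(exons[, 2]))),
            class = "gene_model")
}

#' @noRd
as_segment_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x))
  if (length(m) == 0) return(matrix(integer(), ncol = 2,
                                    dimnames = list(NULL, c("start", "end"))))
  if (ncol(m) != 2) stopf("segments need two columns (start, end)")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("start", "end"))
  if (any(m[, 2] < m[, 1])) stopf("segment end before start")
  m
}

#' @noRd
segments_within <- function(inner, outer) {
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, 1] <= inner[i, 1] & inner[i, 2] <= outer[, 2])
  }, logical(1)))
}

#' @noRd
clip_segments <- function(segs, lower = -Inf, upper = Inf) {
  s <- pmax(segs[, 1], lower); e <- pmin(segs[, 2], upper)
  keep <- s <= e
  if (!any(keep)) return(NULL)
  cbind(start = as.integer(s[keep]), end = as.integer(e[keep]))
}

#' Read gene models from GFF3
#'
#' One `gene_model` per mRNA feature (genes with no mRNA children are taken
#' as their own transcript when they carry exon children). Models whose CDS
#' extends outside their exons are rejected with a warning.
#'
#' @param gff3_path GFF3 file with gene/mRNA/exon/CDS features.
#' @return list of `gene_model` objects.
#' @export
read_gene_models <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  df$Parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else NA_character_

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  genes <- df[df$type == "gene", , drop = FALSE]
  # map transcript -> owning gene id (fall back to the transcript's own ID)
  gene_of <- setNames(ifelse(is.na(mrna$Parent), mrna$ID, mrna$Parent), mrna$ID)

  models <- list()
  for (tid in mrna$ID) {
    kids <- df[!is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    exons <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(exons) == 0) next
    row <- mrna[mrna$ID == tid, ][1, ]
    m <- tryCatch(
      gene_model(gene_id = unname(gene_of[tid]), chrom = as.character(row$seqnames),
                 strand = as.character(row$strand), exons = exons,
                 cds = if (nrow(cds)) cds else NULL),
      error = function(e) {
        warning(sprintf("gene model '%s' rejected: %s", tid, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(m)) { m$transcript_id <- tid; models[[tid]] <- m }
  }
  unname(models)
}

# ---------------------------------------------------------------------------
# Manifest tables

#' Write a manifest table to TSV
#'
#' @param records data frame with columns `marker_id`, `left_flank`,
#'   `right_flank`, `allele_a`, `allele_b` (a single `manifest_record` is
#'   accepted), or a list of `manifest_record`s.
#' @param path output TSV path.
#' @param rendering "iupac" or "bracket" (see [render_manifest()]).
#' @return the path, invisibly. Columns written: marker_id, sequence,
#'   allele_a, allele_b.
#' @export
write_manifest_table <- function(records, path, rendering = c("iupac", "bracket")) {
  rendering <- match.arg(rendering)
  df <- manifest_frame(records)
  if (anyDuplicated(df$marker_id))
    stopf("duplicate marker_id in manifest table")
  out <- data.frame(marker_id = df$marker_id,
                    sequence = if (nrow(df)) render_manifest(df, rendering) else character(0),
                    allele_a = df$allele_a, allele_b = df$allele_b,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
manifest_frame <- function(records) {
  if (inherits(records, "manifest_record")) records <- list(records)
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, logical(1), "manifest_record"))) {
    records <- do.call(rbind, lapply(records, function(r)
      as.data.frame(unclass(r), stringsAsFactors = FALSE)))
  }
  if (length(records) == 0 || nrow(records) == 0) {
    return(data.frame(marker_id = character(), left_flank = character(),
                      right_flank = character(), allele_a = character(),
                      allele_b = character(), stringsAsFactors = FALSE))
  }
  need <- c("marker_id", "left_flank", "right_flank", "allele_a", "allele_b")
  if (!all(need %in% names(records)))
    stopf("manifest records need columns: %s", paste(need, collapse = ", "))
  records
}

#' Read a manifest table written by [write_manifest_table()]
#' @param path TSV path.
#' @return data frame with marker_id, left_flank, right_flank, allele_a,
#'   allele_b columns (rendering auto-detected).
#' @export
read_manifest_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(marker_id = character(), left_flank = character(),
                      right_flank = character(), allele_a = character(),
                      allele_b = character(), stringsAsFactors = FALSE))
  }
  parsed <- parse_manifest_sequence(df$sequence)
  cbind(data.frame(marker_id = df$marker_id, stringsAsFactors = FALSE), parsed)
}

# ---------------------------------------------------------------------------
# Genotype matrices and anchor maps

#' Read a genotype call matrix from TSV
#'
#' Layout: rows are markers, columns are samples, first column `marker_id`;
#' calls are AA/AB/BB with NA (or empty) for missing.
#'
#' @param path TSV path.
#' @return markers x samples character matrix with dimnames.
#' @export
read_genotype_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  check_call_matrix(m)
  m
}

#' Write a genotype call matrix to TSV
#' @param calls markers x samples character matrix (AA/AB/BB/NA).
#' @param path output path.
#' @export
write_genotype_matrix <- function(calls, path) {
  check_call_matrix(calls)
  df <- data.frame(marker_id = rownames(calls), calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
check_call_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("genotype matrix needs marker rownames and sample colnames")
  bad <- !(m %in% c("AA", "AB", "BB") | is.na(m))
  if (any(bad)) stopf("genotype calls must be AA/AB/BB/NA; found '%s'",
                      m[which(bad)[1]])
  invisible(m)
}

#' Read an anchor map (marker genetic + physical positions) from TSV
#'
#' Expected columns: chrom, marker_id, genetic_pos (cM), physical_pos (bp);
#' an optional phys_chrom column records the chromosome of the physical
#' placement when it differs from the linkage group.
#'
#' @param path TSV path.
#' @return data frame sorted by chrom then genetic position.
#' @export
read_anchor_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "marker_id", "genetic_pos", "physical_pos")
  if (!all(need %in% names(df)))
    stopf("anchor map needs columns: %s", paste(need, collapse = ", "))
  if (any(df$genetic_pos < 0)) stopf("genetic positions must be non-negative")
  df[order(df$chrom, df$genetic_pos, df$physical_pos), , drop = FALSE]
}
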