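# Single-effect SNP classifier over gene models, in the style of
# single-annotation SnpEff output: every variant receives exactly one label
# from a fixed 17-category vocabulary, chosen by a severity order when a
# position supports several (e.g. a coding base inside the exonic splice
# region reports its coding consequence).

#' The 17 effect categories, most severe first
#' @export
EFFECT_CLASSES <- c(
  "splice_site_acceptor", "splice_site_donor", "stop_gained", "stop_lost",
  "start_lost", "non_synonymous_start", "non_synonymous_coding",
  "synonymous_stop", "start_gained", "synonymous_coding",
  "splice_site_region", "utr5", "utr3", "intron", "upstream", "downstream",
  "intergenic")

#' Effect-annotation configuration
#'
#' @param upstream_window,downstream_window bp beyond the transcript span
#'   still annotated as upstream/downstream (default 5000, the conventional
#'   SnpEff window).
#' @param donor_acceptor_intron_bases intronic bases at each exon junction
#'   called splice_site_donor/acceptor (default 2, the canonical GT/AG
#'   dinucleotides).
#' @param splice_region_intron_bases intronic distance range (from the exon
#'   boundary) annotated splice_site_region (default 3:8).
#' @param splice_region_exon_bases exonic distance range from an
#'   intron-adjacent boundary annotated splice_site_region (default 1:3).
#' @return list of class `effect_config`.
#' @export
effect_config <- function(upstream_window = 5000, downstream_window = 5000,
                          donor_acceptor_intron_bases = 2,
                          splice_region_intron_bases = 3:8,
                          splice_region_exon_bases = 1:3) {
  if (upstream_window <= 0 || downstream_window <= 0)
    stopf("windows must be positive")
  if (min(splice_region_intron_bases) <= donor_acceptor_intron_bases &&
      length(splice_region_intron_bases) > 0 &&
      min(splice_region_intron_bases) <= 0)
    stopf("invalid splice region range")
  structure(list(upstream_window = upstream_window,
                 downstream_window = downstream_window,
                 donor_acceptor_intron_bases = donor_acceptor_intron_bases,
                 splice_region_intron_bases = splice_region_intron_bases,
                 splice_region_exon_bases = splice_region_exon_bases),
            class = "effect_config")
}

#' Translate a codon under the standard genetic code
#' @param codon 3-base ACGT string (vectorized); ambiguous bases error.
#' @return one-letter amino acid, "*" for stop.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3 | grepl("[^ACGT]", codon)))
    stopf("codon must be an unambiguous 3-base ACGT string")
  unname(Biostrings::GENETIC_CODE[codon])
}

# Precomputed per-gene context shared across many positions.
#' @noRd
gene_context <- function(model, reference) {
  seqs <- as_chrom_strings(reference)
  chrom_seq <- seqs[[model$chrom]]
  ctx <- list(model = model, chrom_seq = chrom_seq)
  if (!is.null(model$cds)) {
    segs <- model$cds
    pieces <- substring(chrom_seq, segs[, 1], segs[, 2])
    if (model$strand == "+") {
      ctx$cds_seq <- paste(pieces, collapse = "")
    } else {
      ctx$cds_seq <- paste(rev(vapply(pieces, revcomp, character(1))),
                           collapse = "")
    }
  }
  if (!is.null(model$utr5)) {
    ex <- model$exons
    pieces <- substring(chrom_seq, ex[, 1], ex[, 2])
    tx <- paste(pieces, collapse = "")
    if (model$strand == "-") tx <- revcomp(tx)
    ctx$tx_seq <- tx
  }
  ctx
}

# CDS coordinate (1-based, in translation order) of a genomic position; NA
# when the position is not coding.
#' @noRd
cds_coord <- function(model, pos) {
  segs <- model$cds
  hit <- which(segs[, 1] <= pos & pos <= segs[, 2])
  if (length(hit) == 0) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1) sum(segs[seq_len(hit - 1), 2] - segs[seq_len(hit - 1), 1] + 1) else 0
    before + (pos - segs[hit, 1] + 1)
  } else {
    n <- nrow(segs)
    after <- if (hit < n) sum(segs[seq(hit + 1, n), 2] - segs[seq(hit + 1, n), 1] + 1) else 0
    after + (segs[hit, 2] - pos + 1)
  }
}

# Transcript coordinate (1-based, 5'->3') of a genomic position; NA outside
# exons.
#' @noRd
tx_coord <- function(model, pos) {
  ex <- model$exons
  hit <- which(ex[, 1] <= pos & pos <= ex[, 2])
  if (length(hit) == 0) return(NA_integer_)
  lens <- ex[, 2] - ex[, 1] + 1
  if (model$strand == "+") {
    (if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0) + (pos - ex[hit, 1] + 1)
  } else {
    n <- nrow(ex)
    (if (hit < n) sum(lens[seq(hit + 1, n)]) else 0) + (ex[hit, 2] - pos + 1)
  }
}

# Effect of one SNP against one gene; NA_character_ when the gene (and its
# windows) does not cover the position. `ctx` from gene_context().
#' @noRd
gene_effect <- function(ctx, pos, ref, alt, config) {
  model <- ctx$model
  span <- model$span
  strand <- model$strand

  if (pos < span[1] || pos > span[2]) {
    d <- if (pos < span[1]) span[1] - pos else pos - span[2]
    before <- pos < span[1] # on the lower-coordinate side
    lab <- if ((before && strand == "+") || (!before && strand == "-")) {
      if (d <= config$upstream_window) "upstream" else NA_character_
    } else {
      if (d <= config$downstream_window) "downstream" else NA_character_
    }
    return(lab)
  }

  ex <- model$exons
  in_exon <- any(ex[, 1] <= pos & pos <= ex[, 2])

  if (!in_exon) {
    # intron: distances to the flanking exon boundaries
    left_end <- max(ex[ex[, 2] < pos, 2])
    right_start <- min(ex[ex[, 1] > pos, 1])
    d_left <- pos - left_end; d_right <- right_start - pos
    da <- config$donor_acceptor_intron_bases
    sr <- config$splice_region_intron_bases
    if (strand == "+") {
      if (d_left <= da) return("splice_site_donor")
      if (d_right <= da) return("splice_site_acceptor")
    } else {
      if (d_left <= da) return("splice_site_acceptor")
      if (d_right <= da) return("splice_site_donor")
    }
    if (d_left %in% sr || d_right %in% sr) return("splice_site_region")
    return("intron")
  }

  labels <- character(0)

  # exonic splice region: near a boundary that adjoins an intron
  if (nrow(ex) > 1) {
    sre <- config$splice_region_exon_bases
    i <- which(ex[, 1] <= pos & pos <= ex[, 2])[1]
    d_start <- pos - ex[i, 1] + 1 # 1 = boundary base
    d_end <- ex[i, 2] - pos + 1
    near_internal <- (i > 1 && d_start %in% sre) ||
      (i < nrow(ex) && d_end %in% sre)
    if (near_internal) labels <- c(labels, "splice_site_region")
  }

  if (is.null(model$cds)) {
    # non-coding transcript: no dedicated category in the vocabulary; only
    # an exonic splice-region call can be made here
    if (length(labels)) return(most_severe(labels))
    return("intron")
  }

  cpos <- cds_coord(model, pos)
  base <- if (strand == "+") ref else comp_base(ref)
  alt_base <- if (strand == "+") alt else comp_base(alt)

  if (!is.na(cpos)) {
    cds_seq <- ctx$cds_seq
    n_codon <- nchar(cds_seq) %/% 3
    ci <- (cpos - 1) %/% 3 + 1
    off <- (cpos - 1) %% 3
    ref_codon <- substr(cds_seq, (ci - 1) * 3 + 1, ci * 3)
    if (substr(ref_codon, off + 1, off + 1) != base)
      stopf("reference allele mismatch at %s:%d in CDS of %s",
            model$chrom, pos, model$gene_id)
    alt_codon <- ref_codon
    substr(alt_codon, off + 1, off + 1) <- alt_base
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alt_codon)
    lab <- if (aa_ref == "*") {
      if (aa_alt == "*") "synonymous_stop" else "stop_lost"
    } else if (aa_alt == "*") {
      "stop_gained"
    } else if (ci == 1 && ref_codon == "ATG") {
      "start_lost" # any substitution destroys the canonical start
    } else if (ci == 1 && aa_ref != aa_alt) {
      "non_synonymous_start" # non-canonical start codon altered
    } else if (aa_ref != aa_alt) {
      "non_synonymous_coding"
    } else {
      "synonymous_coding"
    }
    labels <- c(labels, lab)
    return(most_severe(labels))
  }

  # exonic, non-coding side: UTR by strand
  cds_span <- c(min(model$cds[, 1]), max(model$cds[, 2]))
  before_cds <- pos < cds_span[1]
  utr <- if ((before_cds && strand == "+") || (!before_cds && strand == "-"))
    "utr5" else "utr3"
  labels <- c(labels, utr)
  if (utr == "utr5" && creates_start(ctx, pos, alt_base)) {
    labels <- c(labels, "start_gained")
  }
  most_severe(labels)
}

# Frame-agnostic scan: does substituting the (transcript-strand) alt base
# create an ATG in the mRNA that was not there before?
#' @noRd
creates_start <- function(ctx, pos, alt_base_tx) {
  t <- tx_coord(ctx$model, pos)
  tx <- ctx$tx_seq
  mut <- tx
  substr(mut, t, t) <- alt_base_tx
  for (s in (t - 2):t) {
    if (s < 1 || s + 2 > nchar(tx)) next
    if (substr(mut, s, s + 2) == "ATG" && substr(tx, s, s + 2) != "ATG")
      return(TRUE)
  }
  FALSE
}

#' @noRd
most_severe <- function(labels) {
  labels[which.min(match(labels, EFFECT_CLASSES))]
}

#' Annotate one SNP with its single effect class
#'
#' When several genes cover the position, the gene giving the most severe
#' effect wins; ties are broken by lower gene start, then gene_id. A SNP
#' overlapping no feature and no up/downstream window is intergenic.
#'
#' @param variant list or one-row data frame with chrom, pos, ref, alt.
#' @param gene_models list of [gene_model()] objects.
#' @param reference genome reference (named character vector or
#'   DNAStringSet); needed for codon context.
#' @param config an [effect_config()].
#' @return list with `effect` (one of [EFFECT_CLASSES]) and `gene_id` (NA
#'   for intergenic).
#' @export
annotate_effect <- function(variant, gene_models, reference,
                            config = effect_config()) {
  res <- annotate_effects(as.data.frame(variant[c("chrom", "pos", "ref", "alt")],
                                        stringsAsFactors = FALSE),
                          gene_models, reference, config)
  list(effect = res$effect[1], gene_id = res$gene_id[1])
}

#' Annotate a table of SNPs with effect classes
#'
#' Vectorized driver for [annotate_effect()]; per-gene context (CDS and
#' transcript sequences) is computed once and reused.
#'
#' @param variants data frame with chrom, pos, ref, alt (a `candidate_set`
#'   is accepted).
#' @inheritParams annotate_effect
#' @return the variants data frame with `effect` and `gene_id` columns
#'   filled in.
#' @export
annotate_effects <- function(variants, gene_models, reference,
                             config = effect_config()) {
  df <- variants_frame(variants)
  seqs <- as_chrom_strings(reference)
  ctxs <- lapply(gene_models, gene_context, reference = seqs)
  meta <- data.frame(
    chrom = vapply(gene_models, `[[`, character(1), "chrom"),
    start = vapply(gene_models, function(m) m$span[1], numeric(1)),
    end = vapply(gene_models, function(m) m$span[2], numeric(1)),
    gene_id = vapply(gene_models, `[[`, character(1), "gene_id"),
    stringsAsFactors = FALSE)
  win <- max(config$upstream_window, config$downstream_window)

  eff <- character(nrow(df)); gid <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    pos <- df$pos[i]
    near <- which(meta$chrom == df$chrom[i] &
                    meta$start - win <= pos & pos <= meta$end + win)
    best_lab <- "intergenic"; best_gene <- NA_character_
    best_rank <- match("intergenic", EFFECT_CLASSES) + 1L
    if (length(near)) {
      ord <- near[order(meta$start[near], meta$gene_id[near])]
      for (j in ord) {
        lab <- gene_effect(ctxs[[j]], pos, df$ref[i], df$alt[i], config)
        if (is.na(lab)) next
        r <- match(lab, EFFECT_CLASSES)
        if (r < best_rank) { # strict: ties keep the earlier (lower-start) gene
          best_rank <- r; best_lab <- lab; best_gene <- meta$gene_id[j]
        }
      }
    }
    eff[i] <- best_lab; gid[i] <- best_gene
  }
  df$effect <- eff
  df$gene_id <- gid
  df
}

#' Effect spectrum: percentage of variants per category
#'
#' @param variants annotated variants data frame (column `effect`), or a
#'   character vector of labels.
#' @param digits decimals for the percentages (default 2, so a full table
#'   sums to 100 within rounding).
#' @return data frame with `effect` and `percent`, sorted by descending
#'   percentage.
#' @export
effect_spectrum <- function(variants, digits = 2) {
  labels <- if (is.character(variants)) variants else
    variants_frame(variants)$effect
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stopf("no annotated variants")
  bad <- setdiff(unique(labels), EFFECT_CLASSES)
  if (length(bad)) stopf("unknown effect label(s): %s", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = EFFECT_CLASSES))
  out <- data.frame(effect = names(tab),
                    percent = round_half_up(as.numeric(tab) / length(labels) * 100,
                                            digits),
                    stringsAsFactors = FALSE)
  out <- out[out$percent > 0 | tab > 0, , drop = FALSE]
  out[order(-out$percent, out$effect), , drop = FALSE]
}
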