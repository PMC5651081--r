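# Post-genotyping QC metrics.

#' Per-sample call agreement between two genotype matrices
#'
#' The sample and marker universes are intersected. For each sample,
#' marker pairs with a missing call on either side are excluded; a
#' heterozygous call against a homozygous one counts as disagreement.
#' Samples with zero comparable markers are flagged and excluded from the
#' summary statistics.
#'
#' @param calls_a,calls_b markers x samples character matrices
#'   (AA/AB/BB/NA).
#' @param stratum_filter optional character vector of marker ids: when
#'   given, only those markers are compared (use this to compute e.g.
#'   legacy vs. new-marker strata separately).
#' @param stratum label stored on the report.
#' @param exclude_het if TRUE, marker pairs where either call is
#'   heterozygous are excluded from the denominator instead of counting as
#'   disagreements.
#' @return list of class `agreement_report`: `per_sample` (data frame
#'   sample_id, compared, agreeing, agreement_pct), `summary` (mean,
#'   median, quartiles, min, max over informative samples), `flagged`
#'   (samples with nothing to compare), `stratum`.
#' @export
agreement_rate <- function(calls_a, calls_b, stratum_filter = NULL,
                           stratum = "all", exclude_het = FALSE) {
  samples <- intersect(colnames(calls_a), colnames(calls_b))
  markers <- intersect(rownames(calls_a), rownames(calls_b))
  if (!is.null(stratum_filter)) markers <- intersect(markers, stratum_filter)
  if (length(samples) == 0 || length(markers) == 0)
    stopf("no shared samples/markers to compare")
  a <- calls_a[markers, samples, drop = FALSE]
  b <- calls_b[markers, samples, drop = FALSE]
  usable <- !is.na(a) & !is.na(b)
  if (exclude_het) usable <- usable & a != "AB" & b != "AB"
  agree <- usable & a == b
  compared <- colSums(usable)
  agreeing <- colSums(agree, na.rm = TRUE)
  pct <- ifelse(compared > 0, agreeing / compared * 100, NA_real_)
  per_sample <- data.frame(sample_id = samples, compared = compared,
                           agreeing = agreeing, agreement_pct = pct,
                           row.names = NULL, stringsAsFactors = FALSE)
  ok <- per_sample$compared > 0
  vals <- per_sample$agreement_pct[ok]
  structure(list(
    per_sample = per_sample,
    summary = c(mean = mean(vals), median = median(vals),
                q1 = unname(quantile(vals, 0.25)),
                q3 = unname(quantile(vals, 0.75)),
                min = min(vals), max = max(vals)),
    flagged = per_sample$sample_id[!ok],
    stratum = stratum), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement [%s]: %d sample(s), mean %.1f%%, median %.1f%% (range %.1f-%.1f)\n",
              x$stratum, nrow(x$per_sample), x$summary["mean"],
              x$summary["median"], x$summary["min"], x$summary["max"]))
  if (length(x$flagged))
    cat("flagged (nothing to compare):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Transition/transversion ratio of a variant set
#'
#' @param variants data frame with ref/alt columns (a `candidate_set` is
#'   accepted), or `ref` and `alt` given separately.
#' @param alt alternate alleles when `variants` is the ref vector.
#' @return number of transitions divided by number of transversions.
#' @export
tstv_ratio <- function(variants, alt = NULL) {
  if (is.null(alt)) {
    df <- variants_frame(variants)
    ref <- df$ref; alt <- df$alt
  } else ref <- variants
  cls <- classify_substitution(ref, alt)
  ts <- sum(cls == "transition"); tv <- sum(cls == "transversion")
  if (tv == 0)
    stopf("Ts/Tv undefined: %d transition(s) and no transversions", ts)
  ts / tv
}

#' Percentage of polymorphic markers in a call matrix
#'
#' A marker is polymorphic when at least two distinct non-missing call
#' states are observed across samples.
#'
#' @param calls markers x samples character matrix (AA/AB/BB/NA).
#' @param digits decimals for the percentage (default 1).
#' @return percent of polymorphic markers.
#' @export
polymorphism_rate <- function(calls, digits = 1) {
  if (length(calls) == 0 || nrow(calls) == 0) stopf("empty genotype matrix")
  n_states <- apply(calls, 1, function(r) length(unique(r[!is.na(r)])))
  round_half_up(mean(n_states >= 2) * 100, digits)
}

#' Assay conversion statistics
#'
#' @param designed markers submitted for fabrication.
#' @param working markers yielding a working assay.
#' @param scorable working assays that could be scored.
#' @return list of class `conversion_stats`: counts plus `conversion_pct`
#'   (working/designed) and `scorable_pct` (scorable/working), rounded to
#'   1 decimal. With zero working assays `scorable_pct` is reported as 0
#'   and flagged `degenerate`.
#' @export
conversion_stats <- function(designed, working, scorable = working) {
  if (!(scorable <= working && working <= designed))
    stopf("expected scorable <= working <= designed, got %s/%s/%s",
          scorable, working, designed)
  degenerate <- working == 0
  structure(list(
    designed = designed, working = working, scorable = scorable,
    conversion_pct = round_half_up(working / designed * 100, 1),
    scorable_pct = if (degenerate) 0 else
      round_half_up(scorable / working * 100, 1),
    degenerate = degenerate), class = "conversion_stats")
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat(sprintf("conversion: %d designed -> %d working (%.1f%%) -> %d scorable (%.1f%%)%s\n",
              x$designed, x$working, x$conversion_pct, x$scorable,
              x$scorable_pct, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Genetic vs. physical order concordance
#'
#' Per chromosome (linkage group): Spearman rank correlation between
#' genetic and physical positions, the number of adjacent marker pairs
#' transposed relative to physical order when sorted by genetic position,
#' and a list of unlinked markers — markers whose physical placement is on
#' another chromosome, or further than `max_deviation` bp from the
#' physical position interpolated from their genetic neighbours
#' (leave-one-out linear interpolation).
#'
#' @param anchor_map data frame with chrom, marker_id, genetic_pos,
#'   physical_pos, and optionally phys_chrom (defaults to chrom).
#' @param max_deviation unlinked-marker distance threshold in bp
#'   (default Inf: only cross-chromosome placements are flagged).
#' @return list of class `concordance_report`: `per_chrom` (data frame
#'   chrom, n, rho, adjacent_inversions, n_unlinked, flagged), `unlinked`
#'   (marker data frame).
#' @export
order_concordance <- function(anchor_map, max_deviation = Inf) {
  df <- anchor_map
  if (!"phys_chrom" %in% names(df)) df$phys_chrom <- df$chrom
  rows <- list(); unlinked <- list()
  for (ch in unique(df$chrom)) {
    g <- df[df$chrom == ch, , drop = FALSE]
    g <- g[order(g$genetic_pos, g$physical_pos), , drop = FALSE]
    off_chrom <- g$phys_chrom != ch
    far <- rep(FALSE, nrow(g))
    # greedy outlier peeling: flag the worst leave-one-out deviation, drop
    # it, and re-interpolate, so one displaced marker does not drag its
    # neighbours' expectations with it
    if (is.finite(max_deviation)) {
      repeat {
        same <- which(!off_chrom & !far)
        if (length(same) < 3) break
        dev <- vapply(same, function(i) {
          others <- setdiff(same, i)
          pred <- approx(g$genetic_pos[others], g$physical_pos[others],
                         xout = g$genetic_pos[i], rule = 2, ties = mean)$y
          abs(g$physical_pos[i] - pred)
        }, numeric(1))
        worst <- which.max(dev)
        if (dev[worst] <= max_deviation) break
        far[same[worst]] <- TRUE
      }
    }
    bad <- off_chrom | far
    unlinked[[ch]] <- g[bad, , drop = FALSE]
    gg <- g[!bad, , drop = FALSE]
    n <- nrow(gg)
    if (n < 3) {
      rows[[ch]] <- data.frame(chrom = ch, n = n, rho = NA_real_,
                               adjacent_inversions = NA_integer_,
                               n_unlinked = sum(bad), flagged = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    rho <- suppressWarnings(
      cor(gg$genetic_pos, gg$physical_pos, method = "spearman"))
    inversions <- sum(diff(gg$physical_pos) < 0)
    rows[[ch]] <- data.frame(chrom = ch, n = n, rho = rho,
                             adjacent_inversions = inversions,
                             n_unlinked = sum(bad), flagged = FALSE,
                             stringsAsFactors = FALSE)
  }
  structure(list(per_chrom = do.call(rbind, c(rows, make.row.names = FALSE)),
                 unlinked = do.call(rbind, c(unlinked, make.row.names = FALSE))),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  print(x$per_chrom, row.names = FALSE)
  invisible(x)
}
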