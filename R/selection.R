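# Two-stage marker selection.
#
# Stage A maximises gene coverage: candidates passing lenient thresholds
# (missing <= 20%, design score >= 0.6, boundaries inclusive) are deduplicated
# to one SNP per gene. Stage B then skews marker density toward the distal,
# recombining chromosome arms: each chromosome is partitioned into five
# physical zones, the pericentromeric zone receives no stage-B quota, and the
# remaining budget is split across the four distal zones in proportion to
# their genetic-map length (cM), integerised by largest remainder. Stage-B
# thresholds are stricter (missing < 5%, score > 0.8, boundaries exclusive as
# printed) with per-zone overrides for arms where the genetic:physical ratio
# is extreme, and at most two SNPs per gene counted across both stages.

.ZONE_LEVELS <- c("short_high", "short_low", "pericentromeric",
                  "long_low", "long_high")
.DISTAL_ZONES <- c("short_high", "short_low", "long_low", "long_high")

#' Build a five-zone chromosome partition
#'
#' @param chrom chromosome name.
#' @param breaks numeric vector of 6 physical breakpoints in bp,
#'   `c(0, b1, b2, b3, b4, chrom_length)`; zone i spans `[breaks[i],
#'   breaks[i+1])` (the last zone is closed at the chromosome end).
#' @param genetic_spans numeric vector of 5 genetic-map spans in cM, in zone
#'   order short_high, short_low, pericentromeric, long_low, long_high.
#' @return data frame (class `chromosome_partition` rows) with columns
#'   chrom, zone, start_bp, end_bp, cM.
#' @export
chromosome_partition <- function(chrom, breaks, genetic_spans) {
  if (length(breaks) != 6 || is.unsorted(breaks, strictly = TRUE))
    stopf("breaks must be 6 strictly increasing physical positions")
  if (length(genetic_spans) != 5 || any(genetic_spans < 0))
    stopf("genetic_spans must be 5 non-negative cM values")
  data.frame(chrom = chrom, zone = .ZONE_LEVELS,
             start_bp = breaks[-6], end_bp = breaks[-1],
             cM = as.numeric(genetic_spans), stringsAsFactors = FALSE)
}

#' Read a partition table (chrom, zone, start_bp, end_bp, cM) from TSV
#' @param path TSV path.
#' @return partition data frame covering one or more chromosomes.
#' @export
read_partition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "zone", "start_bp", "end_bp", "cM")
  if (!all(need %in% names(df)))
    stopf("partition table needs columns: %s", paste(need, collapse = ", "))
  for (ch in unique(df$chrom)) validate_partition(df[df$chrom == ch, ])
  df
}

#' @noRd
validate_partition <- function(part) {
  part <- part[match(.ZONE_LEVELS, part$zone), , drop = FALSE]
  if (any(is.na(part$zone)) || nrow(part) != 5)
    stopf("partition must have exactly the five zones %s",
          paste(.ZONE_LEVELS, collapse = ", "))
  if (any(part$end_bp[-5] != part$start_bp[-1]))
    stopf("partition zones must be contiguous")
  if (any(part$end_bp <= part$start_bp)) stopf("empty partition zone")
  if (any(part$cM < 0)) stopf("negative genetic span")
  part
}

#' Threshold filter on missing rate and design score
#'
#' @param candidates candidate variants data frame (or `candidate_set`).
#' @param max_missing,min_score thresholds on `missing_rate` and
#'   `design_score`.
#' @param inclusive if TRUE retain `missing_rate <= max_missing` and
#'   `design_score >= min_score`; if FALSE use strict `<` / `>`.
#'   Records with no design score are always dropped.
#' @return the retained subset of the variants data frame.
#' @export
filter_candidates <- function(candidates, max_missing, min_score,
                              inclusive = TRUE) {
  df <- variants_frame(candidates)
  keep <- if (inclusive) {
    df$missing_rate <= max_missing & df$design_score >= min_score
  } else {
    df$missing_rate < max_missing & df$design_score > min_score
  }
  keep[is.na(keep)] <- FALSE
  df[keep, , drop = FALSE]
}

#' @noRd
variants_frame <- function(candidates) {
  if (inherits(candidates, "candidate_set")) candidates$variants else candidates
}

#' Keep at most `cap` candidates per gene
#'
#' Within a gene, survivors are the top `cap` by design score (descending),
#' then missing rate (ascending), then position (ascending). Candidates with
#' no gene association form singleton groups and always survive.
#'
#' @param candidates variants data frame (needs gene_id, design_score,
#'   missing_rate, pos).
#' @param cap maximum SNPs per gene, >= 1.
#' @return the retained subset, in selection-rank order within the original
#'   row order.
#' @export
dedupe_per_gene <- function(candidates, cap = 1) {
  if (cap < 1) stopf("per-gene cap must be >= 1")
  df <- variants_frame(candidates)
  if (nrow(df) == 0) return(df)
  ord <- selection_order(df)
  ranked <- df[ord, , drop = FALSE]
  has_gene <- !is.na(ranked$gene_id)
  nth <- integer(nrow(ranked))
  nth[has_gene] <- stats::ave(seq_len(sum(has_gene)),
                              ranked$gene_id[has_gene], FUN = seq_along)
  keep <- !has_gene | nth <= cap
  kept <- ranked[keep, , drop = FALSE]
  kept[order(match(kept$id, df$id)), , drop = FALSE]
}

# Canonical ranking used everywhere a subset is taken: design score
# descending, missing rate ascending, position ascending, id as final tie-break
# so selection is fully deterministic.
#' @noRd
selection_order <- function(df) {
  order(-df$design_score, df$missing_rate, df$pos, df$id)
}

#' Zone of a physical position
#'
#' Zones are half-open `[start_bp, end_bp)`; the final zone is closed at the
#' chromosome end.
#'
#' @param partition partition rows for one chromosome.
#' @param physical_pos position(s) in bp.
#' @return character vector of zone labels.
#' @export
assign_zone <- function(partition, physical_pos) {
  part <- validate_partition(partition)
  lo <- part$start_bp[1]; hi <- part$end_bp[5]
  if (any(physical_pos < lo | physical_pos > hi))
    stopf("position outside chromosome [%s, %s]", lo, hi)
  idx <- findInterval(physical_pos, part$start_bp)
  idx[physical_pos == hi] <- 5L
  part$zone[idx]
}

#' Apportion a stage-B budget across zones by genetic-map length
#'
#' The pericentromeric zone receives quota 0. The four distal zones receive
#' quotas proportional to their genetic span (cM), integerised by the
#' largest-remainder method; remainder ties are broken in distal-zone order
#' (short_high, short_low, long_low, long_high). Quotas always sum to the
#' budget and each lies within 1 of its exact rational share.
#'
#' @param partition partition rows for one chromosome.
#' @param budget non-negative integer number of SNPs to allocate.
#' @return named integer vector over the five zones, in zone order.
#' @export
allocate_quota <- function(partition, budget) {
  part <- validate_partition(partition)
  if (budget < 0) stopf("budget must be non-negative")
  spans <- setNames(part$cM, part$zone)
  spans["pericentromeric"] <- 0
  q <- largest_remainder(spans[.DISTAL_ZONES], budget)
  out <- setNames(integer(5), .ZONE_LEVELS)
  out[names(q)] <- q
  out
}

#' @noRd
largest_remainder <- function(weights, total) {
  if (total == 0) return(setNames(integer(length(weights)), names(weights)))
  s <- sum(weights)
  if (s <= 0) stopf("cannot apportion %d among all-zero weights", total)
  exact <- weights / s * total
  base <- floor(exact)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    # ties on the remainder fall back to listed order (order() is stable)
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(weights))
}

#' Stage-A selection: gene-coverage set
#'
#' Applies the lenient inclusive thresholds and keeps one SNP per gene.
#'
#' @param candidates candidate variants (data frame or `candidate_set`).
#' @param config a [selection_config()].
#' @return variants data frame of stage-A picks.
#' @export
select_stage_a <- function(candidates, config = selection_config()) {
  a <- config$stage_a
  passed <- filter_candidates(candidates, a$max_missing, a$min_score,
                              inclusive = a$inclusive)
  dedupe_per_gene(passed, a$per_gene_cap)
}

#' Selection configuration
#'
#' Defaults follow the published design: stage A `missing <= 0.20`,
#' `score >= 0.6`, one SNP per gene; stage B `missing < 0.05`,
#' `score > 0.8`, two SNPs per gene counted across both stages; thresholds
#' relaxed to stage-A levels (still strict inequalities) for the short arm
#' of chromosome 5H, where the genetic:physical map ratio is extreme.
#'
#' @param stage_a,stage_b lists with `max_missing`, `min_score`,
#'   `per_gene_cap`, `inclusive`.
#' @param overrides data frame (chrom, zone, max_missing, min_score) of
#'   per-zone stage-B threshold overrides; NULL for none.
#' @param stage_b_budget named integer vector of per-chromosome stage-B
#'   budgets (names are chromosome names), or a single number applied to
#'   every chromosome.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(
    stage_a = list(max_missing = 0.20, min_score = 0.6, per_gene_cap = 1,
                   inclusive = TRUE),
    stage_b = list(max_missing = 0.05, min_score = 0.8, per_gene_cap = 2,
                   inclusive = FALSE),
    overrides = data.frame(chrom = "5H", zone = "short_high",
                           max_missing = 0.20, min_score = 0.6,
                           stringsAsFactors = FALSE),
    stage_b_budget = 100) {
  structure(list(stage_a = stage_a, stage_b = stage_b,
                 overrides = overrides, stage_b_budget = stage_b_budget),
            class = "selection_config")
}

#' Stage-B selection: recombination-stratified distal enrichment
#'
#' Per chromosome, the stage-B budget is apportioned across the four distal
#' zones by [allocate_quota()]. Within each zone, candidates passing the
#' stage-B thresholds (or that zone's override thresholds) and not already
#' picked in stage A are ranked by design score (desc), missing rate (asc),
#' position (asc) and taken up to quota, never letting any gene exceed
#' `stage_b$per_gene_cap` SNPs counted across stage A and stage B together.
#' Zones that run out of qualifying candidates return their unused quota,
#' which is redistributed by re-running largest-remainder over the
#' chromosome's remaining distal zones; shortfall that no zone can absorb is
#' reported, not filled.
#'
#' @param candidates candidate variants (data frame or `candidate_set`).
#' @param partitions partition data frame covering every chromosome that has
#'   candidates (see [chromosome_partition()]).
#' @param config a [selection_config()].
#' @param stage_a_selection variants data frame of stage-A picks (used both
#'   to exclude them and to count them against the per-gene cap); NULL for
#'   none.
#' @return list of class `stage_b_selection`: `selected` (variants data
#'   frame with a `zone` column), `quotas` (per chrom x zone), `shortfall`
#'   (named per-chromosome unfilled quota).
#' @export
select_stage_b <- function(candidates, partitions, config = selection_config(),
                           stage_a_selection = NULL) {
  df <- variants_frame(candidates)
  b <- config$stage_b
  chroms <- unique(df$chrom)
  missing_part <- setdiff(chroms, unique(partitions$chrom))
  if (length(missing_part))
    stopf("no partition for chromosome(s): %s", paste(missing_part, collapse = ", "))

  budgets <- config$stage_b_budget
  if (is.null(names(budgets)))
    budgets <- setNames(rep(budgets[1], length(chroms)), chroms)

  gene_used <- integer(0)
  if (!is.null(stage_a_selection) && nrow(stage_a_selection) > 0) {
    tab <- table(stage_a_selection$gene_id[!is.na(stage_a_selection$gene_id)])
    gene_used <- setNames(as.integer(tab), names(tab))
    df <- df[!(df$id %in% stage_a_selection$id), , drop = FALSE]
  }
  pool <- df

  selected <- list(); quota_rows <- list(); shortfall <- setNames(numeric(0), NULL)
  for (ch in chroms) {
    part <- validate_partition(partitions[partitions$chrom == ch, ])
    budget <- budgets[[ch]] %||% 0
    cands <- pool[pool$chrom == ch, , drop = FALSE]
    cands$zone <- assign_zone(part, cands$pos)

    # per-zone eligibility under base or override thresholds
    eligible <- split_zones(lapply(.DISTAL_ZONES, function(z) {
      th <- zone_thresholds(config, ch, z)
      zc <- cands[cands$zone == z, , drop = FALSE]
      zc <- filter_candidates(zc, th$max_missing, th$min_score,
                              inclusive = b$inclusive)
      zc[selection_order(zc), , drop = FALSE]
    }))

    quotas <- allocate_quota(part, budget)
    taken <- setNames(vector("list", 4), .DISTAL_ZONES)
    remaining <- quotas[.DISTAL_ZONES]
    spans <- setNames(part$cM, part$zone)

    repeat {
      for (z in .DISTAL_ZONES) {
        need <- remaining[[z]]
        if (need <= 0 || nrow(eligible[[z]]) == 0) next
        got <- take_with_gene_cap(eligible[[z]], need, gene_used,
                                  b$per_gene_cap)
        taken[[z]] <- rbind(taken[[z]], got$taken)
        eligible[[z]] <- got$rest
        gene_used <- got$gene_used
        remaining[[z]] <- remaining[[z]] - nrow(got$taken)
      }
      deficit <- sum(remaining)
      supply <- vapply(eligible, nrow, integer(1)) > 0
      if (deficit == 0 || !any(supply)) break
      # return unfilled quota from dry zones and re-apportion over zones
      # that still have qualifying candidates; each pass either selects a
      # SNP or exhausts a zone, so the loop terminates
      w <- spans[.DISTAL_ZONES][supply]
      if (sum(w) <= 0) w[] <- 1
      redo <- largest_remainder(w, deficit)
      remaining[] <- 0L
      remaining[names(redo)] <- redo
    }

    sel <- do.call(rbind, taken[!vapply(taken, is.null, logical(1))])
    selected[[ch]] <- sel
    quota_rows[[ch]] <- data.frame(chrom = ch, zone = .ZONE_LEVELS,
                                   quota = as.integer(quotas),
                                   stringsAsFactors = FALSE)
    shortfall[ch] <- budget - (if (is.null(sel)) 0 else nrow(sel))
  }

  sel_all <- do.call(rbind, selected[!vapply(selected, is.null, logical(1))])
  if (is.null(sel_all)) { sel_all <- df[0, , drop = FALSE]; sel_all$zone <- character(0) }
  rownames(sel_all) <- NULL
  structure(list(selected = sel_all,
                 quotas = do.call(rbind, quota_rows),
                 shortfall = shortfall),
            class = "stage_b_selection")
}

#' @noRd
split_zones <- function(lst) setNames(lst, .DISTAL_ZONES)

#' @noRd
zone_thresholds <- function(config, chrom, zone) {
  ov <- config$overrides
  if (!is.null(ov) && nrow(ov)) {
    hit <- ov$chrom == chrom & ov$zone == zone
    if (any(hit)) {
      row <- ov[which(hit)[1], ]
      return(list(max_missing = row$max_missing, min_score = row$min_score))
    }
  }
  list(max_missing = config$stage_b$max_missing,
       min_score = config$stage_b$min_score)
}

# Take up to n rows from a ranked frame, skipping rows whose gene already
# reached the cross-stage cap. Skipped rows stay blocked forever (gene
# counts only grow), so `rest` is just the rows not yet considered.
#' @noRd
take_with_gene_cap <- function(ranked, n, gene_used, cap) {
  take <- integer(0); i <- 0L; nr <- nrow(ranked)
  while (i < nr && length(take) < n) {
    i <- i + 1L
    g <- ranked$gene_id[i]
    if (!is.na(g)) {
      used <- if (g %in% names(gene_used)) gene_used[[g]] else 0L
      if (used >= cap) next
      gene_used[g] <- used + 1L
    }
    take <- c(take, i)
  }
  rest <- if (i < nr) ranked[(i + 1L):nr, , drop = FALSE]
          else ranked[0, , drop = FALSE]
  list(taken = ranked[take, , drop = FALSE], rest = rest,
       gene_used = gene_used)
}

#' @export
print.stage_b_selection <- function(x, ...) {
  cat(sprintf("stage_b_selection: %d SNP(s) selected; shortfall: %s\n",
              nrow(x$selected),
              paste(sprintf("%s=%d", names(x$shortfall), x$shortfall),
                    collapse = ", ")))
  invisible(x)
}

#' Run both selection stages
#'
#' @inheritParams select_stage_b
#' @return list with `stage_a` (variants data frame), `stage_b`
#'   (`stage_b_selection`), and `combined` (union of picks; stages are
#'   disjoint by construction).
#' @export
select_markers <- function(candidates, partitions, config = selection_config()) {
  a <- select_stage_a(candidates, config)
  b <- select_stage_b(candidates, partitions, config, stage_a_selection = a)
  combined <- rbind(cbind(a, zone = NA_character_), b$selected)
  rownames(combined) <- NULL
  list(stage_a = a, stage_b = b, combined = combined)
}

#' Selection funnel arithmetic
#'
#' Tracks marker counts through the design funnel: the two selection-stage
#' totals combine into the pre-redundancy count, cross-set duplicates are
#' removed, legacy markers are added back, and (optionally) fabrication and
#' scoring attrition is expressed as conversion rates.
#'
#' @param stage_a,stage_b counts selected in each stage (disjoint sets).
#' @param duplicates count removed as redundant with the legacy set.
#' @param legacy count of legacy markers carried into the design.
#' @param working,scorable optional post-fabrication assay counts.
#' @return list of class `design_funnel`: `stages` (ordered data frame of
#'   stage label and count) and, when `working` is given, `conversion` from
#'   [conversion_stats()].
#' @export
design_funnel <- function(stage_a, stage_b, duplicates = 0, legacy = 0,
                          working = NULL, scorable = NULL) {
  pre <- stage_a + stage_b
  if (duplicates > pre) stopf("more duplicates than candidates")
  new_in_design <- pre - duplicates
  final <- new_in_design + legacy
  stages <- data.frame(
    stage = c("stage_a_gene_coverage", "stage_b_distal_enrichment",
              "pre_redundancy_total", "duplicates_removed",
              "new_in_design", "legacy_in_design", "final_design"),
    count = c(stage_a, stage_b, pre, duplicates, new_in_design, legacy, final),
    stringsAsFactors = FALSE)
  conv <- NULL
  if (!is.null(working)) {
    conv <- conversion_stats(final, working, scorable %||% working)
    stages <- rbind(stages, data.frame(
      stage = c("working_assays", "scorable_assays"),
      count = c(working, scorable %||% working)))
  }
  structure(list(stages = stages, conversion = conv), class = "design_funnel")
}

#' @export
print.design_funnel <- function(x, ...) {
  print(x$stages, row.names = FALSE)
  if (!is.null(x$conversion))
    cat(sprintf("conversion %.1f%%, scorable %.1f%%\n",
                x$conversion$conversion_pct, x$conversion$scorable_pct))
  invisible(x)
}

#' Suggest five-zone partition breakpoints from an anchor map
#'
#' Fits a five-segment piecewise-linear genetic~physical curve by dynamic
#' programming over candidate breakpoints (the anchor positions), minimising
#' within-segment squared error of a per-segment linear fit. This reproduces
#' the visual practice of partitioning a Marey-map plot into short-arm
#' high/low recombination, pericentromeric, and long-arm low/high
#' recombination zones. Suggestions are advisory: explicit partition tables
#' always take precedence in the pipeline.
#'
#' @param anchors anchor map rows for one chromosome (genetic_pos,
#'   physical_pos).
#' @param chrom_length chromosome length in bp (defaults to the max anchor
#'   position).
#' @return a partition data frame (see [chromosome_partition()]) whose cM
#'   spans are the genetic range covered by each zone's anchors.
#' @export
suggest_partition <- function(anchors, chrom_length = NULL) {
  df <- anchors[order(anchors$physical_pos), , drop = FALSE]
  n <- nrow(df)
  if (n < 10) stopf("need at least 10 anchors to suggest a partition")
  x <- df$physical_pos; y <- df$genetic_pos
  chrom_length <- chrom_length %||% max(x)

  sse <- function(i, j) { # residual SS of y~x on rows i..j
    xi <- x[i:j]; yi <- y[i:j]
    if (length(unique(xi)) < 2) return(sum((yi - mean(yi))^2))
    f <- stats::lm.fit(cbind(1, xi), yi)
    sum(f$residuals^2)
  }
  K <- 5
  cost <- matrix(Inf, K, n); choice <- matrix(NA_integer_, K, n)
  for (j in seq_len(n)) cost[1, j] <- sse(1, j)
  for (k in 2:K) {
    for (j in k:n) {
      for (i in (k - 1):(j - 1)) {
        c2 <- cost[k - 1, i] + sse(i + 1, j)
        if (c2 < cost[k, j]) { cost[k, j] <- c2; choice[k, j] <- i }
      }
    }
  }
  cuts <- integer(K - 1); j <- n
  for (k in K:2) { cuts[k - 1] <- choice[k, j]; j <- choice[k, j] }
  # physical breakpoints midway between adjacent anchors across each cut
  bp <- vapply(cuts, function(i) (x[i] + x[i + 1]) / 2, numeric(1))
  breaks <- c(0, bp, chrom_length)
  seg_of <- findInterval(x, breaks, rightmost.closed = TRUE)
  spans <- vapply(1:5, function(k) {
    yy <- y[seg_of == k]
    if (length(yy) == 0) 0 else max(yy) - min(yy)
  }, numeric(1))
  chromosome_partition(df$chrom[1], breaks, spans)
}
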