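# Deterministic fixture generator with planted ground truth. A single root
# seed drives named substreams (one per generator), so adding a generator
# never perturbs the draws of another. All emitted files round-trip through
# the package's own readers.

#' Simulation specification
#'
#' Defaults describe a desk-scale version of the study conditions: an
#' inbreeding crop with recombination concentrated in the distal chromosome
#' arms, candidate SNPs enriched there, transition:transversion odds of
#' 1.92, a genotyping disagreement rate of 1.9% against a legacy call set,
#' and ~97.3% of markers polymorphic.
#'
#' @param seed root seed; every draw is a deterministic function of it.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param genes_per_chrom genes simulated per chromosome.
#' @param exon_count_range,exon_length_range,intron_length_range gene
#'   geometry draws (uniform integer ranges).
#' @param n_candidates total candidate SNPs across chromosomes.
#' @param genic_fraction fraction of candidates placed inside gene spans
#'   (candidates emulate exome-capture calls, which are overwhelmingly
#'   genic); the rest follow the zone densities.
#' @param n_samples samples genotyped per candidate / call set.
#' @param design_score_range,missing_rate_range uniform ranges for the two
#'   per-candidate design attributes.
#' @param zone_density relative candidate density multiplier per partition
#'   zone.
#' @param n_legacy legacy markers planted in the reference.
#' @param duplicate_fraction fraction of legacy loci also emitted as
#'   new-set manifests (planted cross-set duplicates).
#' @param ambiguous_fraction fraction of legacy loci whose 121-mer is
#'   copied verbatim to a second genomic site (planted ambiguous
#'   placements).
#' @param disagreement_rate per-call probability that call set B differs
#'   from call set A (default 0.019, the legacy-marker scale).
#' @param missing_call_rate per-call missing probability in each call set.
#' @param tstv_odds transition:transversion odds for candidate alleles.
#' @param polymorphic_fraction fraction of call-set markers that segregate.
#' @param n_matrix_markers markers in the generated call sets.
#' @param genetic_spans cM spans of the five zones (short_high, short_low,
#'   pericentromeric, long_low, long_high) used for every chromosome's
#'   partition; defaults mirror a typical distally-recombining chromosome.
#' @param zone_breaks_frac fractional physical breakpoints of the five
#'   zones.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(
    seed = 1,
    chrom_lengths = c("1H" = 300000L, "5H" = 300000L),
    genes_per_chrom = 25,
    exon_count_range = c(1, 4),
    exon_length_range = c(120, 360),
    intron_length_range = c(90, 300),
    n_candidates = 2000,
    genic_fraction = 0.7,
    n_samples = 50,
    design_score_range = c(0.4, 1.0),
    missing_rate_range = c(0, 0.3),
    zone_density = c(short_high = 3, short_low = 1.5, pericentromeric = 0.7,
                     long_low = 1.5, long_high = 3),
    n_legacy = 50,
    duplicate_fraction = 0.1,
    ambiguous_fraction = 0.1,
    disagreement_rate = 0.019,
    missing_call_rate = 0.02,
    tstv_odds = 1.92,
    polymorphic_fraction = 0.973,
    n_matrix_markers = 2000,
    genetic_spans = c(40, 7, 7, 18, 66),
    zone_breaks_frac = c(0, 0.12, 0.25, 0.76, 0.88, 1)) {
  rates <- c(duplicate_fraction, ambiguous_fraction, disagreement_rate,
             missing_call_rate, polymorphic_fraction, missing_rate_range)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0,1]")
  structure(as.list(environment()), class = "simulation_spec")
}

#' Default five-zone partitions for simulated chromosomes
#' @param spec a [simulation_spec()].
#' @return partition data frame covering every simulated chromosome.
#' @export
make_partition <- function(spec) {
  do.call(rbind, lapply(names(spec$chrom_lengths), function(ch) {
    L <- spec$chrom_lengths[[ch]]
    chromosome_partition(ch, round(spec$zone_breaks_frac * L),
                         spec$genetic_spans)
  }))
}

#' Simulate a genome reference with planted legacy loci
#'
#' Background sequence is i.i.d. uniform ACGT, so (at these scales) no
#' exact 121-mer repeats occur except where planted: an
#' `ambiguous_fraction` of the legacy loci have their 121-base window
#' copied verbatim to a second site on the same chromosome.
#'
#' @param spec a [simulation_spec()].
#' @return list: `reference` (named uppercase character vector),
#'   `legacy_truth` (data frame locus_id, chrom, pos, ambiguous,
#'   dup_chrom, dup_pos), `reserved` (windows later generators must not
#'   edit).
#' @export
make_reference <- function(spec) {
  min_len <- 2000L
  if (any(spec$chrom_lengths < min_len))
    stopf("chromosome lengths must be at least %d bp", min_len)
  with_stream(spec$seed, "reference", {
    reference <- vapply(names(spec$chrom_lengths), function(ch) {
      paste(sample(c("A", "C", "G", "T"), spec$chrom_lengths[[ch]],
                   replace = TRUE), collapse = "")
    }, character(1))

    # scatter legacy loci across chromosomes, >=150 bp apart, full flanks
    n_leg <- spec$n_legacy
    per_chrom <- as.vector(table(factor(
      sample(names(spec$chrom_lengths), n_leg, replace = TRUE),
      levels = names(spec$chrom_lengths))))
    loci <- list()
    for (i in seq_along(spec$chrom_lengths)) {
      ch <- names(spec$chrom_lengths)[i]
      L <- spec$chrom_lengths[[ch]]
      pos <- spaced_sample(61L, L - 60L, per_chrom[i], min_gap = 150L)
      if (length(pos) < per_chrom[i])
        stopf("chromosome '%s' too short for %d legacy loci", ch, per_chrom[i])
      loci[[ch]] <- data.frame(chrom = rep(ch, length(pos)), pos = pos,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, loci)
    truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
    truth$locus_id <- sprintf("leg_%03d", seq_len(nrow(truth)))
    truth$ambiguous <- logical(nrow(truth))
    truth$dup_chrom <- rep(NA_character_, nrow(truth))
    truth$dup_pos <- rep(NA_integer_, nrow(truth))

    n_amb <- round(spec$ambiguous_fraction * nrow(truth))
    if (n_amb > 0) {
      amb_idx <- sort(sample(seq_len(nrow(truth)), n_amb))
      for (j in amb_idx) {
        ch <- truth$chrom[j]; L <- spec$chrom_lengths[[ch]]
        taken <- c(truth$pos[truth$chrom == ch],
                   truth$dup_pos[!is.na(truth$dup_pos) & truth$dup_chrom == ch])
        repeat {
          tgt <- sample(seq(61L, L - 60L), 1)
          if (all(abs(tgt - taken) > 150)) break
        }
        win <- substr(reference[[ch]], truth$pos[j] - 60, truth$pos[j] + 60)
        substr(reference[[ch]], tgt - 60, tgt + 60) <- win
        truth$ambiguous[j] <- TRUE
        truth$dup_chrom[j] <- ch; truth$dup_pos[j] <- tgt
      }
    }
    reserved <- rbind(
      data.frame(chrom = truth$chrom, start = truth$pos - 60,
                 end = truth$pos + 60, stringsAsFactors = FALSE),
      data.frame(chrom = truth$dup_chrom[truth$ambiguous],
                 start = truth$dup_pos[truth$ambiguous] - 60,
                 end = truth$dup_pos[truth$ambiguous] + 60,
                 stringsAsFactors = FALSE))
    list(reference = reference,
         legacy_truth = truth[, c("locus_id", "chrom", "pos", "ambiguous",
                                  "dup_chrom", "dup_pos")],
         reserved = reserved)
  })
}

# Sample n positions in [lo, hi] pairwise > min_gap apart (rejection).
#' @noRd
spaced_sample <- function(lo, hi, n, min_gap) {
  if (n == 0) return(integer(0))
  pos <- integer(0); tries <- 0L
  while (length(pos) < n && tries < n * 200L) {
    cand <- sample(seq(lo, hi), 1)
    if (all(abs(cand - pos) > min_gap)) pos <- c(pos, cand)
    tries <- tries + 1L
  }
  sort(pos)
}

#' Simulate gene models and inscribe them into the reference
#'
#' Genes are placed non-overlapping (outside reserved windows), given 1-4
#' exons, and their CDS is made translatable in place: an ATG start codon
#' and a TAA stop codon are written into the reference, internal in-frame
#' stop codons are removed, and total CDS length is a multiple of 3.
#'
#' @param spec a [simulation_spec()].
#' @param reference named character vector from [make_reference()].
#' @param reserved data frame of chrom/start/end windows the generator must
#'   not touch (legacy loci).
#' @return list: `models` (list of [gene_model()]), `reference` (edited
#'   sequence).
#' @export
make_gene_models <- function(spec, reference, reserved = NULL) {
  with_stream(spec$seed, "genes", {
    models <- list()
    for (ch in names(reference)) {
      L <- nchar(reference[[ch]])
      res_ch <- if (is.null(reserved)) NULL else
        reserved[reserved$chrom == ch, , drop = FALSE]
      cursor <- 1500L
      for (gi in seq_len(spec$genes_per_chrom)) {
        n_ex <- sample(seq(spec$exon_count_range[1], spec$exon_count_range[2]), 1)
        ex_len <- sample(seq(spec$exon_length_range[1], spec$exon_length_range[2]),
                         n_ex, replace = TRUE)
        in_len <- if (n_ex > 1)
          sample(seq(spec$intron_length_range[1], spec$intron_length_range[2]),
                 n_ex - 1, replace = TRUE) else integer(0)
        glen <- sum(ex_len) + sum(in_len)
        gap <- sample(1200:2500, 1)
        start <- cursor + gap
        end <- start + glen - 1
        if (end > L - 1500L)
          stopf("chromosome '%s' (%d bp) too short for %d genes of this size",
                ch, L, spec$genes_per_chrom)
        # skip forward past reserved windows
        if (!is.null(res_ch) && nrow(res_ch)) {
          while (any(res_ch$start <= end + 10 & start - 10 <= res_ch$end)) {
            start <- max(res_ch$end[res_ch$start <= end + 10 &
                                      start - 10 <= res_ch$end]) + 50L
            end <- start + glen - 1
            if (end > L - 1500L) break
          }
          if (end > L - 1500L) {
            cursor <- L # no more room on this chromosome
            stopf("chromosome '%s' too short for %d genes around reserved windows",
                  ch, spec$genes_per_chrom)
          }
        }
        # exon layout
        exons <- matrix(0L, n_ex, 2)
        p <- start
        for (e in seq_len(n_ex)) {
          exons[e, ] <- c(p, p + ex_len[e] - 1)
          p <- p + ex_len[e] + (if (e < n_ex) in_len[e] else 0L)
        }
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf("gene_%s_%03d", ch, gi)

        # carve a CDS with UTRs in the terminal exons, length % 3 == 0;
        # UTR sizes are capped so at least ~60 bp of CDS always remains
        max_utr <- max(20L, min(80L, (glen - 90L) %/% 2L))
        utr_a <- sample(20:max_utr, 1) # at the low-coordinate end
        utr_b <- sample(20:max_utr, 1)
        cds_lo <- start + utr_a
        cds_hi <- end - utr_b
        cds <- clip_segments(exons, lower = cds_lo, upper = cds_hi)
        if (is.null(cds)) stopf("internal: empty CDS carved for %s", gid)
        cds_len <- sum(cds[, 2] - cds[, 1] + 1)
        trim <- cds_len %% 3
        if (trim > 0) { # shave the high end to a multiple of 3
          last <- nrow(cds)
          if (cds[last, 2] - cds[last, 1] + 1 <= trim)
            stopf("internal: CDS segment too short to trim for %s", gid)
          cds[last, 2] <- cds[last, 2] - trim
        }
        model <- gene_model(gid, ch, strand, exons, cds)
        model$transcript_id <- paste0(gid, ".1")
        reference[[ch]] <- inscribe_cds(reference[[ch]], model)
        models[[gid]] <- model
        cursor <- end
      }
    }
    list(models = unname(models), reference = reference)
  })
}

# Write start/stop codons into the sequence and remove internal in-frame
# stops so the CDS translates cleanly.
#' @noRd
inscribe_cds <- function(chrom_seq, model) {
  set_base <- function(seq, gpos, base_tx) {
    b <- if (model$strand == "+") base_tx else comp_base(base_tx)
    substr(seq, gpos, gpos) <- b
    seq
  }
  # genomic position of CDS coordinate c (translation order)
  gpos_of <- function(c) {
    segs <- model$cds
    lens <- segs[, 2] - segs[, 1] + 1
    if (model$strand == "+") {
      cum <- cumsum(lens); i <- which(c <= cum)[1]
      prev <- if (i > 1) cum[i - 1] else 0
      segs[i, 1] + (c - prev - 1)
    } else {
      ord <- rev(seq_len(nrow(segs)))
      cum <- cumsum(lens[ord]); i <- which(c <= cum)[1]
      prev <- if (i > 1) cum[i - 1] else 0
      segs[ord[i], 2] - (c - prev - 1)
    }
  }
  n <- sum(model$cds[, 2] - model$cds[, 1] + 1)
  for (k in 1:3) chrom_seq <- set_base(chrom_seq, gpos_of(k),
                                       substr("ATG", k, k))
  for (k in 1:3) chrom_seq <- set_base(chrom_seq, gpos_of(n - 3 + k),
                                       substr("TAA", k, k))
  # scan internal codons; demote any stop by rewriting its first base
  ctx <- gene_context(model, setNames(chrom_seq, model$chrom))
  cds_seq <- ctx$cds_seq
  for (ci in 2:(n / 3 - 1)) {
    codon <- substr(cds_seq, (ci - 1) * 3 + 1, ci * 3)
    if (translate_codon(codon) == "*")
      chrom_seq <- set_base(chrom_seq, gpos_of((ci - 1) * 3 + 1), "C")
  }
  chrom_seq
}

#' Simulate candidate variants with planted selection truth
#'
#' Positions are drawn per zone with density multipliers from the spec
#' (distal zones enriched), alleles follow the spec's
#' transition:transversion odds, and each candidate carries a design score
#' and missing rate drawn uniformly from the spec ranges. Gene association
#' is the simple span-overlap used for per-gene deduplication. The truth
#' log counts, per chromosome and zone, candidates qualifying under the
#' default stage-A (missing <= 0.20, score >= 0.6) and stage-B
#' (missing < 0.05, score > 0.8) thresholds.
#'
#' @param spec a [simulation_spec()].
#' @param reference edited reference from [make_gene_models()].
#' @param genes list of gene models.
#' @param partition partition data frame (default [make_partition()]).
#' @param generate_calls set FALSE to skip the per-sample call matrix (the
#'   planted missing counts still determine `missing_rate`); useful when
#'   only the variant table is needed at large n.
#' @return list: `candidates` (a `candidate_set` whose variants carry a
#'   `zone` column), `truth` (per chrom x zone qualifying counts).
#' @export
make_candidates <- function(spec, reference, genes,
                            partition = make_partition(spec),
                            generate_calls = TRUE) {
  with_stream(spec$seed, "candidates", {
    chroms <- names(reference)
    lens <- vapply(reference, nchar, integer(1))
    n_per_chrom <- as.vector(table(factor(
      sample(chroms, spec$n_candidates, replace = TRUE, prob = lens),
      levels = chroms)))
    gene_meta <- data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      chrom = vapply(genes, `[[`, character(1), "chrom"),
      start = vapply(genes, function(g) g$span[1], numeric(1)),
      end = vapply(genes, function(g) g$span[2], numeric(1)),
      stringsAsFactors = FALSE)

    all_rows <- list()
    for (i in seq_along(chroms)) {
      ch <- chroms[i]; L <- lens[[ch]]
      part <- validate_partition(partition[partition$chrom == ch, ])
      gm_ch <- gene_meta[gene_meta$chrom == ch, , drop = FALSE]
      n_genic <- if (nrow(gm_ch)) round(spec$genic_fraction * n_per_chrom[i]) else 0L
      pos_genic <- integer(0)
      if (n_genic > 0) {
        gi <- sample(nrow(gm_ch), n_genic, replace = TRUE)
        pos_genic <- vapply(gi, function(g)
          sample(seq(max(gm_ch$start[g], 61), min(gm_ch$end[g], L - 60)), 1),
          integer(1))
      }
      n_bg <- n_per_chrom[i] - n_genic
      zone_len <- pmin(part$end_bp, L - 60) - pmax(part$start_bp, 61)
      w <- spec$zone_density[part$zone] * pmax(zone_len, 0)
      n_zone <- as.vector(stats::rmultinom(1, n_bg, prob = w))
      pos_bg <- unlist(lapply(seq_len(5), function(z) {
        lo <- max(part$start_bp[z], 61); hi <- min(part$end_bp[z] - 1, L - 60)
        if (n_zone[z] == 0 || hi < lo) return(integer(0))
        sample(seq(lo, hi), min(n_zone[z], hi - lo + 1))
      }))
      pos <- sort(unique(c(pos_genic, pos_bg)))
      all_rows[[ch]] <- data.frame(chrom = ch, pos = pos,
                                   stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, all_rows)
    df$id <- sprintf("cand_%05d", seq_len(nrow(df)))
    df$ref <- vapply(seq_len(nrow(df)), function(i)
      substr(reference[[df$chrom[i]]], df$pos[i], df$pos[i]), character(1))
    is_ts <- runif(nrow(df)) < spec$tstv_odds / (1 + spec$tstv_odds)
    df$alt <- vapply(seq_len(nrow(df)), function(i)
      draw_alt(df$ref[i], is_ts[i]), character(1))
    df$design_score <- runif(nrow(df), spec$design_score_range[1],
                             spec$design_score_range[2])
    rate_draw <- runif(nrow(df), spec$missing_rate_range[1],
                       spec$missing_rate_range[2])
    n_miss <- round(rate_draw * spec$n_samples)
    df$missing_rate <- n_miss / spec$n_samples

    # gene association by span overlap
    df$gene_id <- NA_character_
    for (g in seq_len(nrow(gene_meta))) {
      hit <- df$chrom == gene_meta$chrom[g] &
        df$pos >= gene_meta$start[g] & df$pos <= gene_meta$end[g]
      df$gene_id[hit & is.na(df$gene_id)] <- gene_meta$gene_id[g]
    }
    df$effect <- NA_character_

    # per-sample calls consistent with the planted missing counts
    calls <- NULL
    if (generate_calls) {
      samples <- sprintf("S%03d", seq_len(spec$n_samples))
      calls <- matrix(NA_character_, nrow(df), spec$n_samples,
                      dimnames = list(df$id, samples))
      for (i in seq_len(nrow(df))) {
        p_alt <- runif(1, 0.1, 0.9)
        row <- ifelse(runif(spec$n_samples) < p_alt, "AA", "RR")
        het <- runif(spec$n_samples) < 0.02
        row[het] <- "RA"
        if (n_miss[i] > 0)
          row[sample(spec$n_samples, n_miss[i])] <- NA_character_
        calls[i, ] <- row
      }
    }

    df$zone <- NA_character_
    for (ch in chroms) {
      part <- partition[partition$chrom == ch, ]
      sel <- df$chrom == ch
      df$zone[sel] <- assign_zone(part, df$pos[sel])
    }
    qual_a <- df$missing_rate <= 0.20 & df$design_score >= 0.6
    qual_b <- df$missing_rate < 0.05 & df$design_score > 0.8
    tdf <- data.frame(chrom = df$chrom, zone = df$zone, n = 1L,
                      qualifying_a = as.integer(qual_a),
                      qualifying_b = as.integer(qual_b),
                      stringsAsFactors = FALSE)
    truth <- stats::aggregate(cbind(n, qualifying_a, qualifying_b) ~
                                chrom + zone, data = tdf, FUN = sum)

    vars <- df[, c("id", "chrom", "pos", "ref", "alt", "missing_rate",
                   "design_score", "gene_id", "effect", "zone")]
    list(candidates = candidate_set(vars, calls = calls), truth = truth)
  })
}

#' @noRd
draw_alt <- function(ref, transition) {
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  if (transition) return(ts_partner[[ref]])
  tv <- setdiff(c("A", "C", "G", "T"), c(ref, ts_partner[[ref]]))
  sample(tv, 1)
}

#' Extract legacy manifests (and planted cross-set duplicates)
#'
#' Manifests are taken verbatim from the planted loci of
#' [make_reference()]; the `duplicate_fraction` of them is re-emitted with
#' new-set ids, giving planted duplicates for [find_duplicates()]. A
#' variant catalog holding every legacy locus with its allele pair is
#' returned for placement validation.
#'
#' @param spec a [simulation_spec()].
#' @param reference edited reference.
#' @param legacy_truth truth log from [make_reference()].
#' @return list: `manifests`, `new_duplicates` (manifest data frames),
#'   `catalog` (chrom, pos, allele_a, allele_b), `truth` (legacy_truth
#'   plus allele columns and `planted_duplicate`).
#' @export
make_legacy_markers <- function(spec, reference, legacy_truth) {
  with_stream(spec$seed, "legacy", {
    truth <- legacy_truth
    n <- nrow(truth)
    recs <- lapply(seq_len(n), function(i) {
      ref_base <- substr(reference[[truth$chrom[i]]], truth$pos[i], truth$pos[i])
      alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
      build_manifest(reference, truth$chrom[i], truth$pos[i],
                     ref_base, alt_base, marker_id = truth$locus_id[i])
    })
    manifests <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(unclass(r), stringsAsFactors = FALSE)))
    truth$allele_a <- manifests$allele_a
    truth$allele_b <- manifests$allele_b

    n_dup <- round(spec$duplicate_fraction * n)
    truth$planted_duplicate <- FALSE
    new_dups <- manifests[0, ]
    if (n_dup > 0) {
      di <- sort(sample(seq_len(n), n_dup))
      truth$planted_duplicate[di] <- TRUE
      new_dups <- manifests[di, , drop = FALSE]
      new_dups$marker_id <- sub("^leg_", "new_", new_dups$marker_id)
    }
    catalog <- data.frame(chrom = truth$chrom, pos = truth$pos,
                          allele_a = truth$allele_a,
                          allele_b = truth$allele_b, stringsAsFactors = FALSE)
    list(manifests = manifests, new_duplicates = new_dups,
         catalog = catalog, truth = truth)
  })
}

#' Simulate a pair of genotype call sets with a planted disagreement rate
#'
#' Call set A holds the "true" calls (AA/BB segregating according to
#' `polymorphic_fraction`, occasional AB); call set B differs from A at
#' each non-missing call independently with probability
#' `disagreement_rate`; missing calls are planted independently in each
#' matrix with probability `missing_call_rate`.
#'
#' @param spec a [simulation_spec()].
#' @param markers,samples optional id vectors (defaults derived from the
#'   spec sizes).
#' @return list: `a`, `b` (markers x samples matrices), `truth` (list with
#'   the planted rates and the per-marker polymorphic flag).
#' @export
make_callsets <- function(spec, markers = NULL, samples = NULL) {
  with_stream(spec$seed, "callsets", {
    markers <- markers %||% sprintf("M%05d", seq_len(spec$n_matrix_markers))
    samples <- samples %||% sprintf("S%03d", seq_len(spec$n_samples))
    nm <- length(markers); ns <- length(samples)
    poly <- runif(nm) < spec$polymorphic_fraction
    a <- matrix(NA_character_, nm, ns, dimnames = list(markers, samples))
    for (i in seq_len(nm)) {
      if (poly[i]) {
        row <- sample(c("AA", "BB"), ns, replace = TRUE)
        if (length(unique(row)) == 1) row[1] <- setdiff(c("AA", "BB"), row[1])
        het <- runif(ns) < 0.01
        row[het] <- "AB"
      } else {
        row <- rep("AA", ns)
      }
      a[i, ] <- row
    }
    flip <- matrix(runif(nm * ns) < spec$disagreement_rate, nm, ns)
    b <- a
    for (idx in which(flip)) {
      b[idx] <- sample(setdiff(c("AA", "AB", "BB"), a[idx]), 1)
    }
    a[matrix(runif(nm * ns) < spec$missing_call_rate, nm, ns)] <- NA_character_
    b[matrix(runif(nm * ns) < spec$missing_call_rate, nm, ns)] <- NA_character_
    list(a = a, b = b,
         truth = list(disagreement_rate = spec$disagreement_rate,
                      missing_call_rate = spec$missing_call_rate,
                      polymorphic = setNames(poly, markers)))
  })
}

#' Run every generator and write the files a pipeline run consumes
#'
#' Writes FASTA (reference), GFF3 (genes), VCF + score TSV (candidates),
#' partition TSV, legacy and planted-duplicate manifest TSVs, two call-set
#' TSVs, and the truth logs.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects (reference, models,
#'   candidates, legacy, callsets, partition, paths).
#' @export
simulate_design_inputs <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- make_reference(spec)
  gm <- make_gene_models(spec, ref$reference, reserved = ref$reserved)
  partition <- make_partition(spec)
  cand <- make_candidates(spec, gm$reference, gm$models, partition)
  leg <- make_legacy_markers(spec, gm$reference, ref$legacy_truth)
  cs <- make_callsets(spec)

  p <- function(f) file.path(dir, f)
  write_reference(gm$reference, p("reference.fa"))
  write_gff3(gm$models, p("genes.gff3"))
  write_vcf(cand$candidates, p("candidates.vcf"))
  write.table(data.frame(id = cand$candidates$variants$id,
                         design_score = cand$candidates$variants$design_score),
              p("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(partition, p("partition.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest_table(leg$manifests, p("legacy_manifests.tsv"), "iupac")
  if (nrow(leg$new_duplicates))
    write_manifest_table(leg$new_duplicates, p("planted_duplicates.tsv"), "iupac")
  write_genotype_matrix(cs$a, p("callset_a.tsv"))
  write_genotype_matrix(cs$b, p("callset_b.tsv"))
  write.table(leg$truth, p("truth_legacy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cand$truth, p("truth_zones.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(reference = gm$reference, models = gm$models,
                 candidates = cand$candidates, candidate_truth = cand$truth,
                 legacy = leg, callsets = cs, partition = partition,
                 dir = dir))
}

#' Write gene models as GFF3
#' @param models list of gene models (with `transcript_id`).
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  rows <- lapply(models, function(m) {
    tid <- m$transcript_id %||% paste0(m$gene_id, ".1")
    g <- data.frame(seqid = m$chrom, source = "panelforge",
                    type = c("gene", "mRNA"),
                    start = m$span[1], end = m$span[2], score = ".",
                    strand = m$strand, phase = ".",
                    attributes = c(sprintf("ID=%s", m$gene_id),
                                   sprintf("ID=%s;Parent=%s", tid, m$gene_id)),
                    stringsAsFactors = FALSE)
    ex <- data.frame(seqid = m$chrom, source = "panelforge", type = "exon",
                     start = m$exons[, 1], end = m$exons[, 2], score = ".",
                     strand = m$strand, phase = ".",
                     attributes = sprintf("ID=%s.exon%d;Parent=%s", tid,
                                          seq_len(nrow(m$exons)), tid),
                     stringsAsFactors = FALSE)
    cd <- NULL
    if (!is.null(m$cds)) {
      lens <- m$cds[, 2] - m$cds[, 1] + 1
      ord <- if (m$strand == "+") seq_len(nrow(m$cds)) else rev(seq_len(nrow(m$cds)))
      phase <- integer(nrow(m$cds))
      acc <- 0L
      for (k in ord) { phase[k] <- (3L - acc %% 3L) %% 3L; acc <- acc + lens[k] }
      cd <- data.frame(seqid = m$chrom, source = "panelforge", type = "CDS",
                       start = m$cds[, 1], end = m$cds[, 2], score = ".",
                       strand = m$strand, phase = phase,
                       attributes = sprintf("ID=%s.cds;Parent=%s", tid, tid),
                       stringsAsFactors = FALSE)
    }
    rbind(g, ex, cd)
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a candidate set as VCF 4.2 (with GT fields when calls exist)
#' @param candidates a `candidate_set`.
#' @param path output path.
#' @export
write_vcf <- function(candidates, path) {
  v <- candidates$variants
  calls <- candidates$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=panelforge",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  gt_cols <- NULL
  if (!is.null(calls)) {
    header <- c(header, "FORMAT", colnames(calls))
    inv <- c(RR = "0/0", AA = "1/1", RA = "0/1")
    gt <- matrix(inv[calls], nrow = nrow(calls))
    gt[is.na(gt)] <- "./."
    gt_cols <- cbind("GT", gt)
  }
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(v) > 0) {
    body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".")
    if (!is.null(gt_cols)) body <- cbind(body, gt_cols)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
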