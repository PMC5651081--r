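# Independent oracles and small fixture builders. Every oracle here is a
# deliberately naive re-derivation (direct sorts, exhaustive interval logic,
# hand counting) kept separate from the package's implementation paths.

# --- largest-remainder apportionment, re-derived from exact rational shares
oracle_largest_remainder <- function(weights, total) {
  if (total == 0) return(setNames(rep(0L, length(weights)), names(weights)))
  exact <- weights / sum(weights) * total
  fl <- floor(exact)
  rem <- exact - fl
  left <- total - sum(fl)
  # stable order: largest remainder first, listed order breaks ties
  idx <- order(-rem, seq_along(rem))
  add <- rep(0L, length(weights))
  if (left > 0) add[idx[seq_len(left)]] <- 1L
  setNames(as.integer(fl + add), names(weights))
}

# --- direct sort-based per-gene dedupe
oracle_dedupe <- function(df, cap) {
  df2 <- df[order(-df$design_score, df$missing_rate, df$pos, df$id), ]
  keep <- character(0)
  count <- list()
  for (i in seq_len(nrow(df2))) {
    g <- df2$gene_id[i]
    if (is.na(g)) { keep <- c(keep, df2$id[i]); next }
    n <- count[[g]] %||% 0
    if (n < cap) { keep <- c(keep, df2$id[i]); count[[g]] <- n + 1 }
  }
  df[df$id %in% keep, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force stage-A + stage-B re-selection (independent loops; no
# shared code with the package beyond exported threshold values)
oracle_select <- function(vars, partition, budget_per_chrom,
                          overrides = data.frame(chrom = "5H",
                                                 zone = "short_high",
                                                 max_missing = 0.20,
                                                 min_score = 0.6)) {
  pass_a <- !is.na(vars$design_score) &
    vars$missing_rate <= 0.20 & vars$design_score >= 0.6
  a <- oracle_dedupe(vars[pass_a, ], 1)
  used <- table(a$gene_id[!is.na(a$gene_id)])
  used <- setNames(as.integer(used), names(used))

  pool <- vars[!(vars$id %in% a$id), ]
  picks <- list()
  for (ch in unique(vars$chrom)) {
    part <- partition[partition$chrom == ch, ]
    part <- part[match(c("short_high", "short_low", "pericentromeric",
                         "long_low", "long_high"), part$zone), ]
    cands <- pool[pool$chrom == ch, ]
    zidx <- findInterval(cands$pos, part$start_bp)
    zidx[cands$pos == part$end_bp[5]] <- 5
    cands$zone <- part$zone[zidx]
    distal <- c("short_high", "short_low", "long_low", "long_high")
    elig <- lapply(distal, function(z) {
      ov <- overrides[overrides$chrom == ch & overrides$zone == z, ]
      mm <- if (nrow(ov)) ov$max_missing[1] else 0.05
      ms <- if (nrow(ov)) ov$min_score[1] else 0.8
      zc <- cands[cands$zone == z & !is.na(cands$design_score) &
                    cands$missing_rate < mm & cands$design_score > ms, ]
      zc[order(-zc$design_score, zc$missing_rate, zc$pos, zc$id), ]
    })
    names(elig) <- distal
    spans <- setNames(part$cM, part$zone)
    remaining <- oracle_largest_remainder(spans[distal], budget_per_chrom)
    taken <- lapply(distal, function(z) elig[[z]][0, ])
    names(taken) <- distal
    repeat {
      for (z in distal) {
        while (remaining[[z]] > 0 && nrow(elig[[z]]) > 0) {
          row <- elig[[z]][1, ]
          elig[[z]] <- elig[[z]][-1, ]
          g <- row$gene_id
          if (!is.na(g)) {
            n <- if (g %in% names(used)) used[[g]] else 0L
            if (n >= 2) next
            used[g] <- n + 1L
          }
          taken[[z]] <- rbind(taken[[z]], row)
          remaining[[z]] <- remaining[[z]] - 1L
        }
      }
      deficit <- sum(remaining)
      supply <- vapply(elig, nrow, integer(1)) > 0
      if (deficit == 0 || !any(supply)) break
      w <- spans[distal][supply]
      if (sum(w) <= 0) w[] <- 1
      redo <- oracle_largest_remainder(w, deficit)
      remaining[] <- 0L
      remaining[names(redo)] <- redo
    }
    picks[[ch]] <- do.call(rbind, taken)
  }
  b <- do.call(rbind, picks)
  list(stage_a = a, stage_b = b)
}

# --- exhaustive interval-logic effect oracle: classifies one position by
# mutating the genome and re-deriving everything from first principles
oracle_effect <- function(model, ref, pos, alt, upstream = 5000,
                          downstream = 5000) {
  chrom_seq <- ref[[model$chrom]]
  strand <- model$strand
  span <- model$span
  base <- substr(chrom_seq, pos, pos)

  dist5 <- if (strand == "+") span[1] - pos else pos - span[2]
  dist3 <- if (strand == "+") pos - span[2] else span[1] - pos
  if (pos < span[1] || pos > span[2]) {
    if (dist5 > 0) return(if (dist5 <= upstream) "upstream" else "intergenic")
    return(if (dist3 <= downstream) "downstream" else "intergenic")
  }

  ex <- model$exons
  in_exon <- any(ex[, 1] <= pos & pos <= ex[, 2])
  if (!in_exon) {
    dl <- pos - max(ex[ex[, 2] < pos, 2])
    dr <- min(ex[ex[, 1] > pos, 1]) - pos
    don <- if (strand == "+") dl else dr
    acc <- if (strand == "+") dr else dl
    if (don <= 2) return("splice_site_donor")
    if (acc <= 2) return("splice_site_acceptor")
    if (dl >= 3 && dl <= 8) return("splice_site_region")
    if (dr >= 3 && dr <= 8) return("splice_site_region")
    return("intron")
  }

  i <- which(ex[, 1] <= pos & pos <= ex[, 2])[1]
  in_splice_exon <- (i > 1 && pos - ex[i, 1] + 1 <= 3) ||
    (i < nrow(ex) && ex[i, 2] - pos + 1 <= 3)

  if (is.null(model$cds))
    return(if (in_splice_exon) "splice_site_region" else "intron")

  # translate the whole CDS before and after the mutation
  extract_tx <- function(seq, segs) {
    parts <- substring(seq, segs[, 1], segs[, 2])
    s <- paste(parts, collapse = "")
    if (strand == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  mut_seq <- chrom_seq
  substr(mut_seq, pos, pos) <- alt
  cds_ref <- extract_tx(chrom_seq, model$cds)
  cds_alt <- extract_tx(mut_seq, model$cds)

  in_cds <- any(model$cds[, 1] <= pos & pos <= model$cds[, 2])
  if (in_cds) {
    aa_ref <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds_ref))), "")[[1]]
    aa_alt <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds_alt))), "")[[1]]
    changed <- which(aa_ref != aa_alt)
    # locate the affected codon even for synonymous changes
    nt_changed <- which(strsplit(cds_ref, "")[[1]] != strsplit(cds_alt, "")[[1]])
    ci <- (nt_changed - 1) %/% 3 + 1
    n_codon <- nchar(cds_ref) / 3
    r <- aa_ref[ci]; a <- aa_alt[ci]
    if (r == "*") return(if (a == "*") "synonymous_stop" else "stop_lost")
    if (a == "*") return("stop_gained")
    if (ci == 1 && substr(cds_ref, 1, 3) == "ATG" &&
        substr(cds_alt, 1, 3) != "ATG") return("start_lost")
    if (ci == 1 && r != a) return("non_synonymous_start")
    if (r != a) return("non_synonymous_coding")
    return("synonymous_coding")
  }

  # exonic non-coding side: UTR, possibly start_gained / splice region
  cds_span <- c(min(model$cds[, 1]), max(model$cds[, 2]))
  five <- if (strand == "+") pos < cds_span[1] else pos > cds_span[2]
  if (five) {
    tx_ref <- extract_tx(chrom_seq, ex)
    tx_alt <- extract_tx(mut_seq, ex)
    gained <- FALSE
    for (s in seq_len(nchar(tx_ref) - 2)) {
      if (substr(tx_alt, s, s + 2) == "ATG" &&
          substr(tx_ref, s, s + 2) != "ATG") gained <- TRUE
    }
    if (gained) return("start_gained")
    return(if (in_splice_exon) "splice_site_region" else "utr5")
  }
  if (in_splice_exon) return("splice_site_region")
  "utr3"
}

# --- hand-count identity between two equal-length sequences (IUPAC-aware)
oracle_identity <- function(a, b) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  m <- mapply(function(x, y) length(intersect(expand[[x]], expand[[y]])) > 0,
              av, bv)
  sum(m) / length(m) * 100
}

# --- Spearman rho from first principles (rank then Pearson)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- tiny fixture: one two-exon coding gene inscribed into a random genome
make_toy_gene <- function(seed = 1, strand = "+", chrom_len = 2000L) {
  set.seed(seed)
  seqv <- paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE), collapse = "")
  g <- gene_model("gtoy", "c1", strand,
                  rbind(c(501, 700), c(801, 1000)),
                  rbind(c(551, 700), c(801, 950)))
  ref <- c(c1 = seqv)
  ref["c1"] <- panelforge:::inscribe_cds(ref["c1"], g)
  list(model = g, ref = ref)
}

# default small simulation used across tests (fast: ~1 s); any field can
# be overridden through ...
toy_spec <- function(seed = 1, ...) {
  args <- list(seed = seed,
               chrom_lengths = c("1H" = 150000L, "5H" = 150000L),
               genes_per_chrom = 10, n_candidates = 600, n_legacy = 20,
               n_matrix_markers = 300)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_spec, args)
}
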