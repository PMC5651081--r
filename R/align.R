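# Pairwise nucleotide alignment for 121 bp manifest queries: k-mer seeded
# (k = 11), ungapped extension with match +1 / mismatch -2, bit scores from
# the ungapped nucleotide Karlin-Altschul parameters for that scoring
# (lambda = 1.33, K = 0.621). Gapped alignment is deliberately omitted: for
# short, high-identity probe sequences an ungapped HSP carries all the
# signal the downstream best-hit logic consumes (identity, query coverage,
# a bit score monotone in the raw score). An IUPAC two-base ambiguity
# position matches either of its bases, on both the query and subject side.

.ALN_MATCH <- 1
.ALN_MISMATCH <- -2
.KA_LAMBDA <- 1.33
.KA_K <- 0.621

#' Build a k-mer index over subject sequences
#'
#' @param subjects named character vector (or DNAStringSet) of subject
#'   sequences; IUPAC ambiguity characters are expanded so that both bases
#'   are indexed.
#' @param k seed length (default 11).
#' @return object of class `kmer_index` for use with [align()].
#' @export
kmer_index <- function(subjects, k = 11) {
  seqs <- as_chrom_strings(subjects)
  if (length(seqs) == 0 || any(nchar(seqs) < k))
    stopf("subjects must be non-empty and at least %d bases long", k)
  tabs <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    n <- nchar(s) - k + 1
    km <- substring(s, seq_len(n), seq_len(n) + k - 1)
    dt <- data.table::data.table(kmer = km, subject = nm, pos = seq_len(n))
    amb <- grepl("[RYSWKM]", dt$kmer)
    if (any(amb)) {
      ex <- dt[amb][, .(kmer = expand_iupac(kmer)), by = .(subject, pos)]
      dt <- rbind(dt[!amb], ex[, .(kmer, subject, pos)])
    }
    dt
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  structure(list(index = idx, seqs = seqs,
                 masks = lapply(seqs, seq_to_mask), k = k),
            class = "kmer_index")
}

# All unambiguous expansions of a sequence containing two-base IUPAC codes.
#' @noRd
expand_iupac <- function(kmers) {
  unlist(lapply(kmers, function(km) {
    chars <- strsplit(km, "", fixed = TRUE)[[1]]
    opts <- lapply(chars, function(ch) {
      if (ch %in% names(.IUPAC_UNPAIR)) iupac_alleles(ch) else ch
    })
    apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste, collapse = "")
  }), use.names = FALSE)
}

#' Align a query against an indexed subject database
#'
#' Both strands are searched. Hits are sorted by bit score (descending) and
#' truncated to at most `max_subjects` subject sequences and
#' `max_hsps_per_subject` HSPs per subject, mirroring conventional tabular
#' BLASTN limits. Identity is matches/alignment length x 100; query
#' coverage is aligned query bases/query length x 100.
#'
#' @param query_seq query sequence (ACGT plus IUPAC ambiguity codes).
#' @param subject_db a [kmer_index()].
#' @param query_id id recorded in the hit table.
#' @param max_subjects,max_hsps_per_subject output limits (defaults 3, 3).
#' @param min_seed_hits minimum seed matches on a diagonal before extension
#'   (default 1).
#' @param min_raw_score HSPs scoring below this are suppressed (default 20,
#'   i.e. at least ~20 matched bases beyond noise; spurious seed-length
#'   diagonal hits score ~the seed length and are dropped). This plays the
#'   role an e-value cutoff plays in a full aligner.
#' @return data frame of hits: query_id, subject_id, identity_pct,
#'   query_coverage_pct, bit_score, raw_score, query_start, query_end,
#'   subject_start, subject_end, strand, n_matches, align_length.
#' @export
align <- function(query_seq, subject_db, query_id = "query",
                  max_subjects = 3, max_hsps_per_subject = 3,
                  min_seed_hits = 1, min_raw_score = 20) {
  if (!inherits(subject_db, "kmer_index"))
    stopf("subject_db must be a kmer_index")
  query_seq <- toupper(query_seq)
  if (nchar(query_seq) < subject_db$k) stopf("query shorter than seed length")

  hits <- rbind(
    align_one_strand(query_seq, subject_db, "+", min_seed_hits),
    align_one_strand(revcomp(query_seq), subject_db, "-", min_seed_hits))
  hits <- hits[hits$raw_score >= min_raw_score, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits(query_id))

  qlen <- nchar(query_seq)
  # minus-strand coordinates were computed on the reversed query; express
  # them on the original query
  neg <- hits$strand == "-"
  qs <- hits$query_start; qe <- hits$query_end
  hits$query_start[neg] <- qlen - qe[neg] + 1
  hits$query_end[neg] <- qlen - qs[neg] + 1

  hits$query_id <- query_id
  hits$identity_pct <- hits$n_matches / hits$align_length * 100
  hits$query_coverage_pct <- hits$align_length / qlen * 100
  hits$bit_score <- (.KA_LAMBDA * hits$raw_score - log(.KA_K)) / log(2)

  hits <- hits[order(-hits$bit_score, hits$subject_id, hits$subject_start), ,
               drop = FALSE]
  # per-subject HSP cap, then best-subject cap
  hsp_rank <- stats::ave(seq_len(nrow(hits)), hits$subject_id, FUN = seq_along)
  hits <- hits[hsp_rank <= max_hsps_per_subject, , drop = FALSE]
  keep_subjects <- unique(hits$subject_id)[seq_len(min(max_subjects,
                                                       length(unique(hits$subject_id))))]
  hits <- hits[hits$subject_id %in% keep_subjects, , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "subject_id", "identity_pct", "query_coverage_pct",
           "bit_score", "raw_score", "query_start", "query_end",
           "subject_start", "subject_end", "strand", "n_matches",
           "align_length")]
}

#' @noRd
empty_hits <- function(query_id) {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), query_coverage_pct = numeric(),
             bit_score = numeric(), raw_score = numeric(),
             query_start = integer(), query_end = integer(),
             subject_start = integer(), subject_end = integer(),
             strand = character(), n_matches = integer(),
             align_length = integer(), stringsAsFactors = FALSE)
}

#' @noRd
align_one_strand <- function(qseq, db, strand, min_seed_hits) {
  k <- db$k
  qlen <- nchar(qseq)
  n <- qlen - k + 1
  km <- substring(qseq, seq_len(n), seq_len(n) + k - 1)
  qdt <- data.table::data.table(kmer = km, qpos = seq_len(n))
  amb <- grepl("[RYSWKM]", qdt$kmer)
  if (any(amb)) {
    ex <- qdt[amb][, .(kmer = expand_iupac(kmer)), by = qpos]
    qdt <- rbind(qdt[!amb], ex[, .(kmer, qpos)])
  }
  empty <- data.frame(subject_id = character(), raw_score = numeric(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      strand = character(), n_matches = integer(),
                      align_length = integer(), stringsAsFactors = FALSE)
  seeds <- db$index[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0) return(empty)
  seeds[, diag := pos - qpos]
  diags <- seeds[, .N, by = .(subject, diag)][N >= min_seed_hits]

  qmask <- seq_to_mask(qseq)
  out <- vector("list", nrow(diags))
  for (r in seq_len(nrow(diags))) {
    subj <- diags$subject[r]; d <- diags$diag[r]
    smask <- db$masks[[subj]]
    slen <- length(smask)
    # query positions whose diagonal partner lies on the subject
    q_lo <- max(1L, 1L - d); q_hi <- min(qlen, slen - d)
    if (q_hi - q_lo + 1 < k) next
    qi <- q_lo:q_hi
    match_vec <- bitwAnd(qmask[qi], smask[qi + d]) > 0L
    score_vec <- ifelse(match_vec, .ALN_MATCH, .ALN_MISMATCH)
    seg <- max_subarray(score_vec)
    if (seg$score <= 0) next
    qs <- qi[seg$from]; qe <- qi[seg$to]
    out[[r]] <- data.frame(
      subject_id = subj, raw_score = seg$score,
      query_start = qs, query_end = qe,
      subject_start = qs + d, subject_end = qe + d,
      strand = strand,
      n_matches = sum(match_vec[seg$from:seg$to]),
      align_length = qe - qs + 1, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- empty
  } else {
    # one HSP per (subject, diagonal); collapse exact duplicates produced
    # by ambiguity expansion
    res <- unique(res)
  }
  res
}

# Maximum-scoring contiguous segment (Kadane), 1-based from/to.
#' @noRd
max_subarray <- function(x) {
  best <- -Inf; best_from <- best_to <- 1L
  cur <- 0; cur_from <- 1L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; cur_from <- i }
    else cur <- cur + x[i]
    if (cur > best) { best <- cur; best_from <- cur_from; best_to <- i }
  }
  list(score = best, from = best_from, to = best_to)
}

#' Read a 12-column tabular alignment file as AlignmentHits
#'
#' Shim for users who prefer an external aligner: accepts the conventional
#' tab-separated columns (query, subject, identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore) and
#' converts them to the hit-table layout used by [place_marker()].
#'
#' @param path tabular alignment output.
#' @param query_lengths named vector of query lengths, used to compute
#'   query coverage.
#' @return hit data frame (see [align()]).
#' @export
read_tabular_hits <- function(path, query_lengths) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stopf("expected 12 tab-separated columns")
  names(df)[1:12] <- c("query_id", "subject_id", "identity_pct",
                       "align_length", "mismatches", "gapopen",
                       "query_start", "query_end", "sstart", "send",
                       "evalue", "bit_score")
  strand <- ifelse(df$sstart <= df$send, "+", "-")
  data.frame(query_id = df$query_id, subject_id = df$subject_id,
             identity_pct = df$identity_pct,
             query_coverage_pct = df$align_length /
               as.numeric(query_lengths[df$query_id]) * 100,
             bit_score = df$bit_score, raw_score = NA_real_,
             query_start = df$query_start, query_end = df$query_end,
             subject_start = pmin(df$sstart, df$send),
             subject_end = pmax(df$sstart, df$send),
             strand = strand,
             n_matches = df$align_length - df$mismatches,
             align_length = df$align_length, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Cross-set redundancy

#' Find markers duplicated between a new and a legacy manifest set
#'
#' Both manifest sets are rendered as IUPAC sequences and the legacy set is
#' aligned as queries against the new set, so query coverage is computed on
#' the legacy side. A pair is reported when the query's best hit (top bit
#' score) reaches both thresholds (inclusive).
#'
#' @param new_manifests,legacy_manifests manifest data frames (marker_id,
#'   left_flank, right_flank, allele_a, allele_b).
#' @param min_qcov,min_ident thresholds in percent (defaults 98, 95).
#' @return list: `pairs` (data frame legacy_id, new_id, identity_pct,
#'   query_coverage_pct, bit_score) and `remove` (new-set marker ids to
#'   drop).
#' @export
find_duplicates <- function(new_manifests, legacy_manifests,
                            min_qcov = 98.0, min_ident = 95.0) {
  new_df <- manifest_frame(new_manifests)
  leg_df <- manifest_frame(legacy_manifests)
  if (nrow(new_df) == 0 || nrow(leg_df) == 0)
    return(list(pairs = data.frame(legacy_id = character(),
                                   new_id = character(),
                                   identity_pct = numeric(),
                                   query_coverage_pct = numeric(),
                                   bit_score = numeric()),
                remove = character(0)))
  subj <- setNames(render_manifest(new_df, "iupac"), new_df$marker_id)
  db <- kmer_index(subj)
  rows <- lapply(seq_len(nrow(leg_df)), function(i) {
    q <- render_manifest(leg_df[i, , drop = FALSE], "iupac")
    h <- align(q, db, query_id = leg_df$marker_id[i], max_subjects = 1,
               max_hsps_per_subject = 1)
    if (nrow(h) == 0) return(NULL)
    best <- h[1, ]
    if (best$query_coverage_pct >= min_qcov && best$identity_pct >= min_ident) {
      data.frame(legacy_id = best$query_id, new_id = best$subject_id,
                 identity_pct = best$identity_pct,
                 query_coverage_pct = best$query_coverage_pct,
                 bit_score = best$bit_score, stringsAsFactors = FALSE)
    } else NULL
  })
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(legacy_id = character(), new_id = character(),
                        identity_pct = numeric(),
                        query_coverage_pct = numeric(),
                        bit_score = numeric())
  list(pairs = pairs, remove = unique(pairs$new_id))
}

# ---------------------------------------------------------------------------
# Legacy-marker placement

#' Place a legacy marker from its alignment hits
#'
#' Hits are filtered to `identity >= min_ident`. No surviving hit leaves
#' the marker unmapped. A unique top bit score (compared after rounding to
#' 1 decimal, the precision at which bit scores are conventionally
#' reported) maps the marker to the subject base aligned opposite the
#' query's SNP index; if that index lies outside the aligned segment the
#' marker is unmapped. Two or more tied top scores make the marker
#' ambiguous, with every tied location exported. A mapped marker is
#' validated when `catalog` holds a variant at the predicted (chrom, pos)
#' whose allele pair matches `expected_alleles` unordered and
#' strand-normalized (A/G matches T/C).
#'
#' @param hits hit data frame from [align()] for one marker.
#' @param catalog optional variant catalog: data frame chrom, pos,
#'   allele_a, allele_b from an independent call set.
#' @param expected_alleles the marker's allele pair (length-2 character).
#' @param min_ident identity threshold in percent (default 95, inclusive).
#' @param snp_index 1-based query position of the SNP base (default 61,
#'   the centre of a 121-base manifest).
#' @return list of class `placement_result`: marker_id, status
#'   (mapped_validated / mapped_unvalidated / ambiguous / unmapped),
#'   locations (data frame chrom, pos), matched_polymorphism.
#' @export
place_marker <- function(hits, catalog = NULL, expected_alleles = NULL,
                         min_ident = 95.0, snp_index = 61) {
  marker_id <- if (nrow(hits)) hits$query_id[1] else NA_character_
  hits <- hits[hits$identity_pct >= min_ident, , drop = FALSE]
  no_loc <- data.frame(chrom = character(), pos = integer())
  if (nrow(hits) == 0)
    return(placement_result(marker_id, "unmapped", no_loc, FALSE))

  bits <- round(hits$bit_score, 1)
  top <- which(bits == max(bits))
  if (length(top) >= 2) {
    locs <- do.call(rbind, lapply(top, function(i)
      predicted_location(hits[i, ], snp_index)))
    locs <- unique(locs[!is.na(locs$pos), , drop = FALSE])
    return(placement_result(marker_id, "ambiguous", locs, FALSE))
  }

  loc <- predicted_location(hits[top, ], snp_index)
  if (is.na(loc$pos))
    return(placement_result(marker_id, "unmapped", no_loc, FALSE))

  matched <- FALSE
  if (!is.null(catalog) && !is.null(expected_alleles)) {
    hit_rows <- catalog[catalog$chrom == loc$chrom & catalog$pos == loc$pos, ,
                        drop = FALSE]
    if (nrow(hit_rows) > 0) {
      matched <- alleles_equivalent(expected_alleles,
                                    c(hit_rows$allele_a[1], hit_rows$allele_b[1]))
    }
  }
  status <- if (is.null(catalog)) "mapped_unvalidated"
            else if (matched) "mapped_validated" else "mapped_unvalidated"
  placement_result(marker_id, status, loc, matched)
}

#' @noRd
placement_result <- function(marker_id, status, locations, matched) {
  structure(list(marker_id = marker_id, status = status,
                 locations = locations, matched_polymorphism = matched),
            class = "placement_result")
}

#' @noRd
predicted_location <- function(hit, snp_index) {
  if (snp_index < hit$query_start || snp_index > hit$query_end)
    return(data.frame(chrom = hit$subject_id, pos = NA_integer_))
  pos <- if (hit$strand == "+") {
    hit$subject_start + (snp_index - hit$query_start)
  } else {
    hit$subject_end - (snp_index - hit$query_start)
  }
  data.frame(chrom = hit$subject_id, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# Unordered, strand-normalized allele-pair comparison.
#' @noRd
alleles_equivalent <- function(a, b) {
  norm <- function(p) paste(sort(toupper(p)), collapse = "/")
  norm(a) == norm(b) ||
    norm(vapply(a, comp_base, character(1))) == norm(b)
}

#' Place a whole legacy manifest set on a reference
#'
#' Convenience driver: renders each manifest as an IUPAC query, aligns it
#' against the reference, and applies [place_marker()].
#'
#' @param manifests manifest data frame.
#' @param reference genome reference (or a prebuilt [kmer_index()]).
#' @param catalog optional variant catalog for validation.
#' @param min_ident identity threshold.
#' @return list of `placement_result`s, one per manifest.
#' @export
place_markers <- function(manifests, reference, catalog = NULL,
                          min_ident = 95.0) {
  df <- manifest_frame(manifests)
  db <- if (inherits(reference, "kmer_index")) reference else
    kmer_index(reference)
  lapply(seq_len(nrow(df)), function(i) {
    q <- render_manifest(df[i, , drop = FALSE], "iupac")
    h <- align(q, db, query_id = df$marker_id[i])
    place_marker(h, catalog = catalog,
                 expected_alleles = c(df$allele_a[i], df$allele_b[i]),
                 min_ident = min_ident)
  })
}

#' Summarise placement results
#'
#' @param results list of `placement_result`s.
#' @return list of class `placement_summary`: `counts` per status,
#'   `mappable_pct` (mapped / total x 100) and `validated_pct`
#'   (validated / mapped x 100), both rounded to 1 decimal.
#' @export
placement_summary <- function(results) {
  if (length(results) == 0) stopf("no placement results")
  status <- vapply(results, `[[`, character(1), "status")
  lv <- c("mapped_validated", "mapped_unvalidated", "ambiguous", "unmapped")
  counts <- table(factor(status, levels = lv))
  mapped <- sum(counts[c("mapped_validated", "mapped_unvalidated")])
  structure(list(
    counts = setNames(as.integer(counts), lv),
    total = length(results),
    mappable_pct = round_half_up(mapped / length(results) * 100, 1),
    validated_pct = if (mapped > 0)
      round_half_up(counts[["mapped_validated"]] / mapped * 100, 1)
    else NA_real_
  ), class = "placement_summary")
}

#' @export
print.placement_summary <- function(x, ...) {
  cat(sprintf("placements: %d total; mappable %.1f%%; validated %.1f%%\n",
              x$total, x$mappable_pct, x$validated_pct))
  print(x$counts)
  invisible(x)
}

#' Placement results as a table
#' @param results list of `placement_result`s.
#' @return data frame marker_id, status, chrom, pos, matched (ambiguous
#'   markers contribute one row per tied location).
#' @export
placement_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    if (nrow(r$locations) == 0) {
      data.frame(marker_id = r$marker_id, status = r$status,
                 chrom = NA_character_, pos = NA_integer_,
                 matched = r$matched_polymorphism, stringsAsFactors = FALSE)
    } else {
      data.frame(marker_id = r$marker_id, status = r$status,
                 chrom = r$locations$chrom, pos = r$locations$pos,
                 matched = r$matched_polymorphism, stringsAsFactors = FALSE)
    }
  }))
}
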