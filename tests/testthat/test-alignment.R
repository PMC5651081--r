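# K-mer seeded alignment, duplicate detection, identity boundary.

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("an exact 121-mer match yields one full-identity, full-coverage hit", {
  genome <- c(chr1 = random_seq(5000, 1))
  q <- substr(genome[["chr1"]], 1001, 1121)
  db <- kmer_index(genome)
  h <- align(q, db, query_id = "q1")
  expect_equal(nrow(h), 1)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_coverage_pct, 100)
  expect_equal(h$subject_start, 1001)
  expect_equal(h$subject_end, 1121)
  expect_equal(h$strand, "+")
})

test_that("a 121-mer planted at two loci returns two equal-bit-score hits", {
  g <- random_seq(6000, 2)
  win <- substr(g, 501, 621)
  substr(g, 4001, 4121) <- win
  db <- kmer_index(c(chr1 = g))
  h <- align(win, db)
  expect_equal(nrow(h), 2)
  expect_equal(round(h$bit_score[1], 1), round(h$bit_score[2], 1))
  expect_setequal(h$subject_start, c(501, 4001))
})

test_that("IUPAC ambiguity positions match either base on query or subject side", {
  g <- random_seq(3000, 3)
  substr(g, 1061, 1061) <- "G"
  q <- substr(g, 1001, 1121)
  substr(q, 61, 61) <- "R" # A/G ambiguity over a G
  db <- kmer_index(c(chr1 = g))
  h <- align(q, db)
  expect_equal(h$identity_pct[1], 100)
  # and the reverse: ambiguity in the subject
  g2 <- g
  substr(g2, 1061, 1061) <- "R"
  q2 <- substr(g, 1001, 1121)
  substr(q2, 61, 61) <- "A"
  h2 <- align(q2, kmer_index(c(chr1 = g2)))
  expect_equal(h2$identity_pct[1], 100)
})

test_that("reverse-complement queries are found on the minus strand", {
  g <- random_seq(4000, 4)
  win <- substr(g, 2001, 2121)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  h <- align(rc, kmer_index(c(chr1 = g)))
  expect_equal(h$strand[1], "-")
  expect_equal(h$subject_start[1], 2001)
  expect_equal(h$identity_pct[1], 100)
})

test_that("hit limits cap subjects and HSPs as configured", {
  g <- random_seq(2000, 5)
  win <- substr(g, 301, 421)
  genome <- c(s1 = g,
              s2 = paste0(random_seq(500, 6), win, random_seq(500, 7)),
              s3 = paste0(random_seq(500, 8), win, random_seq(500, 9)),
              s4 = paste0(random_seq(500, 10), win, random_seq(500, 11)),
              s5 = paste0(random_seq(500, 12), win, random_seq(500, 13)))
  h <- align(win, kmer_index(genome), max_subjects = 3)
  expect_lte(length(unique(h$subject_id)), 3)
})

test_that("mismatch count drives identity through the hand-count oracle", {
  g <- random_seq(3000, 14)
  q <- substr(g, 1001, 1121)
  db <- kmer_index(c(chr1 = g))
  set.seed(99)
  mut_positions <- sample(setdiff(10:110, 55:67), 10) # keep seeds available
  qmut <- q
  for (k in seq_along(mut_positions)) {
    p <- mut_positions[k]
    old <- substr(qmut, p, p)
    substr(qmut, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    h <- align(qmut, db)
    if (nrow(h) == 0) next
    best <- h[1, ]
    if (best$query_coverage_pct == 100) {
      target <- substr(g, 1001, 1121)
      expect_equal(best$identity_pct, oracle_identity(qmut, target),
                   tolerance = 1e-10)
    }
  }
})

test_that("duplicate status flips exactly at the 95% identity boundary", {
  # 121-mer pairs differing at 0..10 positions; the hand-count oracle puts
  # 6 mismatches at 115/121 = 95.04% (duplicate) and 7 at 94.2% (not)
  mk_manifest <- function(seqstr, id) {
    ca <- substr(seqstr, 61, 61)
    al <- sort(c(ca, setdiff(c("A", "C", "G", "T"), ca)[1]))
    data.frame(marker_id = id, left_flank = substr(seqstr, 1, 60),
               right_flank = substr(seqstr, 62, 121),
               allele_a = al[1], allele_b = al[2], stringsAsFactors = FALSE)
  }
  base_new <- random_seq(121, 20)
  new_m <- mk_manifest(base_new, "new1")
  rendered_new <- render_manifest(new_m, "iupac")
  # spread mutations across the flanks so seeding always survives
  mut_sites <- c(5, 15, 25, 35, 45, 95, 105, 111, 80, 90)
  for (nmut in 0:10) {
    s <- base_new
    for (p in head(mut_sites, nmut)) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    leg <- mk_manifest(s, "leg1")
    rendered_leg <- render_manifest(leg, "iupac")
    dup <- find_duplicates(new_m, leg)
    expected <- oracle_identity(rendered_leg, rendered_new) >= 95
    expect_equal(nrow(dup$pairs) == 1, expected,
                 info = sprintf("%d mismatches", nmut))
    if (nmut == 6)
      expect_equal(oracle_identity(rendered_leg, rendered_new), 115 / 121 * 100)
    if (nmut == 7)
      expect_equal(oracle_identity(rendered_leg, rendered_new), 114 / 121 * 100)
  }
})

test_that("find_duplicates recovers planted cross-set duplicates and only them", {
  spec <- toy_spec(seed = 30)
  ref <- make_reference(spec)
  gm <- make_gene_models(spec, ref$reference, ref$reserved)
  leg <- make_legacy_markers(spec, gm$reference, ref$legacy_truth)
  # new set: planted duplicates plus unrelated manifests from other loci
  other <- leg$manifests[!leg$truth$planted_duplicate, ][1:5, ]
  other$marker_id <- paste0("unrelated_", seq_len(nrow(other)))
  other$left_flank <- vapply(seq_len(nrow(other)), function(i)
    random_seq(60, 100 + i), character(1))
  new_set <- rbind(leg$new_duplicates, other)
  dup <- find_duplicates(new_set, leg$manifests)
  planted <- leg$truth$locus_id[leg$truth$planted_duplicate]
  expect_setequal(dup$pairs$legacy_id, planted)
  expect_setequal(dup$remove, sub("^leg_", "new_", planted))
})

test_that("tabular alignment shim computes coverage and strand", {
  f <- tempfile()
  writeLines(c("q1\ts1\t98.3\t121\t2\t0\t1\t121\t500\t620\t1e-50\t220.1",
               "q1\ts2\t97.0\t100\t3\t0\t10\t109\t800\t701\t1e-40\t180.0"), f)
  h <- read_tabular_hits(f, c(q1 = 121))
  expect_equal(h$query_coverage_pct, c(100, 100 / 121 * 100))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$subject_start, c(500, 701))
})
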