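# QC metrics: agreement, Ts/Tv, polymorphism, conversion, order concordance.

call_mat <- function(v, markers, samples) {
  matrix(v, length(markers), length(samples),
         dimnames = list(markers, samples))
}

test_that("agreement handles identical matrices, mismatches and missing pairs", {
  mk <- sprintf("m%03d", 1:100)
  a <- call_mat(sample(c("AA", "BB"), 300, TRUE), mk, c("S1", "S2", "S3"))
  r <- agreement_rate(a, a)
  expect_true(all(r$per_sample$agreement_pct == 100))

  b <- a
  b[1:5, "S1"] <- ifelse(a[1:5, "S1"] == "AA", "BB", "AA")
  r2 <- agreement_rate(a, b)
  expect_equal(r2$per_sample$agreement_pct[r2$per_sample$sample_id == "S1"], 95)

  # 10 missing in A, 5 of remaining 90 disagree -> 85/90
  c1 <- a
  c1[1:10, "S2"] <- NA
  b2 <- a
  b2[11:15, "S2"] <- ifelse(a[11:15, "S2"] == "AA", "BB", "AA")
  r3 <- agreement_rate(c1, b2)
  s2 <- r3$per_sample[r3$per_sample$sample_id == "S2", ]
  expect_equal(s2$compared, 90)
  expect_equal(s2$agreement_pct, 85 / 90 * 100)

  # AB against a homozygote is a disagreement unless excluded
  d <- a; d[1, "S3"] <- "AB"
  r4 <- agreement_rate(a, d)
  expect_equal(r4$per_sample$agreement_pct[3], 99)
  r5 <- agreement_rate(a, d, exclude_het = TRUE)
  expect_equal(r5$per_sample$compared[3], 99)
  expect_equal(r5$per_sample$agreement_pct[3], 100)
})

test_that("agreement is symmetric per sample", {
  set.seed(50)
  mk <- sprintf("m%03d", 1:200)
  sm <- sprintf("S%02d", 1:8)
  a <- call_mat(sample(c("AA", "BB", "AB", NA), 1600, TRUE, c(.45, .45, .05, .05)),
                mk, sm)
  b <- call_mat(sample(c("AA", "BB", "AB", NA), 1600, TRUE, c(.45, .45, .05, .05)),
                mk, sm)
  expect_equal(agreement_rate(a, b)$per_sample$agreement_pct,
               agreement_rate(b, a)$per_sample$agreement_pct)
})

test_that("samples with nothing to compare are flagged and excluded from summary", {
  mk <- c("m1", "m2")
  a <- call_mat(c("AA", "AA", NA, NA), mk, c("S1", "S2"))
  b <- call_mat(c("AA", "BB", "AA", "AA"), mk, c("S1", "S2"))
  r <- agreement_rate(a, b)
  expect_equal(r$flagged, "S2")
  expect_equal(unname(r$summary["mean"]), 50)
})

test_that("Ts/Tv counts transitions over transversions", {
  df <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "T"))
  expect_equal(tstv_ratio(df), 2)
  expect_equal(tstv_ratio(c("A", "C"), c("C", "G")), 0)
  expect_error(tstv_ratio(data.frame(ref = "A", alt = "G")), "no transversions")
})

test_that("planted Ts:Tv odds are recovered within 3 binomial SE", {
  spec <- simulation_spec(seed = 6, chrom_lengths = c("1H" = 400000L),
                          genes_per_chrom = 5, n_candidates = 8000,
                          n_legacy = 5, tstv_odds = 1.92)
  ref <- make_reference(spec)
  gm <- make_gene_models(spec, ref$reference, ref$reserved)
  cand <- make_candidates(spec, gm$reference, gm$models)
  v <- cand$candidates$variants
  ratio <- tstv_ratio(v)
  p <- 1.92 / 2.92
  n <- nrow(v)
  se_p <- sqrt(p * (1 - p) / n)
  # delta method on p/(1-p)
  se_ratio <- se_p / (1 - p)^2
  expect_lt(abs(ratio - 1.92), 3 * se_ratio)
})

test_that("polymorphism rate counts markers with >= 2 observed states", {
  m <- matrix(c("AA", "AA", "AA",   # S1
                "AA", "AA", NA,     # S2
                "AA", "BB", NA),    # S3
              3, 3, dimnames = list(sprintf("m%d", 1:3), sprintf("S%d", 1:3)))
  expect_equal(polymorphism_rate(m), round(1 / 3 * 100, 1))
  expect_error(polymorphism_rate(m[0, , drop = FALSE]), "empty")
  spec <- toy_spec(seed = 44, n_matrix_markers = 400, missing_call_rate = 0)
  cs <- make_callsets(spec)
  planted <- mean(cs$truth$polymorphic) * 100
  expect_equal(polymorphism_rate(cs$a), round(planted, 1))
})

test_that("conversion statistics reproduce printed rates and police ordering", {
  cs <- conversion_stats(49267, 44040, 43461)
  expect_equal(cs$conversion_pct, 89.4)
  cs2 <- conversion_stats(100, 100, 100)
  expect_equal(cs2$conversion_pct, 100)
  expect_equal(cs2$scorable_pct, 100)
  cs3 <- conversion_stats(100, 0, 0)
  expect_equal(cs3$conversion_pct, 0)
  expect_equal(cs3$scorable_pct, 0)
  expect_true(cs3$degenerate)
  expect_error(conversion_stats(100, 120, 50), "scorable <= working <= designed")
})

test_that("order concordance: collinear, reversed, single swap, unlinked", {
  am <- data.frame(chrom = "1H", marker_id = sprintf("m%d", 1:6),
                   genetic_pos = 1:6, physical_pos = (1:6) * 1e6)
  r <- order_concordance(am)
  expect_equal(r$per_chrom$rho, 1)
  expect_equal(r$per_chrom$adjacent_inversions, 0)

  rev_map <- am; rev_map$physical_pos <- rev(am$physical_pos)
  expect_equal(order_concordance(rev_map)$per_chrom$rho, -1)

  swap <- am; swap$physical_pos[3:4] <- swap$physical_pos[4:3]
  r3 <- order_concordance(swap)
  expect_equal(r3$per_chrom$adjacent_inversions, 1)
  expect_equal(r3$per_chrom$rho,
               oracle_spearman(swap$genetic_pos, swap$physical_pos))

  # cross-chromosome physical placement flags the marker as unlinked
  off <- am; off$phys_chrom <- c(rep("1H", 5), "2H")
  r4 <- order_concordance(off)
  expect_equal(r4$per_chrom$n_unlinked, 1)
  expect_equal(r4$unlinked$marker_id, "m6")
  expect_equal(r4$per_chrom$n, 5)

  # distance-based unlinked detection via leave-one-out interpolation
  far <- am; far$physical_pos[3] <- 50e6
  r5 <- order_concordance(far, max_deviation = 5e6)
  expect_equal(r5$unlinked$marker_id, "m3")

  tiny <- am[1:2, ]
  r6 <- order_concordance(tiny)
  expect_true(r6$per_chrom$flagged)
  expect_true(is.na(r6$per_chrom$rho))
})

test_that("planted disagreement rates are recovered within 3 binomial SE", {
  for (e in c(0.019, 0.061)) {
    spec <- simulation_spec(seed = 7, disagreement_rate = e,
                            missing_call_rate = 0.02,
                            n_matrix_markers = 2000, n_samples = 50)
    cs <- make_callsets(spec)
    rep <- agreement_rate(cs$a, cs$b)
    n_pairs <- sum(rep$per_sample$compared)
    se <- sqrt(e * (1 - e) / n_pairs) * 100
    expect_lt(abs(unname(rep$summary["mean"]) - 100 * (1 - e)), 3 * se)
  }
})
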