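# Two-stage selection: thresholds, dedupe, zones, quotas, stage B.

cand_frame <- function(id, score, missing, pos = seq_along(id),
                       gene = NA_character_, chrom = "1H") {
  data.frame(id = id, chrom = chrom, pos = pos, ref = "A", alt = "G",
             missing_rate = missing, design_score = score,
             gene_id = gene, effect = NA_character_, stringsAsFactors = FALSE)
}

part_1h <- chromosome_partition("1H", c(0, 30e6, 60e6, 380e6, 470e6, 560e6),
                                c(40, 7, 0, 18, 66))

test_that("stage-A boundaries are inclusive, stage-B exclusive, as printed", {
  df <- cand_frame(c("x1", "x2", "x3"),
                   score = c(0.60, 0.80, 0.70),
                   missing = c(0.20, 0.05, 0.21))
  a <- filter_candidates(df, 0.20, 0.6, inclusive = TRUE)
  expect_true("x1" %in% a$id)        # exactly at both stage-A bounds
  expect_false("x3" %in% a$id)       # 21% missing
  b <- filter_candidates(df, 0.05, 0.8, inclusive = FALSE)
  expect_false("x2" %in% b$id)       # exactly at both stage-B bounds: dropped
  strict <- cand_frame("y", 0.81, 0.049)
  expect_equal(filter_candidates(strict, 0.05, 0.8, inclusive = FALSE)$id, "y")
})

test_that("per-gene dedupe keeps the top-ranked SNPs and matches the sort oracle", {
  df <- cand_frame(c("a", "b", "c", "d", "e"),
                   score = c(0.9, 0.8, 0.7, 0.5, 0.5),
                   missing = c(0.1, 0.1, 0.1, 0, 0),
                   gene = c("G", "G", "G", NA, NA))
  expect_equal(sort(dedupe_per_gene(df, 1)$id), sort(c("a", "d", "e")))
  expect_equal(sort(dedupe_per_gene(df, 2)$id), sort(c("a", "b", "d", "e")))
  expect_error(dedupe_per_gene(df, 0), "cap")
  set.seed(31)
  for (rep in 1:20) {
    n <- 40
    rdf <- cand_frame(sprintf("r%02d", 1:n), score = round(runif(n), 2),
                      missing = round(runif(n, 0, 0.3), 2),
                      pos = sample(1e6, n),
                      gene = sample(c(NA, "g1", "g2", "g3"), n, TRUE))
    cap <- sample(1:3, 1)
    expect_equal(sort(dedupe_per_gene(rdf, cap)$id),
                 sort(oracle_dedupe(rdf, cap)$id))
  }
})

test_that("zone assignment is half-open with the final zone closed", {
  expect_equal(assign_zone(part_1h, 15e6), "short_high")
  expect_equal(assign_zone(part_1h, 200e6), "pericentromeric")
  expect_equal(assign_zone(part_1h, 30e6), "short_low")   # boundary goes right
  expect_equal(assign_zone(part_1h, 560e6), "long_high")  # chromosome end
  expect_error(assign_zone(part_1h, 600e6), "outside")
})

test_that("quota apportionment is largest-remainder with zero pericentromeric quota", {
  expect_equal(unname(allocate_quota(part_1h, 131)), c(40, 7, 0, 18, 66))
  expect_equal(unname(allocate_quota(part_1h, 100)), c(31, 5, 0, 14, 50))
  expect_equal(unname(allocate_quota(part_1h, 0)), rep(0L, 5))
  zero <- chromosome_partition("zz", c(0, 1, 2, 3, 4, 5), c(0, 0, 5, 0, 0))
  expect_error(allocate_quota(zero, 10), "all-zero|apportion")
  set.seed(17)
  spans <- c(40, 7, 18, 66)
  for (budget in sample(0:5000, 400)) {
    q <- allocate_quota(part_1h, budget)
    expect_equal(sum(q), budget)
    exact <- spans / sum(spans) * budget
    expect_true(all(abs(q[c("short_high", "short_low", "long_low",
                            "long_high")] - exact) < 1))
    expect_equal(unname(q), unname(oracle_largest_remainder(
      setNames(c(40, 7, 0, 18, 66), part_1h$zone), budget)))
  }
})

test_that("stage B honours quotas, the 5H override, and cross-stage gene caps", {
  part_5h <- chromosome_partition("5H", c(0, 30e6, 60e6, 380e6, 470e6, 560e6),
                                  c(40, 7, 0, 18, 66))
  # a 5H short-arm candidate at score 0.7 / missing 0.10: only the override
  # thresholds admit it
  ov <- cand_frame("ov1", 0.7, 0.10, pos = 10e6, chrom = "5H")
  cfg <- selection_config(stage_b_budget = 5)
  res <- select_stage_b(ov, part_5h, cfg)
  expect_true("ov1" %in% res$selected$id)
  res_1h <- select_stage_b(cand_frame("ov2", 0.7, 0.10, pos = 10e6),
                           part_1h, cfg)
  expect_false("ov2" %in% res_1h$selected$id)

  # supply-limited zone reports shortfall instead of overfilling
  few <- cand_frame(c("s1", "s2", "s3"), 0.9, 0.01,
                    pos = c(1e6, 2e6, 3e6)) # all short_high
  res2 <- select_stage_b(few, part_1h, selection_config(stage_b_budget = 5))
  expect_equal(nrow(res2$selected), 3)
  expect_equal(unname(res2$shortfall["1H"]), 2)

  # cross-stage cap: gene with a stage-A pick gets at most 1 more in stage B
  gdf <- cand_frame(c("g1", "g2", "g3"), c(0.95, 0.9, 0.85), 0.01,
                    pos = c(1e6, 2e6, 3e6), gene = "GX")
  a <- gdf[1, , drop = FALSE]
  res3 <- select_stage_b(gdf, part_1h, selection_config(stage_b_budget = 5),
                         stage_a_selection = a)
  expect_equal(res3$selected$id, "g2") # one more allowed under cap 2
})

test_that("shortfall redistributes within the chromosome by genetic span", {
  # short_high has no qualifying SNPs; its quota must flow to the others
  df <- rbind(
    cand_frame(sprintf("lo%02d", 1:30), 0.95, 0.01, pos = seq(381e6, 410e6, 1e6)),
    cand_frame(sprintf("hi%02d", 1:60), 0.95, 0.01, pos = seq(471e6, 530e6, 1e6)))
  res <- select_stage_b(df, part_1h, selection_config(stage_b_budget = 40))
  expect_equal(nrow(res$selected), 40)
  expect_equal(unname(res$shortfall["1H"]), 0)
  expect_true(all(res$selected$zone %in% c("short_low", "long_low", "long_high")))
})

test_that("selection is deterministic and stages are disjoint", {
  spec <- toy_spec(seed = 21)
  ref <- make_reference(spec)
  gm <- make_gene_models(spec, ref$reference, ref$reserved)
  cand <- make_candidates(spec, gm$reference, gm$models)
  vars <- cand$candidates$variants; vars$zone <- NULL
  part <- make_partition(spec)
  cfg <- selection_config(stage_b_budget = 30)
  r1 <- select_markers(vars, part, cfg)
  r2 <- select_markers(vars, part, cfg)
  expect_identical(r1$combined$id, r2$combined$id)
  expect_equal(length(intersect(r1$stage_a$id, r1$stage_b$selected$id)), 0)
  expect_equal(nrow(r1$combined), nrow(r1$stage_a) + nrow(r1$stage_b$selected))
})

test_that("no selected SNP violates its thresholds and no gene exceeds its cap", {
  spec <- toy_spec(seed = 22, missing_rate_range = c(0, 0.1),
                   design_score_range = c(0.5, 1))
  ref <- make_reference(spec)
  gm <- make_gene_models(spec, ref$reference, ref$reserved)
  cand <- make_candidates(spec, gm$reference, gm$models)
  vars <- cand$candidates$variants; vars$zone <- NULL
  part <- make_partition(spec)
  res <- select_markers(vars, part, selection_config(stage_b_budget = 40))
  expect_true(all(res$stage_a$missing_rate <= 0.20 &
                    res$stage_a$design_score >= 0.6))
  b <- res$stage_b$selected
  for (i in seq_len(nrow(b))) {
    base <- !(b$chrom[i] == "5H" && b$zone[i] == "short_high")
    if (base) {
      expect_true(b$missing_rate[i] < 0.05 && b$design_score[i] > 0.8)
    } else {
      expect_true(b$missing_rate[i] < 0.20 && b$design_score[i] > 0.6)
    }
  }
  counts <- table(res$combined$gene_id[!is.na(res$combined$gene_id)])
  expect_true(all(counts <= 2))
})

test_that("design funnel arithmetic matches the printed-count identities", {
  fn <- design_funnel(stage_a = 16957, stage_b = 26091, duplicates = 732,
                      legacy = 6951, working = 44040, scorable = 43461)
  st <- setNames(fn$stages$count, fn$stages$stage)
  expect_equal(unname(st["pre_redundancy_total"]), 43048)
  expect_equal(unname(st["new_in_design"]), 42316)
  expect_equal(unname(st["final_design"]), 49267)
  expect_equal(fn$conversion$conversion_pct, 89.4)
  # filtering stages only remove: counts monotone through the funnel
  expect_true(st["new_in_design"] <= st["pre_redundancy_total"])
  expect_error(design_funnel(10, 10, duplicates = 30), "duplicates")
})

test_that("partition suggestion recovers planted breakpoints approximately", {
  set.seed(5)
  # piecewise-linear Marey map: steep-flat-very flat-flat-steep
  breaks <- c(0, 30e6, 60e6, 380e6, 470e6, 560e6)
  slopes <- c(40, 7, 2, 18, 66) / diff(breaks) # cM per bp
  pts <- sort(sample(seq(1e5, 560e6, 1e5), 160))
  gmap <- function(p) {
    cum <- cumsum(c(0, slopes * diff(breaks)))
    i <- findInterval(p, breaks, rightmost.closed = TRUE)
    cum[i] + (p - breaks[i]) * slopes[i]
  }
  anchors <- data.frame(chrom = "1H", marker_id = sprintf("m%03d", seq_along(pts)),
                        genetic_pos = gmap(pts) + rnorm(length(pts), 0, 0.3),
                        physical_pos = pts)
  sug <- suggest_partition(anchors, chrom_length = 560e6)
  expect_equal(nrow(sug), 5)
  expect_true(all(diff(c(sug$start_bp, 560e6)) > 0))
  # pericentromeric zone should cover the long flat middle
  peri <- sug[sug$zone == "pericentromeric", ]
  expect_lt(peri$start_bp, 120e6)
  expect_gt(peri$end_bp, 300e6)
})
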