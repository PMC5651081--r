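# Single-effect classifier: codon changes, splice sites, windows, severity.

test_that("standard genetic code translation", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("GCT"), "A")
  expect_equal(translate_codon(c("GCT", "CCT")), c("A", "P"))
  expect_error(translate_codon("ANG"), "ACGT")
})

test_that("coding, splice and window classes on a hand-built plus-strand gene", {
  set.seed(1)
  seqv <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  g <- gene_model("g1", "c1", "+",
                  rbind(c(6001, 6100), c(6151, 6240)),
                  rbind(c(6021, 6100), c(6151, 6220)))
  ref <- c(c1 = seqv)
  ref["c1"] <- panelforge:::inscribe_cds(ref["c1"], g)
  # scripted all-C 5' UTR so no substitution there can create an ATG
  substr(ref["c1"], 6001, 6020) <- strrep("C", 20)
  probe <- function(pos, alt = NULL) {
    rb <- substr(ref[["c1"]], pos, pos)
    if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
    annotate_effect(list(chrom = "c1", pos = pos, ref = rb, alt = alt),
                    list(g), ref)$effect
  }
  # codon arithmetic: third CDS base of codon 4 (wobble) vs second base
  # use explicit codon edits instead: GCx family at a known codon
  expect_equal(probe(6021, "C"), "start_lost")
  expect_equal(probe(6101), "splice_site_donor")      # intron base 1
  expect_equal(probe(6102), "splice_site_donor")      # intron base 2
  expect_equal(probe(6104), "splice_site_region")     # intron base 4
  expect_equal(probe(6110), "intron")                 # intron base 10
  expect_equal(probe(6148), "splice_site_region")     # 3 bases before exon 2
  expect_equal(probe(6149), "splice_site_acceptor")   # intron base -2
  expect_equal(probe(6150), "splice_site_acceptor")   # intron base -1
  expect_equal(probe(6010), "utr5")
  expect_equal(probe(6230), "utr3")
  expect_equal(probe(5000), "upstream")   # 1,001 bp 5' of the gene
  expect_equal(probe(7200), "downstream") # within the 5 kb window
  expect_equal(probe(300), "intergenic")  # 5,701 bp away: outside windows
  # stop codon at CDS end 6218-6220 is TAA
  expect_equal(substr(ref[["c1"]], 6218, 6220), "TAA")
  expect_equal(probe(6218, "C"), "stop_lost")
  expect_equal(probe(6220, "G"), "synonymous_stop")   # TAA -> TAG
})

test_that("codon substitutions classify by amino-acid change", {
  # micro-gene with a fully scripted CDS: ATG GCT TAC GGA TAA
  cds <- "ATGGCTTACGGATAA"
  left <- strrep("C", 30); right <- strrep("G", 30)
  ref <- c(c1 = paste0(left, cds, right))
  g <- gene_model("g1", "c1", "+", cbind(31L, 45L), cbind(31L, 45L))
  probe <- function(pos, alt) {
    rb <- substr(ref[["c1"]], pos, pos)
    annotate_effect(list(chrom = "c1", pos = pos, ref = rb, alt = alt),
                    list(g), ref)$effect
  }
  expect_equal(probe(36, "C"), "synonymous_coding")      # GCT -> GCC (Ala)
  expect_equal(probe(34, "C"), "non_synonymous_coding")  # GCT -> CCT (Ala->Pro)
  expect_equal(probe(39, "A"), "stop_gained")            # TAC -> TAA (Tyr->stop)
  expect_equal(probe(31, "C"), "start_lost")             # ATG -> CTG
})

test_that("classifier matches the exhaustive brute-force oracle on both strands", {
  for (strand in c("+", "-")) {
    toy <- make_toy_gene(seed = 5, strand = strand)
    g <- toy$model; ref <- toy$ref
    set.seed(99)
    positions <- seq(400, 1100) # spans upstream..downstream context
    for (pos in positions) {
      rb <- substr(ref[["c1"]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      got <- annotate_effect(list(chrom = "c1", pos = pos, ref = rb, alt = alt),
                             list(g), ref)$effect
      want <- oracle_effect(g, ref, pos, alt)
      if (got != want) {
        fail(sprintf("strand %s pos %d %s>%s: got %s, oracle %s",
                     strand, pos, rb, alt, got, want))
        break
      }
    }
    succeed()
  }
})

test_that("strand symmetry: reverse-complemented fixture gives identical labels", {
  toy <- make_toy_gene(seed = 8, strand = "+")
  g <- toy$model; ref <- toy$ref
  L <- nchar(ref[["c1"]])
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ref2 <- c(c1 = rc(ref[["c1"]]))
  flip <- function(x) L - x + 1
  g2 <- gene_model("gtoy", "c1", "-",
                   cbind(flip(g$exons[, 2]), flip(g$exons[, 1])),
                   cbind(flip(g$cds[, 2]), flip(g$cds[, 1])))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(12)
  for (pos in seq(450, 1050, by = 7)) {
    rb <- substr(ref[["c1"]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    e1 <- annotate_effect(list(chrom = "c1", pos = pos, ref = rb, alt = alt),
                          list(g), ref)$effect
    e2 <- annotate_effect(list(chrom = "c1", pos = flip(pos),
                               ref = comp[[rb]], alt = comp[[alt]]),
                          list(g2), ref2)$effect
    expect_equal(e2, e1, info = sprintf("pos %d", pos))
  }
})

test_that("effect spectrum sums to 100 within rounding and recovers planted counts", {
  labels <- c(rep("intron", 2), rep("synonymous_coding", 2))
  sp <- effect_spectrum(labels)
  expect_equal(sp$percent, c(50, 50))
  expect_equal(effect_spectrum("utr5")$percent, 100)
  planted <- rep(c("intron", "upstream", "stop_gained"), c(300, 150, 50))
  sp2 <- effect_spectrum(planted)
  expect_equal(sp2$percent[sp2$effect == "intron"], 60)
  expect_equal(sp2$percent[sp2$effect == "upstream"], 30)
  expect_equal(sp2$percent[sp2$effect == "stop_gained"], 10)
  expect_lt(abs(sum(sp2$percent) - 100), 0.05)
  expect_error(effect_spectrum(character(0)), "no annotated")
  # a 1/3 split rounds to 33.33 x3 = 99.99: still within the documented 0.05
  sp3 <- effect_spectrum(rep(c("intron", "utr3", "upstream"), 1))
  expect_lt(abs(sum(sp3$percent) - 100), 0.05)
})

test_that("overlapping genes resolve to the most severe effect deterministically", {
  cds <- "ATGGCTTACGGATAA"
  ref <- c(c1 = paste0(strrep("C", 30), cds, strrep("G", 30)))
  coding <- gene_model("gA", "c1", "+", cbind(31L, 45L), cbind(31L, 45L))
  hull <- gene_model("gB", "c1", "+", rbind(c(10L, 20L), c(60L, 70L))) # intron over the CDS
  res <- annotate_effect(list(chrom = "c1", pos = 34, ref = "G", alt = "C"),
                         list(hull, coding), ref)
  expect_equal(res$effect, "non_synonymous_coding")
  expect_equal(res$gene_id, "gA")
})
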