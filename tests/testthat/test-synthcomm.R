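test_that("community presets honour their contracts", {
  t1 <- generateCommunity(1, seed = 1, profile = "uniform")
  expect_equal(unname(cellAbundance(t1)), 1.0)
  expect_equal(unname(geneCopies(t1)[, "rpoB"]), 1)
  expect_equal(backgroundRpoB(t1), 0)

  ts <- generateCommunity(4, seed = 7, profile = "soil-like")
  tg <- trueGuildProportions(ts)
  expect_gt(tg["AOA"], tg["comammox"])
  expect_gt(tg["comammox"], tg["AOB"])
  expect_equal(unname(tg["AOA"]), 0.05)
  expect_equal(unname(tg["comammox"]), 0.002)
  expect_equal(unname(tg["AOB"]), 0.0002)
  expect_equal(unname(tg["background"]), 0.9478)
  # every lineage carries exactly one rpoB copy
  expect_true(all(geneCopies(ts)[, "rpoB"] == 1))

  expect_identical(generateCommunity(3, seed = 5, profile = "uniform"),
                   generateCommunity(3, seed = 5, profile = "uniform"))
  expect_identical(generateCommunity(5, seed = 2, profile = "soil-like"),
                   generateCommunity(5, seed = 2, profile = "soil-like"))
  expect_error(generateCommunity(3, seed = 1, profile = "swamp"),
               "unknown community profile")
  expect_error(generateCommunity(0, seed = 1), "positive integer")
})

test_that("expected counts follow the abundance-copies-length model", {
  # zero copies -> zero expectation
  tr <- single_lineage_truth(copies = c(rpoB = 1, amoA = 0),
                             rates = c(rpoB = 1, amoA = NA))
  expect_equal(expectedCount(tr, "L1", "amoA", "DNA", 1e6), 0)

  # doubling cell abundance doubles the expected count (two lineages
  # identical apart from abundance)
  lin <- data.frame(name = c("L1", "L2"), family = "NS-delta",
                    order = "Nitrososphaerales", guild = "AOA",
                    cell_abundance = c(1, 2))
  gc <- matrix(1, 2, 2, dimnames = list(lin$name, c("rpoB", "amoA")))
  er <- gc
  tr2 <- make_truth(lin, gc, er)
  expect_equal(expectedCount(tr2, "L2", "amoA", "DNA", 1e6),
               2 * expectedCount(tr2, "L1", "amoA", "DNA", 1e6))

  # a 1000 bp marker draws exactly twice the reads of a 500 bp marker
  tr3 <- single_lineage_truth(markers = c(rpoB = 1000, amoA = 500),
                              rates = c(rpoB = 1, amoA = 1))
  expect_equal(expectedCount(tr3, "L1", "rpoB", "DNA", 600),
               2 * expectedCount(tr3, "L1", "amoA", "DNA", 600))
  expect_equal(expectedCount(tr3, "L1", "rpoB", "DNA", 600), 400)

  # expectations across all features sum to depth
  ts <- generateCommunity(3, seed = 11, profile = "soil-like")
  feats <- expand.grid(l = c(lineageNames(ts), "background"),
                       m = markerNames(ts), stringsAsFactors = FALSE)
  tot <- sum(mapply(function(l, m)
    expectedCount(ts, l, m, "DNA", 1e6), feats$l, feats$m))
  expect_equal(tot, 1e6)

  expect_error(expectedCount(ts, "nobody", "amoA", "DNA", 1e6),
               "unknown lineage")
  expect_error(expectedCount(ts, "AOA-01", "mcrA", "DNA", 1e6),
               "unknown marker")
})

test_that("simulateCounts is deterministic and matches expectations", {
  ts <- generateCommunity(3, seed = 4, profile = "soil-like")
  expect_error(simulationConfig(0, 1e5), "positive integer")

  cfg <- simulationConfig(1e5, 2e5, seed = 42, mode = "expected")
  mc <- simulateCounts(ts, cfg)
  cts <- SummarizedExperiment::assay(mc, "counts")
  expect_equal(sum(cts[, 1]), 1e5)
  expect_equal(sum(cts[, 2]), 2e5)
  # expected-mode cell equals the closed-form expectation
  expect_equal(cts["AOA-01|amoA", 1],
               expectedCount(ts, "AOA-01", "amoA", "DNA", 1e5))
  expect_equal(cts["AOA-01|amoA", 2],
               expectedCount(ts, "AOA-01", "amoA", "RNA", 2e5))

  cfgS <- simulationConfig(1e5, 1e5, seed = 42, mode = "sampled")
  m1 <- simulateCounts(ts, cfgS)
  m2 <- simulateCounts(ts, cfgS)
  expect_identical(SummarizedExperiment::assay(m1, "counts"),
                   SummarizedExperiment::assay(m2, "counts"))
  expect_equal(colSums(SummarizedExperiment::assay(m1, "counts")),
               c(S1.DNA = 1e5, S1.RNA = 1e5))
  # the simulator must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulateCounts(ts, cfgS)); after <- runif(1)
  expect_identical(before, after)
})

test_that("scaling all cell abundances leaves proportions unchanged", {
  ts <- generateCommunity(3, seed = 8, profile = "soil-like")
  t2 <- CommunityTruth(
    transform(ts@lineages, cell_abundance = cell_abundance * 2),
    geneCopies(ts), expressionRates(ts),
    backgroundRpoB = 2 * backgroundRpoB(ts),
    markerLengths = markerLengths(ts))
  expect_equal(trueGuildProportions(ts), trueGuildProportions(t2))
  cfg <- simulationConfig(1e5, 1e5, seed = 1, mode = "expected")
  p1 <- estimateGuildProportions(simulateCounts(ts, cfg))
  p2 <- estimateGuildProportions(simulateCounts(t2, cfg))
  expect_equal(p1$proportion, p2$proportion)
})

test_that("emitted marker FASTA respects divergence bounds and labels", {
  ts <- generateCommunity(3, seed = 2, profile = "uniform")
  aa0 <- emitMarkerFasta(ts, "amoA", 3, divergence = 0, seed = 5)
  for (ln in unique(S4Vectors::mcols(aa0)$lineage)) {
    s <- as.character(aa0[S4Vectors::mcols(aa0)$lineage == ln])
    expect_length(unique(s), 1L)   # zero divergence: identical
  }

  aa <- emitMarkerFasta(ts, "amoA", 3, divergence = 0.05, seed = 5)
  expect_length(aa, 9L)
  lin <- S4Vectors::mcols(aa)$lineage
  seqs <- as.character(aa)
  within <- c(); between <- c()
  for (i in 1:(length(aa) - 1)) for (j in (i + 1):length(aa)) {
    id <- pairwiseIdentity(seqs[i], seqs[j])
    if (lin[i] == lin[j]) within <- c(within, id)
    else between <- c(between, id)
  }
  expect_true(all(within >= 0.95))
  expect_lt(max(between), min(within))
  # headers carry ground-truth lineage labels
  expect_identical(sub("\\|.*$", "", names(aa)), lin)

  # different seeds: different sequences, identical header structure
  aa2 <- emitMarkerFasta(ts, "amoA", 3, divergence = 0.05, seed = 6)
  expect_identical(names(aa), names(aa2))
  expect_false(identical(as.character(aa), as.character(aa2)))

  expect_error(emitMarkerFasta(ts, "amoA", 3, divergence = 1, seed = 1),
               "divergence")
})

test_that("truth tables round-trip through TSV", {
  ts <- generateCommunity(3, seed = 13, profile = "soil-like")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCommunityTruth(ts, f)
  expect_match(readLines(f, n = 1), "^# truth")
  back <- readCommunityTruth(f)
  expect_equal(cellAbundance(back), cellAbundance(ts))
  expect_equal(geneCopies(back), geneCopies(ts))
  expect_equal(expressionRates(back), expressionRates(ts))
  expect_equal(backgroundRpoB(back), backgroundRpoB(ts))
  expect_equal(markerLengths(back), markerLengths(ts))
})
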