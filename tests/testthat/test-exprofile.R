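test_that("lineage aggregation sums counts with weighted lengths", {
  ids <- c("p1", "p2", "p3")
  cnt <- cbind(S1.RNA = c(3, 7, 5))
  rownames(cnt) <- ids
  mc <- MarkerCounts(cnt,
    featureData = data.frame(
      lineage = c("L1", "L1", "L2"), marker = "amoA",
      length_bp = c(900, 1100, 600), n_members = c(1, 1, 1),
      row.names = ids),
    libraryData = data.frame(sample = "S1", molecule = "RNA",
                             total_reads = 15))
  agg <- lineageAggregate(mc)
  l1 <- agg[agg$lineage == "L1", ]
  expect_equal(l1$count, 10)             # additivity
  expect_equal(l1$length_bp, 1000)       # equal-member weighted mean
  expect_equal(l1$rpkm, rpkm(10, 1000, 15))
  # singleton lineage: aggregate equals the phylotype's own RPKM
  l2 <- agg[agg$lineage == "L2", ]
  expect_equal(l2$rpkm, rpkm(5, 600, 15))
  # member counts weight the representative length
  SummarizedExperiment::rowData(mc)$n_members <- c(3, 1, 1)
  agg2 <- lineageAggregate(mc)
  expect_equal(agg2$length_bp[agg2$lineage == "L1"],
               round(weighted.mean(c(900, 1100), c(3, 1))))
  # unmapped phylotype -> error naming the offender
  SummarizedExperiment::rowData(mc)$lineage <- c("L1", NA, "L2")
  expect_error(lineageAggregate(mc), "p2")
})

test_that("rpoB-normalized profiles encode ok/nd/absent states", {
  p <- rpobProfile(c(amoA = 8, ureC = 0, rpoB = 1), 1,
                   inventory = c(amoA = TRUE, ureC = TRUE,
                                 nirK = FALSE, rpoB = TRUE),
                   lineage = "L1")
  expect_equal(p@log2Ratio[["amoA"]], 3)      # log2(8)
  expect_equal(p@log2Ratio[["rpoB"]], 0)      # anchor maps to 0 exactly
  expect_identical(p@state[["ureC"]], "nd")   # present, no transcripts
  expect_identical(p@state[["nirK"]], "absent")
  # equal expression: log2 of 1
  q <- rpobProfile(c(amoA = 2.5), 2.5, c(amoA = TRUE), "L")
  expect_equal(q@log2Ratio[["amoA"]], 0)
  # counts on an inventory-absent gene warn but stay absent
  expect_warning(
    w <- rpobProfile(c(nirK = 4), 1, c(nirK = FALSE), "L"),
    "absent from the inventory")
  expect_identical(w@state[["nirK"]], "absent")
  # no rpoB transcripts -> profile unavailable
  u <- rpobProfile(c(amoA = 3), 0, c(amoA = TRUE), "L")
  expect_false(u@available)
})

test_that("profiles from expected-mode counts equal log2(copies x rate)", {
  tr <- single_lineage_truth(
    markers = c(rpoB = 3000, amoA = 650, nirK = 950, ureC = 1700),
    copies = c(rpoB = 1, amoA = 1, nirK = 2, ureC = 1),
    rates = c(rpoB = 1, amoA = 8, nirK = 4, ureC = 0.5),
    background = 1)
  mc <- simulateCounts(tr, simulationConfig(1e5, 1e5, seed = 1,
                                            mode = "expected"))
  prof <- expressionProfiles(mc)[["S1|L1"]]
  expect_equal(prof@log2Ratio[["rpoB"]], 0)
  expect_equal(prof@log2Ratio[["amoA"]], log2(8))
  expect_equal(prof@log2Ratio[["nirK"]], log2(2 * 4))
  expect_equal(prof@log2Ratio[["ureC"]], log2(0.5))
  # depth invariance: ratios cancel the totals
  mc2 <- simulateCounts(tr, simulationConfig(1e7, 1e7, seed = 1,
                                             mode = "expected"))
  prof2 <- expressionProfiles(mc2)[["S1|L1"]]
  expect_equal(prof@log2Ratio, prof2@log2Ratio)
})

test_that("fold differences and divergence flags follow the state rules", {
  soil <- rpobProfile(c(amoA = 4, ureC = 2, nirK = 0), 1,
                      c(amoA = TRUE, ureC = TRUE, nirK = TRUE), "soil")
  ref <- new("ExpressionProfile", lineage = "ref",
             log2Ratio = c(amoA = -2, ureC = NA, nirK = 0,
                           atpA = NA),
             state = c(amoA = "ok", ureC = "nd", nirK = "ok",
                       atpA = "absent"),
             available = TRUE)

  fd <- foldDifference(soil, ref, "amoA")
  expect_equal(fd$fold, 16)         # 2^(2 - (-2))
  expect_equal(fd$log2_delta, 4)
  # identity: same profile -> fold 1
  expect_equal(foldDifference(soil, soil, "amoA")$fold, 1)
  expect_identical(foldDifference(soil, ref, "ureC")$incomparable,
                   "reference_nd")
  expect_identical(foldDifference(soil, ref, "nirK")$incomparable,
                   "soil_nd")
  expect_error(foldDifference(soil, ref, "mcrA"), "unknown marker")

  flags <- flagDivergent(soil, ref, fold_cutoff = 10)
  expect_identical(flags$marker, "amoA")
  expect_identical(flags$direction, "higher_in_soil")
  inc <- attr(flags, "incomparable")
  expect_setequal(inc$marker, c("ureC", "nirK"))
  # within-cutoff folds are not flagged; reciprocal rule flags low side
  soil2 <- soil; soil2@log2Ratio[["amoA"]] <- -2 + log2(1 / 20)
  flags2 <- flagDivergent(soil2, ref, 10)
  expect_identical(flags2$direction, "lower_in_soil")
  expect_error(flagDivergent(soil, ref, 1), "fold_cutoff")
})

test_that("averaging across samples propagates nd only when universal", {
  p1 <- rpobProfile(c(amoA = 2, ureC = 0), 1,
                    c(amoA = TRUE, ureC = TRUE), "L")
  p2 <- rpobProfile(c(amoA = 8, ureC = 4), 1,
                    c(amoA = TRUE, ureC = TRUE), "L")
  p3 <- rpobProfile(c(amoA = 4, ureC = 0), 1,
                    c(amoA = TRUE, ureC = TRUE), "L")
  avg <- averageProfiles(list(p1, p2, p3))
  expect_equal(avg@log2Ratio[["amoA"]], mean(c(1, 3, 2)))
  expect_identical(avg@state[["ureC"]], "ok")  # numeric in one sample
  avg2 <- averageProfiles(list(p1, p3))
  expect_identical(avg2@state[["ureC"]], "nd") # nd everywhere
})

test_that("profile matrices round-trip with X and nd vocabulary", {
  soil <- rpobProfile(c(amoA = 4, ureC = 0), 1,
                      c(amoA = TRUE, ureC = TRUE, nirK = FALSE),
                      "NS-delta")
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- writeProfileMatrix(list(soil), f)
  expect_identical(m["nirK", 1], "X")
  expect_identical(m["ureC", 1], "nd")
  back <- readProfileMatrix(f)[["NS-delta"]]
  expect_equal(back@log2Ratio[["amoA"]], 2)
  expect_identical(back@state[["nirK"]], "absent")
  expect_identical(back@state[["ureC"]], "nd")
})

test_that("the shipped synthetic reference panel parses", {
  refs <- readProfileMatrix(system.file(
    "extdata", "reference_profiles_synthetic.tsv",
    package = "nitriquant"))
  expect_length(refs, 3L)
  expect_true(all(vapply(refs, function(p)
    p@log2Ratio[["rpoB"]] == 0, logical(1))))
  expect_identical(refs[[2]]@state[["nirK"]], "absent")
})
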