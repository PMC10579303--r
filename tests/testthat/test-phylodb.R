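test_that("pairwise identity matches hand-derived and enumerated values", {
  expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL"), 1.0)
  expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
  expect_equal(pairwiseIdentity("MKT", "MKTA"), 1.0)  # substring
  expect_error(pairwiseIdentity("", "MKT"), "non-empty")

  # exhaustive enumeration oracle on tiny random pairs
  set.seed(401)
  for (i in 1:40) {
    a <- random_aa(sample(2:6, 1), alphabet = AA20[1:4])
    b <- random_aa(sample(2:6, 1), alphabet = AA20[1:4])
    expect_equal(pairwiseIdentity(a, b), enum_align(a, b)$identity,
                 info = paste(a, b))
  }
  # symmetry
  set.seed(402)
  for (i in 1:20) {
    a <- random_aa(sample(5:25, 1)); b <- random_aa(sample(5:25, 1))
    expect_identical(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  }
})

test_that("alignment score agrees with Biostrings global alignment", {
  sub <- diag(1, length(AA20))
  dimnames(sub) <- list(AA20, AA20)
  set.seed(403)
  for (i in 1:25) {
    a <- random_aa(sample(5:30, 1), alphabet = AA20[1:6])
    b <- random_aa(sample(5:30, 1), alphabet = AA20[1:6])
    ours <- nitriquant:::.alignStats(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, ref, info = paste(a, b))
  }
})

test_that("greedy dereplication satisfies its contract", {
  # exact duplicates collapse
  aa <- Biostrings::AAStringSet(c(a = "MKTAYIAK", b = "MKTAYIAK",
                                  c = "MKTAYIAK"))
  ps <- dereplicate(aa, threshold = 1.0, marker = "amoA")
  expect_length(phylotypeIds(ps), 1L)
  expect_length(phylotypeMembers(ps)[[1]], 3L)

  # one substitution in a 10-mer: split at 1.0, merged at 0.8
  two <- Biostrings::AAStringSet(c(x = "ACDEFGHIKL", y = "ACDEFGHIKV"))
  expect_length(phylotypeIds(dereplicate(two, 1.0, "amoA")), 2L)
  expect_length(phylotypeIds(dereplicate(two, 0.8, "amoA")), 1L)

  # empty input -> empty output
  expect_length(phylotypeIds(dereplicate(Biostrings::AAStringSet(),
                                         1.0, "amoA")), 0L)
  # mixed markers rejected
  mm <- Biostrings::AAStringSet(c(a = "MKT", b = "MKT"))
  S4Vectors::mcols(mm) <- S4Vectors::DataFrame(marker = c("amoA",
                                                          "nirK"))
  expect_error(dereplicate(mm, 1.0), "mix markers")
})

test_that("dereplication matches the brute-force oracle and is order-invariant", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    seqs <- setNames(
      vapply(seq_len(n), function(i)
        random_aa(sample(6:12, 1), alphabet = AA20[1:3]),
        character(1)),
      sprintf("s%02d", seq_len(n)))
    thr <- sample(c(0.5, 0.7, 0.9, 1.0), 1)
    ps <- dereplicate(Biostrings::AAStringSet(seqs), thr, "m")
    oracle <- oracle_dereplicate(seqs, thr)
    expect_identical(unname(as.character(representatives(ps))),
                     oracle$representatives)
    expect_identical(unname(phylotypeMembers(ps)),
                     oracle$members)
    # member-to-representative identity property
    reps <- as.character(representatives(ps))
    for (p in seq_along(reps))
      for (mid in phylotypeMembers(ps)[[p]])
        expect_gte(pairwiseIdentity(seqs[[mid]], reps[p]), thr)
    # shuffling the input changes nothing
    sh <- sample(seq_along(seqs))
    ps2 <- dereplicate(Biostrings::AAStringSet(seqs[sh]), thr, "m")
    expect_identical(as.character(representatives(ps)),
                     as.character(representatives(ps2)))
    expect_identical(phylotypeMembers(ps), phylotypeMembers(ps2))
  }
  # threshold 1.0 on equal-length inputs == exact deduplication
  set.seed(405)
  seqs <- setNames(replicate(30, random_aa(6, AA20[1:2])),
                   sprintf("q%02d", 1:30))
  ps <- dereplicate(Biostrings::AAStringSet(seqs), 1.0, "m")
  expect_setequal(as.character(representatives(ps)), unique(seqs))
})

test_that("family assignment follows best identity with deterministic ties", {
  refs <- Biostrings::AAStringSet(c(refB = "ACDEFGHIKL",
                                    refA = "ACDEFGHIKV"))
  S4Vectors::mcols(refs) <- S4Vectors::DataFrame(
    marker = "amoA", source = "reference", family = c("FamB", "FamA"))

  # exact hit adopts the reference family at identity 1
  ps <- dereplicate(Biostrings::AAStringSet(c(s = "ACDEFGHIKL")), 1,
                    "amoA")
  ps <- assignFamily(ps, refs, min_identity = 0.85)
  expect_identical(unname(assignedFamily(ps)), "FamB")
  expect_equal(unname(bestRefIdentity(ps)), 1.0)

  # below the cutoff: unassigned, best identity still recorded
  far <- dereplicate(Biostrings::AAStringSet(c(s = "WWWWWGHIKL")), 1,
                     "amoA")
  far <- assignFamily(far, refs, min_identity = 0.70)
  expect_true(is.na(assignedFamily(far)))
  expect_equal(unname(bestRefIdentity(far)), 0.5)

  # exact tie between families: lexicographically smaller ref id wins
  tie <- dereplicate(Biostrings::AAStringSet(c(s = "ACDEFGHIKW")), 1,
                     "amoA")
  expect_message(tie <- assignFamily(tie, refs, min_identity = 0.85),
                 "tie")
  expect_identical(unname(assignedFamily(tie)), "FamA")  # refA < refB

  expect_error(assignFamily(ps, Biostrings::AAStringSet()), "empty")
  noFam <- refs; S4Vectors::mcols(noFam)$family <- NA_character_
  expect_error(assignFamily(ps, noFam), "family label")
})

test_that("phylotype families recover synthetic lineage labels exactly", {
  truth <- generateCommunity(5, seed = 3, profile = "uniform")
  aa <- emitMarkerFasta(truth, "amoA", 3, divergence = 0.04, seed = 21)
  refs <- emitMarkerFasta(truth, "amoA", 1, divergence = 0, seed = 21)
  ps <- dereplicate(aa, threshold = 0.97, marker = "amoA")
  ps <- assignFamily(ps, refs, min_identity = 0.85)
  # every phylotype's assigned family equals its members' true family
  fams <- S4Vectors::mcols(aa)$family
  names(fams) <- names(aa)
  for (p in seq_along(phylotypeIds(ps))) {
    member_fams <- unique(fams[phylotypeMembers(ps)[[p]]])
    expect_length(member_fams, 1L)
    expect_identical(unname(assignedFamily(ps)[p]),
                     unname(member_fams))
  }
})

test_that("phylotype tables are written with the documented schema", {
  aa <- Biostrings::AAStringSet(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  ps <- dereplicate(aa, 1.0, "amoA")
  f <- withr::local_tempfile(fileext = ".tsv")
  writePhylotypeTable(ps, f)
  tab <- read.delim(f)
  expect_named(tab, c("phylotype_id", "marker", "representative_id",
                      "n_members", "assigned_family",
                      "best_ref_identity"))
  expect_equal(tab$n_members, 2L)
  expect_identical(tab$representative_id, "a")
})
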