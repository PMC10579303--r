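## A small hand-built panel: 3 orders, 4 families, 6 genomes.
toy_matrix <- function() {
  genomes <- paste0("g", 1:6)
  tx <- data.frame(
    genome = genomes,
    order = c("O1", "O1", "O2", "O2", "O3", "O3"),
    family = c("F1", "F1", "F2", "F3", "F4", "F4"),
    stringsAsFactors = FALSE)
  p <- rbind(
    c1 = c(1, 1, 1, 1, 1, 1),  # universal -> core
    c2 = c(1, 0, 1, 0, 1, 0),  # one genome per order -> core
    c3 = c(1, 1, 1, 1, 0, 0),  # absent from O3 -> not core
    c4 = c(1, 1, 0, 0, 0, 0),  # two F1 genomes only -> F1-specific
    c5 = c(1, 0, 0, 0, 0, 0),  # one genome of 2-genome F1 -> not specific
    c6 = c(0, 0, 0, 1, 0, 0))  # singleton family F3, min 1 -> specific
  colnames(p) <- genomes
  ClusterMatrix(p, tx, annotated = c("c4"))
}

test_that("core classification requires presence in every order", {
  cm <- toy_matrix()
  expect_setequal(classifyCore(cm), c("c1", "c2"))
})

test_that("lineage-specific classification honours minimum genome counts", {
  cm <- toy_matrix()
  spec <- classifyLineageSpecific(cm)
  expect_setequal(spec$F1, "c4")            # 2 genomes, min 2
  expect_false("c5" %in% spec$F1)           # below minimum
  expect_setequal(spec$F3, "c6")            # singleton family, min 1
  expect_length(spec$F2, 0L)
  # explicit override: demand 2 genomes from the singleton family
  spec2 <- classifyLineageSpecific(cm, min_genomes = c(F3 = 2L))
  expect_length(spec2$F3, 0L)
  expect_error(classifyLineageSpecific(cm, min_genomes = c(FX = 1L)),
               "absent from the matrix")
})

test_that("summaries count specific and annotated clusters per family", {
  cm <- toy_matrix()
  sm <- summarizePancore(cm)
  expect_equal(sm$global$n_clusters, 6)
  expect_equal(sm$global$n_core, 2)
  f1 <- sm$families[sm$families$family == "F1", ]
  expect_equal(f1$n_specific, 1)
  expect_equal(f1$n_annotated, 1)
  # with >= 2 orders, core and specific sets are disjoint
  spec <- classifyLineageSpecific(cm)
  expect_length(intersect(classifyCore(cm), unlist(spec)), 0L)
  # degenerate single-order taxonomy is flagged
  tx1 <- cm@taxonomy; tx1$order <- "O1"
  cm1 <- ClusterMatrix(cm@presence, tx1)
  expect_warning(summarizePancore(cm1), "single-order")
})

test_that("classification matches the exhaustive set-logic oracle", {
  set.seed(801)
  for (i in 1:100) {
    cm <- random_cluster_matrix(n_clusters = sample(20:200, 1),
                                n_genomes = sample(5:30, 1),
                                n_orders = sample(1:4, 1),
                                n_families = sample(2:6, 1))
    expect_identical(classifyCore(cm),
                     oracle_core(cm@presence, cm@taxonomy))
    mins <- nitriquant:::.defaultMinGenomes(cm@taxonomy)
    expect_identical(classifyLineageSpecific(cm),
                     oracle_specific(cm@presence, cm@taxonomy,
                                     as.list(mins)))
  }
})

test_that("presence edits act monotonically on the partition", {
  set.seed(802)
  for (i in 1:20) {
    cm <- random_cluster_matrix(40, 12, 3, 4)
    core <- classifyCore(cm)
    # adding a presence never removes a cluster from the core
    p2 <- cm@presence
    cell <- c(sample(nrow(p2), 1), sample(ncol(p2), 1))
    p2[cell[1], cell[2]] <- TRUE
    cm2 <- ClusterMatrix(p2, cm@taxonomy, names(which(cm@annotated)))
    expect_true(all(core %in% classifyCore(cm2)))
    # adding a presence in another family removes lineage specificity
    spec <- classifyLineageSpecific(cm)
    for (f in names(spec)) {
      if (length(spec[[f]]) == 0) next
      cl <- spec[[f]][1]
      other <- which(cm@taxonomy$family != f)[1]
      p3 <- cm@presence; p3[cl, other] <- TRUE
      cm3 <- ClusterMatrix(p3, cm@taxonomy)
      expect_false(cl %in% classifyLineageSpecific(cm3)[[f]])
      break
    }
  }
})

test_that("cluster matrices load from TSV with taxonomy and annotation", {
  cm <- toy_matrix()
  d <- withr::local_tempdir()
  mfile <- file.path(d, "clusters.tsv")
  write.table(data.frame(cluster = rownames(cm@presence),
                         cm@presence + 0, check.names = FALSE),
              mfile, sep = "\t", quote = FALSE, row.names = FALSE)
  tfile <- file.path(d, "taxonomy.tsv")
  write.table(cm@taxonomy, tfile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  afile <- file.path(d, "annot.tsv")
  write.table(data.frame(cluster = "c4"), afile, sep = "\t",
              quote = FALSE, row.names = FALSE)
  back <- readClusterMatrix(mfile, tfile, afile)
  expect_identical(back@presence, cm@presence)
  expect_identical(back@annotated, cm@annotated)
  expect_setequal(classifyCore(back), classifyCore(cm))
})
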