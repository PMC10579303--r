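## Pipeline orchestration: config handling, staged execution into a run
## directory of TSVs, and table validation.

#' Default run configuration
#'
#' All tunable thresholds of the pipeline with their standard values:
#' dereplication identity 1.0 (0.8 for the hypervariable NirK), read
#' mapping at 0.90 identity / 0.60 query coverage, activity threshold at
#' the 1:1 line, 10-fold expression-divergence cutoff, and the
#' single-copy consistency band `[0.5, 2]`.
#'
#' @return Nested named list; see the fields of the returned object.
#' @examples
#' str(defaultRunConfig())
#' @export
defaultRunConfig <- function() {
  list(
    community = list(n_lineages = 4L, profile = "soil-like"),
    simulation = list(depth_dna = 1e6, depth_rna = 1e6, seed = 1L,
                      mode = "sampled"),
    thresholds = list(
      derep_identity = list(default = 1.0, nirK = 0.8),
      map_identity = 0.90,
      map_coverage = 0.60,
      family_min_identity = 0.85,
      activity_threshold = 1.0,
      fold_cutoff = 10,
      single_copy_band = c(0.5, 2)),
    copy_model = NULL,   # path to a copy-model TSV; NULL = defaults
    io = list(truth = NULL, counts = NULL)  # optional input paths
  )
}

#' Read a run configuration from YAML
#'
#' Keys missing from the file fall back to [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultRunConfig(), user)
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks every threshold against its documented range before any stage
#' runs; fails fast with the offending key.
#'
#' @param config config list.
#' @return The config, invisibly, or an error.
#' @export
validateRunConfig <- function(config) {
  th <- config$thresholds
  in01 <- function(x) is.numeric(x) && all(x > 0) && all(x <= 1)
  if (!in01(unlist(th$derep_identity)))
    stop("config error: derep_identity must lie in (0, 1]")
  if (!in01(th$map_identity))
    stop("config error: map_identity must lie in (0, 1]")
  if (!in01(th$map_coverage))
    stop("config error: map_coverage must lie in (0, 1]")
  if (!is.numeric(th$family_min_identity) ||
      th$family_min_identity < 0 || th$family_min_identity > 1)
    stop("config error: family_min_identity must lie in [0, 1]")
  if (!is.numeric(th$activity_threshold) || th$activity_threshold <= 0)
    stop("config error: activity_threshold must be positive")
  if (!is.numeric(th$fold_cutoff) || th$fold_cutoff <= 1)
    stop("config error: fold_cutoff must be > 1")
  band <- th$single_copy_band
  if (length(band) != 2L || band[1] <= 0 || band[1] > 1 || band[2] < 1)
    stop("config error: single_copy_band must bracket 1")
  sim <- config$simulation
  if (sim$depth_dna <= 0 || sim$depth_rna <= 0)
    stop("config error: sequencing depths must be positive")
  if (!sim$mode %in% c("sampled", "expected"))
    stop("config error: simulation mode must be sampled or expected")
  for (p in c(config$io$truth, config$io$counts, config$copy_model))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p)
  invisible(config)
}

## Deterministic config fingerprint (md5 of the canonical deparse).
.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[sort(names(config))]), tf)
  unname(tools::md5sum(tf))
}

#' Run the quantification pipeline into a directory of TSV outputs
#'
#' Executes the stages in dependency order — community (simulated from
#' the config or read from `io$truth`), DNA/RNA count tables (simulated
#' or read from `io$counts`), guild proportions, ureC prevalence,
#' phylotype activity, and per-lineage expression profiles — and writes
#' one TSV per stage.  Every output carries the config hash and seed in a
#' `#` comment header; re-running an identical config reproduces
#' byte-identical files.
#'
#' @param config config list (see [defaultRunConfig()],
#'   [readRunConfig()]).
#' @param outdir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
runQuantify <- function(config = defaultRunConfig(), outdir) {
  validateRunConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("# nitriquant quantify",
           paste0("# config_md5\t", .configHash(config)),
           paste0("# seed\t", config$simulation$seed))
  model <- if (is.null(config$copy_model)) defaultCopyModel()
           else readCopyModel(config$copy_model)

  truth <- if (!is.null(config$io$truth))
    readCommunityTruth(config$io$truth)
  else generateCommunity(config$community$n_lineages,
                         seed = config$simulation$seed,
                         profile = config$community$profile)
  mc <- if (!is.null(config$io$counts)) readCountTable(config$io$counts)
  else simulateCounts(truth,
                      simulationConfig(config$simulation$depth_dna,
                                       config$simulation$depth_rna,
                                       seed = config$simulation$seed,
                                       mode = config$simulation$mode))
  ## cross-validation before any output: every counted feature must be
  ## resolvable against the community's markers
  unknown <- setdiff(unique(markerNames(mc)), markerNames(truth))
  if (length(unknown) > 0)
    stop("validation error: counted marker(s) missing from the ",
         "community definition: ", paste(unknown, collapse = ", "))

  paths <- c(truth = file.path(outdir, "truth.tsv"),
             counts = file.path(outdir, "counts.tsv"),
             proportions = file.path(outdir, "proportions.tsv"),
             prevalence = file.path(outdir, "prevalence.tsv"),
             activity = file.path(outdir, "activity.tsv"),
             activity_families = file.path(outdir,
                                           "activity_families.tsv"),
             profiles = file.path(outdir, "profile_matrix.tsv"))

  writeCommunityTruth(truth, paths["truth"])
  writeCountTable(mc, paths["counts"], extra_header = hdr)

  props <- estimateGuildProportions(mc, model)
  .writeLines(c(hdr, "# proportion: cells per total prokaryote cells",
                .tsvLines(props)), paths["proportions"])

  prev <- genePrevalenceEstimate(mc, gene = "ureC", guild = "AOA")
  .writeLines(c(hdr, .tsvLines(prev)), paths["prevalence"])

  act <- activityTable(mc,
                       threshold = config$thresholds$activity_threshold)
  .writeLines(c(hdr, .tsvLines(act)), paths["activity"])
  fam <- classifyActivity(act,
                          threshold =
                            config$thresholds$activity_threshold)
  .writeLines(c(hdr, .tsvLines(fam)), paths["activity_families"])

  prof <- expressionProfiles(mc)
  writeProfileMatrix(prof, paths["profiles"])

  invisible(paths)
}

#' Validate pipeline tables
#'
#' Schema and invariant checks over written tables: required columns,
#' non-negative counts not exceeding library totals, recovery frequencies
#' summing to one per (sample, pool), and cross-references (every counted
#' feature known to the phylotype table when one is given).
#'
#' @param counts path to a count TSV ([writeCountTable()] schema).
#' @param activity optional path to an activity TSV.
#' @param phylotypes optional path to a phylotype TSV
#'   ([writePhylotypeTable()]).
#' @return data.frame report with columns `table`, `check`, `status`,
#'   `detail`; attribute `ok` is `TRUE` when no check failed.
#' @export
validateTables <- function(counts, activity = NULL, phylotypes = NULL) {
  rep_rows <- list()
  note <- function(tbl, check, status, detail = "") {
    rep_rows[[length(rep_rows) + 1L]] <<-
      data.frame(table = tbl, check = check, status = status,
                 detail = detail, stringsAsFactors = FALSE)
  }
  ## counts are checked on the raw table: the MarkerCounts constructor
  ## refuses invalid objects, so violations must be caught before it
  lines <- tryCatch(readLines(counts), error = function(e) e)
  df <- NULL
  if (!inherits(lines, "error")) {
    df <- tryCatch(read.delim(text = paste(lines[!grepl("^#", lines)],
                                           collapse = "\n"),
                              stringsAsFactors = FALSE),
                   error = function(e) e)
  }
  need <- c("feature_id", "lineage", "marker", "length_bp",
            "sample_id", "molecule", "count")
  if (inherits(lines, "error") || inherits(df, "error") ||
      !all(need %in% names(df))) {
    note("counts", "schema", "FAIL",
         if (is.data.frame(df))
           paste("missing columns:",
                 paste(setdiff(need, names(df)), collapse = ", "))
         else "unreadable table")
    df <- NULL
  } else {
    note("counts", "schema", "PASS")
    if (any(df$count < 0) || any(!is.finite(df$count)))
      note("counts", "non_negative", "FAIL",
           "negative or non-numeric counts present")
    else note("counts", "non_negative", "PASS")
    key <- paste(df$sample_id, df$molecule, sep = ".")
    totals <- tapply(df$count, key, sum)
    tl <- grep("^# total\t", lines, value = TRUE)
    if (length(tl) > 0) {
      parts <- do.call(rbind, strsplit(sub("^# total\t", "", tl),
                                       "\t"))
      totals[paste(parts[, 1], parts[, 2], sep = ".")] <-
        as.numeric(parts[, 3])
    }
    over <- unique(key[df$count > totals[key]])
    if (length(over) > 0)
      note("counts", "counts_le_totals", "FAIL",
           paste("count exceeds total in",
                 paste(over, collapse = ", ")))
    else note("counts", "counts_le_totals", "PASS")
  }
  if (!is.null(activity)) {
    act <- tryCatch(read.delim(activity, comment.char = "#",
                               stringsAsFactors = FALSE),
                    error = function(e) e)
    if (inherits(act, "error") ||
        !all(c("sample", "freq_dna", "freq_rna") %in% names(act))) {
      note("activity", "schema", "FAIL")
    } else {
      note("activity", "schema", "PASS")
      sums <- c(tapply(act$freq_dna, act$sample, sum),
                tapply(act$freq_rna, act$sample, sum))
      bad <- abs(sums - 1) > 1e-8 & sums != 0
      if (any(bad)) note("activity", "frequencies_sum_to_1", "FAIL",
                         "per-sample frequencies do not sum to 1")
      else note("activity", "frequencies_sum_to_1", "PASS")
    }
  }
  if (!is.null(phylotypes) && !is.null(df)) {
    pt <- tryCatch(read.delim(phylotypes, comment.char = "#",
                              stringsAsFactors = FALSE),
                   error = function(e) e)
    if (inherits(pt, "error") || !"phylotype_id" %in% names(pt)) {
      note("phylotypes", "schema", "FAIL")
    } else {
      note("phylotypes", "schema", "PASS")
      missing <- setdiff(unique(df$feature_id), pt$phylotype_id)
      if (length(missing) > 0)
        note("phylotypes", "counts_cross_reference", "FAIL",
             paste("features absent from phylotype table:",
                   paste(head(missing, 5), collapse = ", ")))
      else note("phylotypes", "counts_cross_reference", "PASS")
    }
  }
  report <- do.call(rbind, rep_rows)
  attr(report, "ok") <- !any(report$status == "FAIL")
  report
}
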