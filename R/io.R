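## Plain-text table I/O.  All tables are TSV, UTF-8, LF line endings,
## with `#`-prefixed metadata headers; numbers are written at full
## precision so re-runs are byte-identical.

.writeLines <- function(lines, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

.tsvLines <- function(df) {
  cells <- vapply(seq_len(ncol(df)), function(j) {
    x <- df[[j]]
    if (is.numeric(x)) format(x, digits = 15, trim = TRUE,
                              scientific = FALSE)
    else as.character(x)
  }, character(nrow(df))) |> base::matrix(nrow = nrow(df))
  c(paste(names(df), collapse = "\t"),
    apply(cells, 1, paste, collapse = "\t"))
}

#' Write a MarkerCounts table as TSV
#'
#' Long format with one row per (feature, library): columns `feature_id`,
#' `lineage`, `marker`, `length_bp`, `sample_id`, `molecule`, `count`
#' (plus `family` and `guild` when present).  Library totals are recorded
#' in `# total` comment lines so RPKM denominators survive the round
#' trip.
#'
#' @param mc a [MarkerCounts-class].
#' @param file output path.
#' @param extra_header optional character vector of additional `#` header
#'   lines (written verbatim).
#' @return `file`, invisibly.
#' @export
writeCountTable <- function(mc, file, extra_header = character(0)) {
  stopifnot(is(mc, "MarkerCounts"))
  rd <- as.data.frame(rowData(mc))
  cd <- as.data.frame(colData(mc))
  cts <- assay(mc, "counts")
  rows <- list()
  for (j in seq_len(ncol(cts))) {
    df <- data.frame(
      feature_id = rownames(cts),
      lineage = if ("lineage" %in% names(rd)) rd$lineage else NA,
      marker = rd$marker,
      length_bp = rd$length_bp,
      sample_id = cd$sample[j],
      molecule = cd$molecule[j],
      count = cts[, j],
      stringsAsFactors = FALSE)
    if ("family" %in% names(rd)) df$family <- rd$family
    if ("guild" %in% names(rd)) df$guild <- rd$guild
    rows[[j]] <- df
  }
  df <- do.call(rbind, rows)
  hdr <- c(extra_header,
           sprintf("# total\t%s\t%s\t%s", cd$sample, cd$molecule,
                   format(cd$total_reads, digits = 15, trim = TRUE,
                          scientific = FALSE)))
  .writeLines(c(hdr, .tsvLines(df)), file)
  invisible(file)
}

#' Read a MarkerCounts table written by [writeCountTable()]
#'
#' Also accepts externally produced tables with the same columns; library
#' totals default to per-library count sums when no `# total` lines are
#' present (appropriate when the table lists all mapped reads).
#'
#' @param file TSV path.
#' @return A [MarkerCounts-class].
#' @export
readCountTable <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  df <- read.delim(text = paste(lines[!grepl("^#", lines)],
                                collapse = "\n"),
                   stringsAsFactors = FALSE)
  need <- c("feature_id", "lineage", "marker", "length_bp", "sample_id",
            "molecule", "count")
  if (!all(need %in% names(df)))
    stop("count table misses columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  feats <- unique(df[, intersect(c("feature_id", "lineage", "marker",
                                   "family", "guild", "length_bp"),
                                 names(df))])
  if (anyDuplicated(feats$feature_id))
    stop("inconsistent feature metadata across libraries")
  rownames(feats) <- feats$feature_id
  libs <- unique(df[, c("sample_id", "molecule")])
  key <- function(s, m) paste(s, m, sep = ".")
  cnt <- base::matrix(0, nrow(feats), nrow(libs),
                      dimnames = list(feats$feature_id,
                                      key(libs$sample_id,
                                          libs$molecule)))
  cnt[cbind(df$feature_id, key(df$sample_id, df$molecule))] <- df$count
  totals <- colSums(cnt)
  tl <- grep("^# total\t", hdr, value = TRUE)
  if (length(tl) > 0) {
    parts <- do.call(rbind, strsplit(sub("^# total\t", "", tl), "\t"))
    totals[key(parts[, 1], parts[, 2])] <- as.numeric(parts[, 3])
  }
  MarkerCounts(cnt,
               featureData = feats[, setdiff(names(feats),
                                             "feature_id"),
                                   drop = FALSE],
               libraryData = data.frame(sample = libs$sample_id,
                                        molecule = libs$molecule,
                                        total_reads = unname(totals)))
}

#' Write a CommunityTruth as a TSV ground-truth table
#'
#' One row per lineage with `copies.<marker>` / `rate.<marker>` columns;
#' the background pool and marker lengths go into `# truth` comment
#' headers.
#'
#' @param truth a [CommunityTruth-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCommunityTruth <- function(truth, file) {
  lin <- truth@lineages
  gc <- truth@geneCopies
  er <- truth@expressionRates
  df <- cbind(lin,
              setNames(as.data.frame(gc),
                       paste0("copies.", colnames(gc))),
              setNames(as.data.frame(er), paste0("rate.", colnames(er))))
  hdr <- c("# truth",
           sprintf("# background_rpob\t%s",
                   format(truth@backgroundRpoB, digits = 15,
                          trim = TRUE)),
           sprintf("# length\t%s\t%s", names(truth@markerLengths),
                   format(truth@markerLengths, digits = 15,
                          trim = TRUE)))
  .writeLines(c(hdr, .tsvLines(df)), file)
  invisible(file)
}

#' Read a CommunityTruth written by [writeCommunityTruth()]
#'
#' @param file TSV path.
#' @return A [CommunityTruth-class].
#' @export
readCommunityTruth <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  df <- read.delim(text = paste(lines[!grepl("^#", lines)],
                                collapse = "\n"),
                   stringsAsFactors = FALSE)
  bg <- as.numeric(sub("^# background_rpob\t", "",
                       grep("^# background_rpob\t", hdr, value = TRUE)))
  ll <- strsplit(sub("^# length\t", "",
                     grep("^# length\t", hdr, value = TRUE)), "\t")
  ml <- setNames(as.numeric(vapply(ll, `[`, "", 2L)),
                 vapply(ll, `[`, "", 1L))
  markers <- names(ml)
  gc <- as.matrix(df[paste0("copies.", markers)])
  er <- as.matrix(df[paste0("rate.", markers)])
  colnames(gc) <- markers
  colnames(er) <- markers
  CommunityTruth(df[c("name", "family", "order", "guild",
                      "cell_abundance")],
                 gc, er, backgroundRpoB = bg, markerLengths = ml)
}

#' Write expression profiles as a heatmap-style matrix TSV
#'
#' Rows are markers, columns lineages/strains.  Numeric cells hold the
#' log2 rpoB-normalized ratio; `"X"` marks a gene absent from the
#' lineage, `"nd"` a gene present without detected transcripts.
#'
#' @param profiles named list of [ExpressionProfile-class] (names become
#'   columns; defaults to each profile's lineage).
#' @param file output path.
#' @param markers optional row order (default: union of profile markers).
#' @return The character matrix written, invisibly.
#' @export
writeProfileMatrix <- function(profiles, file, markers = NULL) {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) p@lineage, "")
  if (is.null(markers))
    markers <- Reduce(union, lapply(profiles, function(p)
      names(p@state)))
  m <- base::matrix("X", length(markers), length(profiles),
                    dimnames = list(markers, names(profiles)))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    for (mk in intersect(markers, names(p@state))) {
      m[mk, j] <- switch(p@state[[mk]],
                         ok = format(p@log2Ratio[[mk]], digits = 6,
                                     trim = TRUE),
                         nd = "nd",
                         absent = "X")
    }
  }
  df <- data.frame(marker = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeLines(.tsvLines(df), file)
  invisible(m)
}

#' Read a profile matrix TSV into ExpressionProfile objects
#'
#' Parses the cell vocabulary of [writeProfileMatrix()]: numbers, `"X"`
#' (absent) and `"nd"` (present, no transcripts).  Used for user-supplied
#' pure-culture reference profiles.
#'
#' @param file TSV path (first column `marker`, one column per
#'   lineage/strain).
#' @return Named list of [ExpressionProfile-class].
#' @export
readProfileMatrix <- function(file) {
  df <- read.delim(file, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  markers <- df[[1]]
  out <- list()
  for (col in names(df)[-1]) {
    cells <- as.character(df[[col]])
    state <- ifelse(cells == "X", "absent",
                    ifelse(cells == "nd", "nd", "ok"))
    val <- suppressWarnings(as.numeric(cells))
    val[state != "ok"] <- NA_real_
    if (any(state == "ok" & is.na(val)))
      stop("unparseable cell in column ", col)
    out[[col]] <- new("ExpressionProfile", lineage = col,
                      log2Ratio = setNames(val, markers),
                      state = setNames(state, markers),
                      available = TRUE)
  }
  out
}
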