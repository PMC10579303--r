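## Best-hit classification of peptide reads against the phylotype
## database: a dependency-free stand-in for a protein aligner, reproducing
## identity and query-coverage threshold semantics.

## All ungapped placements of `read` against `subject`; returns the best
## qualifying placement (highest identity, ties by more aligned residues,
## then smallest offset) or NULL.
.bestUngappedPlacement <- function(read_chars, subj_chars,
                                   min_identity, min_coverage) {
  lq <- length(read_chars)
  ls <- length(subj_chars)
  best <- NULL
  for (off in (1L - lq):(ls - 1L)) {
    j0 <- max(1L, 1L - off)
    j1 <- min(lq, ls - off)
    aligned <- j1 - j0 + 1L
    if (aligned < 1L) next
    matches <- sum(read_chars[j0:j1] == subj_chars[(j0:j1) + off])
    identity <- matches / aligned
    coverage <- aligned / lq
    if (identity < min_identity || coverage < min_coverage) next
    if (is.null(best) ||
        identity > best$identity ||
        (identity == best$identity && aligned > best$aligned)) {
      best <- list(identity = identity, coverage = coverage,
                   aligned = aligned, offset = off)
    }
  }
  best
}

#' Best-hit phylotype for one peptide read
#'
#' Scores every ungapped placement of the read against each phylotype
#' representative.  Identity is identical residues over aligned read
#' residues; coverage is aligned read residues over read length (query
#' coverage).  A hit must reach both `min_identity` and `min_coverage`;
#' among qualifying representatives the highest identity wins, ties going
#' to the lexicographically smallest phylotype id (flagged in the result).
#'
#' @param read amino-acid string.
#' @param db a [PhylotypeSet-class] (non-empty).
#' @param min_identity,min_coverage thresholds in `(0, 1]`; defaults 0.90
#'   and 0.60, the short-read protein-mapping thresholds the pipeline is
#'   built around.
#' @return A list with `phylotype` (id or `NA` if unmapped), `identity`,
#'   `coverage` and `tie` (logical).
#' @export
bestHit <- function(read, db, min_identity = 0.90, min_coverage = 0.60) {
  stopifnot(is(db, "PhylotypeSet"))
  if (length(db@representatives) == 0L)
    stop("phylotype database is empty")
  if (min_identity <= 0 || min_identity > 1 ||
      min_coverage <= 0 || min_coverage > 1)
    stop("thresholds must lie in (0, 1]")
  read <- as.character(read)
  if (!nzchar(read)) stop("read sequence must be non-empty")
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  ids <- phylotypeIds(db)
  ord <- order(ids, method = "radix")   # deterministic tie-break by id
  best <- list(phylotype = NA_character_, identity = NA_real_,
               coverage = NA_real_, tie = FALSE)
  for (i in ord) {
    sc <- strsplit(as.character(db@representatives[[i]]), "",
                   fixed = TRUE)[[1]]
    pl <- .bestUngappedPlacement(rc, sc, min_identity, min_coverage)
    if (is.null(pl)) next
    if (is.na(best$identity) || pl$identity > best$identity) {
      best <- list(phylotype = ids[i], identity = pl$identity,
                   coverage = pl$coverage, tie = FALSE)
    } else if (pl$identity == best$identity) {
      best$tie <- TRUE                  # earlier (smaller) id already kept
    }
  }
  best
}

#' Classify and count peptide reads against a phylotype database
#'
#' Runs [bestHit()] on every read and tallies counts per (sample,
#' molecule, phylotype).  Unmapped reads are tallied per library in
#' `metadata(result)$unmapped`, and the number of identity ties is in
#' `metadata(result)$ties`.  Per-library totals (the RPKM denominator)
#' equal the number of mapped reads.  Feature lengths are the
#' representatives' lengths in bp (3 x amino acids).
#'
#' @param reads an [Biostrings::AAStringSet] of peptide reads with mcols
#'   columns `sample` and `molecule` (`"DNA"`/`"RNA"`).
#' @param db a [PhylotypeSet-class].
#' @param min_identity,min_coverage thresholds passed to [bestHit()].
#' @return A [MarkerCounts-class]: phylotypes x libraries.
#' @export
countReads <- function(reads, db, min_identity = 0.90,
                       min_coverage = 0.60) {
  stopifnot(is(db, "PhylotypeSet"))
  if (length(db@representatives) == 0L)
    stop("phylotype database is empty")
  md <- mcols(reads)
  if (is.null(md$sample) || is.null(md$molecule))
    stop("reads need mcols 'sample' and 'molecule'")
  lib_key <- paste(md$sample, md$molecule, sep = ".")
  libs <- unique(data.frame(sample = as.character(md$sample),
                            molecule = as.character(md$molecule),
                            key = lib_key, stringsAsFactors = FALSE))
  libs <- libs[order(libs$key), , drop = FALSE]
  ids <- sort(phylotypeIds(db))
  cnt <- matrix(0, length(ids), nrow(libs),
                dimnames = list(ids, libs$key))
  unmapped <- setNames(rep(0L, nrow(libs)), libs$key)
  ties <- 0L
  for (i in seq_along(reads)) {
    hit <- bestHit(reads[[i]], db, min_identity, min_coverage)
    if (hit$tie) ties <- ties + 1L
    if (is.na(hit$phylotype)) {
      unmapped[lib_key[i]] <- unmapped[lib_key[i]] + 1L
    } else {
      cnt[hit$phylotype, lib_key[i]] <-
        cnt[hit$phylotype, lib_key[i]] + 1
    }
  }
  fam <- pset_family <- assignedFamily(db)[ids]
  fd <- data.frame(
    lineage = unname(fam), marker = db@marker,
    family = unname(fam), guild = NA_character_,
    length_bp = 3L * width(db@representatives)[match(ids,
                                                     phylotypeIds(db))],
    stringsAsFactors = FALSE)
  rownames(fd) <- ids
  mc <- MarkerCounts(cnt, fd,
                     data.frame(sample = libs$sample,
                                molecule = libs$molecule,
                                total_reads = colSums(cnt)))
  metadata(mc)$unmapped <- data.frame(sample = libs$sample,
                                      molecule = libs$molecule,
                                      n_unmapped = as.integer(unmapped))
  metadata(mc)$ties <- ties
  mc
}
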