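## Pangenome classification: core versus lineage-specific protein
## clusters from a presence/absence matrix with genome taxonomy.

#' Core protein clusters of a genome panel
#'
#' A cluster belongs to the core iff, for every order represented in the
#' genome panel, at least one genome of that order contains it.
#'
#' @param matrix a [ClusterMatrix-class].
#' @return Character vector of core cluster ids (matrix row order).
#' @export
classifyCore <- function(matrix) {
  stopifnot(is(matrix, "ClusterMatrix"))
  orders <- unique(matrix@taxonomy$order)
  ind <- vapply(orders, function(o)
    rowSums(matrix@presence[, matrix@taxonomy$order == o,
                            drop = FALSE]) > 0,
    logical(nrow(matrix@presence)))
  ind <- base::matrix(ind, nrow = nrow(matrix@presence))
  rownames(matrix@presence)[rowSums(ind) == length(orders)]
}

## Default per-family minimum genome counts: two genomes, relaxed to one
## for families represented by a single genome in the panel.
.defaultMinGenomes <- function(taxonomy) {
  sizes <- table(taxonomy$family)
  setNames(ifelse(sizes == 1L, 1L, 2L), names(sizes))
}

#' Lineage-specific protein clusters per family
#'
#' A cluster is specific to a family iff every genome containing it
#' belongs to that one family and the number of containing genomes
#' reaches the family's minimum (default 2; automatically 1 for families
#' with a single genome in the panel, the singleton-family exception).
#'
#' @param matrix a [ClusterMatrix-class].
#' @param min_genomes optional named integer vector family -> minimum;
#'   entries override the defaults.  Names must exist in the matrix.
#' @return Named list family -> character vector of specific cluster ids.
#' @export
classifyLineageSpecific <- function(matrix, min_genomes = NULL) {
  stopifnot(is(matrix, "ClusterMatrix"))
  fams <- unique(matrix@taxonomy$family)
  mins <- .defaultMinGenomes(matrix@taxonomy)
  if (!is.null(min_genomes)) {
    unknown <- setdiff(names(min_genomes), fams)
    if (length(unknown) > 0)
      stop("min_genomes names a family absent from the matrix: ",
           paste(unknown, collapse = ", "))
    mins[names(min_genomes)] <- min_genomes
  }
  total <- rowSums(matrix@presence)
  out <- list()
  for (f in fams) {
    inf <- rowSums(matrix@presence[, matrix@taxonomy$family == f,
                                   drop = FALSE])
    spec <- inf == total & inf >= mins[[f]]
    out[[f]] <- rownames(matrix@presence)[spec]
  }
  out
}

#' Summarize the pangenome partition
#'
#' Global totals (number of clusters, core size) and a per-family table of
#' lineage-specific cluster counts with the functionally annotated subset.
#' With only one order in the panel every order-universal cluster is
#' simultaneously core-eligible and potentially family-specific; that
#' degenerate taxonomy is flagged with a warning.
#'
#' @param matrix a [ClusterMatrix-class].
#' @param core optional precomputed core set ([classifyCore()]).
#' @param specific optional precomputed family map
#'   ([classifyLineageSpecific()]).
#' @return list with `global` (data.frame: `n_clusters`, `n_core`,
#'   `n_orders`, `n_families`) and `families` (data.frame: `family`,
#'   `n_specific`, `n_annotated`).
#' @export
summarizePancore <- function(matrix, core = NULL, specific = NULL) {
  stopifnot(is(matrix, "ClusterMatrix"))
  if (is.null(core)) core <- classifyCore(matrix)
  if (is.null(specific)) specific <- classifyLineageSpecific(matrix)
  orders <- unique(matrix@taxonomy$order)
  if (length(orders) == 1L)
    warning("single-order genome panel: core and lineage-specific sets ",
            "are not guaranteed disjoint")
  fams <- data.frame(
    family = names(specific),
    n_specific = vapply(specific, length, 1L),
    n_annotated = vapply(specific, function(cl)
      sum(matrix@annotated[cl]), 1L),
    stringsAsFactors = FALSE)
  rownames(fams) <- NULL
  list(global = data.frame(n_clusters = nrow(matrix@presence),
                           n_core = length(core),
                           n_orders = length(orders),
                           n_families = length(unique(
                             matrix@taxonomy$family))),
       families = fams)
}

#' Read a cluster presence/absence matrix with taxonomy
#'
#' @param matrix_path TSV: rows clusters, columns genomes, cells 0/1;
#'   first column holds cluster ids.
#' @param taxonomy_path TSV with columns `genome`, `order`, `family`.
#' @param annotation_path optional TSV with a `cluster` column listing
#'   functionally annotated clusters.
#' @return A [ClusterMatrix-class].
#' @export
readClusterMatrix <- function(matrix_path, taxonomy_path,
                              annotation_path = NULL) {
  m <- read.delim(matrix_path, row.names = 1, check.names = FALSE)
  tx <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
  ann <- NULL
  if (!is.null(annotation_path)) {
    at <- read.delim(annotation_path, stringsAsFactors = FALSE)
    ann <- as.character(at$cluster)
  }
  ClusterMatrix(as.matrix(m) > 0, tx, ann)
}
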