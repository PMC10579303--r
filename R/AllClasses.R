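## Central S4 containers.

#' CommunityTruth: ground truth of a synthetic nitrifier community
#'
#' Describes a synthetic multi-lineage community: per-lineage cell
#' abundances, gene inventories (per-cell copy numbers), per-gene
#' transcription rates, a background pool of non-target prokaryotes carrying
#' only *rpoB*, and marker gene lengths.  All downstream quantities (guild
#' proportions, expected read counts, expression ratios) are computable in
#' closed form from these fields, which is what makes the simulator usable
#' as ground truth.
#'
#' Invariants enforced by the validity method: every lineage carries exactly
#' one *rpoB* copy transcribed at the reference rate 1 (the single-copy
#' housekeeping anchor assumption); cell abundances are non-negative with at
#' least one positive; marker lengths are positive; a transcription rate is
#' defined for every marker a lineage encodes.
#'
#' @slot lineages data.frame with columns `name`, `family`, `order`,
#'   `guild`, `cell_abundance` (relative cell units), one row per lineage.
#' @slot geneCopies numeric matrix (lineage x marker) of per-cell gene copy
#'   numbers.  Fractional values are allowed and read as population means
#'   (e.g. 2.5 amoA copies per AOB cell).
#' @slot expressionRates numeric matrix (lineage x marker) of transcripts
#'   per gene copy relative to *rpoB* (which is fixed at 1).  `NA` where the
#'   gene is absent.
#' @slot backgroundRpoB single non-negative number: cell-unit abundance of
#'   the non-target prokaryote pool, modelled as a pseudo-lineage carrying
#'   only *rpoB*.
#' @slot markerLengths named numeric vector of marker gene lengths in bp.
#'
#' @seealso [generateCommunity()], [simulateCounts()],
#'   [trueGuildProportions()]
#' @exportClass CommunityTruth
setClass("CommunityTruth",
  slots = c(
    lineages        = "data.frame",
    geneCopies      = "matrix",
    expressionRates = "matrix",
    backgroundRpoB  = "numeric",
    markerLengths   = "numeric"
  )
)

setValidity("CommunityTruth", function(object) {
  lin <- object@lineages
  need <- c("name", "family", "order", "guild", "cell_abundance")
  if (!all(need %in% names(lin)))
    return(paste("lineages must have columns:", paste(need, collapse = ", ")))
  if (nrow(lin) < 1L) return("at least one lineage is required")
  if (anyDuplicated(lin$name)) return("lineage names must be unique")
  if (any(lin$cell_abundance < 0)) return("cell_abundance must be >= 0")
  if (!any(lin$cell_abundance > 0) && object@backgroundRpoB <= 0)
    return("at least one lineage (or the background) must have abundance > 0")
  ml <- object@markerLengths
  if (is.null(names(ml)) || any(!nzchar(names(ml))))
    return("markerLengths must be named")
  if (any(!is.finite(ml)) || any(ml <= 0))
    return("markerLengths must be strictly positive")
  if (!"rpoB" %in% names(ml)) return("markers must include rpoB")
  gc <- object@geneCopies
  er <- object@expressionRates
  if (!identical(dim(gc), dim(er)))
    return("geneCopies and expressionRates must have identical dimensions")
  if (!identical(rownames(gc), lin$name))
    return("geneCopies rows must match lineage names")
  if (!identical(sort(colnames(gc)), sort(names(ml))))
    return("geneCopies columns must match markerLengths names")
  if (any(gc < 0, na.rm = TRUE)) return("gene copies must be >= 0")
  if (any(abs(gc[, "rpoB"] - 1) > 0))
    return("every lineage must carry exactly one rpoB copy")
  if (any(abs(er[, "rpoB"] - 1) > 0, na.rm = TRUE) ||
      any(is.na(er[, "rpoB"])))
    return("rpoB expression rate is the reference and must equal 1")
  pos <- gc > 0
  if (any(is.na(er[pos])) || any(er[pos] < 0))
    return("expression rate must be a non-negative number wherever copies > 0")
  if (length(object@backgroundRpoB) != 1L || object@backgroundRpoB < 0)
    return("backgroundRpoB must be a single non-negative number")
  TRUE
})

#' Construct a CommunityTruth
#'
#' @param lineages data.frame with columns `name`, `family`, `order`,
#'   `guild`, `cell_abundance`.
#' @param geneCopies lineage x marker numeric matrix of per-cell copy
#'   numbers (rownames = lineage names).
#' @param expressionRates lineage x marker numeric matrix of transcripts per
#'   gene copy (rpoB = 1); `NA` where copies are 0.
#' @param backgroundRpoB cell-unit abundance of the non-target rpoB pool.
#' @param markerLengths named vector of marker lengths (bp).
#' @return A [CommunityTruth-class] object.
#' @examples
#' lin <- data.frame(name = "L1", family = "NS-delta",
#'                   order = "Nitrososphaerales", guild = "AOA",
#'                   cell_abundance = 1)
#' gc <- matrix(c(1, 1), 1, dimnames = list("L1", c("rpoB", "amoA")))
#' er <- matrix(c(1, 8), 1, dimnames = list("L1", c("rpoB", "amoA")))
#' CommunityTruth(lin, gc, er, 0, c(rpoB = 3000, amoA = 650))
#' @export
CommunityTruth <- function(lineages, geneCopies, expressionRates,
                           backgroundRpoB = 0,
                           markerLengths) {
  rownames(geneCopies) <- lineages$name
  rownames(expressionRates) <- lineages$name
  geneCopies <- geneCopies[, names(markerLengths), drop = FALSE]
  expressionRates <- expressionRates[, names(markerLengths), drop = FALSE]
  new("CommunityTruth",
      lineages = lineages, geneCopies = geneCopies,
      expressionRates = expressionRates,
      backgroundRpoB = as.numeric(backgroundRpoB),
      markerLengths = markerLengths)
}

#' MarkerCounts: sample x feature mapped-read counts for marker genes
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] carrying one
#' `counts` assay of mapped-read counts.  Rows are features (lineage-marker
#' pairs from the simulator, or phylotypes from read classification) with
#' row metadata `marker` and `length_bp` (plus `lineage`, `family` and
#' `guild` where known).  Columns are sequencing libraries with column
#' metadata `sample`, `molecule` (`"DNA"` or `"RNA"`) and `total_reads`
#' (total mapped reads, the RPKM denominator).
#'
#' @seealso [simulateCounts()], [countReads()], [rpkmMatrix()],
#'   [writeCountTable()]
#' @exportClass MarkerCounts
setClass("MarkerCounts", contains = "SummarizedExperiment")

setValidity("MarkerCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  rd <- rowData(object)
  if (!all(c("marker", "length_bp") %in% colnames(rd)))
    return("rowData must have columns marker and length_bp")
  if (any(rd$length_bp <= 0)) return("feature lengths must be positive")
  cd <- colData(object)
  if (!all(c("sample", "molecule", "total_reads") %in% colnames(cd)))
    return("colData must have columns sample, molecule, total_reads")
  if (!all(cd$molecule %in% c("DNA", "RNA")))
    return("molecule must be 'DNA' or 'RNA'")
  if (any(cd$total_reads < 0)) return("total_reads must be >= 0")
  cts <- assay(object, "counts")
  if (any(cts < 0)) return("counts must be non-negative")
  over <- sweep(cts, 2, cd$total_reads, `>`)
  if (any(over)) return("no count may exceed its library's total_reads")
  TRUE
})

#' Construct a MarkerCounts object
#'
#' @param counts numeric matrix, features x libraries.
#' @param featureData data.frame of row metadata; must contain `marker` and
#'   `length_bp`; `lineage`, `family`, `guild` are used by downstream
#'   summaries when present.
#' @param libraryData data.frame of column metadata with `sample`,
#'   `molecule` and `total_reads`.
#' @return A [MarkerCounts-class] object.
#' @export
MarkerCounts <- function(counts, featureData, libraryData) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(libraryData$sample, libraryData$molecule,
                              sep = ".")
  se <- SummarizedExperiment(
    assays  = list(counts = counts),
    rowData = DataFrame(featureData, row.names = rownames(counts)),
    colData = DataFrame(libraryData, row.names = colnames(counts)))
  new("MarkerCounts", se)
}

#' PhylotypeSet: dereplicated marker protein phylotypes
#'
#' The product of greedy identity-threshold dereplication of one marker's
#' protein sequences.  Each phylotype is represented by its longest member
#' sequence; all members match the representative at or above the
#' dereplication threshold.
#'
#' @slot marker single marker label shared by all phylotypes.
#' @slot threshold the dereplication identity threshold used.
#' @slot representatives [Biostrings::AAStringSet] of representative
#'   sequences; names are phylotype ids.
#' @slot members named list: phylotype id -> character vector of member
#'   record ids (the representative's id included).
#' @slot assignedFamily named character: family from reference panel
#'   assignment, `NA` where unassigned.
#' @slot bestRefIdentity named numeric: identity to the best reference,
#'   `NA` before assignment.
#' @seealso [dereplicate()], [assignFamily()]
#' @exportClass PhylotypeSet
setClass("PhylotypeSet",
  slots = c(
    marker          = "character",
    threshold       = "numeric",
    representatives = "AAStringSet",
    members         = "list",
    assignedFamily  = "character",
    bestRefIdentity = "numeric"
  )
)

setValidity("PhylotypeSet", function(object) {
  n <- length(object@representatives)
  ids <- names(object@representatives)
  if (n > 0 && (is.null(ids) || anyDuplicated(ids)))
    return("representatives must have unique names (phylotype ids)")
  if (length(object@members) != n ||
      (n > 0 && !identical(names(object@members), ids)))
    return("members must be a list named by phylotype id")
  if (n > 0 && any(vapply(object@members, length, 1L) < 1L))
    return("every phylotype must have at least one member")
  if (length(object@assignedFamily) != n ||
      length(object@bestRefIdentity) != n)
    return("assignedFamily and bestRefIdentity must have one entry per phylotype")
  if (length(object@marker) != 1L) return("marker must be a single label")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  TRUE
})

#' ClusterMatrix: protein-cluster presence/absence across genomes
#'
#' Binary presence of protein clusters in a genome panel, with per-genome
#' order/family taxonomy and an optional per-cluster functional-annotation
#' flag.  Input to the pangenome core / lineage-specific classification.
#'
#' @slot presence logical matrix, clusters x genomes.
#' @slot taxonomy data.frame with columns `genome`, `order`, `family`;
#'   one row per genome, same order as the matrix columns.
#' @slot annotated named logical vector, one entry per cluster.
#' @seealso [classifyCore()], [classifyLineageSpecific()],
#'   [summarizePancore()]
#' @exportClass ClusterMatrix
setClass("ClusterMatrix",
  slots = c(
    presence = "matrix",
    taxonomy = "data.frame",
    annotated = "logical"
  )
)

setValidity("ClusterMatrix", function(object) {
  p <- object@presence
  tx <- object@taxonomy
  if (!is.logical(p)) return("presence must be a logical matrix")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("presence must have cluster rownames and genome colnames")
  if (!all(c("genome", "order", "family") %in% names(tx)))
    return("taxonomy needs columns genome, order, family")
  if (!identical(tx$genome, colnames(p)))
    return("taxonomy rows must match presence columns (same order)")
  if (any(!nzchar(tx$order)) || any(!nzchar(tx$family)) ||
      any(is.na(tx$order)) || any(is.na(tx$family)))
    return("every genome needs non-empty order and family labels")
  if (any(rowSums(p) == 0))
    return("every cluster must be present in at least one genome")
  if (length(object@annotated) != nrow(p) ||
      !identical(names(object@annotated), rownames(p)))
    return("annotated must be named by cluster, one entry per cluster")
  TRUE
})

#' Construct a ClusterMatrix
#'
#' @param presence matrix (0/1 or logical), clusters x genomes, with
#'   dimnames.
#' @param taxonomy data.frame with columns `genome`, `order`, `family`.
#'   Rows are matched to the matrix columns by genome id.
#' @param annotated logical vector named by cluster id (default: all
#'   `FALSE`), or a character vector of annotated cluster ids.
#' @return A [ClusterMatrix-class] object.
#' @export
ClusterMatrix <- function(presence, taxonomy, annotated = NULL) {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  taxonomy <- taxonomy[match(colnames(presence), taxonomy$genome), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  if (is.null(annotated)) {
    annotated <- setNames(rep(FALSE, nrow(presence)), rownames(presence))
  } else if (is.character(annotated)) {
    annotated <- setNames(rownames(presence) %in% annotated,
                          rownames(presence))
  } else {
    annotated <- setNames(as.logical(annotated)[seq_len(nrow(presence))],
                          rownames(presence))
  }
  new("ClusterMatrix", presence = presence, taxonomy = taxonomy,
      annotated = annotated)
}

#' ExpressionProfile: rpoB-normalized expression states of one lineage
#'
#' Per-marker expression of a lineage (or pure-culture strain), normalized
#' to its own *rpoB* transcript abundance and log2-transformed.  Each
#' marker carries one of three states: `"ok"` (a finite log2 ratio),
#' `"absent"` (gene not in the lineage's inventory; rendered `"X"` in
#' tables) or `"nd"` (gene present but no transcripts detected).
#'
#' @slot lineage lineage or strain label.
#' @slot log2Ratio named numeric: log2(marker RPKM / rpoB RPKM); `NA` where
#'   the state is not `"ok"`.
#' @slot state named character: `"ok"`, `"absent"` or `"nd"`.
#' @slot available `FALSE` when the lineage had no rpoB transcripts, in
#'   which case the whole profile is unusable.
#' @seealso [rpobProfile()], [foldDifference()], [writeProfileMatrix()]
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  slots = c(
    lineage   = "character",
    log2Ratio = "numeric",
    state     = "character",
    available = "logical"
  )
)

setValidity("ExpressionProfile", function(object) {
  if (length(object@lineage) != 1L) return("lineage must be a single label")
  if (!identical(names(object@log2Ratio), names(object@state)))
    return("log2Ratio and state must be named identically")
  if (!all(object@state %in% c("ok", "absent", "nd")))
    return("states must be 'ok', 'absent' or 'nd'")
  ok <- object@state == "ok"
  if (object@available[1]) {
    if (any(!is.finite(object@log2Ratio[ok])))
      return("log2 ratios must be finite where state is 'ok'")
    if (any(!is.na(object@log2Ratio[!ok])))
      return("log2 ratios must be NA where state is not 'ok'")
  }
  TRUE
})

#' SimulationConfig: sequencing-depth and noise settings for the simulator
#'
#' @slot depthDNA,depthRNA total mapped reads per molecule type.
#' @slot seed integer seed; identical (truth, config) pairs reproduce
#'   byte-identical outputs.
#' @slot mode `"sampled"` draws a multinomial of size depth over features
#'   (conditioning on total depth, matching the "per million mapped reads"
#'   normalization); `"expected"` returns noise-free expectations, which
#'   are generally non-integer.
#' @seealso [simulationConfig()], [simulateCounts()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(depthDNA = "numeric", depthRNA = "numeric",
            seed = "integer", mode = "character"))

#' Create a SimulationConfig
#'
#' @param depth_dna,depth_rna positive integer total mapped reads.
#' @param seed integer seed.
#' @param mode `"sampled"` or `"expected"`.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(1e6, 1e6, seed = 1)
#' @export
simulationConfig <- function(depth_dna, depth_rna, seed = 1L,
                             mode = c("sampled", "expected")) {
  mode <- match.arg(mode)
  if (length(depth_dna) != 1L || !is.finite(depth_dna) || depth_dna <= 0 ||
      depth_dna != round(depth_dna))
    stop("depth_dna must be a positive integer")
  if (length(depth_rna) != 1L || !is.finite(depth_rna) || depth_rna <= 0 ||
      depth_rna != round(depth_rna))
    stop("depth_rna must be a positive integer")
  new("SimulationConfig", depthDNA = as.numeric(depth_dna),
      depthRNA = as.numeric(depth_rna), seed = as.integer(seed),
      mode = mode)
}
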