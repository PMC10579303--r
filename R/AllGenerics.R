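## Generics and accessor methods for the package classes.

#' @name accessors
#' @title Accessors for nitriquant classes
#' @description Small accessor generics: slot access stays behind these
#'   functions so the internal representation can change without breaking
#'   user code.
#' @param x a nitriquant object.
#' @return The corresponding component (see individual functions).
NULL

#' @describeIn accessors lineage names of a `CommunityTruth`, or the
#'   lineage labels of count features.
#' @export
setGeneric("lineageNames", function(x) standardGeneric("lineageNames"))

#' @describeIn accessors marker labels.
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @describeIn accessors named vector of relative cell abundances.
#' @export
setGeneric("cellAbundance", function(x) standardGeneric("cellAbundance"))

#' @describeIn accessors lineage x marker matrix of per-cell gene copies.
#' @export
setGeneric("geneCopies", function(x) standardGeneric("geneCopies"))

#' @describeIn accessors lineage x marker matrix of transcription rates.
#' @export
setGeneric("expressionRates",
           function(x) standardGeneric("expressionRates"))

#' @describeIn accessors abundance of the background (non-target) rpoB pool.
#' @export
setGeneric("backgroundRpoB", function(x) standardGeneric("backgroundRpoB"))

#' @describeIn accessors named vector of marker gene lengths (bp).
#' @export
setGeneric("markerLengths", function(x) standardGeneric("markerLengths"))

#' @describeIn accessors per-library total mapped reads.
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @describeIn accessors per-library molecule type ("DNA"/"RNA").
#' @export
setGeneric("moleculeType", function(x) standardGeneric("moleculeType"))

#' @describeIn accessors phylotype ids of a `PhylotypeSet`.
#' @export
setGeneric("phylotypeIds", function(x) standardGeneric("phylotypeIds"))

#' @describeIn accessors representative sequences of a `PhylotypeSet`.
#' @export
setGeneric("representatives",
           function(x) standardGeneric("representatives"))

#' @describeIn accessors member-id list of a `PhylotypeSet`.
#' @export
setGeneric("phylotypeMembers",
           function(x) standardGeneric("phylotypeMembers"))

#' @describeIn accessors assigned family labels of a `PhylotypeSet`.
#' @export
setGeneric("assignedFamily", function(x) standardGeneric("assignedFamily"))

#' @describeIn accessors best reference identities of a `PhylotypeSet`.
#' @export
setGeneric("bestRefIdentity",
           function(x) standardGeneric("bestRefIdentity"))

setMethod("lineageNames", "CommunityTruth",
          function(x) x@lineages$name)
setMethod("markerNames", "CommunityTruth",
          function(x) names(x@markerLengths))
setMethod("cellAbundance", "CommunityTruth",
          function(x) setNames(x@lineages$cell_abundance, x@lineages$name))
setMethod("geneCopies", "CommunityTruth", function(x) x@geneCopies)
setMethod("expressionRates", "CommunityTruth",
          function(x) x@expressionRates)
setMethod("backgroundRpoB", "CommunityTruth",
          function(x) x@backgroundRpoB)
setMethod("markerLengths", "CommunityTruth", function(x) x@markerLengths)

setMethod("libraryTotals", "MarkerCounts",
          function(x) setNames(colData(x)$total_reads, colnames(x)))
setMethod("moleculeType", "MarkerCounts",
          function(x) setNames(as.character(colData(x)$molecule),
                               colnames(x)))
setMethod("markerNames", "MarkerCounts",
          function(x) as.character(rowData(x)$marker))
setMethod("lineageNames", "MarkerCounts", function(x) {
  rd <- rowData(x)
  if ("lineage" %in% colnames(rd)) as.character(rd$lineage)
  else rep(NA_character_, nrow(x))
})

setMethod("phylotypeIds", "PhylotypeSet",
          function(x) names(x@representatives))
setMethod("representatives", "PhylotypeSet",
          function(x) x@representatives)
setMethod("phylotypeMembers", "PhylotypeSet", function(x) x@members)
setMethod("assignedFamily", "PhylotypeSet", function(x) x@assignedFamily)
setMethod("bestRefIdentity", "PhylotypeSet",
          function(x) x@bestRefIdentity)
setMethod("markerNames", "PhylotypeSet", function(x) x@marker)

setMethod("show", "CommunityTruth", function(object) {
  cat("CommunityTruth with", nrow(object@lineages), "lineage(s) and",
      length(object@markerLengths), "marker(s)\n")
  cat("  markers:", paste(names(object@markerLengths), collapse = ", "),
      "\n")
  tot <- sum(object@lineages$cell_abundance) + object@backgroundRpoB
  cat(sprintf("  background rpoB pool: %.4g (%.2f%% of cells)\n",
              object@backgroundRpoB,
              100 * object@backgroundRpoB / tot))
  guilds <- tapply(object@lineages$cell_abundance,
                   object@lineages$guild, sum)
  for (g in names(guilds))
    cat(sprintf("  %s: %.4g cell units (%d lineages)\n", g, guilds[[g]],
                sum(object@lineages$guild == g)))
  invisible(NULL)
})

setMethod("show", "PhylotypeSet", function(object) {
  n <- length(object@representatives)
  cat("PhylotypeSet:", n, "phylotype(s) for marker", object@marker,
      sprintf("(dereplication threshold %.3g)\n", object@threshold))
  if (n > 0) {
    nm <- sum(vapply(object@members, length, 1L))
    cat("  members:", nm, "sequences;",
        sum(!is.na(object@assignedFamily)), "phylotype(s) with family\n")
  }
  invisible(NULL)
})

setMethod("show", "ClusterMatrix", function(object) {
  cat("ClusterMatrix:", nrow(object@presence), "clusters x",
      ncol(object@presence), "genomes\n")
  cat("  orders:",
      paste(unique(object@taxonomy$order), collapse = ", "), "\n")
  cat("  families:",
      paste(unique(object@taxonomy$family), collapse = ", "), "\n")
  cat("  annotated clusters:", sum(object@annotated), "\n")
  invisible(NULL)
})

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile for", object@lineage)
  if (!object@available[1]) {
    cat(" (unavailable: no rpoB transcripts)\n")
    return(invisible(NULL))
  }
  cat(":", sum(object@state == "ok"), "expressed,",
      sum(object@state == "nd"), "nd,",
      sum(object@state == "absent"), "absent\n")
  invisible(NULL)
})
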