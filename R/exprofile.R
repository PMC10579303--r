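## Per-lineage rpoB-normalized expression profiles: lineage aggregation,
## log2 profile construction with absent/"nd" states, and fold comparison
## against pure-culture reference profiles.

#' Aggregate phylotype counts to (lineage, marker) level
#'
#' Phylotype counts are summed within each (lineage, marker) pair before
#' RPKM conversion; the aggregate's representative gene length is the
#' member-count-weighted mean of the phylotype lengths, rounded to the
#' nearest bp.
#'
#' @param mc a [MarkerCounts-class] (typically RNA libraries of phylotype
#'   counts).
#' @param lineage_map optional named character vector phylotype -> lineage;
#'   defaults to the `lineage` row metadata.  Every counted phylotype must
#'   map to a lineage.
#' @param n_members optional named integer vector of per-phylotype member
#'   counts used as length weights (default 1 each, or the `n_members`
#'   row metadata when present).
#' @param molecule which libraries to aggregate.
#' @return data.frame with columns `sample`, `lineage`, `marker`, `count`,
#'   `length_bp`, `rpkm`.
#' @export
lineageAggregate <- function(mc, lineage_map = NULL, n_members = NULL,
                             molecule = "RNA") {
  stopifnot(is(mc, "MarkerCounts"))
  rd <- rowData(mc)
  ids <- rownames(mc)
  if (is.null(lineage_map)) {
    if (!"lineage" %in% colnames(rd))
      stop("no lineage_map given and no 'lineage' row metadata")
    lineage_map <- setNames(as.character(rd$lineage), ids)
  }
  lin <- lineage_map[ids]
  bad <- ids[is.na(lin) | !nzchar(lin)]
  if (length(bad) > 0)
    stop("phylotype(s) without a lineage: ", paste(bad, collapse = ", "))
  if (is.null(n_members)) {
    n_members <- if ("n_members" %in% colnames(rd))
      setNames(as.integer(rd$n_members), ids)
    else setNames(rep(1L, length(ids)), ids)
  }
  w <- n_members[ids]
  cts <- assay(mc, "counts")
  keep <- which(moleculeType(mc) == molecule)
  tot <- libraryTotals(mc)
  out <- list()
  for (j in keep) {
    key <- paste(lin, rd$marker, sep = "\r")
    agg_count <- tapply(cts[, j], key, sum)
    agg_len <- tapply(seq_along(ids), key, function(ii)
      round(weighted.mean(rd$length_bp[ii], w[ii])))
    parts <- strsplit(names(agg_count), "\r", fixed = TRUE)
    out[[colnames(mc)[j]]] <- data.frame(
      sample = colData(mc)$sample[j],
      lineage = vapply(parts, `[`, "", 1L),
      marker = vapply(parts, `[`, "", 2L),
      count = unname(agg_count),
      length_bp = unname(agg_len),
      rpkm = unname(rpkm(agg_count, agg_len, tot[j])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample, res$lineage, res$marker), , drop = FALSE]
}

#' Build an rpoB-normalized expression profile for one lineage
#'
#' Numeric entries are `log2(marker RPKM / rpoB RPKM)` — no pseudocounts.
#' A marker absent from the lineage's gene inventory is state `"absent"`
#' regardless of counts (counts for an absent gene raise an inconsistency
#' warning); a present marker with zero RPKM is `"nd"` (present, no
#' transcripts detected).  A lineage with no rpoB transcripts yields a
#' profile marked unavailable.
#'
#' @param lineage_rpkm named numeric: marker -> RPKM for the lineage (may
#'   include an `rpoB` entry, which then must equal `rpob_rpkm`).
#' @param rpob_rpkm the lineage's rpoB RPKM.
#' @param inventory named logical (or `"present"`/`"absent"` character)
#'   giving the lineage's gene inventory; markers missing from
#'   `inventory` default to present when they have RPKM, absent otherwise.
#' @param lineage lineage label.
#' @return An [ExpressionProfile-class].
#' @examples
#' rpobProfile(c(amoA = 8, ureC = 0), 1, c(amoA = TRUE, ureC = TRUE,
#'             nirK = FALSE), "NS-delta")
#' @export
rpobProfile <- function(lineage_rpkm, rpob_rpkm, inventory = NULL,
                        lineage = "lineage") {
  if (is.character(inventory)) inventory <- inventory == "present"
  markers <- union(names(lineage_rpkm), names(inventory))
  markers <- union(markers, "rpoB")
  val <- setNames(rep(NA_real_, length(markers)), markers)
  state <- setNames(rep("ok", length(markers)), markers)
  rk <- setNames(rep(0, length(markers)), markers)
  rk[names(lineage_rpkm)] <- lineage_rpkm
  rk["rpoB"] <- if ("rpoB" %in% names(lineage_rpkm))
    lineage_rpkm[["rpoB"]] else rpob_rpkm
  present <- setNames(rep(TRUE, length(markers)), markers)
  if (!is.null(inventory)) {
    known <- intersect(markers, names(inventory))
    present[known] <- inventory[known]
    present[setdiff(markers, names(inventory))] <-
      rk[setdiff(markers, names(inventory))] > 0
  }
  present["rpoB"] <- TRUE
  if (rpob_rpkm <= 0) {
    return(new("ExpressionProfile", lineage = lineage,
               log2Ratio = val,
               state = ifelse(present, "nd", "absent"),
               available = FALSE))
  }
  for (m in markers) {
    if (!present[m]) {
      if (rk[m] > 0)
        warning("marker ", m, " is absent from the inventory of ",
                lineage, " but has counts; kept absent")
      state[m] <- "absent"
    } else if (rk[m] == 0) {
      state[m] <- "nd"
    } else {
      val[m] <- log2(rk[m] / rpob_rpkm)
    }
  }
  new("ExpressionProfile", lineage = lineage, log2Ratio = val,
      state = state, available = TRUE)
}

#' Expression profiles for all lineages of a count table
#'
#' Aggregates RNA counts to lineage level ([lineageAggregate()]) and
#' builds one [ExpressionProfile-class] per (sample, lineage) with each
#' lineage's own rpoB as anchor.  The gene inventory defaults to "a
#' feature exists for this (lineage, marker)" — i.e. the phylotype
#' database's view of presence — and can be overridden per lineage.
#'
#' @param mc a [MarkerCounts-class].
#' @param inventory optional named list lineage -> named logical of marker
#'   presence.
#' @param lineages optional subset of lineages (default: all except
#'   `"background"`).
#' @param molecule which libraries to use (default RNA).
#' @return Named list (`sample|lineage`) of [ExpressionProfile-class]
#'   objects.
#' @export
expressionProfiles <- function(mc, inventory = NULL, lineages = NULL,
                               molecule = "RNA") {
  agg <- lineageAggregate(mc, molecule = molecule)
  if (is.null(lineages))
    lineages <- setdiff(unique(agg$lineage), "background")
  out <- list()
  for (s in unique(agg$sample)) {
    for (ln in lineages) {
      a <- agg[agg$sample == s & agg$lineage == ln, , drop = FALSE]
      if (nrow(a) == 0) next
      rk <- setNames(a$rpkm, a$marker)
      inv <- if (!is.null(inventory) && ln %in% names(inventory))
        inventory[[ln]]
      else setNames(rep(TRUE, nrow(a)), a$marker)
      rpob <- if ("rpoB" %in% names(rk)) rk[["rpoB"]] else 0
      out[[paste(s, ln, sep = "|")]] <-
        rpobProfile(rk, rpob, inv, lineage = ln)
    }
  }
  out
}

#' Average expression profiles of one lineage across samples
#'
#' Arithmetic mean of the log2 ratios over the samples where the marker is
#' numeric; `"nd"` propagates only when the marker is `"nd"` in every
#' sample, `"absent"` when absent everywhere it appears.  Unavailable
#' profiles (no rpoB transcripts) are skipped.
#'
#' @param profiles list of [ExpressionProfile-class] for the same lineage.
#' @return A single [ExpressionProfile-class].
#' @export
averageProfiles <- function(profiles) {
  profiles <- Filter(function(p) p@available[1], profiles)
  if (length(profiles) == 0L) stop("no available profiles to average")
  lineage <- profiles[[1]]@lineage
  markers <- unique(unlist(lapply(profiles, function(p) names(p@state))))
  val <- setNames(rep(NA_real_, length(markers)), markers)
  state <- setNames(rep("absent", length(markers)), markers)
  for (m in markers) {
    st <- vapply(profiles, function(p)
      if (m %in% names(p@state)) p@state[[m]] else NA_character_, "")
    xs <- vapply(profiles, function(p)
      if (m %in% names(p@log2Ratio)) p@log2Ratio[[m]] else NA_real_,
      numeric(1))
    if (any(st == "ok", na.rm = TRUE)) {
      state[m] <- "ok"
      val[m] <- mean(xs[which(st == "ok")])
    } else if (any(st == "nd", na.rm = TRUE)) {
      state[m] <- "nd"
    }
  }
  new("ExpressionProfile", lineage = lineage, log2Ratio = val,
      state = state, available = TRUE)
}

.profileState <- function(profile, marker) {
  if (!marker %in% names(profile@state))
    stop("unknown marker: ", marker)
  profile@state[[marker]]
}

#' Fold difference between a soil lineage profile and a reference profile
#'
#' Both profiles being numeric for the marker, the fold is
#' `2^(soil - ref)` of the log2 rpoB-normalized ratios (with
#' `log2_delta = soil - ref`).  If either side is `"absent"` or `"nd"` the
#' comparison is incomparable and the blocking state is named.
#'
#' @param soil,ref [ExpressionProfile-class] objects (reference profiles
#'   use the same class).
#' @param marker marker to compare; must exist in both profiles.
#' @return list with `fold` and `log2_delta`, or list with `incomparable`
#'   (one of `"soil_absent"`, `"soil_nd"`, `"reference_absent"`,
#'   `"reference_nd"`).
#' @export
foldDifference <- function(soil, ref, marker) {
  ss <- .profileState(soil, marker)
  rs <- .profileState(ref, marker)
  if (ss != "ok")
    return(list(incomparable = paste0("soil_", ss)))
  if (rs != "ok")
    return(list(incomparable = paste0("reference_", rs)))
  d <- soil@log2Ratio[[marker]] - ref@log2Ratio[[marker]]
  list(fold = 2^d, log2_delta = d)
}

#' Flag markers whose soil expression diverges from the reference
#'
#' Markers whose fold difference (or its reciprocal) exceeds
#' `fold_cutoff` are returned with a direction; markers incomparable
#' because of absent/nd states are listed in the `incomparable`
#' attribute.
#'
#' @param soil,ref [ExpressionProfile-class] objects.
#' @param fold_cutoff fold-change cutoff (> 1), default 10.
#' @return data.frame with columns `marker`, `fold`, `log2_delta`,
#'   `direction` (`"higher_in_soil"`/`"lower_in_soil"`); attribute
#'   `incomparable` is a data.frame of skipped markers and reasons.
#' @export
flagDivergent <- function(soil, ref, fold_cutoff = 10) {
  if (fold_cutoff <= 1) stop("fold_cutoff must be > 1")
  markers <- intersect(names(soil@state), names(ref@state))
  rows <- list()
  inc <- list()
  for (m in markers) {
    fd <- foldDifference(soil, ref, m)
    if (!is.null(fd$incomparable)) {
      inc[[m]] <- data.frame(marker = m, reason = fd$incomparable,
                             stringsAsFactors = FALSE)
    } else if (fd$fold > fold_cutoff || 1 / fd$fold > fold_cutoff) {
      rows[[m]] <- data.frame(
        marker = m, fold = fd$fold, log2_delta = fd$log2_delta,
        direction = if (fd$fold > 1) "higher_in_soil" else
          "lower_in_soil",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), fold = numeric(0),
               log2_delta = numeric(0), direction = character(0))
  rownames(res) <- NULL
  attr(res, "incomparable") <- if (length(inc)) {
    x <- do.call(rbind, inc); rownames(x) <- NULL; x
  } else data.frame(marker = character(0), reason = character(0))
  res
}
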