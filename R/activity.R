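## Transcript-to-gene ratio activity classification: per-phylotype
## relative recovery frequencies in DNA and RNA libraries and per-family
## active fractions.

#' Relative recovery frequencies within a phylotype group
#'
#' Each phylotype's mapped-read count divided by the group total (e.g. a
#' phylotype's amoA reads relative to total AOA amoA reads in the
#' library); frequencies sum to 1.
#'
#' @param counts named non-negative counts of the group's phylotypes.
#' @param group_total the group total; must equal `sum(counts)` and be
#'   positive.
#' @return Named proportions summing to 1.
#' @examples
#' recoveryFrequency(c(A = 30, B = 70), 100)
#' @export
recoveryFrequency <- function(counts, group_total = sum(counts)) {
  if (group_total <= 0) stop("group total must be positive")
  if (abs(sum(counts) - group_total) > 1e-8 * max(1, group_total))
    stop("group_total must equal the sum of the group's counts")
  counts / group_total
}

#' Transcript-to-gene recovery ratio
#'
#' RNA recovery frequency over DNA recovery frequency.  A phylotype seen
#' only in RNA returns `Inf` (transcripts prove activity without a
#' detected gene); one seen in neither returns `NaN` (undefined).
#'
#' @param freq_rna,freq_dna recovery frequencies in `[0, 1]`.
#' @return Non-negative real, `Inf`, or `NaN`.
#' @examples
#' transcriptGeneRatio(0.10, 0.05)  # 2
#' @export
transcriptGeneRatio <- function(freq_rna, freq_dna) {
  if (any(c(freq_rna, freq_dna) < 0) || any(c(freq_rna, freq_dna) > 1))
    stop("frequencies must lie in [0, 1]")
  if (freq_dna > 0) return(freq_rna / freq_dna)
  if (freq_rna > 0) return(Inf)
  NaN
}

.activityStatus <- function(freq_dna, freq_rna, ratio, threshold) {
  if (freq_dna == 0 && freq_rna == 0) return("undetected")
  if (freq_dna == 0) return("rna_only")
  if (ratio > threshold) "active" else "low"
}

#' Per-phylotype activity records from DNA and RNA counts
#'
#' For every sample with both a DNA and an RNA library, computes each
#' group phylotype's recovery frequency in the two pools, the
#' transcript-to-gene ratio, and a status: `"active"` (ratio strictly
#' above `threshold`), `"low"`, `"rna_only"` (transcripts without a
#' detected gene) or `"undetected"`.
#'
#' @param mc a [MarkerCounts-class] with paired DNA/RNA libraries.
#' @param marker marker defining the group (default `"amoA"`).
#' @param guild optional guild to restrict the group to (default
#'   `"AOA"`; `NULL` for all features of the marker).
#' @param threshold activity threshold on the ratio; the default 1 is the
#'   1:1 line (equal relative recovery in both pools), with strict `>`.
#' @return data.frame with columns `phylotype`, `family`, `sample`,
#'   `freq_dna`, `freq_rna`, `ratio`, `status`.
#' @export
activityTable <- function(mc, marker = "amoA", guild = "AOA",
                          threshold = 1.0) {
  stopifnot(is(mc, "MarkerCounts"))
  rd <- rowData(mc)
  sel <- rd$marker == marker
  if (!is.null(guild) && "guild" %in% colnames(rd))
    sel <- sel & rd$guild == guild
  if (!any(sel)) stop("no features for marker ", marker)
  cts <- assay(mc, "counts")[sel, , drop = FALSE]
  fam <- if ("family" %in% colnames(rd)) as.character(rd$family)[sel]
         else rep(NA_character_, sum(sel))
  cd <- colData(mc)
  out <- list()
  for (s in unique(as.character(cd$sample))) {
    jd <- which(cd$sample == s & cd$molecule == "DNA")
    jr <- which(cd$sample == s & cd$molecule == "RNA")
    if (length(jd) != 1L || length(jr) != 1L) next
    dna <- cts[, jd]; rna <- cts[, jr]
    fd <- if (sum(dna) > 0) dna / sum(dna) else dna * 0
    fr <- if (sum(rna) > 0) rna / sum(rna) else rna * 0
    ratio <- mapply(transcriptGeneRatio, fr, fd)
    status <- mapply(.activityStatus, fd, fr, ratio,
                     MoreArgs = list(threshold = threshold))
    out[[s]] <- data.frame(
      phylotype = rownames(cts), family = fam, sample = s,
      freq_dna = unname(fd), freq_rna = unname(fr),
      ratio = unname(ratio), status = unname(status),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-family summary of transcriptionally active phylotypes
#'
#' A phylotype counts as active if, in at least one sample, its
#' transcript-to-gene ratio strictly exceeds `threshold` or it was
#' recovered in RNA only.  Phylotypes undetected in every sample are
#' excluded from the denominator; families with no detected phylotype are
#' dropped with a warning.
#'
#' @param records activity records from [activityTable()].
#' @param threshold activity threshold (strict `>`).
#' @return data.frame with columns `family`, `n_phylotypes` (detected),
#'   `n_active`, `fraction_active`.
#' @export
classifyActivity <- function(records, threshold = 1.0) {
  need <- c("phylotype", "family", "ratio", "status")
  if (!all(need %in% names(records)))
    stop("records must come from activityTable()")
  out <- list()
  for (f in unique(records$family)) {
    rf <- records[records$family %in% f, , drop = FALSE]
    det <- tapply(rf$status != "undetected", rf$phylotype, any)
    if (!any(det)) {
      warning("family ", f, " has no detected phylotype; excluded")
      next
    }
    act <- tapply(
      (rf$status == "rna_only") |
        (is.finite(rf$ratio) & rf$ratio > threshold),
      rf$phylotype, any)
    act <- act[names(det)][det]
    out[[f]] <- data.frame(
      family = f, n_phylotypes = sum(det), n_active = sum(act),
      fraction_active = mean(act), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(family = character(0), n_phylotypes = integer(0),
                      n_active = integer(0),
                      fraction_active = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
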