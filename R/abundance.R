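## RPKM normalization and copy-number-corrected community proportions of
## nitrifier guilds against the single-copy rpoB anchor.

#' Default gene copy-number model
#'
#' Per-guild, per-marker gene copy numbers used to convert marker-gene
#' RPKM into cell-equivalent abundance: one *rpoB* per prokaryotic genome,
#' one *amoA* per AOA cell, 2.5 per AOB cell, 1.5 per comammox cell, and
#' four *nxrB* copies per *Nitrospira* cell.  The defaults ship as a
#' plain-text config (`inst/extdata/copy_model.tsv`) so they are data, not
#' code; [readCopyModel()] loads alternatives.
#'
#' @return data.frame with columns `guild`, `marker`, `copies`.
#' @examples
#' defaultCopyModel()
#' @export
defaultCopyModel <- function() {
  readCopyModel(system.file("extdata", "copy_model.tsv",
                            package = "nitriquant"))
}

#' Read a copy-number model from TSV
#'
#' @param path TSV with columns `guild`, `marker`, `copies` (positive).
#' @return data.frame copy model.
#' @export
readCopyModel <- function(path) {
  cm <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("guild", "marker", "copies") %in% names(cm)))
    stop("copy model needs columns guild, marker, copies")
  if (any(cm$copies <= 0)) stop("copy numbers must be positive")
  cm
}

#' Look up a copy number
#'
#' @param model copy model data.frame.
#' @param guild,marker entry to retrieve.
#' @return The copy number (positive real).
#' @export
copyNumber <- function(model, guild, marker) {
  i <- which(model$guild == guild & model$marker == marker)
  if (length(i) != 1L)
    stop("no copy-number entry for (", guild, ", ", marker, ")")
  model$copies[i]
}

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (length_bp * total_reads)`: read counts normalized by
#' gene length (kb) and sequencing depth (million mapped reads), the unit
#' in which all downstream proportions and ratios are computed.
#' Vectorized over its arguments.
#'
#' @param count mapped-read count(s), non-negative.
#' @param length_bp gene length(s) in bp, positive.
#' @param total_reads total mapped reads in the library, positive.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' @export
rpkm <- function(count, length_bp, total_reads) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count * 1e9 / (length_bp * total_reads)
}

#' RPKM matrix of a MarkerCounts object
#'
#' @param x a [MarkerCounts-class].
#' @return Numeric matrix of RPKM values, same shape as the counts.
#' @export
rpkmMatrix <- function(x) {
  stopifnot(is(x, "MarkerCounts"))
  tot <- libraryTotals(x)
  if (any(tot <= 0)) stop("all library totals must be positive for RPKM")
  cts <- assay(x, "counts")
  ## numerator and denominator are kept as single products so that
  ## scaling counts and totals by a common factor cancels exactly in
  ## floating point (one correctly-rounded division per cell)
  (cts * 1e9) / outer(as.numeric(rowData(x)$length_bp), tot)
}

#' Copy-number-corrected guild proportion
#'
#' Converts a guild's marker-gene RPKM into a cell-proportion of the total
#' prokaryotic community: RPKM is divided by the guild's per-cell gene
#' copy number, then by the community-wide *rpoB* RPKM (one copy per
#' genome).
#'
#' @param guild_marker_rpkm summed marker RPKM of the guild.
#' @param guild,marker copy-model entry to correct with.
#' @param model copy model (see [defaultCopyModel()]).
#' @param rpob_total_rpkm total prokaryotic rpoB RPKM (positive).
#' @return Proportion of cells.
#' @examples
#' guildProportion(5, "AOB", "amoA", defaultCopyModel(), 100)  # 0.02
#' @export
guildProportion <- function(guild_marker_rpkm, guild, marker, model,
                            rpob_total_rpkm) {
  if (rpob_total_rpkm <= 0) stop("rpob_total_rpkm must be positive")
  (guild_marker_rpkm / copyNumber(model, guild, marker)) / rpob_total_rpkm
}

#' Canonical (non-comammox) Nitrospira proportion by differencing
#'
#' Total *Nitrospira* cells are estimated from *nxrB* (4 copies per cell)
#' and comammox cells from their *amoA* (1.5 copies); canonical
#' nitrite-oxidizers are the difference.  A negative difference (possible
#' under sampling noise or variable nxrB copy number) is clamped to zero
#' with a warning.  The difference is taken on the proportion scale, so
#' `comammoxProp + canonical == totalNitrospiraProp` holds exactly
#' whenever no clamp fires.
#'
#' @param nxrb_rpkm total Nitrospira nxrB RPKM.
#' @param comammox_amoa_rpkm comammox amoA RPKM.
#' @param model copy model.
#' @param rpob_total_rpkm total prokaryotic rpoB RPKM.
#' @return Canonical Nitrospira cell proportion (>= 0).
#' @examples
#' canonicalNitrospira(8, 1.5, defaultCopyModel(), 100)  # 0.01
#' @export
canonicalNitrospira <- function(nxrb_rpkm, comammox_amoa_rpkm, model,
                                rpob_total_rpkm) {
  total <- guildProportion(nxrb_rpkm, "Nitrospira", "nxrB", model,
                           rpob_total_rpkm)
  com <- guildProportion(comammox_amoa_rpkm, "comammox", "amoA", model,
                         rpob_total_rpkm)
  d <- total - com
  if (d < 0) {
    ## warn only for genuinely negative differences, not floating-point
    ## residue around a true zero
    if (d < -1e-12 * max(total, com))
      warning("canonical Nitrospira difference negative (",
              signif(d, 4), "); clamped to 0")
    d <- 0
  }
  d
}

#' Comammox share of the total Nitrospira population
#'
#' @param comammox_amoa_rpkm comammox amoA RPKM.
#' @param nxrb_rpkm total Nitrospira nxrB RPKM (positive).
#' @param model copy model.
#' @return Proportion in `[0, 1]`; values above 1 clamp with a warning.
#' @examples
#' comammoxFractionOfNitrospira(0.75, 8, defaultCopyModel())  # 0.25
#' @export
comammoxFractionOfNitrospira <- function(comammox_amoa_rpkm, nxrb_rpkm,
                                         model) {
  if (nxrb_rpkm <= 0) stop("nxrb_rpkm must be positive")
  f <- (comammox_amoa_rpkm / copyNumber(model, "comammox", "amoA")) /
       (nxrb_rpkm / copyNumber(model, "Nitrospira", "nxrB"))
  if (f > 1) {
    warning("comammox fraction ", signif(f, 4), " exceeds 1; clamped")
    f <- 1
  }
  f
}

#' Gene-to-rpoB abundance ratio with copy-class consistency flag
#'
#' Within a lineage, the RPKM ratio of a gene to the single-copy *rpoB*
#' anchor approaches the per-cell copy number: about 1 for single-copy
#' core genes, above 1 for multi-copy genes, below 1 for genes not present
#' in every cell (facultative).  The flag records whether the observed
#' ratio is consistent with the expected class; the single-copy band
#' defaults to `[0.5, 2]`.
#'
#' @param gene_rpkm gene RPKM within the lineage.
#' @param rpob_rpkm rpoB RPKM within the lineage (positive).
#' @param expected_class `"single"`, `"multi"` or `"facultative"`.
#' @param band length-2 numeric: the single-copy consistency band.
#' @return list with `ratio` and `flag` (`"consistent"`/`"inconsistent"`).
#' @examples
#' copyRatio(3, 1, "multi")
#' @export
copyRatio <- function(gene_rpkm, rpob_rpkm,
                      expected_class = c("single", "multi", "facultative"),
                      band = c(0.5, 2)) {
  expected_class <- match.arg(expected_class)
  if (rpob_rpkm <= 0) stop("rpob_rpkm must be positive")
  r <- gene_rpkm / rpob_rpkm
  ok <- switch(expected_class,
               single = r >= band[1] && r <= band[2],
               multi = r > 1,
               facultative = r < 1)
  list(ratio = r, flag = if (ok) "consistent" else "inconsistent")
}

#' Gene prevalence within a guild from rpoB-normalized abundance
#'
#' Fraction of a guild's cells that encode a gene, estimated as the ratio
#' of the gene's RPKM to the guild's rpoB RPKM, in percent.  Ratios above
#' 1 (multi-copy genes break the prevalence reading) clamp to 100% with a
#' warning.
#'
#' @param gene_rpkm gene RPKM within the guild.
#' @param rpob_rpkm guild rpoB RPKM (positive).
#' @return Percentage in `[0, 100]`.
#' @examples
#' genePrevalence(0.9, 1.0)  # 90
#' @export
genePrevalence <- function(gene_rpkm, rpob_rpkm) {
  if (rpob_rpkm <= 0) stop("rpob_rpkm must be positive")
  r <- gene_rpkm / rpob_rpkm
  if (r > 1) {
    warning("gene:rpoB ratio ", signif(r, 4),
            " exceeds 1; prevalence clamped to 100%")
    r <- 1
  }
  100 * r
}

#' Estimate guild proportions from a marker count table
#'
#' For every library of the requested molecule type: the community-wide
#' rpoB RPKM anchors the denominator; AOA, AOB and comammox proportions
#' come from their summed amoA RPKM corrected by guild copy number; total
#' *Nitrospira* from nxrB; canonical *Nitrospira* by differencing
#' ([canonicalNitrospira()]).  Features must carry `guild` and `marker`
#' row metadata (as produced by [simulateCounts()]).
#'
#' @param mc a [MarkerCounts-class].
#' @param model copy model (default [defaultCopyModel()]).
#' @param molecule which libraries to evaluate.
#' @return data.frame with columns `sample`, `molecule`, `guild`,
#'   `marker`, `rpkm`, `copy_corrected_rpkm`, `proportion`.
#' @export
estimateGuildProportions <- function(mc, model = defaultCopyModel(),
                                     molecule = "DNA") {
  stopifnot(is(mc, "MarkerCounts"))
  rd <- rowData(mc)
  if (!"guild" %in% colnames(rd))
    stop("features need a 'guild' annotation to estimate proportions")
  rk <- rpkmMatrix(mc)
  keep <- which(moleculeType(mc) == molecule)
  out <- list()
  for (j in keep) {
    s <- colData(mc)$sample[j]
    v <- rk[, j]
    rpob_tot <- sum(v[rd$marker == "rpoB"])
    if (rpob_tot <= 0)
      stop("no rpoB signal in library ", colnames(mc)[j])
    gsum <- function(g, m) sum(v[rd$guild == g & rd$marker == m])
    rows <- list()
    for (g in c("AOA", "AOB", "comammox")) {
      rv <- gsum(g, "amoA")
      cc <- rv / copyNumber(model, g, "amoA")
      rows[[g]] <- data.frame(
        sample = s, molecule = molecule, guild = g, marker = "amoA",
        rpkm = rv, copy_corrected_rpkm = cc,
        proportion = cc / rpob_tot, stringsAsFactors = FALSE)
    }
    nxrb <- sum(v[rd$marker == "nxrB"])
    cn <- copyNumber(model, "Nitrospira", "nxrB")
    canon <- canonicalNitrospira(nxrb, gsum("comammox", "amoA"), model,
                                 rpob_tot)
    ## the reported total is assembled from its parts so that
    ## comammox + canonical == total holds exactly; it agrees with the
    ## direct nxrB-based estimate to floating-point rounding (and is
    ## floored at the comammox estimate when the clamp fired)
    total_prop <- rows$comammox$proportion + canon
    rows$nitrospira_total <- data.frame(
      sample = s, molecule = molecule, guild = "Nitrospira_total",
      marker = "nxrB", rpkm = nxrb, copy_corrected_rpkm = nxrb / cn,
      proportion = total_prop, stringsAsFactors = FALSE)
    rows$nitrospira_canonical <- data.frame(
      sample = s, molecule = molecule, guild = "Nitrospira_canonical",
      marker = "nxrB-amoA", rpkm = NA_real_,
      copy_corrected_rpkm = NA_real_,
      proportion = canon, stringsAsFactors = FALSE)
    out[[colnames(mc)[j]]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate a gene's prevalence within a guild from counts
#'
#' Sums the gene's RPKM and the anchor gene's RPKM over the guild's
#' features and applies [genePrevalence()].  By default the denominator is
#' the guild's single-copy *rpoB*; `denominator = "amoA"` uses amoA
#' instead (meaningful for AOA, where amoA is also single copy).
#'
#' @param mc a [MarkerCounts-class] with `guild` row metadata.
#' @param gene marker whose prevalence to estimate (e.g. `"ureC"`).
#' @param guild guild to restrict to (default `"AOA"`).
#' @param denominator anchor marker, `"rpoB"` or `"amoA"`.
#' @param molecule which libraries to evaluate.
#' @return data.frame with columns `sample`, `gene`, `prevalence_percent`.
#' @export
genePrevalenceEstimate <- function(mc, gene = "ureC", guild = "AOA",
                                   denominator = c("rpoB", "amoA"),
                                   molecule = "DNA") {
  denominator <- match.arg(denominator)
  rd <- rowData(mc)
  rk <- rpkmMatrix(mc)
  keep <- which(moleculeType(mc) == molecule)
  res <- lapply(keep, function(j) {
    num <- sum(rk[rd$guild == guild & rd$marker == gene, j])
    den <- sum(rk[rd$guild == guild & rd$marker == denominator, j])
    data.frame(sample = colData(mc)$sample[j], gene = gene,
               prevalence_percent = genePrevalence(num, den),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-lineage gene:rpoB RPKM ratios
#'
#' Computes, within each lineage and library, the RPKM ratio of every
#' marker to the lineage's own rpoB — the copy-number validation quantity
#' (expected to approach the per-cell copy number).
#'
#' @param mc a [MarkerCounts-class] with `lineage` row metadata.
#' @param molecule which libraries to evaluate.
#' @return data.frame with `sample`, `lineage`, `marker`, `ratio`.
#' @export
copyRatioTable <- function(mc, molecule = "DNA") {
  rd <- rowData(mc)
  rk <- rpkmMatrix(mc)
  keep <- which(moleculeType(mc) == molecule)
  out <- list()
  for (j in keep) {
    for (ln in unique(rd$lineage)) {
      sel <- rd$lineage == ln
      rpob <- sum(rk[sel & rd$marker == "rpoB", j])
      if (rpob <= 0) next
      mks <- setdiff(unique(rd$marker[sel]), "rpoB")
      for (m in mks) {
        out[[length(out) + 1L]] <- data.frame(
          sample = colData(mc)$sample[j], lineage = ln, marker = m,
          ratio = sum(rk[sel & rd$marker == m, j]) / rpob,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
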