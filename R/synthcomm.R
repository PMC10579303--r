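## Synthetic community generator: ground-truth communities, expected and
## sampled read counts, and marker protein FASTA emission.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Default marker gene lengths (bp), order-of-magnitude realistic for the
## genes they stand for.
.DEFAULT_MARKER_LENGTHS <- c(
  rpoB = 3000, amoA = 650, nxrB = 1300, nirK = 950, ureC = 1700, accB = 500
)

.AOA_FAMILIES <- c("Nitrososphaeraceae", "NS-delta", "NS-beta",
                   "NS-epsilon", "NS-beta-associated", "NS-gamma",
                   "NS-zeta", "NP-delta", "Nitrosotenuaceae")

.orderForFamily <- function(family) {
  ifelse(family %in% c("NP-delta", "Nitrosotenuaceae"),
         "Nitrosopumilales", "Nitrososphaerales")
}

#' Derive a nitrifier guild from taxonomy and gene inventory
#'
#' Ammonia-oxidizing archaea are recognised by their archaeal orders,
#' ammonia-oxidizing bacteria by *Nitrosomonadales*, and *Nitrospirales*
#' genomes split into comammox (carrying amoA) versus canonical
#' nitrite-oxidizers.
#'
#' @param order taxonomic order label(s).
#' @param has_amoa logical, whether the lineage carries an amoA gene.
#' @return character vector of guild labels: `"AOA"`, `"AOB"`,
#'   `"comammox"`, `"NOB"` or `"other"`.
#' @export
guildForOrder <- function(order, has_amoa = FALSE) {
  has_amoa <- rep_len(has_amoa, length(order))
  out <- rep("other", length(order))
  out[order %in% c("Nitrososphaerales", "Nitrosopumilales",
                   "Nitrosotaleales")] <- "AOA"
  out[order == "Nitrosomonadales"] <- "AOB"
  nsp <- order == "Nitrospirales"
  out[nsp & has_amoa] <- "comammox"
  out[nsp & !has_amoa] <- "NOB"
  out
}

#' Generate a synthetic nitrifier community with known ground truth
#'
#' Two presets are available.  `"uniform"` produces `n_lineages` equal-
#' abundance AOA lineages with a shared gene inventory and no background
#' pool (the simplest fully symmetric test bed).  `"soil-like"` emulates
#' the guild structure of an upland-soil nitrifier assemblage: `n_lineages`
#' AOA lineages share 5% of community cells (split by a seed-determined
#' Dirichlet draw), a comammox *Nitrospira* lineage holds 0.2%, an AOB
#' lineage 0.02%, and the remaining 94.78% is a background pool of
#' non-target prokaryotes contributing only *rpoB*.  Per-lineage amoA
#' transcription rates vary log-normally, with NS-delta-labelled lineages
#' fixed at a low rate to emulate a numerically dominant but
#' transcriptionally quiet family.
#'
#' @param n_lineages number of AOA lineages (>= 1).
#' @param seed integer seed; identical calls are byte-identical.
#' @param profile `"uniform"` or `"soil-like"`.
#' @return A [CommunityTruth-class] object.
#' @examples
#' truth <- generateCommunity(4, seed = 7, profile = "soil-like")
#' trueGuildProportions(truth)
#' @export
generateCommunity <- function(n_lineages, seed = 1L,
                              profile = c("uniform", "soil-like")) {
  if (length(n_lineages) != 1L || n_lineages < 1 ||
      n_lineages != round(n_lineages))
    stop("n_lineages must be a positive integer")
  if (is.character(profile) && length(profile) == 1L &&
      !profile %in% c("uniform", "soil-like"))
    stop("unknown community profile: ", profile)
  profile <- match.arg(profile)
  n <- as.integer(n_lineages)
  ml <- .DEFAULT_MARKER_LENGTHS
  fam <- rep_len(.AOA_FAMILIES, n)
  aoa <- data.frame(
    name = sprintf("AOA-%02d", seq_len(n)),
    family = fam,
    order = .orderForFamily(fam),
    guild = "AOA",
    cell_abundance = NA_real_,
    stringsAsFactors = FALSE)

  mk <- function(name) matrix(0, nrow = 1, ncol = length(ml),
                              dimnames = list(name, names(ml)))
  if (profile == "uniform") {
    aoa$cell_abundance <- 1.0
    gc <- matrix(0, n, length(ml), dimnames = list(aoa$name, names(ml)))
    er <- gc
    gc[, c("rpoB", "amoA", "nirK", "ureC", "accB")] <-
      rep(c(1, 1, 2, 1, 1), each = n)
    er[, c("rpoB", "amoA", "nirK", "ureC", "accB")] <-
      rep(c(1, 8, 4, 2, 1), each = n)
    er[gc == 0] <- NA_real_
    return(CommunityTruth(aoa, gc, er, backgroundRpoB = 0,
                          markerLengths = ml))
  }

  ## soil-like: AOA 5%, comammox 0.2%, AOB 0.02%, background 94.78%
  draws <- withr::with_seed(as.integer(seed), {
    list(w = rgamma(n, shape = 2, rate = 1),
         amoa_rate = rlnorm(n, meanlog = log(6), sdlog = 0.5))
  })
  if (n >= 2) {
    ## the urease-negative lineage (the last one) holds a fixed 12% of
    ## AOA cells, so that 88% of AOA encode urease, squarely within the
    ## prevalence range reported for upland-soil AOA; the carriers split
    ## the rest by a seed-determined Dirichlet draw
    w <- draws$w[-n] / sum(draws$w[-n])
    aoa$cell_abundance <- 0.05 * c(0.88 * w, 0.12)
  } else {
    aoa$cell_abundance <- 0.05
  }

  gc <- matrix(0, n, length(ml), dimnames = list(aoa$name, names(ml)))
  er <- matrix(NA_real_, n, length(ml),
               dimnames = list(aoa$name, names(ml)))
  gc[, "rpoB"] <- 1; er[, "rpoB"] <- 1
  gc[, "amoA"] <- 1
  er[, "amoA"] <- ifelse(aoa$family == "NS-delta", 0.8, draws$amoa_rate)
  ## nirK: two copies per cell, transcribed at the rpoB reference rate;
  ## with amoA rates in the low-to-mid single digits this puts the AOA
  ## pool's amoA:nirK transcript ratio in the ~2:1 region seen in
  ## agricultural soils
  gc[, "nirK"] <- 2; er[, "nirK"] <- 1
  gc[, "accB"] <- 1; er[, "accB"] <- 1
  gc[, "ureC"] <- 1; er[, "ureC"] <- 2
  if (n >= 2) { # one urease-negative AOA lineage, as seen in real soils
    gc[n, "ureC"] <- 0; er[n, "ureC"] <- NA_real_
  }

  com <- data.frame(name = "comammox-01", family = "Nitrospiraceae",
                    order = "Nitrospirales", guild = "comammox",
                    cell_abundance = 0.002, stringsAsFactors = FALSE)
  gcc <- mk("comammox-01"); erc <- mk("comammox-01"); erc[] <- NA_real_
  gcc[, "rpoB"] <- 1; erc[, "rpoB"] <- 1
  gcc[, "amoA"] <- 1.5; erc[, "amoA"] <- 0.5  # minimally transcribed
  gcc[, "nxrB"] <- 4;  erc[, "nxrB"] <- 8     # highly expressed

  aob <- data.frame(name = "AOB-01", family = "Nitrosomonadaceae",
                    order = "Nitrosomonadales", guild = "AOB",
                    cell_abundance = 0.0002, stringsAsFactors = FALSE)
  gcb <- mk("AOB-01"); erb <- mk("AOB-01"); erb[] <- NA_real_
  gcb[, "rpoB"] <- 1; erb[, "rpoB"] <- 1
  gcb[, "amoA"] <- 2.5; erb[, "amoA"] <- 0.2

  lineages <- rbind(aoa, com, aob)
  CommunityTruth(lineages,
                 rbind(gc, gcc, gcb),
                 rbind(er, erc, erb),
                 backgroundRpoB = 0.9478,
                 markerLengths = ml)
}

## Expected-read weight of every feature (lineage x marker with copies > 0,
## plus the background rpoB pseudo-feature).  Expected counts are these
## weights normalized to the configured depth.
.expectedWeights <- function(truth, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  gc <- truth@geneCopies
  er <- truth@expressionRates
  ml <- truth@markerLengths
  cells <- cellAbundance(truth)
  idx <- which(gc > 0, arr.ind = TRUE)
  lineage <- rownames(gc)[idx[, 1]]
  marker <- colnames(gc)[idx[, 2]]
  w <- cells[idx[, 1]] * gc[idx] * ml[marker]
  if (molecule == "RNA") w <- w * er[idx]
  df <- data.frame(
    feature_id = paste(lineage, marker, sep = "|"),
    lineage = lineage, marker = marker,
    family = truth@lineages$family[match(lineage, truth@lineages$name)],
    guild = truth@lineages$guild[match(lineage, truth@lineages$name)],
    length_bp = unname(ml[marker]),
    weight = unname(w),
    stringsAsFactors = FALSE)
  if (truth@backgroundRpoB > 0) {
    df <- rbind(df, data.frame(
      feature_id = "background|rpoB", lineage = "background",
      marker = "rpoB", family = "background", guild = "background",
      length_bp = unname(ml["rpoB"]),
      weight = truth@backgroundRpoB * ml[["rpoB"]]))
  }
  df <- df[order(df$feature_id), , drop = FALSE]
  rownames(df) <- df$feature_id
  df
}

#' Expected mapped-read count of one lineage-marker feature
#'
#' Inverts the RPKM model: the expected number of reads mapping to a gene
#' is proportional to cell abundance x per-cell copy number x gene length
#' (DNA), additionally x transcription rate for RNA, normalized so that
#' expectations over all features (background rpoB pool included) sum to
#' the sequencing depth.
#'
#' @param truth a [CommunityTruth-class].
#' @param lineage lineage name (or `"background"`).
#' @param marker marker name.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param depth total mapped reads.
#' @return Expected count (non-negative real; 0 when the lineage does not
#'   carry the marker).
#' @examples
#' truth <- generateCommunity(2, seed = 1, profile = "uniform")
#' expectedCount(truth, "AOA-01", "amoA", "DNA", 1e6)
#' @export
expectedCount <- function(truth, lineage, marker,
                          molecule = c("DNA", "RNA"), depth) {
  molecule <- match.arg(molecule)
  if (!lineage %in% c(lineageNames(truth), "background"))
    stop("unknown lineage: ", lineage)
  if (!marker %in% markerNames(truth))
    stop("unknown marker: ", marker)
  if (depth <= 0) stop("depth must be positive")
  w <- .expectedWeights(truth, molecule)
  id <- paste(lineage, marker, sep = "|")
  if (!id %in% w$feature_id) return(0)
  depth * w$weight[w$feature_id == id] / sum(w$weight)
}

#' Simulate DNA and RNA mapped-read count tables for a community
#'
#' In `"expected"` mode counts equal the (generally non-integer)
#' expectations exactly; in `"sampled"` mode each library is one
#' multinomial draw of size `depth` over the features with probabilities
#' proportional to the expectations, i.e. noise conditioned on total
#' sequencing depth.  A single RNG stream derived from the config seed is
#' used and the caller's RNG state is untouched.
#'
#' @param truth a [CommunityTruth-class].
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @param sample_id label for the simulated sample.
#' @return A [MarkerCounts-class] with one DNA and one RNA library.
#' @examples
#' truth <- generateCommunity(3, seed = 2, profile = "soil-like")
#' mc <- simulateCounts(truth, simulationConfig(1e5, 1e5, seed = 9))
#' @export
simulateCounts <- function(truth, config, sample_id = "S1") {
  stopifnot(is(truth, "CommunityTruth"), is(config, "SimulationConfig"))
  wd <- .expectedWeights(truth, "DNA")
  wr <- .expectedWeights(truth, "RNA")
  stopifnot(identical(wd$feature_id, wr$feature_id))
  exp_dna <- config@depthDNA * wd$weight / sum(wd$weight)
  exp_rna <- config@depthRNA * wr$weight / sum(wr$weight)
  if (config@mode == "expected") {
    cnt <- cbind(exp_dna, exp_rna)
    totals <- c(sum(exp_dna), sum(exp_rna))
  } else {
    cnt <- withr::with_seed(config@seed, {
      cbind(rmultinom(1, config@depthDNA, wd$weight)[, 1],
            rmultinom(1, config@depthRNA, wr$weight)[, 1])
    })
    totals <- c(config@depthDNA, config@depthRNA)
  }
  rownames(cnt) <- wd$feature_id
  colnames(cnt) <- paste(sample_id, c("DNA", "RNA"), sep = ".")
  MarkerCounts(
    cnt,
    featureData = wd[, c("lineage", "marker", "family", "guild",
                         "length_bp")],
    libraryData = data.frame(sample = sample_id,
                             molecule = c("DNA", "RNA"),
                             total_reads = totals))
}

#' Closed-form guild proportions of a synthetic community
#'
#' The cell-share truth the copy-number-corrected pipeline should recover:
#' each guild's summed cell abundance over total cells (background pool
#' included).  `nitrospira_total` is comammox plus canonical
#' nitrite-oxidizing *Nitrospira*.
#'
#' @param truth a [CommunityTruth-class].
#' @return Named numeric vector of proportions: `AOA`, `AOB`, `comammox`,
#'   `nitrospira_canonical`, `nitrospira_total`, `background`.
#' @export
trueGuildProportions <- function(truth) {
  cells <- cellAbundance(truth)
  guild <- setNames(truth@lineages$guild, truth@lineages$name)
  tot <- sum(cells) + truth@backgroundRpoB
  gsum <- function(g) sum(cells[guild %in% g]) / tot
  c(AOA = gsum("AOA"), AOB = gsum("AOB"), comammox = gsum("comammox"),
    nitrospira_canonical = gsum("NOB"),
    nitrospira_total = gsum(c("comammox", "NOB")),
    background = truth@backgroundRpoB / tot)
}

#' Emit synthetic marker protein sequences with known lineage labels
#'
#' For each lineage carrying the marker, generates
#' `phylotypes_per_lineage` protein variants of a lineage base sequence.
#' Each variant substitutes exactly `floor(divergence * L / 2)` uniformly
#' chosen positions (no indels), so within-lineage pairwise identity is at
#' least `1 - divergence` by construction, while independently drawn
#' lineage base sequences keep between-lineage identity far lower.
#' Sequence names follow `<lineage>|<marker>|pt<i>`, carrying the
#' ground-truth lineage label.
#'
#' @param truth a [CommunityTruth-class].
#' @param marker marker whose protein sequences to emit.
#' @param phylotypes_per_lineage number of variants per lineage.
#' @param divergence within-lineage divergence in `[0, 1)`.
#' @param seed integer seed.
#' @param file optional FASTA path; when given, sequences are also written
#'   (60-character lines).
#' @return An [Biostrings::AAStringSet] with mcols `lineage`, `family` and
#'   `marker`.
#' @examples
#' truth <- generateCommunity(3, seed = 1, profile = "uniform")
#' aa <- emitMarkerFasta(truth, "amoA", 3, divergence = 0.05, seed = 4)
#' @export
emitMarkerFasta <- function(truth, marker = "amoA",
                            phylotypes_per_lineage = 1L,
                            divergence = 0.05, seed = 1L, file = NULL) {
  if (!marker %in% markerNames(truth))
    stop("unknown marker: ", marker)
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  if (phylotypes_per_lineage < 1)
    stop("phylotypes_per_lineage must be >= 1")
  carriers <- lineageNames(truth)[truth@geneCopies[, marker] > 0]
  if (length(carriers) == 0)
    stop("no lineage carries marker ", marker)
  L <- max(10L, as.integer(round(truth@markerLengths[[marker]] / 3)))
  k <- as.integer(floor(divergence * L / 2))
  seqs <- withr::with_seed(as.integer(seed), {
    ## lineage base sequences are drawn first so they depend only on
    ## (seed, lineage order, length): a panel emitted at divergence 0 is
    ## a consistent reference for variants emitted at any divergence
    bases <- lapply(carriers, function(ln)
      sample(.AA20, L, replace = TRUE))
    names(bases) <- carriers
    out <- character(0)
    for (ln in carriers) {
      for (i in seq_len(phylotypes_per_lineage)) {
        v <- bases[[ln]]
        if (k > 0) {
          pos <- sample.int(L, k)
          v[pos] <- vapply(v[pos], function(a)
            sample(setdiff(.AA20, a), 1L), character(1))
        }
        out[paste(ln, marker, paste0("pt", i), sep = "|")] <-
          paste(v, collapse = "")
      }
    }
    out
  })
  aa <- AAStringSet(seqs)
  fam <- truth@lineages$family[match(sub("\\|.*$", "", names(aa)),
                                     truth@lineages$name)]
  mcols(aa) <- DataFrame(lineage = sub("\\|.*$", "", names(aa)),
                         family = fam, marker = marker)
  if (!is.null(file))
    writeXStringSet(aa, file, width = 60L)
  aa
}
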