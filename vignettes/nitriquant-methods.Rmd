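---
title: "Quantifying nitrifier guilds from marker genes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nitrifier guilds from marker genes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitriquant)
```

# The problem

Soil nitrifier communities mix guilds of very different abundance:
ammonia-oxidizing archaea (AOA) commonly make up a few percent of all
prokaryotic cells, while ammonia-oxidizing bacteria (AOB) and complete
ammonia oxidizers (comammox *Nitrospira*) sit orders of magnitude lower.
Shotgun metagenomes and metatranscriptomes see these guilds through
protein-coding marker genes — *amoA* for ammonia oxidizers, *nxrB* for
*Nitrospira*, *rpoB* as a universal single-copy anchor — but raw mapped-read
counts confound cell abundance with gene length, sequencing depth, and
per-cell gene copy number.  nitriquant implements the normalization chain
that removes each of these factors in turn, together with the marker-gene
machinery around it (phylotype construction, read classification,
transcript:gene activity ratios, expression profiles, pangenome
partitioning), and a synthetic-community simulator whose ground truth is
available in closed form so every stage can be validated end to end.

# The abundance model

Counts are first normalized as reads per kilobase per million mapped reads:

$$\mathrm{RPKM} = \frac{c \cdot 10^9}{L \cdot N}$$

with $c$ the mapped-read count of a gene, $L$ its length in bp and $N$ the
library's total mapped reads.  A guild's cell proportion then divides its
marker RPKM by the guild's per-cell gene copy number and by the
community-wide *rpoB* RPKM:

$$p_{\mathrm{guild}}
  = \frac{\mathrm{RPKM}_{\mathrm{marker}} / k_{\mathrm{guild}}}
         {\mathrm{RPKM}_{rpoB,\ \mathrm{all\ prokaryotes}}}$$

on the assumptions that every prokaryotic genome carries one *rpoB* copy,
AOA one *amoA* copy, AOB 2.5, comammox 1.5, and *Nitrospira* four *nxrB*
copies.  These copy numbers ship as data
(`inst/extdata/copy_model.tsv`, loaded by `defaultCopyModel()`), never as
code, so user panels with different inventories are a one-file change.

Canonical (strictly nitrite-oxidizing) *Nitrospira* are not observable
through a marker of their own: they are estimated by differencing, total
*Nitrospira* (from *nxrB*/4) minus comammox (from *amoA*/1.5).  A negative
difference — possible under sampling noise, or when real *nxrB* copy
numbers deviate from four — is clamped to zero and reported.

## Numerical choices in the abundance stage

* **One rounding per RPKM.**  `rpkmMatrix()` evaluates each cell as a
  single division of the exact products $c \cdot 10^9$ and $L \cdot N$.
  Because IEEE division rounds the exact rational quotient, multiplying all
  counts and all totals by a common factor leaves every RPKM — and
  everything derived from it — bit-identical, a property the test suite
  asserts for factors 2, 10 and 137.
* **Exactly conservative Nitrospira partition.**  Floating point does not
  guarantee $x + (z - x) = z$, so the reported total-*Nitrospira*
  proportion is assembled as comammox + canonical.  The partition is then
  conservative bit for bit; the assembled total agrees with the direct
  *nxrB*-based estimate to rounding error and is floored at the comammox
  estimate on the (noise-driven) occasions the clamp fires.
* **Clamp logging threshold.**  Differences below $10^{-12}$ of the larger
  term are treated as floating-point residue around a true zero and
  clamped silently; anything larger warns.

## Copy-ratio validation and gene prevalence

Within a lineage, the RPKM ratio of a gene to the lineage's own *rpoB*
estimates the per-cell copy number: near one for single-copy core genes,
above one for multi-copy genes, below one for genes not carried by every
cell.  `copyRatio()` flags consistency against an expected class; the
single-copy band defaults to $[0.5, 2]$, a deliberately loose package
default since the underlying expectation is only "approaches one".
`genePrevalence()` reads the same ratio as the fraction of a guild's cells
encoding a gene (e.g. urease, *ureC*), in percent, with *rpoB* as the
default denominator because it is the stricter single-copy anchor (*amoA*
is available by flag for AOA).

# Phylotypes, read classification

Marker proteins are dereplicated into phylotypes by CD-HIT-style greedy
incremental clustering: records sorted by length (descending; ties by id)
each join the first phylotype whose representative they match at or above
the identity threshold (default 1.0; 0.8 for the hypervariable NirK —
just a parameter, not special logic).  Identity is computed from a global
Needleman–Wunsch alignment with linear gap penalty (match +1, mismatch 0,
gap −1) as identical residues over the shorter sequence length, the
CD-HIT convention under which substrings collapse at 100%.

Two details make the result deterministic:

* Among equally scoring alignments the number of "identical aligned
  residues" is not unique, so the DP maximises the pair (score, matches)
  lexicographically.  This is implemented as a single standard DP with
  scores (match $C{+}1$, mismatch 0, gap $-C$), $C$ = shorter length + 1,
  from which the match count is recovered exactly as the value modulo $C$.
* All ties (processing order, family assignment, best hits) break on
  lexicographic ids, and greedy order is canonicalised by the length/id
  sort, so output is invariant to input order.

Family assignment adopts the best-identity reference's family when that
identity reaches `min_identity` (default 0.85 — the literature describes
family assignment only as "high sequence similarity", so the cutoff is an
explicit, configurable package choice).

Peptide reads are classified by `bestHit()` against phylotype
representatives with ungapped sliding placements: identity = identical
residues / aligned read residues, coverage = aligned read residues / read
length, thresholds 0.90 and 0.60 by default.  Ungapped placement (rather
than Smith–Waterman) is sufficient here because the contract is the
threshold semantics, not alignment fidelity; externally produced count
tables from a real aligner are accepted through the same
`readCountTable()` interface.

# Activity and expression profiles

Per phylotype and sample, `activityTable()` computes recovery frequencies
(count over group total, e.g. a phylotype's share of all AOA *amoA* reads)
separately in the DNA and RNA pools, and their ratio.  A ratio strictly
above 1 marks disproportionate transcription ("active"); a phylotype
recovered only in RNA is active by sentinel (`Inf`); one recovered in
neither is undetected and excluded from family denominators.  Family
summaries count a phylotype active if it is active in at least one sample
— the "any sample" rule, configurable via the threshold argument.

`rpobProfile()` builds per-lineage expression profiles as
$\log_2(\mathrm{RPKM}_{\mathrm{gene}} / \mathrm{RPKM}_{rpoB})$ after
summing phylotype counts within each lineage (with a member-count-weighted
representative length).  No pseudocounts are used: a present gene with
zero transcripts is rendered `nd`, an inventory-absent gene `X`, exactly
the states a heatmap of such profiles distinguishes; a lineage without
*rpoB* transcripts yields an unavailable profile rather than a fabricated
one.  Profiles are compared against pure-culture reference profiles
(user-supplied TSVs; the shipped
`reference_profiles_synthetic.tsv` is an invented toy panel for tests
only) by `foldDifference()` and `flagDivergent()` (default cutoff
10-fold).  Averaging across samples takes the mean of numeric log2 values;
`nd` propagates only when universal.

# Pangenome partition

From a cluster × genome presence/absence matrix with order/family
taxonomy, `classifyCore()` keeps clusters present in at least one genome
of *every* order, and `classifyLineageSpecific()` keeps clusters whose
carriers all belong to one family with at least `min_genomes` of them
(default 2, automatically 1 for families represented by a single genome —
the singleton-family exception).  Copy number within a genome is ignored;
presence is binary.  With at least two orders the two sets are provably
disjoint; a single-order panel is flagged as degenerate.  Orthology
inference itself is out of scope: the matrix is input.

# The synthetic community simulator

`generateCommunity()` fixes the study conditions the pipeline is validated
under.  The `soil-like` preset places AOA at 5% of community cells,
comammox *Nitrospira* at 0.2%, AOB at 0.02%, and a background pool of
non-target prokaryotes — modelled as a single pseudo-lineage contributing
only *rpoB*, because that is exactly what the denominator sees — at
94.78%.  AOA cells split across `n_lineages` family-labelled lineages by a
seed-determined Dirichlet draw, with two deliberate structural features:
the last lineage lacks urease genes and holds a fixed 12% of AOA cells (so
88% of AOA encode *ureC*, within the prevalence range reported for upland
soils), and NS-delta-labelled lineages receive a low fixed *amoA*
transcription rate, emulating a numerically dominant but transcriptionally
quiet family.  Other *amoA* rates vary log-normally (median 6); *nirK*
carries two copies transcribed at the reference rate, which puts the AOA
pool's *amoA*:*nirK* transcript ratio in the ~2:1 region observed in
agricultural soils.  The `uniform` preset is the symmetric testbed: equal
abundances, shared inventory, no background.

Expected read counts invert the RPKM model: DNA weight = cells × copies ×
length, RNA additionally × transcription rate (transcripts per gene copy,
*rpoB* ≡ 1).  `simulateCounts()` either returns these expectations exactly
(`expected` mode — generally non-integer, and the mode in which pipeline
estimates must equal closed-form truth to machine precision) or draws one
multinomial of size `depth` per library (`sampled` mode).  The multinomial
— rather than independent Poissons — matches the "per million mapped
reads" conditioning: RPKM denominators are totals, so depth is fixed by
construction.  Gene copy numbers are represented as non-negative reals
(per-cell population means), which is what makes 2.5 *amoA* copies per AOB
cell exactly invertible by the copy-model correction.

`emitMarkerFasta()` writes marker proteins with ground-truth lineage
labels in the headers.  Lineage base sequences are drawn independently per
lineage (so between-lineage identity stays near the random-alignment
baseline), and each variant substitutes exactly
$\lfloor d \cdot L / 2 \rfloor$ positions — substitutions only, no indels
— so within-lineage pairwise identity is at least $1 - d$ by exact
arithmetic, not in expectation.  Bases are drawn before variants, so the
panel emitted at divergence 0 is a consistent reference set for variants
emitted at any divergence under the same seed.

Every simulator operation consumes one RNG stream derived from its
explicit seed (via `withr::with_seed`), leaving the caller's RNG state
untouched; identical (truth, config) pairs are byte-identical.

## What the simulator does and does not emulate

It reproduces the quantities the normalization chain manipulates:
relative abundances across orders of magnitude, per-cell copy-number
structure, gene inventories with gaps, expression-rate differences,
length/depth confounding, and depth-conditioned multinomial noise.  It
does **not** emulate nucleotide-level sequencing error, read-length or GC
biases, assembly artefacts, chimeras, indel variation among homologs, or
within-lineage abundance structure below the lineage level.  Green tests
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to upstream sequencing pathology.

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `derep_identity` | 1.0 (0.8 for NirK) | phylotype dereplication identity threshold |
| `family_min_identity` | 0.85 | reference identity needed for family assignment |
| `map_identity` / `map_coverage` | 0.90 / 0.60 | read-classification thresholds |
| copy numbers | 1 / 1 / 2.5 / 1.5 / 4 | rpoB; amoA per AOA, AOB, comammox cell; nxrB per Nitrospira cell |
| `activity_threshold` | 1.0 (strict >) | transcript:gene ratio above which a phylotype is active |
| `single_copy_band` | [0.5, 2] | gene:rpoB ratio band consistent with single copy |
| `fold_cutoff` | 10 | expression fold difference flagged as divergent |

All of these live in one run configuration (`defaultRunConfig()`, YAML via
`readRunConfig()`); `runQuantify()` stamps outputs with the config hash
and seed, and reruns of an identical configuration are byte-identical.

# Problem sizes used in validation

The shipped validation suite exercises sampled libraries of $10^6$ reads
(50 seeds for guild-proportion coverage, 20 seeds each for copy-ratio,
activity and profile recovery), 1000 random inputs for the conservation
identity, 100 random sequence sets (up to 50 sequences) against a
brute-force dereplication oracle, and 100 random presence/absence matrices
(up to 30 genomes × 200 clusters) against an exhaustive set-logic oracle.
These sizes make the full suite run in about a minute on one CPU while
keeping every stochastic check's expected failure rate far below its
tolerance.

# Known limitations

* Read classification is ungapped and protein-space only; nucleotide
  reads, six-frame translation and gapped alignment are out of scope — use
  a real aligner and import its count table when those matter.
* Family assignment is purely identity-based; phylogenetic placement and
  tree-topology curation are deliberately not reimplemented.
* The prevalence reading of gene:rpoB ratios assumes single-copy genes;
  multi-copy genes clamp at 100% with a warning rather than pretending to
  a cell fraction.
* Copy-number correction is exactly as good as the copy model: where real
  *nxrB* copy numbers deviate from four, canonical-*Nitrospira*
  differencing inherits that bias (the clamp records only its most extreme
  symptom).
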