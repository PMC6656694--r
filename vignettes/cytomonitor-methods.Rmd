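---
title: "CytoMonitor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CytoMonitor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CytoMonitor)
```

CytoMonitor implements a standardized mass-cytometry (CyTOF) immune
monitoring workflow around a fixed 33-antibody reference panel: bead-based
drift correction, barcode deconvolution, transforms, automated pre-gating
and hierarchical gating, SOM clustering with automatic lineage annotation,
panel-coverage and reproducibility QC, and negative-binomial differential
abundance between clinical groups. This vignette documents the models, the
tunable parameters, and the design decisions behind each stage, and states
precisely what the bundled synthetic-data generator does and does not
emulate.

## The reference panel and lineage definitions

The assay is a fixed panel of 33 metal-tagged antibodies covering the major
immune lineages (17 lineage markers), established subsets (8 markers such
as CD45RA, CCR7, CD25, CD127, FoxP3), activation (Ki-67, Tbet) and
checkpoint molecules (PD-1, PD-L1, Tim-3, CD152), plus two exclusion
markers (CD235ab, CD61). Auxiliary non-antibody channels are the two
iridium DNA intercalators, cisplatin viability (194Pt/195Pt), event
length, acquisition time, and the bead-exclusive 140Ce channel. Three
antibodies (CD235ab, CD61, CD3) are placed on open lanthanide channels
because their printed metal assignments are not machine-readable; the
panel file flags these as `inferred`.

Populations are defined by *marker-sign tables*: each population lists the
antigens that distinguish it from its siblings, at one of four levels —
`pos`/`neg` relative to a per-antigen **primary cutoff** and `high`/`low`
relative to a per-antigen **secondary cutoff**. Graded levels are what
make Treg logic (CD25^high^ CD127^low^ FoxP3^+^) or the
classical/intermediate/non-classical monocyte split expressible. Two
profiles ship with the package: `pbmc_core` (22 leaf populations for
healthy PBMC) and `bmt_subsets` (30 leaves, adding post-transplant
populations such as HLA-DR^−^CD16^+^ cells, CD117^+^ progenitors, DN/DP
T cells and transitional B cells). Both are human-editable YAML and are
validated against the panel (unique metals/antigens, tree shape, sibling
separability by at least one sign clause) by `validatePanel()`.

Sibling order in the table encodes gating priority: an event descends into
the first matching child. Priority children (e.g. Treg before the
CD45RA/CCR7 maturation quadrants) deliberately overlap their siblings;
`applyGating()` reports an overlap warning naming any sibling pair that
co-matches more than 1% of a node's events, which on the packaged trees is
expected for exactly these priority populations.

## Transforms and cutoffs

Raw dual counts are transformed with `asinh(x / 5)`; the cofactor 5 is the
mass-cytometry convention. For clustering, each antibody channel is then
divided by its 99.5th percentile (`percentileNormalize()`), computed per
sample; the divisors are stored in the object so that a cutoff table on
the arcsinh scale can be mapped onto the normalized scale exactly
(`rescaleCutoffs()`), making gating and annotation invariant to the
normalization. Invariance to a global instrument gain is approximate: the
arcsinh turns a gain into an additive shift only in its logarithmic
regime, so small gains leave assignments essentially unchanged while
large gains can move graded-level (secondary-cutoff) decisions.

Cutoffs are data: `defaultCutoffs()` ships the table matched to the
generator (primary 1.8; secondary 3.4 for pos-vs-low antigens, 5.0 for
high-vs-pos antigens, on the arcsinh scale), flagged `manual`.
`estimateCutoffs()` provides a density-based alternative (deepest valley
between the two largest modes; a half-Gaussian 99th-percentile fallback
for unimodal channels), flagged `estimated`. Real analyses are expected to
review estimated cutoffs; the workflow treats them as ordinary inputs.

## The synthetic-data generator

Every downstream stage is tested against simulated data with ground
truth. Marker intensities are Gaussian per population on the arcsinh scale
(censored at zero, mirroring the zero-count spike of real ion counts),
with the four expression levels at fixed locations 0.5 / 2.6 / 4.2 / 5.8
(sd 0.4) and unlisted antigens at the negative baseline. Each population's
profile is the accumulation of its sign clauses from root to leaf, plus a
curated set of population-typical extra markers chosen so that every
template carries at least four positively identifying antigens. These
locations are a synthetic calibration — the source study reports no
per-population intensity distributions — chosen so that positive and
negative modes are separated about as cleanly as in a well-stained panel
(roughly 6 sd between mode and primary cutoff, 2 sd for graded levels).

The generator emulates, per event: EQ calibration beads (high in all five
bead metals, DNA-negative), cisplatin-high dead cells, cell-cell doublets
(raw intensity sums with doubled DNA and ~1.6x event length),
palladium barcode patterns, acquisition time, and a configurable
multiplicative sensitivity drift applied to all mass channels. Per-sample
composition is multinomial over template frequencies; cohorts draw
per-sample frequencies around group medians with logit-normal dispersion.

What it does **not** emulate: mass-spectral physics (ion-cloud overlap,
oxide formation, isotopic spillover), acquisition-rate-dependent doublet
structure, staining batch effects beyond a per-channel location shift, or
non-Gaussian population shapes (e.g. smeared activation continua). Passing
tests therefore demonstrate the *analysis logic* — recovery of known
composition under the stated noise — not robustness to every artifact of
real instruments.

Bundled conditions:

* `pbmc_default`: healthy-donor composition over the 22 `pbmc_core`
  leaves; 5% beads, 2% doublets, 3% dead in the standard test sample.
* `bmt`: a 28-sample cohort (15 donors, 3 with GvHD, up to two pooled
  time points) with lineage medians T 29.0%, monocytes 27.0%, NK 7.1%;
  the GvHD group's CD27^−^ B cells at 0.44% (vs 3.33%) and naive CD4
  T cells at 0.09% (vs 0.3%). The HLA-DR^−^CD16^+^ population absorbs the
  per-sample remainder so the named medians are exact generator
  parameters. The between-sample logit-normal sd is 0.7, matching the
  order of magnitude implied by the published cohort's bootstrap SEMs
  (several tens of percent relative spread — post-transplant composition
  is highly variable); healthy-donor settings use 0.3.

Determinism: all generation uses R's default Mersenne-Twister generator
and is bitwise-reproducible given the seed.

## Bead normalization and debarcoding

`identifyBeads()` requires positivity in *all* five EQ bead metals plus
DNA negativity; bead–cell doublets (bead-positive, DNA-positive) are
excluded from both beads and cells. `fitBeadModel()` windows the beads by
event count (default 500 beads per window, falling back to two windows for
short acquisitions) — windows in events rather than seconds are robust to
acquisition pauses. The per-window factor is the median over bead channels
of (global bead median / window median), a single scalar per window;
per-channel slopes are deliberately not fitted (adequate for multiplicative
drift, simpler to audit). Factors are linearly interpolated between window
centers and applied to every mass channel, including the bead channels, so
that a second application is the identity to within bead sampling noise
(~1–2%). A sharp step in sensitivity is corrected in ratio but smeared
across the transition window by the interpolation; the guarantees are
stated for smooth drift.

`debarcode()` rescales the barcode channels to [0, 1] within each event,
assigns the event to the code matching its top-k channels when the
separation between the k-th and (k+1)-th rescaled intensity reaches the
cutoff (default 0.1, the conventional debarcoder default), and leaves
union-pattern cross-sample doublets unassigned.

## Pre-gating and hierarchical gating

`pregate()` applies, in order: non-beads, DNA^+^, singlets (DNA below the
doublet bound *and* event length below cutoff), live, CD45^+^,
CD235ab/CD61^−^, and a non-neutrophil rule. The neutrophil rule (exclude
CD16^+^ CD14^−^ HLA-DR^−^ CD11b^high^ events) is a documented default that
activates only when the input is declared to contain granulocytes; for
PBMC it is a recorded no-op. The attrition report lists events in/out per
stage and telescopes exactly.

`applyGating()` evaluates the tree depth-first with first-match child
priority; events matching no child stay at the internal node
("ungated-at-level") and are counted as unassigned at leaf level.
Frequencies are fractions of pre-gated events (percent only at the
reporting layer; event indices are 0-based in serialized outputs).

## SOM clustering and automatic annotation

`trainSOM()` is a batch self-organizing map on a 10x10 default grid over
the lineage and subset antigens only (activation and checkpoint channels
are summarized per cluster post hoc, not clustered). The codebook is
initialized from a quantile grid of the data along its first principal
axis; the Gaussian neighborhood radius decays linearly from max(grid)/2 to
zero, with the final three epochs running as pure vector-quantization
(k-means) updates in which empty nodes are re-seeded at the events
farthest from their centroids — the standard empty-cluster handling, which
guarantees small isolated populations representation in the codebook.
Training is deterministic given the seed.

`metacluster()` cuts an average-linkage dendrogram of the codebook at k
(default 30 for the BMT profile, matching the ~30 annotated subsets the
workflow reports). `annotateClusters()` scores every metacluster median
profile against every definition — the score is the fraction of sign
clauses on the correct side of their cutoff — and assigns the deepest
definition whose whole ancestor chain scores at least 0.9; ties prefer the
more specific definition (deeper, then more clauses), then the larger
score, then the lexicographically smaller name. Clause-fraction scores
rather than continuous distances keep labels auditable: every label can be
traced to a set of median-vs-cutoff comparisons.

A single global clustering at k = 30 cannot resolve subsets that are rare
in a 20,000-event sample, so `clusterAnnotate()` refines recursively:

1. every internal population is re-clustered on its own events
   (`subcluster()`), using only the antigens that discriminate its
   subtree, an adaptive grid of about one node per 15 events, and
   node-resolution annotation (k = number of nodes);
2. the subtree root carries the accumulated clause path, so events pooled
   into the wrong lineage by the global pass fail the root and are
   expelled;
3. root-level leaf populations (pDC, basophils, ...) are purified the same
   way; and
4. the expelled/unassigned residue is re-annotated against the full tree
   at fine node resolution, so rare populations absorbed by a foreign
   metacluster (e.g. CD38^high^ B cells inside a pDC cluster) resurface.

With these defaults the bundled BMT samples recover subset frequencies
down to ~10–20 events per sample with relative errors typically under
15%; populations below ~10 events per sample can still be lost to
quantization, which is the expected granularity limit of cluster-level
annotation.

## Statistics

* **Coverage** (`antigenCoverage()`): per-event count of antigens at or
  above their primary cutoff; reported as the median and the fraction of
  cells with at least k (default 4) positives, optionally per lineage.
* **Reproducibility** (`replicateRegression()`,
  `clusterSampleProfiles()`): OLS and Pearson r of gated frequencies
  pooled over populations and donors, on the raw frequency scale (matching
  the published linear fits); complete-linkage hierarchical clustering of
  sample frequency profiles with a mutual-nearest-leaf utility for
  replicate pairing.
* **Bootstrap SEM of the median** (`bootstrapSemMedian()`): sd of the
  median over 1000 resamples with replacement, seeded.
* **Label agreement** (`agreement()`): per-population one-vs-rest
  precision, recall, F1 and MCC with the zero-denominator convention
  MCC = 0, plus macro means.
* **Differential abundance** (`differentialAbundance()`): per population,
  a negative-binomial GLM of counts with log(sample total) offset and a
  group indicator. The dispersion is a method-of-moments estimate with an
  n/(n−2) degrees-of-freedom correction, shrunk halfway toward the cohort
  median (weight configurable); the group coefficient is tested by Wald
  with a t reference on n−2 degrees of freedom and a quasi-likelihood
  Pearson scale factor (floored at 1) guarding against residual
  overdispersion from heavy-tailed between-sample mixing. p-values are
  BH-corrected across populations; time points are pooled. This Wald
  variant diverges from the quasi-likelihood F-test of edgeR by design —
  it is self-contained and simulation-calibrated (per-population type-I
  error 0.04–0.06 at alpha 0.05 under a 1000-rep cohort-shaped null in
  the test suite); a QL-F mode is future work. Populations with all-zero
  counts in a group are flagged and assigned p = 1.

## Numerical and degenerate-input conventions

Zero-event matrices write and read as valid header-only FCS; all-zero
channels pass percentile normalization unscaled with a warning; windows
with zero bead medians are dropped from interpolation; `metacluster(k =
nodes)` is the identity map; metaclusters containing no events annotate as
Unassigned. FCS I/O stores float32 on disk and float64 in memory (stable
percentile and median computations); the reader accepts FCS 3.0/3.1
little- or big-endian float data, the writer emits FCS 3.1 little-endian
list mode with a single DATA segment.

## Problem sizes in the test suite

The bundled checks run on one 50,000-event PBMC sample (coverage, gating
assignment), five 2x20,000-event replicate pairs (reproducibility), one
28x20,000-event BMT cohort through the full clustering pipeline (median
recovery), a 50-seed count-level replication of the cohort design (FDR
ranking), and a 1000-rep count-level null (test calibration). These sizes
reproduce the study design at event counts where the multinomial error of
every reported quantity is well below its between-sample spread.

## Known limitations

Cluster-level annotation cannot resolve populations below ~10 events per
sample; the non-neutrophil pre-gate is a documented convention, not a
published rule; bead normalization fits a single scalar per window (no
per-channel slopes); the DA model pools time points rather than modeling
donors as random effects; and tSNE/Scaffold embeddings are out of scope —
the tested core ends at tables of labels, frequencies and test statistics.
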