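---
title: "Methods: screen scoring, image quantification and interactome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen scoring, image quantification and interactome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectopiscan)
```

`ectopiscan` implements the computational backbone of an image-based
genome-wide RNAi screen for regulators of CENP-A localization, together
with the two downstream quantification arms such a screen feeds:
microscopy measurement of nuclear and metaphase-spread CENP-A signal, and
label-free IP-MS differential interactome statistics. This vignette
documents the models, the tunable parameters, and the design decisions
behind each stage, including where the package deliberately departs from a
naive reading of the underlying assay descriptions.

## 1. Screen scoring

### Data model

A screen consists of 384-well plates with siRNAs stamped into columns
1--22 (three unique, non-pooled siRNAs per gene) and columns 23--24
reserved for controls: a negative (non-targeting) siRNA, a biological
positive control that raises the reporter signal, and a cell-death
transfection control. The per-well readout is the median nuclear
YFP-CENP-A intensity over all imaged cells in the well.

### Plate QC

Each plate's Z'-factor is

$$Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|},$$

computed from the positive- and negative-control wells with sample SDs.
Plates pass at `zprime_min = 0.3` by default — the conventional lower
bound for a usable high-throughput assay window; the threshold is a
parameter because screening campaigns differ in how aggressively they
re-run plates. Manual (visual-inspection) exclusions enter as an explicit
`exclude_plates` list, so they are reproducible inputs rather than silent
edits. Genes whose every plate failed are reported as *untested*, never as
zero scores: absence of evidence must not mimic a null phenotype.

### Normalization and Z-scores

Within each passing plate, every well is expressed as a fold of the
negative-control median (`norm_value`) and as a Z-score against the
negative-control mean and SD (`raw_z`). The Z basis uses the negative
controls rather than all sample wells because a genome-wide library is not
guaranteed effect-free, and the assay was designed around a per-plate
negative reference. A robust variant (median / 1.4826·MAD) is available
behind `robust = TRUE` for plates with control outliers.

### Seed-based off-target correction

siRNAs sharing a guide-strand seed (positions 2--8, a 7-mer — the
standard seed definition; the package represents seeds as 7-mers over
A/C/G/U) repress overlapping off-target transcript sets and therefore
share phenotype regardless of their intended targets. For every seed
family the package estimates a family effect as the **median raw Z of the
member siRNAs, excluding all siRNAs of the gene being scored**
(leave-own-gene-out): a gene cannot vouch for its own phenotype, and a
seed observed only once carries no cross-gene evidence (effect 0). The
gross off-target contribution of an siRNA is the weighted sum of its
family effects — by default a single guide-seed term with weight 1,
because nothing in the assay identifies additional match classes; the
weights and the family aggregator (median or 20% trimmed mean) are
configurable extension points. The on-target score is then

$$z_{on} = z_{raw} - \textstyle\sum_j w_j\,\hat e_j,$$

an identity the package maintains exactly. Gene scores are medians of the
member on-target Z-scores (even-sized medians are midpoints — the
standard median, stable under permutation), and hits are called at
`|gene_z| > 2` with strict inequalities; an optional twofold
median-intensity filter mirrors the reporting convention of intensity
screens.

### The screen generator

`simulate_screen()` embodies this design with known ground truth.
Single-cell intensities are log-normal (fluorescence intensities are
strictly positive and right-skewed) with CV 0.3 and ~1500 cells per well
(Poisson), matching the seeding density of a 384-well high-content assay;
the per-well value is the median cell intensity, so the well-level SD is
the sampling error of a median (`≈ 1.2533·σ/√n`). Planted gene effects
and seed-family effects are expressed in units of that SD — the scale on
which Z-scores live. Plate-level multiplicative shifts (log-SD 0.05)
model batch effects and cancel under within-plate normalization.

Seed families need gene-level structure to be a meaningful challenge: a
gene contributing only one of its three siRNAs to a family is immune at
the gene level, because the median of {shifted, null, null} is null. The
generator therefore populates families from dedicated "confounded" genes
contributing two siRNAs each (to *different* families), while each family
still spans many distinct genes so the leave-own-gene-out estimator has
information to work with. Confounded genes and true-hit genes are
disjoint so sensitivity and false-positive measurements do not interact.

What the generator does **not** model: sequence-realistic seed-match
thermodynamics, spatial within-plate gradients, cross-contamination, or
cell-count-dependent intensity bias. Passing tests therefore demonstrate
correctness of the scoring machinery under the stated statistical model,
not robustness to every artifact of a physical screen.

## 2. Image quantification

### Nuclear segmentation

Nuclei are segmented from the DAPI channel: Gaussian smoothing (σ = 2 px),
a global Otsu threshold, hole filling, and connected components.
Two numerical details matter:

* **The Otsu threshold is computed on log intensity.** Condensed mitotic
  figures are several-fold brighter per pixel than interphase nuclei;
  on a linear histogram a handful of them can capture the threshold and
  push every interphase nucleus below it. The log transform compresses
  the bright tail so the threshold separates background from nuclei.
  Because the image is max-normalized first and the threshold is
  recomputed per image, segmentation is invariant to global intensity
  scaling.
* **Intensities are measured over a 4-px-eroded core** of each component.
  Edge pixels of a blurred object carry partial signal; including them
  biases the mean downward by several percent. Erosion also severs dim
  bridges between close nuclei. The border filter accounts for the
  erosion by adding its radius back when testing proximity to the image
  edge.

In the 1-D Otsu (`otsu_threshold()`), empty histogram bins between two
modes tie exactly in between-class variance; the package splits
mid-valley, which keeps the threshold centred and the classification
invariant to adding constants (hence, on the log scale, to gain changes).

### QC filters

Cells on the image border are removed (their areas and integrated
intensities are truncated). Mitotic figures are flagged when the mean
DAPI exceeds the population **median + 2 × (1.4826·MAD)** *and* the area
is below half the median area. The robust center/spread replaces the
population mean/SD deliberately: with a realistic mitotic fraction the
moment estimates are contaminated by the very outliers the filter must
catch, and measured recall collapses. The two criteria together encode
"condensed and bright": a large G2 nucleus fails the area test, a small
debris particle fails the DAPI test.

### Cell-cycle gating

The EdU/DAPI gate reproduces image-cytometry practice deterministically
rather than with hand-drawn polygons: EdU-positive nuclei (Otsu on log
mean EdU) are S phase; EdU-negative nuclei are split on log integrated
DAPI into G1 (2N) and G2 (4N). The fitted `GateModel` (EdU threshold,
2N/4N modes, split point, and the mode-ratio separation metric) is
returned for audit. If the EdU-negative DAPI distribution is effectively
unimodal (mode ratio < 1.4; a true 4N/2N ratio is ~2) the gate *fails
loudly* instead of assigning phases — a collapsed DAPI distribution means
a staining or segmentation problem that silent assignment would hide.

### Metaphase spreads

The spread pipeline substitutes an automated partition for the manual
ROI-based inspection used at the bench, and its acceptance surface is
generator truth, not manual measurements. Centromeric regions are found
by scale-normalized Laplacian-of-Gaussian blob detection on the CENP-C
(centromere marker) channel within the DAPI chromosome mask, thresholded
at median + 8·MAD of the in-mask response and dilated to a 4-px radius.
Background is the **median** intensity outside the chromosome mask
(robust to bright debris). Centromeric and noncentromeric (arm) means are
background-corrected; negative corrected means are clamped to zero and
flagged rather than silently truncated.

The spread generator places 46 elongated chromosomes with two sister
centromeric foci each (6 px apart, σ = 1.2 px — roughly 0.6 µm separation
and 0.3 µm spot size at 0.1 µm/px). The planted `mislocalization_fraction`
sends that fraction of each chromosome's total CENP-A to a uniform arm
component and the rest to the foci, so condition pairs with a known
arm-signal ratio (e.g. the 5.6× median change used in the tests) can be
recovered as a fold change of per-spread medians. A small, known bias
remains: the Gaussian tails of bright foci leak past the dilated
centromeric region into the arm estimate (sub-percent at moderate
mislocalization fractions).

## 3. Label-free interactome statistics

The differential pipeline follows the canonical processing order:
**filter → impute → (bait-normalize) → test**.

* **Detection filter.** A protein is kept only if it is detected in 100%
  of replicates of at least one condition, with the uninduced/beads-only
  control excluded from qualifying — a protein seen only in the control
  pulldown is background.
* **Downshifted imputation.** Missing LFQ values are left-censored (low
  abundance drops out first), so missing cells are drawn from
  `Normal(μ − 1.8σ, (0.3σ)²)` with μ, σ computed per sample column from
  observed values (total-matrix moments behind a flag). Imputation is
  deterministic given its seed.
* **Bait normalization.** Subtracting the bait's log2 intensity per
  sample expresses prey abundance relative to captured bait, cancelling
  differences in bait expression or pulldown efficiency: any constant
  multiplicative change to one sample's linear intensities leaves every
  bait-normalized value unchanged.
* **s0-moderated test.** `stat = Δmean / (s_p·√(1/n_a+1/n_b) + s0)` — the
  pooled-variance Student t with a SAM-style fudge constant in the
  denominator that damps tiny fold changes measured with tiny variance.
  At `s0 = 0` the statistic is exactly Student's t; |stat| is
  non-increasing in s0. Pooled variance (not Welch) is the default to
  match two-sample Student testing; Welch is a natural extension point.
* **Permutation FDR.** For each threshold `t`,
  `FDR(t) = mean permuted count(|stat*| ≥ t) / observed count(|stat| ≥ t)`,
  with label permutations enumerated exhaustively when the number of
  distinct assignments is ≤ 10,000 (all assignments, including the
  identity) and 250 random assignments otherwise. A protein's q-value is
  the minimum estimated FDR over thresholds at or below its own |stat|,
  capped at 1 — monotone in |stat| by construction. The estimator is
  validated against brute-force enumeration in the tests.

Two consequences of this construction are worth stating plainly. First,
because the identity assignment is part of the enumerated null, every
FDR estimate has a floor of `2/n_assignments` (the observed labeling and
its mirror always count); with a 5v5 design no q-value can fall below
~0.008. Second, strongly differential proteins contaminate the permuted
null through mixed-label assignments, making the estimator conservative
when many large effects are present. Both behaviors are inherent to
all-assignment permutation FDR, and both limit attainable power at very
strict thresholds (e.g. FDR 0.01 combined with a fold-change filter sitting
exactly at the planted effect size); the tests measure this honestly
rather than masking it.

The IP-MS generator plants a wide log2-normal baseline abundance range
(mean 26, SD 2.5), replicate noise of SD 0.4 log2 units, condition-level
effects, per-condition bait offsets (an uninduced control carries a large
negative offset), and missing-not-at-random dropout: detection
probability is a logistic function of true intensity centred at a
detection-limit quantile — the soft left-censoring that downshifted
imputation assumes. A dropout quantile of 0 disables missingness
entirely.

## 4. I/O and reproducibility

Tables are UTF-8 CSV; intensity matrices are tab-separated in the
proteinGroups dialect (zeros are missing markers; `CON__`/`REV__` rows
are dropped on load). Channel stacks are multi-page 32-bit float TIFFs;
since the TIFF float range is [0, 1] and this build of the TIFF writer
exposes no per-page description tags, each page is max-scaled and the
channel names plus scale factors live in a plain-text sidecar
(`<stack>.tif.channels.csv`). Pixel coordinates are row-major and
0-based everywhere.

`run_pipeline()` executes configured stages in order, writes each table
through a `.partial` rename so interrupted runs never leave
complete-looking files, and emits a manifest (package version, config
hash, input checksums, per-stage row counts). Every stochastic stage
takes an explicit integer seed; identical config + seed reproduces
bit-identical outputs.

## 5. Problem sizes and limitations

The test-suite and acceptance problem sizes — a 600-gene screen with 40
planted hits and ten 20-member seed families; 20 effect-free 200-gene
screens for null calibration; 200-protein 5v5 matrices; 512--640 px
images with 50--110 nuclei or 46 chromosomes — were chosen as the
smallest designs in which every statistical property being asserted is
identifiable with comfortable margins.

Known limitations:

* The screen model has no spatial plate effects; the off-target model has
  a single seed term per siRNA with unit weight (multi-term weighted
  sums are supported by the API but not exercised by the generator).
* Image simulation is 2-D with elliptical geometry and no optics model
  (no PSF, no depth effects); segmentation results on real micrographs
  will degrade in ways these tests cannot measure.
* The permutation FDR reproduces the threshold-scan estimator family; it
  is not a reimplementation of any specific proprietary tool, and its
  small-design floor (above) should be kept in mind when combining
  strict FDR levels with small replicate counts.
* The 1-D Otsu gates assume reasonably balanced, separated populations;
  the gate-quality `separation` metric should be inspected when cell
  populations are heavily skewed.
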