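---
title: "Classifying Zingiberaceae spices by multi-spectral data fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Zingiberaceae spices by multi-spectral data fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dried Zingiberaceae fruits (cardamom-family spices such as *Amomum
kravanh*, *Amomum tsaoko*, *Alpinia oxyphylla*) look alike once dried,
peeled and ground, which invites substitution and adulteration. Two
complementary measurement families can tell them apart: untargeted GC–MS of
the volatile fraction, which names and quantifies individual metabolites
but separates species poorly on its own, and NIR/MIR absorption
spectroscopy, which is fast and non-destructive but not compound-resolved.
`spicefuse` implements the full chemometric workflow over both: metabolite
profiling (hierarchical clustering, PCA, OPLS-DA, VIP screening,
permutation validation) and species classification by PLS-DA on three
NIR+MIR multi-block fusion strategies, compared on one shared
Kennard–Stone calibration/validation split.

The original instrument data are not publicly deposited, so the package is
organised around a synthetic-data generator that emulates the study design
from the published per-species summaries; every stage downstream of data
acquisition is implemented and tested against that generator.

## The synthetic-data generator

The emulated design is 13 species × 15 samples (195 samples), with 3
instrument replicates per sample and modality.

**Metabolite table.** Each species' six main volatile metabolites are
tabulated in the packaged reference (`load_table1_fixture()`) with mean ±
SD of relative content (%). The union across species spans 31 metabolites;
a metabolite absent from a species' six is fixed at 0. Sample contents are
drawn from a normal distribution with the species' (mean, SD), truncated
at zero by rejection, because relative contents cannot be negative and
only mean ± SD is published. At the published magnitudes (means ≥ 3.6 SDs
above zero for the dominant compounds) the truncation bias is negligible,
which is why the large-*n* sample mean recovers the tabulated mean within
Monte-Carlo error.

**Spectra.** Each spectrum is a sum of Gaussian bands plus a smooth random
baseline and white channel noise, on the acquisition grids of the study:
NIR 12,000–4000 cm⁻¹ at 8 cm⁻¹ (1001 channels), MIR 4000–400 cm⁻¹ at
16 cm⁻¹ (226 channels). Band positions are the family-common peaks
reported for these spices (NIR 8330/6803/5696/5179/4693 cm⁻¹; MIR
3289/2921/2854/1623/1425/1369/1315/1240/1010 cm⁻¹). Three ingredients give
the classes their spectral identity:

1. *Compound bands.* The amplitude of band *k* for sample *i* is
   `base_k + Σ_m L[k, m] · content[i, m]` with a sparse nonnegative
   loading map `L`: each metabolite loads its 3 strongest bands
   (exponential draws, normalised, 0.06 AU per % content), and each
   compound's contribution sits at its own position within roughly half a
   bandwidth of the shared centre (uniform offsets, ±60 cm⁻¹ NIR,
   ±20 cm⁻¹ MIR). Family-common peaks then arise from overlapping
   compound-specific absorptions — without the offsets the spectra would
   collapse onto a 14-dimensional amplitude space, which is neither
   realistic nor separable for 13 classes.
2. *Species matrix contribution.* The non-volatile bulk (saccharides,
   pectin, fibre) dominates real powder spectra and differs between
   species; the common-band base amplitudes are therefore modulated by a
   fixed per-class offset (15% relative SD between classes) plus
   per-sample within-class variation (3% relative SD, shared by a
   sample's replicates). This is what makes even the low-volatile species
   (e.g. *Alpinia katsumadai*, *Zingiber striolatum*) spectrally
   identifiable, as they are in practice.
3. *Instrument effects.* Replicates of a sample differ only by a smooth
   random baseline (first four Chebyshev polynomials, coefficient SD
   `baseline_drift_sd = 0.01` AU) and white noise (`noise_sd = 0.005`
   AU) — typical FT-instrument magnitudes.

The loading map, band offsets, base amplitudes, and per-class matrix
offsets are drawn once under a fixed internal seed: they are properties of
the simulated instrument + chemistry, deliberately independent of the data
seed, so different data seeds re-sample the *study* (new samples, noise)
rather than a new universe. Identical `(specs, config)` reproduce output
bit for bit.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: chromatographic/mass-spectral artefacts,
retention behaviour, water/scatter effects in reflectance spectra
(SNV/MSC are therefore out of scope), instrument drift between sessions,
nonlinear detector response, and between-batch biological structure beyond
the published per-species mean ± SD. The generator's class separability is
by construction consistent with the study's outcome (all fusion models
reach 100% accuracy); it cannot *demonstrate* that the real species are
separable, only that the workflow recovers separability where it exists.

## Preprocessing and partitioning

Instrument replicates are arithmetically averaged per sample before any
modelling. Variable scaling defaults follow standard chemometrics
practice: autoscaling (unit variance) for metabolite tables, whose
variables live on very different scales, and mean-centering for spectra,
where channel variance carries information. Zero-variance variables keep
scale 1 with a warning rather than erroring, so degenerate columns survive
round-trips.

The calibration/validation split is Kennard–Stone (greedy maximin under
Euclidean distance, most-distant pair first, lowest-index tie-breaks),
applied *within each species* with `ceiling(0.7 × 15) = 11` calibration
samples per class. Only this stratified reading reproduces the study's
143/52 partition from 195 samples — a plain 70% of 195 gives 136 or 137 —
so it is adopted as the package's interpretation. The split is computed
once on the averaged, mean-centered, low-level-fused matrix and reused by
every block and strategy, so all models are compared on identical sample
partitions.

## Latent-variable models

PCA, PLS-DA and OPLS-DA are fitted component-by-component with deflation,
the NIPALS family. One implementation detail matters: the literal NIPALS
inner loop is a power iteration whose convergence rate degrades without
bound as the leading eigenvalues of the cross-covariance kernel approach
each other, which reliably happens beyond ~20 components on 13-class
data. Each component's weight is therefore computed as the *exact* fixed
point of that iteration — the leading eigenvector of the small K × K
kernel `(Y'X)(X'Y)` (PCA: the n × n kernel `XX'`) — which is
deterministic, sign-fixed, and keeps the per-component deflation semantics
that the VIP formula relies on. Fits agree with an independent reference
implementation (mixOmics) to numerical precision.

Classes are dummy-coded (one-hot, sorted class order); Y is
mean-centered; prediction is by row-wise argmax of the predicted
indicators. OPLS-DA removes a configurable number of Y-orthogonal
components — one shared set against the full 13-class indicator matrix,
rather than per-class contrasts — before the predictive fit; with zero
orthogonal components it is prediction-identical to PLS-DA.

VIP is `sqrt(p · Σ_a SSY_a w²_ja / Σ_a SSY_a)` over predictive
components, so mean squared VIP is exactly 1. Screening uses the
inclusive cut `VIP ≥ 1` for differential metabolites, and the strict
`VIP > 1` in mid-level fusion — each convention following its own source
in the workflow being reproduced.

Cross-validation is 7-fold with venetian-blind assignment within each
class (deterministic, no RNG), refitting the scaling inside every fold;
`Q² = 1 − PRESS/SSY`, `RMSECV = sqrt(PRESS/(nK))`. The final fusion
models use the comparison's standard latent-variable counts (23/22/12);
elsewhere a count can be chosen as the smallest A whose Q² is within 0.01
of the maximum (`select_components()`).

## Fusion strategies

* **Low-level**: concatenate the centered blocks, each divided by the
  square root of its total calibration variance so the 1001-channel NIR
  block cannot dominate the 226-channel MIR block by width alone
  (config-overridable).
* **Mid-level (VIP > 1)**: per block, a 10-component PLS-DA on calibration
  rows yields VIPs; variables with VIP > 1 are kept and the reduced blocks
  concatenated as above. An empty selection in any block is an error
  naming the block.
* **Mid-level (latent variables)**: per block, 5 PLS-DA scores and 5 PCA
  scores (counts configurable — the original description does not state
  them) are extracted on calibration rows and concatenated.

Every selection and projection parameter is estimated on calibration rows
only; the test suite verifies that perturbing validation rows changes
neither the selected variables nor the fused calibration matrices.

## Validation conventions

The permutation test refits the model under `n` random label
permutations (the study's setting is n = 200), recording |correlation|
between permuted and original vectorised indicator matrices, training R²Y
and cross-validated Q². Intercepts come from ordinary least-squares lines
through the permuted points *plus* the original point at correlation 1 —
the convention of the standard validation plot — with no robust
weighting. On structured data the Q² intercept falls near or below zero
while the original Q² stands clear of the permuted cloud.

Hierarchical clustering operates on per-metabolite z-scores; the default
linkage is Ward on Euclidean distances (ward.D2), the common choice for
metabolomics heatmaps, with average/complete/single available.
"Upregulated in class c" is not formally defined in the source workflow;
the package adopts the rule *class-mean z-score maximal over classes and
positive*, which assigns each metabolite to at most one class and so
yields disjoint per-class counts of the kind the original heatmap caption
enumerates. This is an interpretive choice, documented as such.

## Numerical and degenerate-input conventions

Wavenumbers are stored descending (the plotting convention); readers
enforce every container invariant as errors, except two documented
warning-level fallbacks (unknown compound class → "other"; zero-variance
variable under autoscaling → scale 1). Eigenvector signs are fixed by
making the largest-magnitude element positive. Ties in Kennard–Stone break
toward the lowest index. A fold that would lose an entire class, a
single-class discrimination, an out-of-range component count, and
non-positive internal-standard areas are all errors.

## Problem sizes

The packaged analyses and tests run the full emulated design (195 samples,
1001 + 226 channels, three replicates) for the fusion comparison, 10,000
samples for generator-recovery checks, and reduced permutation counts (20–50)
in the test suite with the full n = 200 exercised in the metabolite-profiling
driver; these sizes were chosen so the whole suite runs comfortably on a
laptop while leaving every statistical conclusion stable under the fixed
seeds.

## Known limitations

* The affine content→amplitude map and the matrix-offset magnitudes are
  artifact conventions; no quantitative forward model links metabolite
  content to band intensity in the source material.
* OPLS-DA explained-variation figures on the synthetic content table need
  not match figures measured on the real chromatographic data; only
  quantities that are recomputable from published inputs are asserted
  exactly.
* No spectral pretreatment beyond scaling (no SNV/MSC/derivatives); hooks
  exist in the scaling layer but implementations are out of scope.
* High-level (decision-level) fusion is not implemented — the comparison
  under study evaluates low- and mid-level strategies only.
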