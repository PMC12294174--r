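---
title: "Methods: from hypercube to variety call"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from hypercube to variety call}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

jujuspec implements a complete visible/near-infrared (400–1000 nm)
hyperspectral classification workflow of the kind used to discriminate
dried-fruit varieties, exercised end to end on synthetic spectra. This
vignette is the package's account of the science: the model behind each
stage, the tunable parameters and why their defaults are what they are,
what the synthetic generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## The synthetic study

The generator emulates a study design of 15 dried jujube varieties with
180 fruit each, measured as per-fruit mean-ROI reflectance over 229 bands.
Each variety has a noise-free template: a sigmoid rising through the
visible/NIR transition (pericarp browning pushes reflectance up toward the
NIR), minus Gaussian absorption dips at 650 and 670 nm (chlorophyll), 920
and 970 nm (O–H overtones of water), plus a broad water-related bump near
870 nm. Varieties differ three ways, all deterministic in the class index:
a per-class wavelength shift of every absorption feature
(`class_peak_shifts`, default evenly spaced over ±7 nm), a per-class
modulation of feature depths (±25% on a class-indexed sine), and slight
baseline differences (sigmoid midpoint ±3 nm, NIR plateau ±0.01).

Individual fruit deviate from their template by

* a multiplicative scatter gain, `N(1, 0.10)` — particle-size and
  path-length effects;
* an additive offset, `N(0, 0.02)` reflectance;
* a linear baseline tilt, `N(0, 0.03)` reflectance across the full range —
  drift and geometry;
* i.i.d. band noise, `N(0, 0.0015)` — small, because ROI-mean spectra
  average hundreds of pixels.

This noise budget was chosen once, at design time, to reproduce the
difficulty *ordering* that such studies report rather than any particular
number: raw spectra are hardest (scatter, offset and tilt swamp the
between-variety signal), scatter-correcting (MSC) or differentiating
(SG1st) preprocessing recovers it, and tuned models then sit in the
low-to-mid 90s of percent prediction accuracy. What the generator does
**not** emulate: wavelength-correlated (pink) noise, instrument smile,
detector nonlinearity, within-variety biological subpopulations, or any
spatial texture. Passing tests therefore demonstrate that the pipeline's
machinery is correct and leak-free under a realistic covariance structure
— not that any particular accuracy will transfer to real fruit.

Gross outliers (`inject_outliers()`) are a separate mechanism, emulating
acquisition failures: a corrupted sample receives a ±0.3 reflectance
offset, a ±60% gain error, or i.i.d. spikes of sd 0.3 — an order of
magnitude beyond nominal variation, matching the "scattered on the
periphery" character of real spectral outliers. Exactly
`floor(fraction * n)` rows are corrupted so count arithmetic is exact.

## Reflectance calibration and ROI extraction

Raw counts are converted to relative reflectance with the classic
white/dark normalization `R = (raw − dark) / (white − dark)`, elementwise
over the cube. References may be single `cols × bands` frames broadcast
across scan rows, as in line-scan practice. A zero white−dark denominator
is an error naming the first offending pixel/band; reflectance outside
[0, 1] is passed through with a warning rather than clipped, since
clipping would silently bias downstream statistics. Segmentation is plain
threshold-on-grayscale (mean over bands by default; the threshold and
band are deliberately configurable because acquisition setups differ),
optionally keeping the largest 4-connected component; the ROI spectrum is
the arithmetic per-band mean over the mask. The synthetic scene encodes a
known spectrum through the same algebra, so calibration must invert it to
machine precision (≤ 1e−12) — a hard correctness gate, not a statistical
one.

## Isolation-Forest screening

Outlier screening fits an isolation forest on the *raw* reflectance rows,
before any preprocessing — screening is quality control on what the
instrument produced, and preprocessing is fitted downstream of the split.
Scores follow the standard construction: trees of uniformly random
axis-aligned splits grown on subsamples of ψ = min(256, n) rows to depth
⌈log2 ψ⌉, path lengths credited `c(leaf size)` at truncated leaves, and
`s(x) = 2^(−E[h(x)]/c(ψ))`. Defaults (100 trees, ψ = 256) are the
standard literature values. Flagging is top-k by score with
k = ⌊contamination · n⌋ rather than a score threshold, so the survivor
count is deterministic (2700 samples at 5% contamination leave exactly
2565). Screening is global by default; `by_class = TRUE` screens within
each variety instead. Global was chosen as the default because per-class
quotas cap recall when the true outliers are not evenly spread across
varieties — with uniformly random corruption, the multinomial spill over a
per-class quota alone costs ~13% recall in expectation.

## Preprocessing

Three alternatives, applied independently (never chained), all
row-independent and deterministic:

* **Baseline**: subtract the chord through the first and last band (the
  400/1000 nm grid endpoints); corrected endpoints are exactly zero.
* **MSC**: regress each spectrum on a reference (`x ≈ a + b·ref`) and
  return `(x − a)/b`. The reference is the *calibration-set* mean. Rows
  with |b| below 1e−10 pass through with a warning — dividing by a
  near-zero slope would manufacture infinities from a spectrum that
  simply does not resemble the reference.
* **SG1st**: Savitzky–Golay first derivative, window 5, polynomial order
  2 by default (the narrowest quadratic-exact filter; wider windows
  smooth more but blur the 650/670 nm chlorophyll pair, which is only
  ~20 nm wide). Derivatives are per nm — the grid is explicit, so units
  should be physical; the filter is scaled by the mean band spacing and
  assumes a uniform grid. Edges use the polynomial fit of the first/last
  full window, so polynomials up to the fit order differentiate exactly
  everywhere.

Every statistic a preprocessing step estimates (the MSC reference, and
the band-autoscaling centers/scales below) is computed on calibration
rows only and reused for prediction rows; a pipeline test asserts this.

## Band autoscaling and the (C, g) box

The SVM stage works on band-autoscaled features: each band centered,
scaled to unit variance, then divided by √p (p = band count), so the
expected squared distance between unrelated samples is ≈ 2 regardless of
preprocessing. This matters because the hyperparameter box is fixed at
`[0.001, 100]²` for both the cost C and the RBF width g: raw reflectance
and SG1st derivatives differ by three orders of magnitude in native
scale, and without autoscaling a single box cannot serve both (for
derivative features every g ≤ 100 leaves the kernel numerically
indistinguishable from 1). Autoscaling uses calibration statistics only.

## CARS wavelength selection

CARS runs `n_mc` (default 500) sampling runs. Run *i*:

1. draw 80% of the samples (Monte Carlo subsampling);
2. fit a PLS model on the currently retained bands — class labels are
   one-hot encoded, making a multi-response PLS2 problem; each band is
   scored by the Euclidean norm of its coefficient row across responses;
3. the exponentially decreasing function (EDF) fixes how many bands
   survive: `r_i = a·e^(−k·i)` with `a`, `k` pinned by
   `⌈r_1·p⌉ = p` and `⌈r_N·p⌉ = 2`;
4. *which* bands survive is competitive: a weighted draw without
   replacement, probabilities ∝ coefficient magnitude (adaptive
   reweighted sampling). A literal "keep top-K then redraw K from those
   K" would make the ARS step a set-level no-op, so the EDF is read as
   fixing the count and ARS as choosing the members — both mechanisms
   stay live and the count invariant `|retained_i| = ⌈p·r_i⌉` holds
   exactly;
5. the retained set is scored by 10-fold RMSECV (pooled over the one-hot
   responses) on the full calibration set, with a fold assignment fixed
   once per CARS call so runs are comparable.

The selected set is the retained set at minimal RMSECV; because run 1
retains all bands, the selected subset can never score worse than the
full set. The PLS core is SIMPLS, centered internally, with component
extraction stopping early on rank collapse; the maximum component count
defaults to `min(15, p, n − 1)`.

## Hyperparameter search

Four population metaheuristics minimize the SVM's 5-fold stratified CV
misclassification rate over (C, g), all under the study budget:
population 15, 30 iterations, dimension 2, box `[0.001, 100]²`, clipping
to the box after every update, one seeded RNG stream per run, and a
best-so-far trace (monotone by construction):

* **GWO**: candidates steered by the three best solutions via
  `X_k = X_leader − A·|C·X_leader − x|`, `A = 2aλ₁ − a`, `C = 2λ₂`, with
  `a` decaying linearly 2 → 0; the candidate is the mean of the three
  pulls and replaces the member unconditionally (standard grey-wolf
  behavior — the monotone trace is bookkeeping, not greedy acceptance).
* **PSO**: inertia ω = 0.729 with c₁ = c₂ = 1.49445 (the constriction
  values); velocities start at zero.
* **GA**: roulette selection needs positive maximization fitness, so the
  minimized error f maps to `f_sel = (max f − f) + ε`; arithmetic
  crossover with a fresh α ~ U[0,1] per mating (rate 0.9), per-gene
  mutation `N(0, 0.1·range)` at rate 0.1, elitism 1. These are standard
  literature rates; the algorithm-level texts leave them open.
* **ZOA**: a foraging phase toward the pioneer (best) zebra,
  `x + r(PZ − I·x)` with I ∈ {1,2}, then a defense phase — with
  probability ½ a shrinking local perturbation
  `x + 0.01(2r − 1)(1 − t/T)·x`, otherwise a move relative to a random
  herd member — with greedy acceptance in both phases. The published
  zebra-algorithm description is prose plus a population matrix; these
  update forms follow the 2022 source algorithm.

Two engineering choices around the fitness:

* The first population member is initialized at (C, g) = (1, 1), so the
  tuned CV fitness provably never exceeds the off-the-shelf default's —
  a cheap argmin guarantee that costs one of the 465 evaluations.
* `tune_svm()` evaluates the CV fitness on a seeded stratified subsample
  of the calibration rows (default 30 per class). A full-calibration
  evaluation costs several seconds per candidate at the study scale,
  which would put a single tuning run far beyond any interactive budget;
  the subsampled surface is a surrogate with the same leak-free
  construction, and the final model is always refit on the complete
  calibration set at the best (C, g). Set
  `fitness_max_per_class = Inf` to score on everything.

The SVM itself is libsvm C-classification (one-vs-one voting) with the
kernel fixed to `exp(−g‖x − z‖²)` on the features exactly as passed
(`scale = FALSE`), so g means the same thing everywhere in the package.

## Splitting and reporting

Kennard–Stone runs per class (so every variety appears in both sets) with
the classic max–min trace: seed with the most distant pair, then
repeatedly add the sample maximizing its minimal distance to the selected
set, until ⌈0.75·n_class⌉ calibration samples; ties break to the lowest
row index, making the split fully deterministic. Reported accuracy is
percent trace of the confusion matrix; calibration accuracy is
resubstitution accuracy of the refit model (the CV error is reported
separately as the tuning fitness — the texts this follows do not say
which convention their "calibration accuracy" uses, so both numbers are
surfaced). Truth labels unseen in training raise an error by default
rather than silently inflating a row.

## Problem sizes used by the tests and the acceptance script

The unit tests run on reduced designs (4–6 classes, 20–24 samples per
class, 40–60 bands) chosen to exercise every code path in seconds. The
acceptance-level checks run the full synthetic design (15 × 180 × 229)
for screening, splitting and the SG1st + GWO pipeline; CARS recovery
checks use 60 bands with 5 planted informative bands at 50 sampling runs,
and the full 500-run schedule is exercised in the acceptance script. The
sphere benchmark runs all four optimizers at the study budget over 20
seeds.

## Known limitations

* The generator's class structure is deterministic and low-rank; real
  varietal differences are messier, and absolute accuracies here say
  nothing about field performance.
* The ZOA update equations follow the cited source algorithm's prose;
  other implementations differ in how the intensity I is drawn (per
  member here, per dimension elsewhere).
* RMSECV inside CARS uses plain random folds (class-stratified), not
  venetian blinds or contiguous blocks; on time-ordered real data a
  structured CV would be safer.
* `sg1st()` assumes a uniform wavelength grid; strongly non-uniform
  grids would need a local-spacing formulation.
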