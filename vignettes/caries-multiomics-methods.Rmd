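---
title: "Methods: salivary proteomic and oral microbial biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salivary proteomic and oral microbial biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Early childhood caries is a polymicrobial disease with a salivary host
component. `cariomics` implements a complete case/control biomarker-discovery
pipeline for two complementary assays: SELDI-TOF mass-spectrometry profiles
of saliva (an intensity trace over m/z, acquired on an affinity chip) and a
checkerboard DNA-DNA hybridization array measuring the abundance of oral
bacterial taxa (default 82 probes). The pipeline takes raw replicate spectra
and spot-signal tables to a fused feature matrix, screens features with a
rank-based score, and estimates out-of-sample classification performance for
caries-active versus caries-free children under a repeated random-subsampling
protocol.

Because clinical cohorts of this kind are rarely shareable, the package
ships a synthetic cohort generator with planted ground truth. Its defaults
emulate the study design the pipeline targets: 86 caries-active and 118
caries-free subjects, duplicate spectra per subject on one chip/laser
condition, roughly 2,000 detectable spectral peaks between 1,500 and
40,000 Da, and an 82-taxon array with two antagonistic differential
communities.

# Spectral preprocessing

`preprocess_cohort()` applies five steps in a fixed order, recording each in
the spectrum's provenance:

1. **Cube-root variance stabilization** — `sign(y)·|y|^(1/3)`; signed so
   detector ringing below zero is tolerated. The transform is monotone, so
   downstream rank-based screening is unaffected by it.
2. **Baseline subtraction** — the baseline is the moving-window local
   minimum (default width 201 time points, the odd rounding of the
   classical ~200-point window) smoothed by a moving average of the same
   width; corrected intensities are clipped at zero. The estimator is
   parameter-free beyond the window width and tracks the decaying matrix
   background without following peaks, provided peaks are narrower than the
   window.
3. **Total ion current (TIC) normalization** — intensities are scaled so
   the ion current summed over 1,500–16,500 Da equals the cohort's mean
   in-range TIC (a fixed target is also supported). Normalization is
   idempotent and removes per-spectrum multiplicative scale.
4. **Gaussian smoothing** — discrete convolution on the tick axis,
   reflective boundaries, kernel weights summing to one. The default kernel
   SD is 1 tick: peaks in linear-TOF spectra can be only a few ticks wide,
   and a broader kernel (e.g. 5 ticks) measurably merges neighbouring peaks
   at the low-mass end, where the quadratic tick-to-Dalton map is coarsest.
5. **Peak-based dynamic-programming alignment** — see below.

The TIC quality-control rule excludes spectra whose in-range TIC deviates
from the cohort mean by more than 2 SD; the mean and SD are computed within
each chip × laser condition because the TIC scale differs across
acquisition conditions. QC runs after stabilization and baseline
correction — on the signal the normalization itself will see — and before
normalization; running it on raw currents instead would flag the same
gross outliers but at a scale confounded by baseline area. Surviving
replicates are averaged pointwise into one profile per patient after
alignment.

## Alignment

Spectra are miscalibrated relative to each other by a small relative m/z
shift (the generator draws it uniformly within `±warp_max`). Alignment
works on landmarks — the most prominent strict local maxima (up to 300 per
spectrum), with sub-tick parabolic apex refinement because shifts smaller
than one grid step are otherwise invisible. Landmarks of each spectrum are
matched to a reference landmark list by order-preserving dynamic
programming minimizing the total relative shift, with a gap penalty per
unmatched landmark and a hard maximum relative shift (default 0.5%). The
DP is exact; its inner recurrence is a prefix-minimum and vectorizes, so
cohort-scale alignment stays cheap.

Two details matter and are easy to get wrong:

* **The reference.** The mean of miscalibrated spectra is blurred by the
  very shifts being corrected — at 40 kDa a ±0.1% miscalibration is tens
  of ticks, so mean-profile apexes are unstable. The first pass therefore
  aligns to a single sharp spectrum (the one with median in-range TIC) and
  then subtracts the cohort-mean shift field from every warp, centring the
  consensus frame on the cohort instead of inheriting that spectrum's own
  miscalibration. The second pass refines against the mean of the aligned
  spectra, which is sharp. Because two single spectra can differ by twice
  the per-spectrum miscalibration, the first pass doubles the DP matching
  window and gap penalty; the applied warp is still clamped at the
  configured maximum.
* **Resampling.** Warps from all passes are composed and the original
  intensities are resampled once per pass from the accumulated field;
  repeatedly interpolating narrow peaks attenuates them.

Spectra in which no landmark can be matched are passed through unaligned
with a warning.

# Peak calling

Peak selection is two-stage. Positions are identified on the mean profile
of the profiles supplied for identification — inside resampling validation
that is the training fold's profiles only, recomputed per split (the
default; a single global peak set is available but is leakage-prone and
off by default). A tick is a peak if it is strictly maximal within ±5
ticks and exceeds a prominence threshold above the local median; positions
are restricted to 1,500–40,000 Da. Intensities are then assigned to every
profile as the mean over ±radius ticks (radius defaults to the window), which
damps single-tick noise.

The default prominence threshold is 3 × a *local* MAD of the detrended
signal, plus a dynamic-range floor of 2% of the largest prominence. A
global MAD — the textbook choice — misbehaves here for a specific reason:
after cube-root stabilization the noise floor varies strongly along the
axis (the transform expands values near zero), so a single global scale
under-calls quiet regions and over-calls loud ones. The local MAD is the
same statistic estimated in a running window; the dynamic-range floor
keeps residual sub-permille wiggles from being called in regions where the
averaged noise is minute.

# Microbial abundances

Checkerboard spot signals are converted to comparable abundances against
the universal-probe standard lanes:
`abundance = signal × standard_count / mean(universal signals of the sample)`.
The universal lanes carry the per-sample DNA amount, so the ratio removes
it; the `standard_count` constant (default 100) only fixes the unit.
Low-quality spots are masked and imputed as zero — absence of signal in a
checkerboard is informative (undetected taxon) — and samples with more
than half their spots masked are dropped with a logged reason.

# Screening, models and validation

Features are scored by the two-sided Wilcoxon rank-sum P value between
classes; the reported score is −log10 P (base configurable). The exact
permutation distribution is used for small untied samples (total n ≤ 25),
otherwise the normal approximation with tie and continuity corrections.
Being rank-based, the score is invariant to monotone transforms, so it is
indifferent to the stabilization step.

Three classifiers are evaluated: a linear SVM (cost 1 on standardized
features), the same SVM restricted to the top-k Wilcoxon features, and a
random forest (500 trees, √p candidate features per node). k defaults to
20 on the microbial block alone and 100 on the wide proteomic or fused
blocks. Validation is stratified random subsampling: 70:30 train/test,
40 repeats, means ± SD of test error, sensitivity (caries-active is the
positive class) and specificity. Every data-dependent choice —
standardization statistics, Wilcoxon filtering, peak identification —
is computed from the training fold only; models are never modified after
training. ROC curves are built by sweeping the decision threshold over
pooled test-fold scores (for score-based classifiers this traces the same
operating points as varying the misclassification cost), with AUC by the
trapezoid rule and its SD over per-split AUCs. Forest importance is the
permutation measure averaged over the 40 fitted forests, normalized to a
maximum of one.

# Fusion

`match_and_fuse()` inner-joins patients on id and concatenates the
microbial and proteomic blocks column-wise; label conflicts are errors and
dropped patients are reported. Standardization is deferred to model
fitting (training statistics only) because abundances and peak intensities
differ by orders of magnitude. `run_experiment()` evaluates every model on
microbial-only, proteomic-only, and fused data under one shared split
schedule, so cross-condition comparisons are paired.

# The synthetic generator

Each spectrum is `scale × (Σ Gaussian peaks + baseline) + noise` observed
under a per-spectrum miscalibration, on a quadratic tick→Dalton map
(m/z ∝ tick², linear-TOF-like). Peak width grows proportionally with m/z;
centres sit on a jittered log-uniform grid, which makes the
spacing-to-width ratio constant along the axis so neighbours are equally
resolvable everywhere. The baseline is a decaying exponential plus a small
linear term; intensities are stored raw so stabilization is meaningful.
Subject-level biology enters through per-peak log-normal height variation,
and class effects through log-fold changes on a differential subset (15
enriched per direction by default). Within each direction a shared
per-subject latent factor co-varies the markers — communities and
co-regulated proteins move together — which caps block-level separability
realistically instead of letting it grow with the square root of the
marker count. The microbial model mirrors this: 82 taxa, two disjoint
antagonistic communities (6 + 6 differential taxa, log-fold 1.3), shared
community factors, per-sample DNA scale carried by the universal lanes.

Default effect sizes were fixed once so that the three data conditions
land in the qualitative regimes the method is known for: the microbial
block classifies best with the forest at roughly 9–20% error, the
proteomic block is weaker, and the fused data beat both for the margin
classifiers, while the forest on the full fused matrix is rescued by
top-100 filtering. After those defaults were set they were not revisited.

What the generator does *not* emulate: chip chemistry beyond a metadata
tag, isotope structure, site-resolved plaque sampling (one microbial
profile per subject), heavy-tailed spot artifacts, or batch effects.
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
internal correctness and its directional behaviour, not clinical
performance.

A note on peak counts: 2,000 peaks are planted, and the caller recovers
roughly 1,100–1,400 at study scale. At the simulated resolution the
low-mass end cannot hold 2,000 baseline-resolved peaks of proportional
width, so a fraction merge — the fused matrix still has well over a
thousand columns, which is the regime that matters for the
dimensionality-sensitivity experiment.

# Numerical choices and degenerate inputs

* Windows are odd and centred; the baseline window must be ≥ 3 and no
  wider than the spectrum.
* Zero in-range ion current, a zero universal-probe signal, single-class
  labels, empty landmark sets, and out-of-axis peak positions are all
  explicit errors (or warnings with pass-through, for alignment).
* Ties in scores are broken by original feature order; splits and forests
  are seeded, and every generator, split schedule and fit derives from one
  master seed, so a full `run_experiment()` is byte-identical across runs.
* All-tied rank-sum input returns P = 1 rather than NaN.

# Validation scales

The test-suite checks run at reduced but structurally faithful scales
chosen once: sparse 30-peak cohorts for recovery and alignment checks; a
300-peak/8,192-tick geometry for null calibration (three independent null
cohorts of 204 subjects, averaged, because a single finite cohort carries
chance feature-label structure that resampling validation legitimately
detects); and the full 2,000-peak, 204-subject, 40-split design for the
fusion experiment. The acceptance script reruns the same computations from
scratch at the same scales.

# Known limitations

* Alignment estimates a consensus frame; a cohort-wide calibration offset
  of a fraction of the per-spectrum miscalibration can remain. It cancels
  in any cross-sample analysis and shrinks with cohort size.
* The checkerboard model starts from background-subtracted spot signals;
  image quantification is upstream of this package.
* No nested hyperparameter tuning and no probability calibration; the
  models are used exactly as the validation protocol specifies.
* The univariate screen is used for ranking and filtering only; no
  multiple-testing-corrected inference is offered.
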