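---
title: "Unhealthy white matter connectivity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unhealthy white matter connectivity: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwmc)
```

## The measure

White matter hyperintensities (WMH) are bright lesions on T2 FLAIR MRI and a
marker of cerebral small vessel disease. Conventional summaries (global or
lobar lesion volume) ignore *where* lesions sit relative to the brain's
wiring. Unhealthy white matter connectivity (UWMC) localizes lesion burden on
the connectome: for an unordered pair of brain regions $\{a, b\}$ with $T$
end-to-end tractography streamlines between them, of which $U$ pass through
at least one WMH voxel,

$$\mathrm{UWMC}_{ab} = U_{ab} / T_{ab} \in [0, 1].$$

A streamline counts toward a pair only when its two endpoints land in two
distinct labeled regions ("end-to-end"); streamlines with an unlabeled end or
both ends in one region are ignored. Lobar UWMC for a bilateral lobe is the
ratio of sums $\sum U / \sum T$ over pairs with both regions in that lobe —
a ratio of sums, not a mean of per-pair ratios, so well-connected pairs carry
proportionally more weight — and global UWMC is the same ratio over every
pair in the brain. Pairs with $T = 0$ are retained with UWMC 0 and a
zero-denominator flag rather than dropped: zero connectivity is data, and the
downstream log transform handles the zeros explicitly.

The package consumes co-registered inputs on one voxel grid (a labeled
parcellation, a lesion mask or FLAIR image, a tractogram in world mm) and
refuses grid mismatches rather than resampling; registration is an upstream
concern, and silent resampling hides its errors.

## Streamline–lesion intersection geometry

Whether a polyline "passes through" a voxel mask needs a concrete geometric
rule. We use the nearest-neighbour convention throughout: a world point
belongs to the voxel whose index is the rounded inverse-affine image, so each
voxel owns a unit cell centred on its grid coordinate. `passes_through()`
then enumerates, per polyline segment, every cell boundary crossing and tests
each traversed cell — an exact computation in which a single touched lesion
voxel counts, with no minimum overlap length.

We initially considered the simpler rule of densifying each segment to
half-voxel spacing and testing sample points. That approximation misses
lesions clipped by a chord shorter than the step — on random streamline sets
it disagreed with a 0.01 mm dense-sampling reference in several percent of
cases — so exact traversal is the default, and `intersection_config()` keeps
sampled mode only as an explicit option. Endpoint-to-region matching is
exact-voxel by default; an optional Chebyshev-radius majority vote
(`endpoint_dilation`) is available for parcellations that do not quite reach
the tract termini, with ties resolving to "unlabeled".

## WMH segmentation

Segmentation reproduces a minimal intensity-only chain:

1. **Reference normalization.** Every FLAIR voxel is rescaled to
   $(x - \mu_{\mathrm{ref}}) / \sigma_{\mathrm{ref}}$ using the mean and SD
   over a cerebellar white matter mask, a territory spared by supratentorial
   small vessel disease. This puts subjects with arbitrary scanner scaling on
   one intensity scale.
2. **Two-class fuzzy c-means.** On the 1-D intensities of cerebral-mask
   voxels we minimise $\sum_i \sum_k u_{ik}^m (x_i - c_k)^2$ with the
   standard membership update. Defaults: fuzzifier $m = 2$ (the classical
   choice; the literature on FLAIR lesion clustering rarely departs from
   it), convergence when the largest centroid move drops below $10^{-5}$,
   cap of 300 iterations. Centroids are initialised at the 10th and 90th
   percentiles of the in-mask intensities: deterministic, so no RNG and no
   label-swap ambiguity — the "high" class is simply the larger converged
   centroid. The per-iteration objective is retained so tests can assert it
   never increases. No spatial regularisation is applied: the model is a
   per-voxel intensity classification.
3. **Threshold.** A voxel is WMH iff its high-intensity membership strictly
   exceeds 0.75 (`>`, not `>=`; a membership of exactly 0.75 is excluded).
   The threshold is applied to the raw membership map, with no smoothing and
   no minimum-cluster-size cleanup, and no manual editing stage exists.

Degenerate inputs fail loudly: a zero-variance reference, an empty cerebral
mask, or identical in-mask intensities are errors; hitting the iteration cap
returns a result flagged `converged = FALSE` with a warning rather than
silently proceeding.

## Lobar lesion volume

As the proof-of-concept comparator, lobar WMH volume is the lesion voxel
count per lobe label times the voxel volume $|\det A_{3\times3}|$ (correct
for anisotropic voxels), normalized by intracranial volume to a unitless
ratio. Lesion voxels outside the four lobes are tallied under `other`, never
dropped. Published tables sometimes print this ratio on an unstated
multiplicative scale; we report the raw ratio and expose a display
multiplier (default 1) rather than guess a hidden constant.

## Statistical pipeline

**Transforms.** Connectivity fractions, lesion volumes, and weekly physical
activity are right-skewed, so models use natural logs, with exact zeros
replaced by 0.05 before the log. Natural log is what justifies the reporting
rule: for a coefficient $\beta$ on $\ln(\mathrm{UWMC})$, a 1% greater
predictor changes the outcome by $\beta \ln(1.01) \approx \beta / 100$, so
`per_percent_effect()` is exactly $\beta/100$, reported to 3 decimals.

**Stability selection.** With hundreds of candidate pairs and ~200
participants, single-fit feature selection is unstable. Each of 120
repetitions removes a fresh random 10% of participants, standardizes the
candidate features on the remaining 90% (covariates enter unpenalized and
unstandardized; the outcome is untouched), and fits an elastic net
(mixing parameter 0.5) whose penalty is chosen by 10-fold cross-validation;
features with nonzero coefficients at the chosen penalty count as selected
for that repetition, and features chosen in at least 90% of repetitions
survive. The forced covariates are age, sex, racialized group, education,
physical activity, diabetes, hypertension, high cholesterol, and APOE ε4.

The penalty is the cross-validation *one-standard-error* value, not the MSE
minimum. At these dimensions the MSE-minimizing penalty sits near zero in
almost every refit, admitting dozens of spurious features each time; because
the resampled subsets overlap heavily, the same spurious features recur and
reach selection frequency 1.0, defeating the frequency filter entirely. The
1-SE rule is the standard parsimonious cross-validation choice for
screening, and under it simulated active sets are recovered exactly while
pure-noise panels select nothing. `penalty_choice = "min"` remains available.
All resampling derives from `seed + repetition`, so frequency maps are
bit-reproducible and independent of feature column order.

**Robust regression.** Each selected predictor enters its own Huber
M-regression of the cognition score on the log predictor plus the covariate
set (racialized group only in full-sample models), fitted by iteratively
reweighted least squares with tuning constant 1.345 (95% Gaussian
efficiency), scale re-estimated by MAD each iteration, and a coefficient
change tolerance of $10^{-8}$. Connectivity fractions produce genuine
outliers — zero-inflated logs among them — and the Huber loss bounds their
influence while remaining an ordinary least-squares fit whenever no
standardized residual exceeds the threshold. P-values use the large-sample
normal approximation on the robust standard error; the reference
distribution for these fits is not settled in the applied literature, and at
the sample sizes involved the normal and $t$ versions are practically
indistinguishable.

**FDR and the conditional interaction rule.** Benjamini–Hochberg step-up
control at $q = 0.05$ is applied per analysis column: the full-sample tests
of one pathology-set analysis form one family, and each stratified column
its own family. The group-by-predictor interaction is fitted in the full
sample only when exactly one stratum's test was rejected — the question
"does racialization modify this association?" only arises when the strata
disagree — and is otherwise reported as absent.

**Descriptives and validation.** Group comparisons use Mann–Whitney U for
continuous variables (median with quartiles) and Pearson chi-square for
categorical ones, switching to Fisher's exact test when any expected cell is
below 5. The median split on global UWMC assigns values exactly at the
median to the high group. Lobar UWMC is validated against lobar WMH volume
by Spearman rank correlation with average ranks for ties.

## The synthetic-data generator

No imaging data ship with the package; every test input is generated.

`make_phantom()` builds spherical labeled regions, streamline bundles as
jittered curves with a sinusoidal mid-course offset (endpoints strictly
inside their spheres, so endpoint labeling is unambiguous without dilation),
and a lesion mask planted to hit each bundle's target crossing fraction
*exactly*: each designated crossing streamline receives one lesion voxel
near its midpoint that no other streamline's geometric cell set touches, and
an independent 0.1 mm dense-sampling pass re-verifies the pattern before the
phantom is returned. Optional bulk lesion voxels (placed only in cells no
streamline traverses) give segmentation-mode runs a realistic lesion load
without altering any crossing. The synthetic FLAIR is N(0, 1) background
with lesion voxels at N(6, 1) by default — a well-separated mixture — plus a
disjoint N(0, 1) reference block standing in for cerebellar white matter.

`make_cohort()` draws covariates matched to a community-dwelling
older-adult cohort (age uniform 50–89; prevalences 0.667 female, 0.497 BA,
0.383 hypertension, 0.353 high cholesterol, 0.313 APOE ε4, 0.169 diabetes;
education near 14 years; activity log-normal with median 9.3 h/week).
Per-pair UWMC is Beta(2, 8) — right-skewed with mass near zero, the shape
lobar connectivity fractions show in practice — zero-inflated at 5%, with an
optional Beta-mean shift for the BA group reproducing the qualitative
BA > nHW burden pattern. The cognition score is a linear model on the log
features and covariates plus Gaussian noise, clipped to [0, 30] and rounded,
with every generating parameter recorded in a `truth` attribute.

What the generator does *not* emulate: scanner physics (bias fields, motion,
partial volume), anatomically curved fasciculi, spatially contiguous lesion
growth, correlated covariates, or the real cohort's exact distributions.
Passing tests therefore demonstrate correctness of the computation and
recoverability under the stated generative model, not clinical performance
on real scans.

## Problem sizes and numerical choices

Test suites run phantoms of 32–48 voxels per side with bundles of 4–10
streamlines, selection studies at $n = 300$ with 50 candidate features over
20 replicate seeds, and regression studies at $n = 200$; these sizes give
stable pass/fail behaviour for the properties under test while keeping a
full run in minutes on one core. Coordinates are world RAS mm with 0-based
voxel indices; volumes refuse affine mismatches above $10^{-4}$; FCM
tolerance is $10^{-5}$ on centroid movement; IRLS tolerance is $10^{-8}$ on
coefficients; ties in the endpoint majority vote resolve to "unlabeled", and
ties in rank correlations use average ranks.

## Known limitations

- Tractography quality control (alignment checks, topology-informed
  pruning) is upstream; the package consumes tractograms as given and only
  logs counts.
- The candidate pair panels derived from the bundled label table enumerate
  all $n(n-1)/2$ pairs of each pathology set (861 amyloid, 66 tau);
  published analyses have sometimes used one pair fewer under exclusion
  rules that are not stated, so any such exclusion is left to configuration.
- The bundled pathology-set flags are reconstructed from field-standard
  composites (the amyloid-PET composite regions; the meta-temporal set) and
  are labelled synthetic; study-specific sets should be supplied as a TSV.
- Streamline counts are unweighted; length- or volume-weighted connectomes,
  directed connectivity, and lesion subtypes are out of scope.
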