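---
title: "Echo-equivalent grading of LV diastolic dysfunction from 4D flow MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo-equivalent grading of LV diastolic dysfunction from 4D flow MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowgrade)
```

## The grading algorithm

`flowgrade` implements the threshold-based, multiparametric 2016 ASE/EACVI
decision tree for LV diastolic function, adapted so the same structure runs
on either echocardiographic or 4D flow MRI measurements. The tree has two
stages.

**Routing and diagnosis.** Subjects with depressed EF (below the
modality-specific routing threshold) or known structural myocardial disease
enter the grading stage directly. All others pass a four-criterion
diagnosis stage:

* average E/e′ > 14 (E over the mean of septal and lateral e′),
* reduced e′: septal e′ < 7 cm/s **or** lateral e′ < 10 cm/s (one
  criterion, matching the structure of the guideline algorithm),
* elevated pulmonary arterial pressure: TR > 2.8 m/s (echo) or
  t_vortex > 15 % (4D flow),
* enlarged left atrium: LAVI above the modality's threshold.

More than half of the *available* criteria positive diagnoses dysfunction;
exactly half is indeterminate; fewer than half is normal. On echo, a
non-detectable tricuspid regurgitation makes the pressure criterion
*unavailable* rather than negative — absence of a measurable jet is not
evidence of normal pressure. The 4D arm has no unavailable criteria:
t_vortex is always evaluable from the same acquisition, which is one of
the method's practical advantages.

**Grading.** E/A ≤ 0.8 with E ≤ 50 cm/s is grade 1 (impaired relaxation);
E/A ≥ 2.0 is grade 3 (restrictive filling). Otherwise three criteria
(average E/e′, pulmonary pressure, LA size) decide: at least two positive →
grade 2 (pseudonormal); at least two negative → grade 1; a 1-vs-1 split
with the third unavailable → indeterminate. A subject who reached grading
through a positive diagnosis receives at minimum grade 1 — an indeterminate
split cannot demote an established diagnosis — whereas subjects routed by
depressed EF or myocardial disease may legitimately end indeterminate.

All cutoff comparisons are strict, exactly as thresholds are conventionally
printed ("E/e′ > 14"); the complementary grading branches use ≤ / ≥ so a
value exactly at a threshold classifies deterministically on the
non-positive side. The boundary behaviour is pinned by tests that flip each
criterion with an epsilon across its cutoff.

## Cutoff transfer between modalities

The 4D flow cutoff set differs from the echocardiographic one in exactly
three slots, derived by two rules.

**Rule 1 — bias adjustment (volumetric parameters).** For each paired
parameter the package computes the classical Bland–Altman comparison:
bias = mean(echo − 4D), 95 % limits of agreement bias ± 1.96·SD of the
differences (the 1.96 normal multiplier, not a t quantile — the classical
convention), Pearson r, and a zero-bias test gated by Shapiro–Wilk at
α = 0.05 (one-sample t when normality is not rejected, Wilcoxon signed-rank
otherwise). A threshold c on the echo scale transfers to c − bias on the 4D
scale. The default policy adjusts EF and LAVI only — volumetric measures
differ systematically between modalities (endocardial border conventions,
atrial foreshortening) while the velocity parameters do not — and an
`"auto"` policy instead applies the α = 0.05 gate per parameter. Adjusted
cutoffs are rounded to integers, the precision at which volumetric
thresholds are stated; with the conventional biases −5 % (EF) and
−13 mL/m² (LAVI) this yields 55 % and 47 mL/m².

**Rule 2 — the vortex surrogate (pressure parameter).** TR is not measured
by the single 4D flow acquisition; the duration of vortical flow in the
main pulmonary artery stands in for it. The link is a segmented linear
model through the peak tricuspid pressure gradient pTR = 4·TR² (mmHg):

t_vortex = slope · max(0, pTR − pTR₀).

`fit_segmented` minimises the residual sum of squares over (pTR₀,
slope ≥ 0) by profiling: for a fixed breakpoint the slope has a closed-form
least-squares solution on the hinge covariate, with flat-segment points
contributing their zero-prediction residuals (they are part of the model,
not discarded). The surrogate cutoff is the model prediction at
pTR(2.8 m/s) = 31.36 mmHg, with a subject-level percentile bootstrap CI
(default 2000 resamples, refitting per resample, seeded). Only subjects
with detectable TR enter the fit — pTR is unknown, not zero, for the rest.

## Numerical choices

* **Breakpoint search.** 200 grid candidates across the observed pTR range
  locate the global basin; `stats::optimize` (golden-section plus parabolic
  interpolation) then refines within the bracketing interval to a 1e-8
  tolerance. The objective is piecewise smooth in the breakpoint with one
  kink per data point, so a grid of this density cannot miss the global
  basin at realistic n; tests verify the profile fit never exceeds a dense
  brute-force grid oracle and that noiseless data are recovered to 1e-6.
* **Slope constraint.** A negative unconstrained slope optimum is clamped
  to 0 and flagged (`slope_clamped`); a zero-slope model yields a zero
  surrogate cutoff flagged as degenerate.
* **Fit quality** is reported as R = sqrt(1 − SSE/SST), the square root of
  the coefficient of determination about the mean response, clamped at 0.
* **Degenerate Bland–Altman inputs** (constant differences) keep the
  documented semantics: limits collapse onto the bias, the normality p is
  `NA`, and the zero-bias p is 1 for identical series and 0 for a constant
  non-zero shift.
* **Kappa CI.** The paper-tier convention for a weighted kappa interval is
  the large-sample (Fleiss–Cohen–Everitt) variance with a normal
  approximation; that is what `weighted_kappa` reports. Linear disagreement
  weights |i−j|/(k−1) are the default: on the package's reference 5×5
  table they reproduce the conventional headline value (0.84), while
  quadratic weights would overstate it (≈ 0.94).
* **Bowker symmetry test.** The McNemar-type trend test on a 5×5 table is
  computed over off-diagonal pairs with at least one discordant count;
  empty pairs are excluded from the degrees of freedom. Note the statistic
  is *not* invariant under adding a symmetric matrix to the table — the
  discordant differences are, but the pair totals grow — so the tests
  assert monotonicity rather than invariance.
* **Accuracies** use exact Clopper–Pearson intervals (via
  `stats::binom.test`), rounded to integer percent as conventionally
  printed.
* **ICC.** Interobserver reliability uses ICC(A,1) of McGraw & Wong
  (two-way model, single measure, absolute agreement) with the standard
  F-based CI; absolute agreement penalises systematic rater offsets, which
  a consistency ICC would forgive.

## The synthetic cohort generator

`simulate_cohort` emulates the *statistical structure* of a paired
validation cohort, not its physiology. Defaults encode the study
conditions the analysis assumes:

* 94 subjects with echo-grade mixture 51/9/13/13/8 over
  normal/indeterminate/grade 1/2/3, enforced exactly by per-subject
  rejection sampling against the echo decision tree;
* grade-conditional latent parameter distributions chosen so the tree
  assigns the intended grade with high probability before rejection
  (per-grade velocity distributions are not published; these are the
  package's own plausible choices, and indeterminate subjects are
  produced by targeting an exact 2-of-4 criterion split, the only route
  to indeterminate in the normal-EF path);
* inter-modality biases (echo − 4D) of −5 % EF and −13 mL/m² LAVI,
  unbiased velocities;
* inter-modality correlations EF 0.75, LAVI 0.80, E 0.87, A 0.84 (via
  E/A), septal e′ 0.80, lateral e′ 0.86, achieved by splitting measurement
  noise equally across the two arms with per-arm SD
  τ = σ_latent·sqrt((1−r)/r), where σ_latent is the mixture SD implied by
  the grade-conditional distributions (delta-method approximation for A);
* t_vortex generated from the latent TR through the segmented model
  (breakpoint 18.4 mmHg, slope 1.19 %/mmHg) plus a Gaussian residual of
  SD 2 percentage points floored at 0;
* echocardiographically non-detectable TR with probability 25/94,
  recorded as missing;
* myocardial disease probability 1 for grades 1–3 and 0 otherwise,
  mirroring a two-arm recruitment design in which the
  structural-heart-disease patients are the graded-dysfunction subjects.

What the generator does **not** emulate: within-subject physiological
coupling beyond the grade labels (E with e′, LAVI with NYHA class, …),
non-Gaussian measurement error, rater effects, or any imaging content.
Consequently, green end-to-end tests demonstrate that the pipeline's
statistics recover the structure they assume — they do not demonstrate
clinical performance on real data. One visible artefact of the simple TR
structure is that the default cohorts separate the vortex relationship
more cleanly than real data would (fit R typically above the ≈ 0.9 a real
cohort shows).

Determinism: the generator, the bootstrap and the pipeline draw all
randomness from explicit seeds; identical (config, seed) reproduces a
cohort byte-for-byte, and pipeline artifacts are written at fixed rounding
so re-runs are bit-identical.

## Design decisions on genuinely open points

* **Fused E/A.** When A is absent or zero, E/A is undefined and grading
  raises a diagnostic error rather than guessing; irregular-rhythm
  exclusion makes this rare in the intended population.
* **One e′ site missing.** The error contract names only the
  both-sites-missing case, so a single available site is used alone for
  the average and the reduced-e′ criterion.
* **Rounding of transferred cutoffs** uses the computed bias rounded to
  the stated precision of the target threshold (integer for EF/LAVI);
  whether published values were rounded before or after adjustment is not
  recoverable from stated results.
* **CI method for the surrogate cutoff** is unspecified in the
  conventional reporting; the package uses a subject-level percentile
  bootstrap as the assumption-light choice, so reproduction of any
  particular published interval is approximate by construction.
* **Flat-segment residuals** are included in the SSE (zero-prediction
  residuals); excluding or down-weighting them would bias the breakpoint
  towards the data minimum.

## Problem sizes

The shipped tests run the generator at n = 94 (and one 10× calibration
check at n = 940), the segmented-fit recovery at n = 69 with 200
replicates, the statistic-oracle comparisons on 100 random 5×5 tables,
and bootstrap CIs at 100–500 resamples; the full suite completes in well
under a minute. These sizes were chosen to match the scale of the study
design the package addresses while keeping the suite fast; all of them
are arguments, so heavier replications are one call away.

## Known limitations

* The grading tree covers the general-population branch of the 2016
  algorithm only; special-population rules (atrial fibrillation, mitral
  stenosis, pacing) are out of scope by design.
* Calibration is constant-bias only; a proportional (regression-based)
  bias would require a different transfer rule.
* The kappa CI is asymptotic; for very sparse tables a bootstrap or exact
  method would be preferable.
* The surrogate cutoff inherits the segmented model's assumption of a
  sharp breakpoint; a smooth transition would bias pTR₀ slightly upward.
* No multi-rater (> 2) agreement statistics.
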