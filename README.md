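# flowgrade

Grading of left ventricular (LV) diastolic dysfunction from 4D flow MRI,
validated against echocardiography.

## The problem

Echocardiography is the reference method for non-invasive evaluation of LV
diastolic function. The 2016 ASE/EACVI recommendation grades dysfunction
with a multiparametric, threshold-based decision tree over EF, LAVI, the
transmitral velocities E and A, the early diastolic annular velocities
(septal and lateral e', averaged for E/e'), and the tricuspid regurgitant
peak velocity TR. 4D flow MRI measures echo-equivalent counterparts of all
of these from a single acquisition — except TR, for which the duration of
vortical blood flow along the main pulmonary artery (t_vortex, in % of the
cardiac interval) serves as a surrogate marker of elevated pulmonary
arterial pressure.

`flowgrade` is for imaging researchers who want to (a) run the
echo-equivalent grading tree on either modality and (b) reproduce the full
method-comparison analysis that justifies transferring echocardiographic
cutoffs to 4D flow:

1. **Bias-adjusted volumetric cutoffs** — Bland–Altman analysis of paired
   EF/LAVI values; with bias b = mean(echo − 4D), the echo threshold c
   becomes c − b on the 4D scale (50% → 55% for EF with b = −5;
   34 → 47 mL/m² for LAVI with b = −13). Velocity thresholds are kept
   where the zero-bias test is non-significant.
2. **Surrogate pressure cutoff** — the segmented (hockey-stick) linear
   model t_vortex = slope · max(0, pTR − pTR₀), with pTR = 4·TR² (mmHg,
   simplified Bernoulli), fitted by profiled least squares over the
   breakpoint. Evaluated at pTR(2.8 m/s) = 31.4 mmHg, the fitted model
   (pTR₀ = 18.4 mmHg, slope = 1.19 %/mmHg) predicts the grading cutoff
   t_vortex > 15%.
3. **Agreement statistics** — 5×5 grade cross-classification,
   linear-weighted Cohen's kappa with asymptotic CI, Bowker symmetry
   (McNemar-type) test for directional over/under-grading, exact
   Clopper–Pearson accuracy intervals, and two-way absolute-agreement
   single-measure ICC for interobserver data.

A synthetic paired-cohort generator (`simulate_cohort`) reproduces the
statistical structure such a validation study assumes — grade mixture,
grade-conditional parameter distributions, inter-modality biases and
correlations, the segmented vortex relationship, and non-detectable TR in
about a quarter of subjects — so the whole pipeline is exercisable without
patient data.

## Worked example

```r
library(flowgrade)
cohort <- simulate_cohort(cohort_config(), seed = 7)
res <- run_full_pipeline(cohort, seed = 7, n_boot = 500)
print(res)
```

```
Diastolic-dysfunction grading validation pipeline

Diastolic grading cutoffs (flow4d)
  EF < 54 %   LAVI > 47 mL/m^2
  E > 50 cm/s   E/A in (0.8, 2)
  septal e' < 7 cm/s   lateral e' < 10 cm/s   E/e' > 14
  t_vortex > 16 %

Segmented linear model: t_vortex = slope * max(0, pTR - pTR_0)
  pTR_0 = 18.12 mmHg   slope = 1.205 %/mmHg   R = 0.972
  n = 76 points
  surrogate t_vortex cutoff: 16.0% (15.1%, 16.9%)

Grade cross-classification (rows = method A, cols = method B), n = 94 
               b
a               normal indeterminate grade1 grade2 grade3 Sum
  normal            47             2      0      0      0  49
  indeterminate      3             5      0      0      0   8
  grade1             1             0     13      0      0  14
  grade2             0             2      0     13      1  16
  grade3             0             0      0      0      7   7
  Sum               51             9     13     13      8  94
Cohen's weighted kappa (linear weights): 0.91 (0.85, 0.97)
  n = 94, discordant = 9
Bowker symmetry test: chi^2 = 4.200, df = 4, p = 0.380
```

Reading the output: the simulated cohort's true inter-modality biases are
−5% (EF) and −13 mL/m² (LAVI), so the calibrated 4D cutoffs land next to
55% / 47 mL/m²; the segmented fit recovers the generating breakpoint and
slope (truth 18.4 mmHg, 1.19 %/mmHg) and turns them into a surrogate
t_vortex cutoff near 15%; grading both arms with their own cutoff sets
then agrees almost perfectly (weighted κ > 0.8), with no evidence of
systematic over- or under-grading (Bowker p ≫ 0.05).

The built-in reference cross-classification is available directly:

```r
res <- run_full_pipeline(table4 = TRUE)
round(res$agreement$kappa$kappa, 2)      # 0.84
round(res$agreement$symmetry$p.value, 2) # 0.53
```

## Package tour

| Function | Purpose |
| --- | --- |
| `default_cutoffs`, `grading_cutoffs` | threshold sets per modality |
| `grade_subject`, `grade_cohort` | the adapted ASE/EACVI decision tree |
| `bland_altman`, `bias_adjust_cutoff`, `calibrate_cutoffs` | cutoff transfer (rule 1) |
| `tr_to_ptr`, `fit_segmented`, `surrogate_cutoff` | vortex surrogate model (rule 2) |
| `build_contingency`, `weighted_kappa`, `bowker_symmetry`, `accuracy_ci`, `icc_absolute_single` | agreement statistics |
| `parameter_report` | per-parameter bias/correlation/accuracy tables |
| `simulate_cohort`, `cohort_config`, `fixture_table4` | synthetic cohorts and the reference table |
| `run_full_pipeline` | calibrate → fit → grade → agree, with artifacts |

See the methods vignette (`vignettes/diastolic-grading.Rmd`) for the model
details, the generator's assumptions, and known limitations.
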