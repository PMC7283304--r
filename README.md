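# ctpfiv

Tools for comparing **arrival-time-sensitive (ATS)** and
**arrival-time-insensitive (ATI)** CT-perfusion post-processing in their
ability to predict the **final infarct volume (FIV)** in acute ischemic
stroke — the question a stroke-imaging group faces when deciding which
deconvolution family and which map thresholds to trust.

CT perfusion yields a 4D attenuation dataset; deconvolving each voxel
curve $C(t)$ against an arterial input function $a(t)$ under the
indicator-dilution model

$$C(t) = \mathrm{CBF}\cdot (a \circledast R)(t - \delta), \qquad
\mathrm{CBV} = \mathrm{CBF}\cdot\mathrm{MTT}/60,$$

gives the parametric maps CBF, CBV, MTT, TTP and Tmax (the time of the
residue maximum, which recovers the bolus-arrival delay $\delta$).  ATS
solves the causal Toeplitz system by truncated SVD and degrades under
delay (CBF underestimated, MTT overestimated); ATI solves the
block-circulant, zero-padded system and is delay-invariant.  Binary
lesion predictions from full-range threshold sweeps over each map (e.g.
Tmax 1–16 s in 0.5 s steps — 31 thresholds) are scored voxel-wise against
the FIV; each threshold is one ROC point, optimal thresholds maximize the
Youden index (sensitivity + specificity − 1) or Dice coefficient
$2|P\cap R|/(|P|+|R|)$, and predicted volumes are correlated with FIV by
Pearson's r.

Because the patient datasets behind such comparisons are not
redistributable, the package ships a digital perfusion phantom with known
regional CBF/CBV/MTT/delay truth and a treatment-dependent ground-truth
FIV (whole hypoperfused territory for untreated/failed-thrombectomy
subjects, core only after successful thrombectomy), so every pipeline
stage is testable end to end.

## Worked example

A full synthetic experiment — 54 subjects (25 group A, 29 group B), both
algorithms, full-range sweeps, pooled per-group ROC, optimal thresholds
and volume correlations:

```r
library(ctpfiv)
res <- run_pipeline(list(seed = 1))

res$optimal_thresholds
#>   group algorithm parameter criterion threshold     score
#> 1     A       ATI      tmax      dice      2.00 0.9276555
#> 2     A       ATI      tmax    youden      2.00 0.8878056
#> 3     B       ATI   cbf_rel      dice      0.25 0.7336739
#> 4     B       ATI   cbf_rel    youden      0.45 0.9438999

res$correlations
#>   group criterion     r_ati     r_ats     p_vs_ats
#> 1     A      dice 0.9774361 0.9634919 1.670287e-01
#> 2     A    youden 0.9774361 0.9634919 1.670287e-01
#> 3     B      dice 0.8861659 0.8227116 1.199682e-02
#> 4     B    youden 0.9580037 0.8227116 7.621097e-05

subset(res$auc, parameter %in% c("tmax", "cbf_rel") & algorithm == "ATI")
#>    group algorithm parameter       auc
#> 12     A       ATI      tmax 0.9503891
#> 13     A       ATI   cbf_rel 0.9960137
#> 28     B       ATI      tmax 0.9886353
#> 29     B       ATI   cbf_rel 0.9950227
```

Reading: on this phantom the pooled group-A Dice-optimal Tmax threshold is
2 s with Dice 0.93 (the noiseless-lesion boundary sits just above the
normal-tissue Tmax, so low thresholds already separate; noise broadens the
per-subject distribution), ATI volume correlations exceed the ATS
factory-rule correlations in both groups, and Tmax / relative CBF are
strong cohort-level discriminators.  The phantom's crisp regions make all
scores higher than clinical values; the comparisons, not the absolute
numbers, are the point.

Lower-level entry points: `build_subject()` / `build_cohort()` /
`planted_delay_cohort()` (phantom), `deconvolve_ats()` /
`deconvolve_ati()` / `compute_map_set()` / `compute_relative_maps()`
(maps), `resample_mask()` / `make_eval_mask()` (alignment),
`make_threshold_grid()` / `roc_curve()` / `optimal_threshold()` /
`per_subject_optima()` / `ats_default_prediction()` (threshold
evaluation), `mask_volume()` / `correlate_volumes()` / `compare_groups()`
(cohort statistics).  See the vignette in `vignettes/` for the model,
numerical choices and experiment designs.

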