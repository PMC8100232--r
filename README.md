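# alpsdti

Quantifying glymphatic function from diffusion tensor imaging with the
ALPS ("analysis along the perivascular space") index, and asking a
clinical question with it: is peritumoral brain edema (PTBE) around
meningiomas associated with impaired glymphatic clearance?

The package is aimed at neuroimaging researchers who want a tested,
scriptable version of the full analysis chain — from diffusion-weighted
volumes to the case-control statistics — together with synthetic
phantoms and cohort simulators that make every stage verifiable without
patient data.

## What it computes

At the level of the lateral ventricle body, the deep medullary veins and
their perivascular spaces run right–left (image x axis), perpendicular
to both the corona radiata projection fibres (craniocaudal, z) and the
superior longitudinal fasciculus association fibres
(anterior–posterior, y). Excess water mobility along x in those fibre
populations is attributed to the perivascular compartment and condensed
into one ratio of tensor diagonal elements averaged over two
single-slice ROIs:

```
ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)
```

An index of 1 means no preferential perivascular diffusion; higher
values mean more. Around this the package provides:

* **tensor** — the monoexponential forward model, weighted log-linear
  per-voxel tensor estimation from 4-D NIfTI + FSL bval/bvec input, FA /
  principal-direction / directionally-encoded colour maps
  (`synthesize_signal()`, `fit_tensor()`, `scalar_maps()`);
* **alps** — ROI extraction of the four axis diffusivities, the index,
  and two-observer averaging (`extract_axis_diffusivities()`,
  `compute_alps()`, `average_observers()`);
* **volumetry** — tumor/edema volumes from stacks of planar polygonal
  ROIs (shoelace area × slice thickness, multi-lesion summation) or
  binary masks (`polygon_area()`, `stack_volume()`, `mask_volume()`);
* **phantom** — a periventricular diffusion phantom with a tunable
  perivascular diffusivity boost and closed-form ground truth
  `(λ⊥ + boost)/λ⊥`, plus a cohort simulator calibrated to published
  group parameters (`generate_phantom()`, `generate_cohort()`,
  `simulate_two_observers()`);
* **stats** — Lilliefors normality screening, absolute-agreement
  two-way random-effects ICC with F-based CI, age/sex-adjusted ANCOVA
  with Bonferroni pairwise contrasts, Pearson correlation, variance
  inflation factors and p-value-driven stepwise regression
  (`ks_normality()`, `icc_absolute_agreement()`, `ancova_pairwise()`,
  `pearson()`, `vif()`, `stepwise_regression()`);
* **pipeline** — file-based orchestration and reporting
  (`run_alps_pipeline()`, `run_group_comparison()`,
  `run_correlation_analysis()`, `study_report()`), plus a thin CLI at
  `inst/cli/alpsdti` with `simulate-phantom`, `simulate-cohort`,
  `alps`, `volumes`, `compare`, `correlate` and `report` subcommands.

## Worked example

A noiseless phantom with `λ⊥ = 0.8e-3` and perivascular boost `0.4e-3`
has closed-form index 1.5; fitting tensors from its synthesized signals
and extracting the ROI diffusivities recovers it:

```r
library(alpsdti)
ph  <- generate_phantom(phantom_config(lambda_perp = 0.8e-3,
                                       perivascular_boost = 0.4e-3,
                                       snr = 0))
alps_from_phantom(ph)$right
#> alps_result: subject phantom, right hemisphere, 1 observer(s), index 1.5000
```

A simulated right-side cohort (group sizes 13/31/44 at the published
ALPS means and SDs) through the full statistical pipeline:

```r
cohort <- generate_cohort(cohort_config(seed = 7))
grid <- run_group_comparison(cohort, sides = "right")
grid[grid$response == "alps_right",
     c("pair", "difference", "p_adj", "ci_low", "ci_high")]
#>                                    pair difference    p_adj ci_low ci_high
#> 1         control vs meningioma_no_ptbe    -0.3301 1.27e-13 -0.419  -0.241
#> 2            control vs meningioma_ptbe    -0.0421 4.04e-01 -0.110   0.026
#> 3 meningioma_no_ptbe vs meningioma_ptbe     0.2880 5.14e-11  0.198   0.378
```

The meningiomas without edema sit well above both other groups
(Bonferroni-adjusted p ≪ 0.001, joint 95% CIs excluding 0), while the
edema group is indistinguishable from controls — the qualitative
pattern the adjusted contrasts are designed to resolve. In the edema
group, the ipsilateral index dominates the correlates of edema volume:

```r
run_correlation_analysis(cohort)
#> correlation analysis in the edema group (n = 31)
#>           variable      r        p  n
#> 1              age  0.047 8.01e-01 31
#> 2              sex  0.246 1.82e-01 31
#> 3      tumor_grade -0.281 1.25e-01 31
#> 4             ki67  0.203 2.73e-01 31
#> 5         location  0.059 7.54e-01 31
#> 6     tumor_volume  0.157 3.98e-01 31
#> 7 alps_ipsilateral -0.785 1.69e-07 31
#> stepwise: selected alps_ipsilateral, ki67 (R^2 = 0.671)
#>           variable           b   beta        p
#> 1 alps_ipsilateral -289.256393 -0.794 5.76e-08
#> 2             ki67    3.233873  0.233 4.07e-02
```

The negative standardized coefficient on the ipsilateral index is the
simulated inverse ALPS–edema relationship being recovered; the Ki-67
term in this particular draw is the kind of occasional noise selection
a p≤0.05 entry rule is expected to admit (see the vignette). Two
observers' measurements are screened for agreement with the
absolute-agreement two-way random-effects ICC:

```r
icc_absolute_agreement(cbind(obs1 = c(1.42, 1.31, 1.27, 1.55, 1.22, 1.38),
                             obs2 = c(1.45, 1.28, 1.30, 1.52, 1.25, 1.41)))
#> ICC(A,1) = 0.965, 95% CI 0.801-0.995, P = 0.000255 (n = 6, k = 2)
```

## Documentation

The methods vignette
(`vignettes/alps-glymphatic-pipeline.Rmd`) documents the model and its
assumptions, the phantom and cohort-simulator design decisions, the
exact forms of every statistic, and known limitations.
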