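---
title: "Quantifying glymphatic function with the DTI-ALPS index: models, phantoms and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glymphatic function with the DTI-ALPS index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The measurement problem

The glymphatic system moves cerebrospinal fluid through the perivascular
spaces of penetrating vessels, flushing interstitial solutes out of brain
parenchyma. Its activity cannot be observed directly in routine imaging,
but at the level of the lateral ventricle body the deep medullary veins —
and with them the perivascular spaces — run right–left (the image x
axis), while the two dominant white-matter populations there run
craniocaudally (corona radiata projection fibres, z) and
anterior–posteriorly (superior longitudinal fasciculus association
fibres, y). Water mobility along x in those fibres is therefore *not*
explained by the fibres themselves, and the excess is attributed to the
perivascular compartment.

The ALPS index condenses this into one ratio of diffusion-tensor
diagonal elements averaged over two single-slice ROIs:

$$
\mathrm{ALPS} \;=\;
\frac{\operatorname{mean}\!\left(D_{x,\mathrm{proj}},\, D_{x,\mathrm{assoc}}\right)}
     {\operatorname{mean}\!\left(D_{y,\mathrm{proj}},\, D_{z,\mathrm{assoc}}\right)} ,
$$

where $D_{x,\mathrm{proj}}$ is the mean $D_{xx}$ over the
projection-fibre ROI, $D_{y,\mathrm{proj}}$ the mean $D_{yy}$ there, and
$D_{x,\mathrm{assoc}}$, $D_{z,\mathrm{assoc}}$ the analogous means over
the association-fibre ROI. An index of 1 means no preferential x
mobility; values above 1 indicate diffusivity along the perivascular
direction beyond what the fibre geometry predicts. `compute_alps()`
implements exactly this ratio; "x-axis diffusivity" is read as the
tensor diagonal element in image coordinates, not as a projection onto
any fitted vessel direction, and the final per-subject value is the
arithmetic mean of the two observers' indices
(`average_observers()`) rather than of their diffusivities — the two
differ only at second order in the inter-observer differences.

The package applies this measurement to a clinical question: does
peritumoral brain edema (PTBE) around meningiomas reflect failing
glymphatic clearance? The analysis compares the index across meningioma
patients without PTBE, with PTBE, and controls (adjusting for age and
sex), and asks which of seven clinical covariates explains PTBE volume.

## Tensor model and estimation

Signals follow the monoexponential tensor model
$S_k = S_0 \exp(-b_k\, g_k^\top D\, g_k)$ over an acquisition with at
least one $b=0$ volume and at least six non-collinear directions
(`acquisition_scheme()` checks unit norms; identifiability is checked by
the rank of the diffusion-weighted design). The default scheme mirrors
a clinical protocol: 20 directions at $b = 1000\,\mathrm{s/mm^2}$, one
unweighted volume.

`fit_tensor()` solves the log-linearised model per voxel: an ordinary
least-squares pass on $\log S$ for every voxel at once, then one
signal-squared-weighted refinement, which is the standard correction for
the heteroscedasticity introduced by the log transform and is fully
deterministic — at $b = 1000$ a nonlinear fit buys essentially nothing.
Numerical choices:

* multiple $b=0$ volumes are averaged before fitting;
* non-positive signals are floored at `min_signal` (default $10^{-8}$)
  and the voxel flagged `floored`;
* fitted tensors failing a Sylvester positive-definiteness check are
  eigendecomposed, eigenvalues clipped at `eig_floor` ($10^{-6}$
  mm²/s — small enough not to bias white-matter diffusivities, large
  enough to keep downstream ratios defined) and the voxel flagged
  `clipped`; ROI extraction warns when a clipped voxel contributes;
* all-zero voxels get a zero tensor and are flagged rather than
  propagating `-Inf` through the fit.

`scalar_maps()` derives FA, the principal eigenvector and the
directionally encoded colour map used to place ROIs (projection fibres
dominant in the z/blue channel, association fibres in y/green).

## The periventricular phantom

`generate_phantom()` builds the minimal geometry the index needs, not a
brain: two axis-aligned fibre slabs per hemisphere in an isotropic
background. Projection voxels carry
$\mathrm{diag}(\lambda_\perp + \beta,\ \lambda_\perp,\ \lambda_\parallel)$,
association voxels
$\mathrm{diag}(\lambda_\perp + \beta,\ \lambda_\parallel,\ \lambda_\perp)$,
where the perivascular boost $\beta$ is the tunable x-diffusivity excess
emulating perivascular water movement. The ground truth is closed-form:

$$\mathrm{ALPS}_{\mathrm{true}} = \frac{\lambda_\perp + \beta}{\lambda_\perp},$$

independent of $\lambda_\parallel$, of $S_0$ and of global diffusivity
scaling — which is what makes the phantom a sharp identifiability test
for the whole fitting/extraction chain.

Defaults, chosen once as the simulated study conditions: a
64×64×12 patch of 2 mm isotropic voxels (matching a 128 matrix over a
256 mm field of view with 2 mm sections), $\lambda_\parallel = 1.4$,
$\lambda_\perp = 0.8$, background $0.8$ (all $\times 10^{-3}$ mm²/s,
typical deep white matter values), $\beta = 0.2\times10^{-3}$ (ground
truth 1.25, a plausible control-range index), SNR 30 with 4 signal
averages (the protocol's NSA), additive Gaussian noise. Gaussian rather
than Rician noise is a deliberate simplification: at SNR ≥ 10 the
Rician bias is negligible and the additive model keeps the noise
invertible for round-trip tests. Slabs are `nx/8` voxels wide and span
the central three quarters of y; the measurement ROIs are the full slab
cross-section on the middle slice. These phantom ROIs are much larger
than the ~29 mm² clinical ROIs: averaging several hundred voxels is
what pushes the noise-induced index error below 0.01 at SNR 30 (the
package's identifiability tests); clinically sized ROIs work but give
proportionally noisier estimates. What the phantom does *not* emulate —
anatomy, CSF spaces, tumor signal, partial-volume mixtures, spatially
correlated noise, observer variability in ROI placement — bounds what a
passing round trip shows: the estimator chain is correct, not that real
measurements are this precise.

## The cohort simulator

`generate_cohort()` draws subject tables with the structure the
statistics consume. Group sizes and per-hemisphere ALPS normals default
to the published right-side comparison parameters
(`study_group_params()`): 13 meningiomas without PTBE
(right ALPS $1.502 \pm 0.089$), 31 with PTBE ($1.260 \pm 0.112$), 44
controls ($1.215 \pm 0.093$), with the corresponding left-side columns.
PTBE volume in the edema group uses a truncated-normal marginal
($67.1 \pm 46.8$ cm³, truncated at 0) — the published information is a
mean, an SD and bin counts, so the shape is a declared stand-in, not an
inference. The inverse correlation between edema volume and the
ipsilateral index (default $\rho = -0.68$) is induced by a Gaussian
copula: the ipsilateral ALPS z-score and a latent volume z-score are
drawn jointly normal, and the volume then receives its truncated-normal
marginal through its quantile function. This honours non-negative
volumes while distorting the Pearson correlation by well under 0.01 at
these parameters. Age is normal truncated to [18, 95]
($58.8 \pm 13.5$ for patients, $53.3 \pm 10.0$ for controls), sex
Bernoulli (43/80 women), grade II/III 19/80, skull-base location 15/80,
Ki-67 $4.8 \pm 3.1$ truncated at 0, tumor volume $58.6 \pm 45.3$
truncated at 0.5 cm³. All draws are seed-reproducible, and the RNG
state of the session is restored afterwards.

`reference_cohort()` is different in kind: a deterministic
80-row table whose *marginals* match the published descriptive counts
exactly (sex 37/43; locations 12/1/2/39/23/2/1; grades 61/15/4; volume
bins 7/15/28/22/8 and 24/15/15/17/9; sides 44/36; mean age 58.8). The
joint assignment of attributes to rows is an arbitrary construction —
the published table gives no joint information — so the object is a
loading/descriptive fixture, shipped as
`inst/extdata/reference_cohort_synthetic.csv`, and nothing more.

## The statistical battery

* **Normality screen** — `ks_normality()` wraps the
  Lilliefors-corrected one-sample Kolmogorov–Smirnov test
  (`nortest::lillie.test`), the correct form when mean and SD are
  estimated from the sample. The flag is recorded; the pipeline's
  comparisons proceed parametrically, as the study design prescribes.
* **Inter-observer agreement** — `icc_absolute_agreement()` computes the
  single-rater, absolute-agreement, two-way random-effects intraclass
  correlation (McGraw–Wong ICC(A,1)) from the two-way ANOVA mean
  squares, with the F-distribution confidence interval and p-value.
  Absolute agreement is the right form for interchangeable observers:
  a rater with a constant offset is penalised, where a consistency ICC
  would score 1. Zero between-subject variance leaves the coefficient
  undefined and is flagged rather than silently returned.
* **Group comparison** — `ancova_pairwise()` fits the additive model
  `response ~ group + age + sex` and reports all pairwise differences of
  covariate-adjusted group means. Under an additive model those equal
  the differences of the group coefficients, so the contrasts, their
  pooled-variance standard errors and p-values come straight from the
  fit (verified against estimated-marginal-means software in the test
  suite). Each raw p is multiplied by the number of pairs (3) and capped
  at 1; intervals are widened to the matching joint level. The
  Bonferroni family is the three pairwise contrasts of one response in
  one tumor-side cohort — families are not pooled across the four
  side × hemisphere combinations, mirroring one model per reported row.
  `run_group_comparison()` assembles the full 2 sides × 2 responses × 3
  pairs grid and skips a side whose cohort lacks a group. One caveat
  worth stating: with covariates whose true effect is zero, the
  covariate-adjusted contrast p is *close to* but not identical to the
  unadjusted ANOVA p in any finite sample (the fitted covariate
  coefficients are never exactly zero), so the package's tests check
  calibration and close tracking, not numerical identity.
* **Correlates of edema volume** — `run_correlation_analysis()` takes
  the PTBE subset (n ≥ 10), computes seven Pearson correlations against
  edema volume — age, sex, grade, Ki-67, location, tumor volume and the
  ipsilateral ALPS index, with binary variables on their 0/1 coding
  (man = 0/woman = 1, grade I = 0/II–III = 1, non-skull-base = 0/
  skull-base = 1), i.e. point-biserial correlations — screens the same
  candidates with variance inflation factors
  ($\mathrm{VIF}_j = 1/(1-R_j^2)$, exact collinearity reported as
  infinite and flagged), and runs `stepwise_regression()`.
* **Stepwise selection** — classic p-value-driven stepwise: forward
  entry of the smallest partial-F p at or below 0.05, backward removal
  at or above 0.10 after every entry, ties broken by the smaller entry
  p then by candidate order; the thresholds are the common defaults of
  the clinical statistics software the procedure originates from. An
  intercept-only model is a valid, non-error outcome. Standardized
  coefficients ($\beta = b\,s_x/s_y$) are reported for the final model.
  A property worth knowing when reading simulation results: with one
  strong predictor and $m$ null candidates at entry level $\alpha$, the
  probability that the selected set is *exactly* the true predictor is
  about $(1-\alpha)^m$ (≈ 0.74 for $m = 6$, $\alpha = 0.05$) — the null
  candidates each retain their ~5% entry rate regardless of how strong
  the true effect is. Selection procedures at these conventional
  thresholds are expected to drag an occasional noise variable along;
  only the *inclusion* of the true predictor is near-certain.

## Worked example

```{r example, eval = FALSE}
# phantom -> tensors -> index (noiseless: recovers the closed form)
ph <- generate_phantom(phantom_config(lambda_perp = 0.8e-3,
                                      perivascular_boost = 0.4e-3,
                                      snr = 0))
alps_from_phantom(ph)$right$index        # 1.5 to within 1e-6

# simulated right-side cohort through the full statistical pipeline
cohort <- generate_cohort(cohort_config(seed = 7))
run_group_comparison(cohort, sides = "right")
run_correlation_analysis(cohort)
```

## Problem sizes and runtime choices

The test suite runs its Monte-Carlo checks at sizes chosen to keep the
whole suite in the low minutes while leaving the acceptance tolerances
honest: 1000 replicates for the group-contrast pattern, the correlation
recovery and the stepwise power checks; 400 replicates for the stepwise
null-calibration rate; 200 for the ANCOVA-calibration property; marginal
convergence at $n = 10^4$ against 3-standard-error bands; phantom
identifiability over a seven-point boost grid at SNR 30. Where a check
needs many tensor fits, the tests use a 16×16×6 phantom — every
property being tested is resolution-independent — and the default
64×64×12 phantom appears where its noise-averaging matters.

## Limitations

The phantom validates estimator mechanics, not biological claims; the
cohort simulator reproduces the *reported group structure*, so pipeline
results on simulated cohorts say nothing about patient-level data
beyond what those printed moments imply. Volumetry assumes
area × thickness with no inter-slice interpolation, polygons drawn to
exclude dural tails/necrosis/calcification are the ROI author's
responsibility, and no registration, ROI automation, eddy/motion
correction or non-Gaussian diffusion modelling is attempted.
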