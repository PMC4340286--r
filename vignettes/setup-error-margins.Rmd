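---
title: "Setup-error decomposition, van Herk margins and paired-modality comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Setup-error decomposition, van Herk margins and paired-modality comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setupmargins)
```

## The model

Daily image-guided localization records, for each treatment fraction, the
couch translation that aligns the day's cone-beam CT to a reference image
(the planning CT, or here also a simulation MRI). The standard population
model for those shifts, per axis $a \in \{AP, SI, LR\}$, is

$$ x_{pfa} = \mu_a + s_{pa} + \varepsilon_{pfa}, \qquad
   s_{pa} \sim N(0, \Sigma_a^2), \quad
   \varepsilon_{pfa} \sim N(0, \sigma_a^2), $$

where $\mu_a$ is the cohort bias, $s_{pa}$ the patient's *systematic*
error (one draw per patient, constant over the course: a planning or setup
offset repeated every day) and $\varepsilon_{pfa}$ the *random*
inter-fraction error. The estimators, which are what
`decompose_setup_error()` computes:

* $M_a$ — mean over patients of the per-patient mean shifts;
* $\Sigma_a$ — sample SD ($n-1$ divisor) over patients of the per-patient
  mean shifts;
* $\sigma_a$ — RMS (divisor $n$, the number of patients) of the
  per-patient daily-shift sample SDs.

Patients are weighted equally regardless of fraction count: each
contributes one mean and one SD. Per-patient summarization
(`summarize_patients()`) uses the $n-1$ sample SD; a patient needs at
least two fractions for a defined SD, and zero-variance patients are legal
(they contribute 0 to the RMS). Missing shift cells are dropped per axis,
not per record, to keep the remaining axes' data.

The CTV-to-PTV margin follows the van Herk population recipe

$$ \text{margin}_a = 2.5\,\Sigma_a + 0.7\,\sigma_a , $$

which targets delivery of at least 95% of the prescribed dose to the CTV
for 90% of the population: the factor 2.5 is the radius (in per-axis SDs)
of the sphere enclosing ~90% of an isotropic 3D Gaussian systematic-error
distribution, and 0.7 converts the dose blurring caused by random errors
into an equivalent expansion. `coverage_monte_carlo()` makes the first
claim checkable: the chi distribution with 3 degrees of freedom gives
$P(\lVert Z \rVert \le 2.5) = `r round(pchisq(2.5^2, 3), 4)`$, and the
Monte-Carlo estimate converges to it.

```{r coverage}
coverage_monte_carlo(1e5, 2.5, seed = 1)
```

## Rounding modes

Published cohort tables round $\Sigma$ and $\sigma$ to two decimals and
then apply the margin formula, and round the margin again. The package
exposes both conventions: `rounding = "table"` (the default, and the mode
under which the bundled cohort's six published margins reproduce exactly)
and `rounding = "raw"`, under which `margin == 2.5*Sigma + 0.7*sigma`
holds to machine precision. Report output rounds half *away from zero*
(`round_away()`), matching clinical table formatting, rather than base R's
round-half-to-even.

```{r margins}
summ <- read_summary_table(fixture_path("table4_patient_summaries.csv"))
decompose_setup_error(summ, "CT")
```

One documented quirk of the bundled cohort: the published $\sigma$ cell on
the CT SI axis prints 0.43 while recomputation from the printed
per-patient SDs gives 0.42 — and the published margin (0.64) matches the
*recomputed* value, suggesting the original $\sigma$ row was taken from
unrounded raw data. The fixtures carry the recomputable value; tests
assert agreement within 0.01 and flag the cell.

## Paired-modality comparison

When every patient's CBCTs are registered to both a CT and an MRI
reference, `compare_modalities()` reports per-patient differences of mean
shifts (MRI − CT) and their cohort mean and SD. The pairing level is
recorded explicitly as `patient_mean`: from published per-patient
summaries only patient-level means are recoverable, whereas a
fraction-level SD of differences would need the raw paired shifts. The
direction convention (MRI − CT) and the antisymmetry property
(swapping roles negates all means) are fixed by tests.

The decomposition excludes patients from *all four* statistics when asked
(`exclude =`): an outlier whose anatomy differed between the two
simulation sessions (bowel preparation) distorts $M$ as well as $\Sigma$,
so a partial exclusion would be incoherent.

Registration reproducibility (`registration_reproducibility()`) pools
within-task sample variances over repeated registrations of the same image
pair and reports the per-axis square-root mean — an estimate of the
registration operation's own noise floor, separate from patient motion.

## Volume and dose comparison

`percent_difference()` is $100\,(V_{CT} - V_{MRI})/V_{MRI}$ — how much
larger the CT-based measurement is, relative to MRI. Cohort summaries
average *per-patient* percent differences (a mean of ratios): with skewed
volume distributions this differs noticeably from the ratio of means, and
it is the convention under which the bundled cohort's published summary
rows (39.7 / −1.7 / 61.1 / 27.5 % for volumes; −1.01 / −0.11 / 0.12 % for
doses) reproduce exactly. The significance test is a two-sided *paired*
t-test on the raw values (not the percentages), $t = \bar d / (s_d/\sqrt
n)$ with $n-1$ df. Degenerate inputs ($s_d = 0$) are flagged rather than
tested: p = 1 when all differences are zero, p = 0 for a nonzero constant
difference.

The bundled dose fixture's published SD row prints negative values for two
metrics, which cannot be standard deviations; those cells are not
reproduced (the fixture's provenance note says so) and the package reports
the SD of the per-patient percent differences instead. The bulk
electron-density assignment behind the MRI dose recalculation (bone
480 HU, soft tissue 0 HU, air −1000 HU) is carried as a documented
constant (`bulk_density_map()`); no dose calculation is in scope.

## The synthetic cohort generator

`synthetic_cohort_config()` parameterizes a generative counterpart of
every input. Its defaults *are* the bundled cohort's conditions, chosen
once and not tuned: nine evaluable patients; 42 fractions per patient
(from the 75.6 Gy / 42-fraction prescription — the per-patient fraction
counts were not published); CT-reference $M, \Sigma, \sigma$ from the
cohort's decomposition (with the recomputable $\sigma_{SI} = 0.42$);
MRI-minus-CT bias $(-0.15, 0.05, -0.01)$ cm; registration noise at the
measured reproducibility $(0.08, 0.09, 0.07)$ cm; a prostate volume
log-normal fitted to the ten MRI volumes (meanlog 3.76, sdlog 0.46) with
relative CT–MRI discrepancy $\delta \sim N(0.397, 0.185^2)$; and dose
baselines near the prescription with the cohort's plan-max discrepancy.
The discrepancy draw is truncated at $-0.99$ so CT values stay positive.

What the generator emulates — and what it does not. It reproduces the
Gaussian systematic/random hierarchy, the additive inter-modality bias
with independent registration noise, and multiplicative measurement
discrepancies. Real shift logs additionally show time trends (e.g.
progressive weight loss), non-Gaussian tails, couch-correction truncation
to millimetre resolution, and modality noise that is correlated with
anatomy rather than independent per fraction; the inter-modality model in
particular is an assumption, since no published noise model links CT- and
MRI-referenced daily shifts. Passing parameter-recovery tests therefore
validates the *estimators under the stated model*, not the model's fit to
any clinic's data. An optional heterogeneity switch
(`sigma_heterogeneity`) draws per-patient random-error SDs from a scaled
chi distribution whose RMS equals $\sigma_a$, off by default because the
population model specifies no inter-patient variation in $\sigma$.

### Validation choices and numerical notes

* **Single-cohort recovery** (50 patients × 40 fractions) is tested
  against 3-standard-error bands using
  $SE(\hat\Sigma) \approx \Sigma/\sqrt{2(n-1)}$ and
  $SE(\hat\sigma) \approx \sigma/\sqrt{2n(m-1)}$.
* **Bias over replicates** is checked on the *variance* scale. The
  SD-of-patient-means estimator is not unbiased at $n = 9$: its square has
  expectation $\Sigma^2 + \sigma^2/m$, and the square root adds the usual
  small-sample deflation. Both effects vanish on the variance scale after
  subtracting $\hat\sigma^2/m$, where
  $E[S^2_{\text{means}} - \hat\sigma^2/m] = \Sigma^2$ exactly, so 200
  replicate means are compared to the truth within 2 Monte-Carlo SEs
  there. (At margin scale the net SD-scale bias is below 0.01 cm — far
  inside clinical relevance — but a bias *check* should test an unbiased
  quantity.)
* **Determinism**: every generator takes its seed from the config and
  restores the caller's RNG state; identical config + seed gives
  identical tables, and the report pipeline is byte-identical across runs
  (the provenance block carries an MD5 of the numerical report body,
  no timestamps).
* **Problem sizes** used by the test-suite simulations (200 registration
  tasks, 200 replicate cohorts, 50×40 recovery cohorts, $2\times10^5$ to
  $10^6$ coverage draws) keep every Monte-Carlo tolerance at 2–4 SEs while
  the whole suite runs in seconds.
* **Tie-breaks and degenerate inputs**: zero-variance patients are
  accepted; a cohort reduced below two patients by exclusions raises an
  `insufficient_data_error`; non-finite shifts are rejected at the door;
  units are normalized to cm on read (`# units: mm`) to prevent silent
  10× errors.

## Known limitations

* Fraction-level modality differences (the ± SDs published alongside the
  cohort mean differences) are not recoverable from per-patient summaries;
  the package reports patient-mean pairing and labels it.
* The margin recipe is fixed to the $2.5\Sigma + 0.7\sigma$ population
  formalism (the coefficient pair is a config argument, but no alternative
  recipes are provided).
* No DICOM, image registration, contouring or dose calculation: inputs
  are shift logs and scalar measurement tables.
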