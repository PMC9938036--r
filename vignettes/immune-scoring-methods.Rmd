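---
title: "Methods: percentile immune-cell scores, synthetic cohorts, and prognostic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: percentile immune-cell scores, synthetic cohorts, and prognostic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphoscore)
```

## The scoring procedure

The package scores tumor immune infiltrates from a panel of eight regional
densities: four markers (CD3, CD8, CD20, CD138; cells/mm²) in two regions,
the tumor center (CT) and the invasive margin (IM). Patients contribute
1–4 tissue-microarray cores per region; `aggregate_cores()` averages them
arithmetically into the regional density.

Each component density is converted to a cohort-relative percentile with
the Hazen definition

$$\mathrm{pct}(x_i) = 100\,\frac{r_i - 1/2}{n},$$

where $r_i$ is the ascending rank (ties receive the average rank) and $n$
the number of non-missing values. Several percentile conventions exist;
Hazen was chosen because it is symmetric around 50 (each column has mean
exactly 50 when nothing is missing), never produces the degenerate
extremes 0 or 100, and — like all rank-based definitions — is invariant
under any strictly increasing transform of the densities, so the score
depends only on a patient's relative position in the cohort. The
reference distribution is the analysis cohort itself; no external
reference population is assumed.

The T cell score is the mean of the CD3 CT, CD3 IM, CD8 CT and CD8 IM
percentiles; the B cell/plasma cell score analogously combines CD20 and
CD138. A patient missing any component has a missing score and is
excluded from grouping (the exclusion is reported, not silent).

`tertile_groups()` splits the scored cohort into three ordinal groups.
The exact rule matters at the margins and is fixed deterministically:
patients are sorted by ascending score with ties broken by stable input
order, each group receives $\lfloor n/3 \rfloor$ patients, and the
remainder is allocated one extra patient first to the low, then to the
intermediate group. For $n = 221$ this gives sizes (74, 74, 73). The
stable tie-break makes the assignment reproducible; with
continuous-valued scores exact ties essentially never occur.

## Association and correlation analysis

`association_table()` cross-tabulates score groups against each
clinicopathological factor (sex, age group, tumor location, AJCC stage,
grade, lymphovascular invasion, MMR status, BRAF status) and applies
Pearson's $\chi^2 = \sum (O-E)^2/E$ with $(r-1)(c-1)$ degrees of freedom
and no continuity correction — the default of standard statistical
crosstab routines. Missing factor values are excluded pairwise per test.
No multiple-testing adjustment is applied; two-sided p-values below 0.05
are conventionally read as significant, mirroring common practice in
clinicopathological tables.

Spearman correlations are computed as the Pearson correlation of
average-tie ranks over pairwise-complete observations
(`spearman_cor()`, `correlation_matrix()`).

## Survival analysis

`make_endpoint()` builds the two endpoints. Cancer-specific survival
(CSS) treats death from the index cancer as the event and censors
other-cause deaths at the death time — cause-specific censoring, not a
Fine–Gray competing-risks model, which is a deliberate non-goal.
Overall survival (OS) counts death from any cause. Patients flagged as
30-day surgical deaths are removed before analysis, and follow-up is
capped at 120 months with censoring.

Kaplan–Meier curves use the product-limit estimator; group comparison
uses the standard unweighted log-rank test. Cox models are fitted by
partial-likelihood maximization through the `survival` package. Efron tie
handling is the default because it is the more accurate approximation
when event times tie; Breslow is available for comparison with software
whose default it is (on tie-free data the two agree to well under 1%
relative hazard ratio, which the test suite checks). Inference is Wald
throughout — $\exp(\hat\beta \pm 1.96\,\mathrm{se})$ intervals and normal
p-values — matching the "HR (95% CI)" reporting style. Reference levels
are reported explicitly with HR ≡ 1.

The ordinal trend test (`p_trend()`) enters the score as a single linear
numeric term coded 0/1/2, adjusted for the same covariates as the
categorical model, and reports the Wald p-value of that coefficient.
"Trend" tests are rarely defined precisely in clinical reports; the
linear-coding Wald test is the most common reading and reduces to the
categorical model when the effect is exactly log-linear.

Multivariable models adjust for age (<65, 65–75, >75 years), sex, stage
(collapsed to I–II / III / IV), MMR status, BRAF status, tumor location,
and grade; the two composite scores additionally adjust for each other.
Stage is collapsed because stages I and II rarely separate with modest
event counts. Patients missing any model covariate are dropped listwise
per model, with counts recorded on the fit object. Monotone likelihood
(complete separation) is flagged as non-convergence when any
$|\hat\beta|$ exceeds 15 on the log scale; flagged models are reported,
never silently dropped.

## The synthetic cohort generator

No patient-level dataset accompanies this kind of study, so the
generator is a first-class, tested component that emulates the
statistical structure the analysis assumes.

**Densities.** A Gaussian copula: latent multivariate normal with
Pearson correlation $r = 2\sin(\pi \rho_s/6)$ for each target Spearman
$\rho_s$ (the exact bivariate-normal relation), pushed through log-normal
marginal quantile functions. Log-normal marginals were chosen because
cell densities are positive and right-skewed; defaults put medians at
plausible colorectal scales (e.g. CD3 IM 500, CD8 CT 100, CD20 CT 40
cells/mm², all with log-sd 0.9). Five Spearman targets are published
values for specific marker pairs (0.606, 0.459, 0.442, 0.421, 0.246);
all remaining pairs default to a mild positive 0.2 — immune infiltrates
are broadly positively correlated, but no full matrix is published, so
these are declared defaults, not inferences. The latent matrix is
eigendecomposed with small negative eigenvalues clamped at zero, which
also handles exactly singular cases such as a comonotone pair
($\rho_s = 1$). A clearly non-positive-definite target matrix is a
configuration error reported with the most suspicious pair named.

**Covariates.** Categorical draws from marginals matching a 221-patient
series (the documented defaults), with two refinements: stage can be
drawn conditionally on the T score group from a column-normalized 4×3
table, embedding the published stage–score association; and missing
values are injected at fixed counts (1 stage, 1 grade, 1 MMR, 2 LVI per
221) to mirror the pairwise-missing structure of real
clinicopathological tables.

**Survival.** Two independent exponential latent times (cancer death,
other-cause death) with patient hazard
$\lambda_0 \exp(\beta^\top z)$, where the default group effects on the
cancer hazard are 1 / 0.53 / 0.22 across T score groups. The other-cause
group effects (0.421, 0.818) are derived from the all-cause targets
1 / 0.49 / 0.44 via the exponential identity
$\mathrm{HR}_{os} = (\lambda_c \mathrm{HR}_c + \lambda_o \mathrm{HR}_o)/
(\lambda_c + \lambda_o)$. Administrative censoring arises from uniform
accrual over 80 months with database lock 80 months after accrual ends,
capped at 120 months. Baseline rates (0.0061 and 0.00355 per month) were
calibrated once so that a 219-patient cohort accrues about 104 deaths,
59 of them cancer deaths, with a censored-case median follow-up near 118
months; reproducing those follow-up quantiles exactly is a calibration
exercise, not a contract the package tests enforce tightly. Finally, a
fixed number of patients (default 2) is flagged post hoc as 30-day
surgical deaths (death within the first month, not attributed to
cancer), which the survival stage excludes.

**Reproducibility.** One seed drives a cohort; per-stage sub-seeds are
derived deterministically from it, so changing the hazard specification
does not perturb the density draws, and an identical configuration and
seed produce a byte-identical cohort file (numbers are written with the
shortest decimal representation that round-trips the double exactly).

**What the generator does not emulate.** Tissue-core dropout, staining
artifacts, image-analysis noise, non-proportional hazards,
non-exponential baselines, and covariate effects on the hazard beyond
the score groups (covariate log-HRs default to zero). Passing tests
therefore demonstrate that the analysis machinery is correct and well
calibrated under the assumed structure — not that any particular
biological effect holds in real cohorts.

## Numerical and testing choices

- Percentiles, tertile sizes, χ² statistics, KM curves and log-rank
  statistics are checked against independent brute-force oracles
  (exhaustive rank counting, direct cell sums, hand product-limit and
  risk-set enumeration); Cox estimates are checked on tiny instances
  against direct partial-likelihood maximization by grid search.
- Copula calibration is verified at 50,000 patients, where the sample
  Spearman of targeted pairs sits within ±0.02 of target.
- Hazard-ratio recovery is verified two ways: the mean log-HR over 200
  simulated cohorts of 2,000 patients lies within three Monte-Carlo
  standard errors of the truth, and a single 10,000-patient cohort
  (the acceptance script) recovers the published hazard ratios to a few
  percent. These sizes keep the full suite fast while leaving
  Monte-Carlo error well below the tolerances being asserted.
- The null calibration of the log-rank test is checked empirically:
  rejection rate at nominal 5% within [3%, 7%] over 1,000 null
  replicates.

## Limitations

The package analyses one cohort at a time with cohort-relative
percentiles, so scores are not transportable across cohorts without a
shared reference distribution. CSS uses cause-specific censoring, which
estimates hazard-based associations but not cumulative-incidence
quantities under competing risks. The trend test assumes log-linearity
in the ordinal coding. The generator's defaults describe one published
cohort composition; other settings should supply their own marginals and
hazard specification via `cohort_config()`.
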