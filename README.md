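# lymphoscore

Percentile-based immune-cell scoring and prognostic survival analysis for
colorectal-cancer cohorts.

Tumor-infiltrating lymphocytes carry prognostic information in colorectal
cancer. The Immunoscore approach quantifies CD3+ and CD8+ T cell densities
(cells/mm²) in two regions — the tumor center (CT) and the invasive margin
(IM) — converts them to cohort percentiles, and averages them into a single
score. `lymphoscore` implements this T cell score, its B-lineage analogue
built from CD20+ B cell and CD138+ plasma cell densities, and the full
downstream prognostic analysis, for biostatisticians and
immuno-oncology researchers working with regional cell-density panels.

## The score and the analysis

For each of the four component densities the cohort-relative Hazen
percentile is

&nbsp;&nbsp;&nbsp;&nbsp;pct(xᵢ) = 100 · (rᵢ − ½) / n,

where rᵢ is the ascending rank of patient *i* (average ranks for ties) and
*n* the number of scored patients. The patient's score is the mean of the
four percentiles (CD3 CT, CD3 IM, CD8 CT, CD8 IM for the T cell score;
CD20 CT, CD20 IM, CD138 CT, CD138 IM for the B cell/plasma cell score),
and the cohort is split into low / intermediate / high tertile groups —
equal thirds, remainder going first to low, then to intermediate, so 221
patients split 74/74/73.

Downstream, the package provides:

- **Association tables** — score group × clinicopathological factor
  contingency tables with Pearson χ² = Σ(O−E)²/E tests (no continuity
  correction), missing data handled pairwise per factor;
- **Correlation structure** — tie-corrected Spearman correlation matrices
  of the eight density variables;
- **Survival analysis** — Kaplan–Meier product-limit curves, the
  unweighted log-rank test, and univariable/multivariable Cox
  proportional-hazards models (Efron or Breslow ties) reporting hazard
  ratios with Wald 95% CIs, plus an ordinal trend test (score coded
  0/1/2 as one linear term). Cancer-specific survival censors other-cause
  deaths; overall survival counts any death; 30-day surgical deaths are
  excluded and follow-up is capped at 120 months.

Because matched patient-level data of this kind are rarely public, the
package includes a first-class synthetic cohort generator: a Gaussian
copula draws the eight densities with any target Spearman matrix (latent
Pearson r = 2 sin(πρ/6)) and log-normal marginals; covariates follow
configurable category marginals (optionally with stage drawn conditionally
on the T score group); and event times follow cause-specific exponential
proportional hazards with uniform accrual and administrative censoring.

## Worked example

```r
library(lymphoscore)

cohort <- simulate_cohort(cohort_config(), seed = 1)
tscore <- compute_score(cohort, "t")
attr(tscore, "sizes")
#>          low intermediate         high
#>           74           74           73

assoc <- association_table(cohort, tscore$group)
assoc$stage$test
#> Pearson chi-square: X^2 = 32.28, df = 6, p = 1.443e-05

css    <- make_endpoint(cohort, "css")   # 219 patients: 2 surgical deaths excluded
merged <- merge(css, data.frame(patient_id = cohort$patient_id,
                                grp = tscore$group), sort = FALSE)
log_rank(merged, merged$grp)$p_value
#> 7.3e-05

cox_fit(merged, "grp")
#> Cox proportional hazards (efron ties): n = 219, events = 67
#>  term        level            hr_ci      p_value
#>   grp          low     1 (referent)           NA
#>   grp intermediate 0.81 (0.49-1.35) 4.257409e-01
#>   grp         high 0.19 (0.08-0.44) 8.075672e-05
```

The default configuration embeds a protective T cell score effect (true
cancer-specific hazard ratios 1 / 0.53 / 0.22 across groups) and a
stage–score association, so the simulated cohort shows what the analysis
looks like when the score is prognostic: the χ² test links score group to
stage, and the high-score group has a markedly lower cancer-specific
mortality hazard. `run_study("out_dir", seed = 1)` runs every stage —
scores, association tables for all eight factors, the 8×8 correlation
matrix, KM step tables, and 40 Cox models (both scores plus all eight
density components, univariable and multivariable, for both endpoints) —
and writes deterministic TSV/JSON artifacts. A thin CLI wrapper lives at
`inst/scripts/run_study.R`.

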