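# psmcea

Partitioned-survival cost-effectiveness modelling of first-line
pembrolizumab plus platinum–pemetrexed chemotherapy versus chemotherapy
alone in untreated advanced pleural mesothelioma, from the Chinese
healthcare-system perspective.

The package is aimed at health-economics analysts who want a fully scripted,
testable version of this evaluation: every input is a plain-text
configuration, every stage (survival-curve machinery, pseudo-IPD
reconstruction, cohort engine, sensitivity analyses) is an ordinary R
function, and the shipped configurations reproduce the reference results for
the whole trial population and the epithelioid / non-epithelioid histology
subgroups.

## The model

A three-state partitioned-survival (cohort) model with states
progression-free (PFS), progressed disease (PD) and death.  State occupancy
is read directly off the two survival curves at each cycle boundary *t*:

```
pfs(t)  = min{ S_PFS(t), S_OS(t) }
pd(t)   = S_OS(t) − pfs(t)
dead(t) = 1 − S_OS(t)
```

with 21-day cycles over a 10-year horizon (174 cycles).  Costs (drug
acquisition with per-drug cycle caps, administration, laboratory and CT
monitoring, subsequent treatment in PD, end-of-life, first-cycle
adverse-event management) and utilities (0.706 in PFS, 0.565 in PD, minus a
one-off first-cycle adverse-event disutility) are accrued per cycle with
half-cycle correction and discounted at 5% per year.  Incremental results
are summarised as

```
ICER = ΔC / ΔE        INHB(λ) = ΔE − ΔC/λ        INMB(λ) = ΔE·λ − ΔC
```

at a willingness-to-pay threshold λ = $38,042.49/QALY (three times China's
2023 per-capita GDP).  OS and PFS are parametric: exponential, Weibull
(AFT and PH), gamma, generalized gamma (Prentice), Gompertz, log-logistic
and lognormal families are supported, selected by AIC/BIC on pseudo
individual-patient data reconstructed from digitized Kaplan–Meier curves
and number-at-risk tables.

Two study-level durations are not published anywhere and are therefore
calibrated once against the reference per-arm cost totals and stored in the
shipped configurations: the duration of subsequent treatment in PD, and the
number of assistance-program paid pembrolizumab cycles.  See the methods
vignette (`vignettes/partitioned-survival-cea.Rmd`) for the full accounting
of conventions, calibrations and known limitations.

## Worked example

```r
library(psmcea)

cfg <- load_study_config(example_config("non_epithelioid"))
res <- run_cea(cfg)
print(res)
#> Partitioned-survival cost-effectiveness analysis (non_epithelioid population)
#>   pembro_chemo                       cost $  29316.04   QALYs  0.963
#>   chemo                              cost $  12177.59   QALYs  0.458
#>   incremental: dC $17138.45, dE 0.5048 QALYs
#>   ICER  $33950.38/QALY  (WTP $38042.49)
#>   INHB 0.0543 QALYs   INMB $2065.73
```

The combination strategy costs an extra $17,138 and gains 0.50 QALYs in the
non-epithelioid subgroup; at $33,950/QALY the ICER is below the threshold,
so the positive INMB says the strategy is cost-effective there (it is not in
the whole population or the epithelioid subgroup, where the ICER is far
above λ).  A one-way sensitivity analysis ranks the drivers:

```r
tor <- owsa(cfg)
print(tor, n = 3)
#> One-way sensitivity analysis (base ICER $33950.38/QALY)
#>                 name icer_low icer_high    width
#> 1 cost_pembrolizumab  26304.6   41596.1 15291.46
#> 2        utility_pfs  40745.2   29097.9 11647.34
#> 3     cost_nivolumab  36499.3   31401.4  5097.93
```

and `psa(cfg, n = 10000, seed = 1)` runs the probabilistic analysis
(gamma-distributed costs, beta-distributed utilities/probabilities, survival
parameters fixed), returning the per-draw cloud and the cost-effectiveness
acceptability curve.  `run_study(cfg, out_dir = "out")` writes all of the
above as CSV plus a seed- and hash-stamped JSON run summary.

Other entry points: `fit_parsurv()` / `fit_parsurv_set()` /
`select_best()` (maximum-likelihood survival fitting with AIC/BIC
selection), `reconstruct_ipd()` (pseudo-IPD from digitized curves),
`simulate_trial()` (synthetic two-endpoint trials for testing the
pipeline without any external data).

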