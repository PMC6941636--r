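# recurjoint

Joint frailty models for **two types of recurrent events** — for example
local (loco-regional) tumour recurrence and distant metastasis after
breast-cancer surgery — with an optional terminal event, for
biostatisticians analysing registry-style follow-up cohorts.

## The model

Subject *i* carries a latent log-frailty pair shared across follow-up.
On calendar time *t* since surgery the two recurrent processes have
conditional intensities

```
lambda_1i(t) = h01(t) * exp(beta_1' Z_i + u_i)
lambda_2i(t) = h02(t) * exp(beta_2' Z_i + v_i)

(u_i, v_i) ~ N(0, Sigma),   Sigma = | theta          rho*sqrt(theta*eta) |
                                    | rho*sqrt(.)    eta                 |
```

`theta` and `eta` capture within-subject clustering of each process and
`rho` the association between the two recurrence types; an optional death
hazard `h0D(t) * exp(beta_D' Z + alpha_1 u + alpha_2 v)` links both
frailties to survival. Baseline hazards are nonnegative M-spline
expansions with exact I-spline cumulative hazards, estimated by
**penalized marginal likelihood**: the frailty pair is integrated out by
Gauss–Hermite quadrature (20 nodes/dimension after Cholesky
standardisation), a curvature penalty `kappa * int h0''(t)^2 dt` smooths
each baseline, and BFGS with an analytic gradient maximises the
objective over log spline coefficients, `log theta`, `log eta` and
`atanh rho`. Wald standard errors come from the observed information of
the unpenalized marginal likelihood.

The package also provides Kaplan–Meier disease-free survival (first
recurrence of either type) with Greenwood standard errors, descriptive
frequency tables with half-up percentage rounding, a counting-process
validator/reader/writer for long-format CSV data, and a calibrated
synthetic-cohort generator with known ground truth (`cohort_preset()`)
emulating a 342-patient breast-cancer registry cohort. Everything is
tibble-in / tibble-out with `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(recurjoint)

sim <- simulate_cohort(cohort_preset(n_subjects = 342, seed = 1))
sim$history
#> <event_history> 342 subjects, 910 at-risk intervals (time in months)
#>   event_type intervals events
#> 1 1                430     88
#> 2 2                480    148

km <- kaplan_meier(disease_free_times(sim$history))
survival_at(km, c(12, 36, 60))
#>    time survival std_err
#> 1    12    0.901  0.0163
#> 2    36    0.798  0.0227
#> 3    60    0.751  0.0251

fit <- fit_joint_frailty(sim$history, model_spec(), seed = 1)
fit
#> <joint_frailty_fit> n = 342 | marginal logLik = -1352.9304 | converged: TRUE
#>    process covariate level       hr ci_low ci_high reference
#>  2 1       age_group <=40     2.98   1.44     6.17 FALSE
#>  6 1       grade     III      2.45   1.24     4.86 FALSE
#> 16 2       grade     III      3.19   1.18     8.59 FALSE
#> 20 2       size      >=20     2.60   1.03     6.54 FALSE
#> ...
#> theta = 0.912 (SE 0.337), eta = 6.276 (SE 1.044), rho = 0.422
```

The simulated cohort was generated with true hazard ratios taken from a
published registry analysis and frailty variances `theta = 1.10`,
`eta = 7.39`, `rho = 0.5`; the fit above recovers them from one
realisation: hazard ratios above 1 for grade III and large tumours on
both processes, a moderate `theta` and a large `eta` (strong unexplained
heterogeneity in metastasis risk), and a positive cross-process
correlation. `tidy(fit)` returns the coefficient table,
`hazard_ratio_table(fit)` the HR/CI rendering shown above,
`autoplot(fit)` the fitted baseline hazards, and `run_pipeline()` drives
simulate → describe → km → fit → report as one reproducible step.

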