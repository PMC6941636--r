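---
title: "Joint frailty modelling of two recurrent event processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint frailty modelling of two recurrent event processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurjoint)
```

## The problem

After breast-cancer surgery a patient can experience two kinds of
recurrence repeatedly over follow-up: local (loco-regional) recurrence and
distant metastasis. The two processes are not independent — a patient at
elevated risk of one tends to be at elevated risk of the other — and both
can be cut short by death or loss to follow-up. Analysing either process
alone with a Cox-type model discards this cross-process association and
can bias covariate effects when recurrences within a patient are
correlated.

`recurjoint` models both processes jointly. Subject $i$ carries a pair of
latent log-frailties $(u_i, v_i)$, and the conditional intensities of the
two recurrent processes on calendar time $t$ since surgery are

$$
\lambda_{1i}(t) = h_{01}(t)\, e^{\beta_1' Z_i^{(1)} + u_i}, \qquad
\lambda_{2i}(t) = h_{02}(t)\, e^{\beta_2' Z_i^{(2)} + v_i},
$$

with

$$
\begin{pmatrix} u_i \\ v_i \end{pmatrix} \sim
N\!\left( \mathbf 0,\;
\begin{pmatrix} \theta & \rho\sqrt{\theta\eta} \\
\rho\sqrt{\theta\eta} & \eta \end{pmatrix} \right).
$$

$\theta$ measures within-subject clustering of the first process, $\eta$
that of the second, and $\rho$ the association between the two processes.
An optional terminal event (death) with hazard
$h_{0D}(t)\,e^{\beta_D' Z_i + \alpha_1 u_i + \alpha_2 v_i}$ lets both
frailties also drive mortality; it is off by default because the model for
the two recurrences is identified without it, and data without death
records are common.

### Time scale

Risk intervals are counting-process records $(start, stop]$ on calendar
time since surgery (Andersen–Gill-style), so a subject's second recurrence
is at risk from the time of the first. A gap-time formulation (clock reset
at each event) is a different model and is deliberately not implemented:
with calendar time the baseline hazard keeps a single clinical
interpretation (time since surgery) for every event of a process.

## Estimation

### Baseline hazards

Each baseline hazard is a linear combination of M-splines,
$h_0(t) = \sum_j c_j M_j(t)$ with $c_j \ge 0$, which keeps the hazard
nonnegative by construction. The cumulative hazard uses the exact
integrals of the basis functions (I-splines), so no numerical quadrature
enters the likelihood. Boundary knots sit at $0$ and the longest
follow-up; interior knots (default 7) sit at equispaced quantiles of the
observed event times of that process. Order 4 (cubic) is the default;
order 1 with no interior knots gives a constant hazard, which is the
configuration used by the closed-form consistency checks.

### Penalized marginal likelihood

The frailty pair is integrated out of each subject's conditional
likelihood:

$$
\ell(\psi) = \sum_i \log \iint
  \exp\{\ell_i^{c}(\psi \mid b)\}\,\varphi(b;\Sigma)\,db
  \; - \; \sum_k \kappa_k \int h_{0k}''(t)^2\,dt .
$$

The integral uses fixed Gauss–Hermite quadrature, 20 nodes per dimension
by default, after standardising $b$ through the Cholesky factor of
$\Sigma$ (the $\theta$-dimension leads; with the event counts this package
targets, that orientation gave the smaller quadrature error in our
two-integrator comparisons). Log-sum-exp keeps the computation stable.
A zero variance collapses its dimension to a point mass, so
$\theta=\eta=0$ reproduces the plain (no-frailty) likelihood exactly; this
identity, and agreement with an independent dense-grid trapezoid
integrator on small cohorts, are both enforced by tests.

The curvature penalties $\kappa_k \int h_{0k}''^2$ use the exact Gram
matrix of second derivatives (per-interval Gauss–Legendre, exact for
polynomial splines). The default is $\kappa_k = 0$ — plain maximum
marginal likelihood — because no data-driven selection rule is applied
silently: spline-coefficient positivity already guarantees a valid hazard,
and `scan_kappa()` lets the analyst profile a grid of weights with an
AIC-style score (marginal log-likelihood minus the effective degrees of
freedom of the spline blocks) before choosing one.

### Optimisation

All parameters are transformed to an unconstrained scale — log spline
coefficients, $\log\theta$, $\log\eta$, $\operatorname{atanh}\rho$ — and
the penalized objective is maximised by BFGS with an *analytic* gradient
(validated against central finite differences at random interior points to
relative $10^{-5}$). Starting values matter on this surface: the variance
block is initialised from the Poisson–log-normal moment identity
$E[N(N-1)]\,/\,E[N]^2 = e^{\sigma^2}$ applied to exposure-adjusted
per-subject counts, and three seeded starts (the default) jitter the
initial point, with a wider spread on the variance block where the surface
is flattest. Ties are broken by highest penalized likelihood, then
smallest gradient norm. `|atanh(rho)|` is clamped at 12 during line
searches so the Cholesky factor stays finite; estimates reaching that
clamp indicate a correlation at the boundary.

### Standard errors

Wald standard errors come from the inverse of the observed information of
the *marginal, unpenalized* log-likelihood in the regression/frailty
block, obtained by central finite differences of the analytic gradient
with spline coefficients held at their estimates. Variance-scale and
correlation-scale SEs are mapped by the delta method. A singular
information matrix does not abort the fit: SEs are flagged unavailable and
`hazard_ratio_table()` marks its intervals accordingly.

## The synthetic cohort generator

No patient-level data accompany the analysis this package implements, so
`cohort_preset()` emulates the published cohort's statistical structure
with known ground truth:

* **Size and follow-up.** 342 subjects, administrative horizon 187 months,
  exponential dropout with rate $\log 2 / 113$, giving a median follow-up
  near 113 months.
* **Covariates.** Age group ($\le 40$ / 40–60 / $>60$, probabilities
  0.25/0.60/0.15 from a normal age distribution with mean 47.84 and SD
  11.75), tumour size ($<20$ mm 21.1%), tumour grade (I/II/III
  0.20/0.50/0.30) and HER2 status (25% positive). Grade and HER2
  frequencies are field-typical choices; the published descriptives do not
  print them.
* **Effects and frailty.** True log hazard ratios are the logs of the
  published estimates for both processes; $\theta = 1.10$, $\eta = 7.39$,
  $\rho = 0.5$ ($\rho$ is not published; a moderate positive value matches
  the published conclusion of positively associated recurrence types).
* **Baselines.** Piecewise-constant with relative level $(1, 0.6, 0.3)$ on
  cuts at 36 and 84 months — an early recurrence peak that declines — with
  scales $2.5\times10^{-4}$ (local) and $4\times10^{-5}$ (metastasis) per
  month, calibrated once so that roughly a quarter of subjects experience
  any recurrence, matching the published 87/342.
* **Event generation.** Exact inversion of the conditional cumulative
  hazard (closed form for both baseline families), sequential on calendar
  time; at most 6 recurrences per process are generated. Because
  generation stops *at* the capping event, the emitted risk sets remain an
  exactly specified counting process and the likelihood stays correct.
* **Reproducibility.** Each subject draws covariates, frailties and events
  from an independent substream derived from the master seed, so records
  are invariant to cohort reordering or enlargement.

What the generator does **not** emulate: time-varying covariates, cure
fractions, informative censoring beyond the optional terminal event,
measurement error in recorded times, or the registry's actual baseline
hazard shape. Passing recovery tests therefore demonstrate that the
estimator recovers parameters *under the model's own assumptions*, not
that the published registry estimates are correct.

## Numerical choices and degenerate inputs

* Intervals are half-open $(start, stop]$; events occur at `stop`.
  Kaplan–Meier ties resolve events before censorings; the median is the
  smallest time with $\hat S(t) \le 0.5$.
* Frequency-table percentages round half-up to one decimal — the
  convention that reproduces every self-consistent printed percentage from
  its printed count.
* A recurrent process with zero events aborts the fit with an
  identifiability diagnostic (it would need its variance fixed at zero and
  a fixed baseline, which the fitting surface does not expose).
* Missing covariate values are rejected at validation, mirroring the
  complete-case design of the source analysis; no imputation.
* `validate_counting_process()` is total: it returns a violation table and
  never raises, so arbitrary malformed tables can be triaged.

## Problem sizes used by the test-suite experiments

The simulation-based checks run at sizes chosen to keep the full suite in
a few minutes of CPU: parameter recovery uses 50 replicates of the full
preset (n = 342) fitted with the default three starts at 20 quadrature
nodes; the bootstrap-coverage property for $\rho$ uses ten 60-subject
cohorts with 60 subject-level resamples each at 8 nodes; Monte-Carlo
moment checks use $10^5$ frailty draws and cohorts of 2000–3000 subjects.
Medians of the frailty-variance estimates over the recovery replicates are
required to fall within 25% of truth — a tolerance that reflects the small
per-subject event counts the preset deliberately reproduces.

## Known limitations

* Fixed (non-adaptive) Gauss–Hermite quadrature loses accuracy for
  subjects with many events when a frailty variance is large (e.g.
  $\eta \approx 7$); accuracy checks in the test suite pin the error on
  small cohorts, and raising `quad_nodes` is the remedy at scale. The
  maximum-likelihood variance estimates themselves carry the usual
  downward finite-sample bias when informative subjects are few.
* Two recurrent processes only; no gamma-frailty variant; no time-varying
  covariates; no left truncation or interval censoring; no martingale
  residual diagnostics.
* $\hat\rho$ is weakly identified in small cohorts and can reach the
  $\pm 1$ boundary, where its Wald SE is unavailable; the bootstrap is the
  honest alternative there.
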