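---
title: "Dose-response MMRM: model, simulator and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response MMRM: model, simulator and operating characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dose-finding trials in chronic kidney disease increasingly use urinary
albumin-to-creatinine ratio (UACR) as the endpoint. Log UACR is highly
variable both between and within subjects, so saturated mixed models for
repeated measures (MMRM) — one free mean per treatment-by-visit cell — are
the standard analysis: they are unbiased but parameter-heavy and cannot
interpolate between doses. An Emax regression on end-of-study data alone
(DR-EOS) borrows strength across doses but throws away every earlier visit.
The dose-response MMRM (DR-MMRM) combines the two: each visit keeps its own
placebo response and Emax, while a single ED50 is shared across visits, and
residuals within a subject follow a first-order autoregressive (AR(1))
correlation. This package implements all three estimators together with the
trial simulator and a Monte-Carlo engine that measures their precision,
bias and RMSE.

## Simulation model

The simulator generates log-scale changes from baseline
(`duacr`, in log(mg/g)) for subject $i$ in the arm with dose $d$ at
post-baseline week $t$:

$$ y_{it} = f(d, t) + \eta_i + \varepsilon_{it}, \qquad
   \eta_i \sim N(0, \omega^2), \quad
   (\varepsilon_{i1},\dots,\varepsilon_{i9}) \sim
   N\!\big(0,\ \sigma^2 R(\rho)\big), $$

where $R(\rho)_{jk} = \rho^{|j-k|}$ counts lag in *visit positions* — the
closely spaced week-14/15/16 visits correlate as strongly as the 2-week
spaced ones. The true drug effect is an Emax curve in dose with a
time-course multiplier:

$$ f(d, t) = E_{\max}(ED_{50})\, m(t)\, \frac{d}{ED_{50} + d}, \qquad
   E_{\max}(ED_{50}) = \log(0.6)\,\frac{100 + ED_{50}}{100}, $$

so that the 100 mg dose attains exactly a 40% UACR reduction
($\log 0.6 \approx -0.51$) at full effect, whatever the ED50. The
multiplier $m(t)$ is 1 for a *direct* effect, $1 - e^{-t \log 2 / 1.75}$
for an *exponential* onset (half-life 1.75 weeks), and $\min(t/16, 1)$ for
a *linear* ramp reaching full effect at the last visit (week 16). The
placebo response is identically zero: every evaluated quantity is
placebo-adjusted, so any common placebo drift would cancel exactly, and
simulating it would only add code without changing a single operating
characteristic.

Default parameters are the study conditions throughout: baseline mean 5.63
log(mg/g) (carried only for the absolute-scale export; change scores do not
depend on it), between-subject SD $\omega = 0.3716$, residual SD
$\sigma = 0.50$, lag-1 correlation $\rho = 0.226$ per visit, post-baseline
visits at weeks 2, 4, 6, 8, 10, 12, 14, 15, 16, and arms placebo +
3/10/30/100 mg (or 10/30/100 mg in the three-dose configuration).

Two printed design quantities pin down how $\omega$ enters the model. The
per-arm sample size of 39 comes from requiring 95% power for a 40%
reduction with per-subject SD $\sqrt{\omega^2 + \sigma^2}$, and the
reference sampling SD of an arm-contrast,
$\sqrt{\omega^2 + \sigma^2}\,\sqrt{2/n} \approx 0.14$, makes the same
assumption. Both are only consistent with a generative model in which the
subject-level shift $\eta_i$ (SD $\omega$) survives into the change score —
the random-intercept reading implemented here — rather than a baseline
measurement error that cancels on differencing.

```{r}
library(drmmrm)
design <- uacr_design()
required_sample_size(log(0.6), sqrt(0.3716^2 + 0.50^2))  # 39
theoretical_rmse(0.3716, 0.50, 39)                       # 0.141 log(mg/g)
```

The sample-size rule is the normal-approximation two-sample formula
$n = 2 (z_{1-\alpha/2} + z_{\mathrm{power}})^2 \mathrm{sd}^2 /
\mathrm{effect}^2$ rounded up ($38.65 \to 39$). The exact noncentral-$t$
power at $n = 39$ is 94.7%, just under the nominal 95%: the printed design
size matches the normal approximation, and `empirical_power()` (which runs
actual Welch $t$-tests) reproduces the 94.7% rather than the idealized 95%.

## The three estimators

**MMRM** (`fit_mmrm`): the saturated arm-by-visit cell-means model,
estimated by generalized least squares with the AR(1) correlation profiled
out of the restricted likelihood. On a balanced complete panel the point
estimates are the cell sample means for *any* working correlation — the
correlation only moves the standard errors. The placebo-adjusted effect at
dose $d$ and visit $t$ is the cell-mean difference against placebo.

**DR-EOS** (`fit_dreos`): the three-parameter Emax model
$y_i = Plc + E_{\max} d_i / (ED_{50} + d_i) + e_i$ fitted to last-visit
data only by bounded nonlinear least squares. For a fixed ED50 the model is
linear in $(Plc, E_{\max})$, so the search is one-dimensional on
$\log ED_{50}$ with the linear part solved exactly at each step. Standard
errors use the delta method on the Jacobian-based parameter covariance.

**DR-MMRM** (`fit_drmmrm`): the longitudinal Emax model with per-visit
placebo and effect parameters and one global ED50, AR(1) residuals. It is
fitted once per nonzero dose arm in the reference-dose parameterization

$$ y = Plc_t + E_{dose,t}\,
   \frac{d}{ED_{50} + d}\cdot\frac{ED_{50} + dose_m}{dose_m}, $$

which collapses to $y = Plc_t + E_{dose,t}$ when $d = dose_m$: the
placebo-adjusted effect at the reference arm and its standard error are
read directly off the fit, and the per-arm estimates assembled across the
3 or 4 refits share one ED50. $E_{\max,t}$ is back-calculated as
$E_{dose,t} (ED_{50} + dose_m)/dose_m$.

## Numerical choices

* **Profiled GLS.** All mixed-model fits profile the linear parameters and
  the scale out of the criterion, leaving a 1-d (MMRM: $\rho$) or 2-d
  (DR-MMRM: $\log ED_{50}$, $\mathrm{atanh}\,\rho$) bounded optimization.
  The AR(1) inverse and determinant use their closed tridiagonal forms, and
  the DR-MMRM inner solve exploits the Kronecker structure of the
  reference-dose design, so one criterion evaluation is $O(nm^2)$. Both are
  verified in the tests against dense multivariate-normal computations to
  $10^{-6}$ in log-likelihood.
* **ML for DR-MMRM, REML for MMRM.** The MMRM/GLS core defaults to REML,
  the convention of mixed-model software (maximum likelihood is an option;
  on balanced complete data the point estimates are criterion-invariant).
  The DR-MMRM outer criterion is profiled *maximum* likelihood: for a mean
  that is nonlinear in ED50, the REML adjustment $\log|X'V^{-1}X|$ depends
  on the column scaling of the chosen parameterization — with an
  Emax-scaled design it diverges as ED50 grows, spuriously favoring the
  upper bound — whereas the ML criterion depends only on the column space.
  That makes the ED50 estimate identical whichever arm is the reference
  (verified to $10^{-4}$ relative in the tests) and matches nonlinear GLS
  practice (`nlme::gnls` is ML-only). REML remains available, anchored to
  the reference-dose design.
* **ED50 bounds and multi-start.** ED50 is searched log-uniformly in
  $[0.01, 10^4]$ mg. The Emax likelihood can be flat or multimodal in ED50
  when the true value is far above the top dose, so the search starts from
  {1, 10, 30, 100, 300} mg; the two best starts under the criterion are
  polished by bounded quasi-Newton steps and a final derivative-free
  simplex pass. Estimates within $10^{-3}$ relative distance of a bound are
  flagged `ed50_at_bound`. The working-correlation start is the sample
  lag-1 autocorrelation of cell-demeaned residuals.
* **Standard errors and intervals.** 95% intervals use the normal quantile
  1.96 ($n = 39$/arm makes $t$ vs $z$ negligible). DR-MMRM per-visit SEs
  come from the Jacobian of the mean in the $(Plc_t, E_{dose,t}, ED_{50})$
  parameterization weighted by the fitted AR(1) covariance, so ED50
  uncertainty propagates into them; the per-fit ED50 SE is the
  corresponding diagonal entry (a convenience output — study summaries use
  percentiles across replicates instead). Near-boundary fits fall back to
  a pseudo-inverse for the covariance.
* **Convergence accounting.** A DR-MMRM parameterization counts as
  converged when the outer optimizer succeeds and the inner solve is
  positive definite; a *study* is a complete failure only when all 3 or 4
  parameterizations fail simultaneously. Partially failed studies keep the
  surviving arms' estimates.
* **Degenerate inputs.** Single-visit panels make $\rho$ inestimable; the
  fit returns $\rho = 0$ with `rho_estimable = FALSE`. Rank-deficient
  designs raise a singular-design error. The linear ramp is capped at 1
  beyond week 16 so the time-course is total.

## Operating characteristics

`run_study()` simulates the scenario grid (7 true ED50 values from 2 to
128 mg crossed with the 3 time-courses; 1000 replicates per scenario at
full scale), fits the requested methods, and summarizes the last-visit
placebo-adjusted estimates: bias, relative bias in percent of the maximal
effect ($100\,b/|\log 0.6|$), empirical SD, and
$\mathrm{RMSE} = \sqrt{sd^2 + bias^2}$, plus median and 2.5/97.5
percentiles of ED50 and last-visit Emax. Medians are used for ED50/Emax
because bound-adjacent estimates distort means. The truth for bias is the
last-visit true effect at each dose.

An unbiased estimator's mean relative bias over $n_{rep}$ replicates
fluctuates within $\pm 2$ SD:
`unbiasedness_band_pct(n_reps)` $= 100 \cdot 2\,\sqrt{\omega^2 +
\sigma^2}\sqrt{2/n}/\sqrt{n_{rep}}/|\log 0.6|$, the $\pm 1.7\%$ band at
1000 replicates. `band_exceedance_count()` audits a method's 63- or 84-cell
grid against the band recomputed from each cell's replicate count — the
band is an SE-of-mean quantity and scales as $1/\sqrt{n_{rep}}$, so
scaled-down runs are audited against their own band, never the 1000-rep
one.

### Problem sizes used by the shipped tests

The package's test suite exercises the full 4-dose scenario grid with all
three methods at 150 replicates per scenario (3,150 simulated trials,
12,600 DR-MMRM parameterization fits) — large enough that the band audit,
the bias bounds and the RMSE ordering are informative, small enough to run
routinely. All Monte-Carlo tolerances are recomputed for that scale: the
unbiasedness band via `unbiasedness_band_pct(150)`, worst-case bias bounds
as the full-scale bound plus 3.5 per-cell SDs, and the cellwise RMSE
ordering DR-MMRM $\le$ MMRM as a paired comparison of squared errors with
a 3-SE allowance (the two methods see identical data, so the paired SE is
small). Full-scale runs (1000 replicates, both arm configurations) use the
same code path via `run_study()` or `cmd_study()` and take a few hours on
one CPU with checkpointed resumability.

## What the simulator does and does not emulate

It reproduces the variance anatomy that drives the estimator comparison:
between-subject heterogeneity, autocorrelated within-subject noise, the
Emax dose-response and its time-course, and balanced complete follow-up.
It does **not** simulate dropout (so DR-EOS is not handicapped the way an
end-of-study analysis would be in practice — with informative dropout the
gap would widen), non-normal errors, placebo time trends, visit-time
deviations, or a sigmoid (Hill) Emax. Passing tests therefore demonstrate
the methods' behavior under a correctly specified Emax world; they say
nothing about robustness to model misspecification.

## Known limitations

* The working covariance is AR(1) only; most production MMRM analyses use
  an unstructured covariance. Without dropout and with homogeneous visit
  variances this does not change the comparisons.
* Emax is an unbounded linear parameter here. When the true ED50 is at or
  above the top dose, replicate ED50 estimates pile up at the search bound
  and the back-calculated Emax develops a heavy upper tail; extreme
  percentile summaries of Emax are then tail-unstable, and cross-method
  width comparisons are only made on interior scenarios or in aggregate.
* ED50 estimation degrades by design when the true ED50 exceeds the dose
  range (3–100 mg): the data cannot identify the plateau, medians drift
  and spreads widen. This is the phenomenon the study quantifies, not an
  implementation defect.
* Model averaging, sigmoid-Emax estimation, multiple-contrast (MCP-Mod
  style) testing and continuous-time longitudinal models are out of scope.
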