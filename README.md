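# drmmrm

Dose-response mixed models for repeated measures: simulation and
estimation toolkit for longitudinal dose-finding trials with a highly
variable endpoint, using log urinary albumin-to-creatinine ratio (UACR) —
the proteinuria biomarker increasingly used in chronic kidney disease
phase-2 trials — as the working example.

## What it does

Saturated MMRM analyses of repeated-measure endpoints are unbiased but
parameter-heavy: every treatment-by-visit cell gets its own mean, no
information is shared across doses, and interpolation to unstudied doses
is impossible. Fitting an Emax dose-response to end-of-study data alone
(DR-EOS) shares information across arms but discards every earlier visit.
The dose-response MMRM (DR-MMRM) keeps per-visit placebo and Emax
parameters while sharing a single ED50 across visits:

    y = Plc_t + Emax_t * d / (ED50 + d) + eta_i + eps_it,

with a subject-level shift `eta_i ~ N(0, omega^2)` and AR(1)-correlated
residuals `eps` (`corr = rho^|lag|` over visit positions). The package
provides:

* a trial simulator for log-scale UACR changes from baseline under an
  Emax dose-response with direct, exponential or linear effect
  time-courses (`uacr_design()`, `simulate_trial()`), at the default
  conditions n = 39/arm, omega = 0.3716, sigma = 0.50, rho = 0.226/visit;
* the three estimators — `fit_mmrm()`, `fit_dreos()`, `fit_drmmrm()` —
  built on a profiled AR(1) generalized-least-squares core. DR-MMRM is
  fitted once per dose arm in the reference-dose parameterization
  `y = Plc_t + E_dose_t * (d/(ED50+d)) * ((ED50+dose_m)/dose_m)`, which
  collapses to `Plc_t + E_dose_t` at the reference arm so the
  placebo-adjusted effect and its SE are read directly off the fit, with
  one shared ED50 across all parameterizations;
* a Monte-Carlo study engine (`run_study()`, `band_exceedance_count()`,
  `empirical_power()`) that measures bias, relative bias, RMSE
  (`sqrt(sd^2 + bias^2)`) and ED50/Emax recovery across replicate trials,
  with checkpointed, seed-reproducible orchestration (`cmd_study()`) and a
  thin command-line wrapper (`inst/cli/drmmrm.R`).

See the methods vignette (`vignettes/dose-response-mmrm.Rmd`) for the
model, the numerical choices and the design rationale.

## Worked example

```r
library(drmmrm)
design <- uacr_design()
design
#> UACR trial design (four_dose)
#>   arms: placebo, 3mg, 10mg, 30mg, 100mg  (n = 39/arm)
#>   post-baseline weeks: 2, 4, 6, 8, 10, 12, 14, 15, 16
#>   variance: omega = 0.3716, sigma = 0.50, rho = 0.226/visit

grid <- scenario_grid(design, ed50_values = 32, timecourses = "linear",
                      n_reps = 1, master_seed = 2026)
trial <- simulate_trial(grid[1, ], design, rep = 1)
fit_drmmrm(trial)
#> <DRMMRM fit>
#>   ED50 = 13.3 mg
#>   placebo-adjusted estimates (last visit):
#>  dose week estimate      se  ci_low  ci_high
#>     3   16  -0.1309 0.06511 -0.2585 -0.00328
#>    10   16  -0.3055 0.10784 -0.5169 -0.09413
#>    30   16  -0.4936 0.11096 -0.7111 -0.27613
#>   100   16  -0.6292 0.11704 -0.8586 -0.39981
```

For this simulated trial (true ED50 = 32 mg, linear onset) the fitted
ED50 is 13.3 mg and the last-visit placebo-adjusted log-UACR changes run
from -0.13 at 3 mg to -0.63 at 100 mg (the truth is -0.66·d/(32+d), i.e.
-0.50 at 100 mg; a single noisy trial lands within its own confidence
intervals). A small operating-characteristics run compares methods:

```r
study <- run_study(scenario_grid(design, ed50_values = c(8, 32),
                                 timecourses = "linear",
                                 n_reps = 40, master_seed = 2026),
                   design, methods = c("mmrm", "drmmrm"))
study
#> Simulation study summary: 16 scenario cells, methods: drmmrm, mmrm
#>   per method: mean RMSE / max |relative bias| (% of max effect)
#>     drmmrm  0.1021 / 6.39%
#>     mmrm    0.1322 / 5.79%

subset(study$estimates, dose == 10,
       select = c(ed50_true, method, bias, sd_est, rmse))
#>                               ed50_true method         bias     sd_est      rmse
#> four_dose.linear.8.drmmrm.10          8 drmmrm -0.006722829 0.12129823 0.12148439
#> four_dose.linear.32.drmmrm.10        32 drmmrm -0.018321394 0.09135828 0.09317729
#> four_dose.linear.8.mmrm.10            8   mmrm -0.002625501 0.14538464 0.14540834
#> four_dose.linear.32.mmrm.10          32   mmrm -0.002116527 0.11399066 0.11401031
```

At the 10 mg dose the DR-MMRM RMSE (0.121/0.093 for true ED50 8/32 mg) is
well below the MMRM's (0.145/0.114, tracking the theoretical
`sqrt(omega^2+sigma^2)*sqrt(2/39) = 0.141` up to Monte-Carlo noise at 40
replicates): sharing information across doses and visits buys precision at
the lower doses, at the cost of a small dose-response-model bias.

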