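#' Root mean squared error from SD and bias
#'
#' \code{RMSE = sqrt(sd^2 + bias^2)}: the composite precision/accuracy
#' measure used for the last-visit placebo-adjusted estimates.
#'
#' @param sd Empirical standard deviation (nonnegative).
#' @param bias Mean error (estimate minus truth).
#' @return RMSE, same units as the inputs.
#' @export
rmse <- function(sd, bias) {
  if (!is.numeric(sd) || any(!is.finite(sd)) || any(sd < 0))
    stop("'sd' must be nonnegative and finite", call. = FALSE)
  sqrt(sd^2 + bias^2)
}

#' Theoretical RMSE of an unbiased two-arm contrast
#'
#' The sampling SD of a difference of two arm means at a single visit, with
#' per-subject variance \code{omega^2 + sigma^2}:
#' \code{sqrt(omega^2 + sigma^2) / sqrt(n) * sqrt(2)}.  At the default
#' design (omega 0.3716, sigma 0.50, n 39) this is about 0.14 log(mg/g), the
#' reference line for the saturated MMRM.
#'
#' @param omega Between-subject SD.
#' @param sigma Residual SD (positive).
#' @param n Subjects per arm (>= 1).
#' @return Theoretical RMSE in log(mg/g).
#' @export
theoretical_rmse <- function(omega, sigma, n) {
  stopifnot(is.numeric(omega), omega >= 0, is.numeric(sigma), sigma > 0,
            n >= 1)
  sqrt(omega^2 + sigma^2) / sqrt(n) * sqrt(2)
}

#' Bias as a percentage of the maximal effect
#'
#' Expresses a log-scale bias relative to the maximal drug effect (a 40%
#' UACR reduction, |log(0.6)|).
#'
#' @param bias_log Bias on the log change-from-baseline scale.
#' @param target_reduction UACR ratio defining the maximal effect; default
#'   0.6.
#' @return Percent of the maximal effect (signed).
#' @export
relative_bias_pct <- function(bias_log, target_reduction = 0.6) {
  100 * bias_log / abs(log(target_reduction))
}

#' Expected Monte-Carlo variability band for an unbiased estimator
#'
#' Half-width (+-2 SD of the Monte-Carlo mean) of the relative bias expected
#' from an unbiased estimator across \code{n_reps} replicate studies:
#' \code{100 * 2 * theoretical_rmse(omega, sigma, n) / sqrt(n_reps) /
#' |log(0.6)|}.  At 1000 replicates and the default design this is the
#' +-1.7% band; it widens as \code{1/sqrt(n_reps)} at reduced replicate
#' counts.
#'
#' @param n_reps Replicates per scenario (>= 1).
#' @param omega,sigma,n Design variance parameters and per-arm sample size.
#' @param target_reduction UACR ratio defining the maximal effect.
#' @return Band half-width in percent of the maximal effect.
#' @export
unbiasedness_band_pct <- function(n_reps, omega = 0.3716, sigma = 0.50,
                                  n = 39, target_reduction = 0.6) {
  stopifnot(n_reps >= 1)
  100 * 2 * theoretical_rmse(omega, sigma, n) / sqrt(n_reps) /
    abs(log(target_reduction))
}

#' Empirical power of the design's two-sample comparison
#'
#' Monte-Carlo power of a two-sided two-sample t-test on last-visit change
#' from baseline, highest dose versus placebo, with per-subject SD
#' \code{sqrt(omega^2 + sigma^2)}.  At the default design and a 40%
#' reduction (effect log(0.6)) this reproduces the 95% power requirement
#' that fixed n = 39 per arm.
#'
#' @param design A [uacr_design()].
#' @param effect Log-scale effect in the active arm; default \code{log(0.6)}.
#' @param n_reps Number of replicate comparisons (>= 100).
#' @param seed Integer seed.
#' @param alpha Two-sided level; default 0.05.
#' @return Rejection fraction in \[0, 1\].
#' @export
empirical_power <- function(design = uacr_design(), effect = log(0.6),
                            n_reps = 2000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(design, "uacr_design"), n_reps >= 100)
  sd_tot <- sqrt(design$omega^2 + design$sigma^2)
  n <- design$n_per_arm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y1 <- matrix(rnorm(n_reps * n, effect, sd_tot), n_reps, n)
  y0 <- matrix(rnorm(n_reps * n, 0, sd_tot), n_reps, n)
  # Welch two-sample t statistic, vectorized across replicates
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  v1 <- apply(y1, 1, var); v0 <- apply(y0, 1, var)
  se <- sqrt(v1 / n + v0 / n)
  tt <- (m1 - m0) / se
  df <- (v1 / n + v0 / n)^2 / ((v1 / n)^2 / (n - 1) + (v0 / n)^2 / (n - 1))
  mean(2 * pt(-abs(tt), df) < alpha)
}
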