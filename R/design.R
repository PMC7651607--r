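#' Trial design for the simulated UACR dose-finding study
#'
#' Defines the visit schedule, dose arms, per-arm sample size and the
#' variance model of the simulated log-UACR change from baseline: a
#' between-subject SD \code{omega}, a residual SD \code{sigma} and a lag-1
#' autocorrelation \code{rho} per visit (AR(1) over visit positions).
#'
#' @param n_per_arm Subjects per arm (default 39, from the 95% power
#'   requirement for a 40% UACR reduction; see [required_sample_size()]).
#' @param omega Between-subject SD of the change score, log(mg/g); default
#'   0.3716.
#' @param sigma Residual SD, log(mg/g); default 0.50.
#' @param rho Lag-1 AR(1) residual correlation per visit; default 0.226.
#' @param baseline_mean Mean baseline log UACR, log(mg/g); default 5.63.
#'   Carried only for the absolute-scale export ([export_absolute_scale()]);
#'   change scores do not depend on it.
#' @param visit_weeks Post-baseline visit weeks; default
#'   \code{c(2,4,6,8,10,12,14,15,16)}.
#' @param baseline_weeks Baseline sampling weeks; default \code{c(-2,-1,0)}.
#' @param arm_config \code{"four_dose"} (placebo + 3/10/30/100 mg) or
#'   \code{"three_dose"} (placebo + 10/30/100 mg).
#' @return An object of class \code{uacr_design}: a list with the fields
#'   above plus \code{arms}, a data.frame of arm labels and doses (dose 0 =
#'   placebo).
#' @examples
#' d <- uacr_design()
#' d$arms
#' @export
uacr_design <- function(n_per_arm = 39, omega = 0.3716, sigma = 0.50,
                        rho = 0.226, baseline_mean = 5.63,
                        visit_weeks = c(2, 4, 6, 8, 10, 12, 14, 15, 16),
                        baseline_weeks = c(-2, -1, 0),
                        arm_config = c("four_dose", "three_dose")) {
  arm_config <- match.arg(arm_config)
  stopifnot(is.numeric(n_per_arm), length(n_per_arm) == 1L, n_per_arm >= 1,
            n_per_arm == round(n_per_arm),
            is.numeric(omega), omega >= 0, is.finite(omega),
            is.numeric(sigma), sigma > 0, is.finite(sigma),
            is.numeric(rho), abs(rho) < 1,
            is.numeric(baseline_mean), is.finite(baseline_mean))
  if (any(diff(visit_weeks) <= 0) || any(diff(baseline_weeks) <= 0))
    stop("visit weeks must be strictly increasing", call. = FALSE)
  doses <- switch(arm_config,
                  four_dose = c(0, 3, 10, 30, 100),
                  three_dose = c(0, 10, 30, 100))
  arms <- data.frame(
    arm = ifelse(doses == 0, "placebo", paste0(doses, "mg")),
    dose = doses, stringsAsFactors = FALSE)
  structure(list(n_per_arm = as.integer(n_per_arm), omega = omega,
                 sigma = sigma, rho = rho, baseline_mean = baseline_mean,
                 visit_weeks = visit_weeks, baseline_weeks = baseline_weeks,
                 arm_config = arm_config, arms = arms),
            class = "uacr_design")
}

#' @export
print.uacr_design <- function(x, ...) {
  cat("UACR trial design (", x$arm_config, ")\n", sep = "")
  cat("  arms: ", paste0(x$arms$arm, collapse = ", "),
      "  (n = ", x$n_per_arm, "/arm)\n", sep = "")
  cat("  post-baseline weeks: ", paste(x$visit_weeks, collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  variance: omega = %.4f, sigma = %.2f, rho = %.3f/visit\n",
              x$omega, x$sigma, x$rho))
  invisible(x)
}

#' Per-arm sample size for a two-sample comparison
#'
#' Smallest n per arm for a two-sided two-sample t-test to detect a log-scale
#' effect with the requested power, by the normal-approximation formula
#' \code{n = 2 * (z[1-alpha/2] + z[power])^2 * sd^2 / effect^2}, rounded up.
#' With \code{effect = log(0.6)} and \code{sd = sqrt(0.3716^2 + 0.50^2)} this
#' gives 38.65, i.e. 39 per arm, the design default.
#'
#' @param effect_log Log-scale effect size (nonzero).
#' @param sd_total Total per-subject SD of the endpoint (positive).
#' @param power Target power, in (0,1); default 0.95.
#' @param alpha Two-sided significance level, in (0,1); default 0.05.
#' @return Integer sample size per arm.
#' @examples
#' required_sample_size(log(0.6), sqrt(0.3716^2 + 0.50^2))
#' @export
required_sample_size <- function(effect_log, sd_total, power = 0.95,
                                 alpha = 0.05) {
  vals <- c(effect_log, sd_total, power, alpha)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all arguments must be finite numbers", call. = FALSE)
  if (effect_log == 0) stop("'effect_log' must be nonzero", call. = FALSE)
  if (sd_total <= 0) stop("'sd_total' must be positive", call. = FALSE)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("'power' and 'alpha' must lie in (0, 1)", call. = FALSE)
  n <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * sd_total^2 / effect_log^2
  as.integer(ceiling(n - 1e-12))
}

#' Simulation scenario grid
#'
#' Expands the Cartesian product of true ED50 values, effect time-courses and
#' arm configurations into one scenario per row, each with a distinct
#' reproducible sub-seed derived from \code{master_seed}.  The default grid
#' (7 ED50 x 3 time-courses) gives 21 scenarios per arm configuration, i.e.
#' 21,000 simulated studies at 1000 replicates each.
#'
#' @param design A [uacr_design()] (supplies defaults; arm configuration may
#'   be overridden per scenario via \code{arm_configs}).
#' @param ed50_values True ED50 values in mg; default
#'   \code{c(2,4,8,16,32,64,128)}. Must be distinct.
#' @param timecourses Subset of \code{c("direct","exponential","linear")}.
#' @param arm_configs Subset of \code{c("four_dose","three_dose")}; default
#'   the design's own configuration.
#' @param n_reps Replicate studies per scenario; default 1000.
#' @param master_seed Integer master seed.
#' @return A data.frame of class \code{scenario_grid} with columns
#'   \code{scenario_id, ed50_true, timecourse, arm_config, n_reps, seed}.
#' @export
scenario_grid <- function(design = uacr_design(),
                          ed50_values = c(2, 4, 8, 16, 32, 64, 128),
                          timecourses = c("direct", "exponential", "linear"),
                          arm_configs = design$arm_config,
                          n_reps = 1000, master_seed = 20200731) {
  stopifnot(inherits(design, "uacr_design"),
            length(ed50_values) >= 1, length(timecourses) >= 1,
            length(arm_configs) >= 1, n_reps >= 1)
  if (anyDuplicated(ed50_values))
    stop("'ed50_values' must be distinct", call. = FALSE)
  timecourses <- match.arg(timecourses,
                           c("direct", "exponential", "linear"),
                           several.ok = TRUE)
  arm_configs <- match.arg(arm_configs, c("four_dose", "three_dose"),
                           several.ok = TRUE)
  g <- expand.grid(ed50_true = ed50_values, timecourse = timecourses,
                   arm_config = arm_configs, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g$n_reps <- as.integer(n_reps)
  g$seed <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(master_seed)
    sample.int(.Machine$integer.max - 1L, nrow(g))
  })
  g$scenario_id <- sprintf("%s_ed50-%g_%s", g$arm_config, g$ed50_true,
                           g$timecourse)
  g <- g[, c("scenario_id", "ed50_true", "timecourse", "arm_config",
             "n_reps", "seed")]
  class(g) <- c("scenario_grid", "data.frame")
  g
}
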