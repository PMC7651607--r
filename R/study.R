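#' Run the Monte-Carlo simulation study
#'
#' For every scenario in the grid, simulates \code{n_reps} replicate trials,
#' fits the requested analysis methods and aggregates their last-visit
#' placebo-adjusted estimates into operating characteristics: bias, relative
#' bias (percent of the maximal effect), empirical SD, RMSE, and the
#' median/2.5th/97.5th percentiles of the ED50 and last-visit Emax estimates
#' for the dose-response informed methods.  Medians are used for ED50/Emax
#' because boundary estimates distort the mean.  Per-fit convergence
#' failures are logged and excluded from that method's summaries; for
#' DR-MMRM a study is dropped only when all reference-dose
#' parameterizations fail simultaneously.
#'
#' @param scenarios A [scenario_grid()] (or subset of its rows).
#' @param design A [uacr_design()] supplying sample size, variance
#'   parameters and visit schedule.
#' @param methods Subset of \code{c("dreos", "mmrm", "drmmrm")}.
#' @param n_reps Optional override of each scenario's replicate count
#'   (useful for scaled-down runs).
#' @param keep_raw Keep the per-replicate estimate archive; default TRUE.
#' @param progress Print per-scenario progress; default FALSE.
#' @return An object of class \code{study_summary}: list with
#'   \code{estimates} (per arm_config x timecourse x ed50_true x method x
#'   dose: n_reps_used, mean_est, sd_est, bias, relative_bias_pct, rmse,
#'   truth), \code{params} (ED50/Emax percentile summaries per scenario x
#'   method), \code{failures} (complete-failure counts), \code{raw}
#'   (per-replicate archive or NULL), and the design stored as an attribute.
#' @export
run_study <- function(scenarios, design = uacr_design(),
                      methods = c("dreos", "mmrm", "drmmrm"),
                      n_reps = NULL, keep_raw = TRUE, progress = FALSE) {
  stopifnot(inherits(design, "uacr_design"), nrow(scenarios) >= 1)
  methods <- match.arg(methods, c("dreos", "mmrm", "drmmrm"),
                       several.ok = TRUE)
  raw_list <- vector("list", nrow(scenarios))
  fail_list <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, , drop = FALSE]
    if (!is.null(n_reps)) sc$n_reps <- as.integer(n_reps)
    if (progress)
      message(sprintf("[%d/%d] %s (%d reps)", i, nrow(scenarios),
                      sc$scenario_id, sc$n_reps))
    res <- .run_scenario(sc, design, methods)
    raw_list[[i]] <- res$raw
    fail_list[[i]] <- res$failures
  }
  raw <- do.call(rbind, raw_list)
  failures <- do.call(rbind, fail_list)
  summ <- summarize_study(raw, design)
  structure(list(estimates = summ$estimates, params = summ$params,
                 failures = failures, raw = if (keep_raw) raw else NULL),
            design = design, class = "study_summary")
}

# one scenario: simulate + fit all reps, return tidy per-rep records
.run_scenario <- function(sc, design, methods) {
  last_week <- max(design$visit_weeks)
  tp <- truth_params(sc$ed50_true, sc$timecourse)
  rows <- vector("list", sc$n_reps * length(methods))
  k <- 0L
  n_fail <- setNames(integer(length(methods)), methods)
  for (rep in seq_len(sc$n_reps)) {
    trial <- simulate_trial(sc, design, rep)
    for (mth in methods) {
      fit <- switch(mth, mmrm = fit_mmrm(trial), dreos = fit_dreos(trial),
                    drmmrm = fit_drmmrm(trial))
      k <- k + 1L
      if (!isTRUE(fit$converged) || is.null(fit$estimates)) {
        n_fail[mth] <- n_fail[mth] + 1L
        next
      }
      e <- fit$estimates[fit$estimates$week == last_week, , drop = FALSE]
      rows[[k]] <- data.frame(
        scenario_id = sc$scenario_id, arm_config = sc$arm_config,
        timecourse = sc$timecourse, ed50_true = sc$ed50_true,
        method = mth, rep = rep, dose = e$dose, week = e$week,
        estimate = e$estimate, se = e$se,
        truth = true_effect(tp, e$dose, e$week),
        ed50_hat = if (!is.null(fit$params$ed50_hat)) fit$params$ed50_hat else NA_real_,
        emax_hat = .last_emax(fit),
        stringsAsFactors = FALSE)
    }
  }
  list(raw = do.call(rbind, rows[seq_len(k)]),
       failures = data.frame(scenario_id = sc$scenario_id,
                             arm_config = sc$arm_config,
                             timecourse = sc$timecourse,
                             ed50_true = sc$ed50_true,
                             method = methods, n_reps = sc$n_reps,
                             n_failed = as.integer(n_fail),
                             stringsAsFactors = FALSE))
}

# last-visit Emax estimate of a dose-response informed fit (NA for MMRM)
.last_emax <- function(fit) {
  if (is.null(fit$params)) return(NA_real_)
  if (fit$method == "dreos") return(fit$params$emax_hat)
  em <- fit$params$emax_hat
  em[length(em)]
}

#' Aggregate a per-replicate archive into operating characteristics
#'
#' @param raw Per-replicate records as produced by [run_study()].
#' @param design The [uacr_design()] used (for the band recomputation).
#' @return List of \code{estimates} and \code{params} summary data.frames.
#' @export
summarize_study <- function(raw, design = uacr_design()) {
  stopifnot(is.data.frame(raw), nrow(raw) >= 1)
  key <- c("arm_config", "timecourse", "ed50_true", "method", "dose")
  est <- do.call(rbind, lapply(split(raw, raw[key], drop = TRUE), function(g) {
    err <- g$estimate - g$truth
    s <- stats::sd(g$estimate)
    b <- mean(err)
    data.frame(g[1, key, drop = FALSE], n_reps_used = nrow(g),
               truth = g$truth[1], mean_est = mean(g$estimate),
               sd_est = s, bias = b,
               relative_bias_pct = relative_bias_pct(b),
               rmse = rmse(s, b), row.names = NULL)
  }))
  keyp <- c("arm_config", "timecourse", "ed50_true", "method")
  prm <- raw[!is.na(raw$ed50_hat) & !duplicated(raw[c(keyp, "rep")]), ,
             drop = FALSE]
  params <- if (nrow(prm)) do.call(rbind, lapply(
    split(prm, prm[keyp], drop = TRUE), function(g) {
      qe <- stats::quantile(g$ed50_hat, c(0.025, 0.5, 0.975), names = FALSE)
      qm <- stats::quantile(g$emax_hat, c(0.025, 0.5, 0.975), names = FALSE)
      data.frame(g[1, keyp, drop = FALSE], n_reps_used = nrow(g),
                 ed50_q025 = qe[1], ed50_median = qe[2], ed50_q975 = qe[3],
                 emax_q025 = qm[1], emax_median = qm[2], emax_q975 = qm[3],
                 row.names = NULL)
    })) else NULL
  ord <- order(est$method, est$timecourse, est$ed50_true, est$dose)
  list(estimates = est[ord, , drop = FALSE], params = params)
}

#' Count cells outside the unbiasedness band
#'
#' Audits a method's last-visit relative biases against the expected
#' Monte-Carlo variability of an unbiased estimator (+-2 SD,
#' [unbiasedness_band_pct()]), with the band recomputed from each cell's
#' replicate count.  The grid must be complete: 3 time-courses x 7 ED50
#' values x all nonzero doses of the arm configuration (84 cells for the
#' 4-dose design, 63 for the 3-dose design).
#'
#' @param summary A \code{study_summary} from [run_study()].
#' @param method One of \code{"dreos"}, \code{"mmrm"}, \code{"drmmrm"}.
#' @return List with \code{count}, \code{total}, and the audited cell table
#'   (\code{cells}) including each cell's band half-width.
#' @export
band_exceedance_count <- function(summary, method) {
  stopifnot(inherits(summary, "study_summary"))
  design <- attr(summary, "design")
  est <- summary$estimates
  est <- est[est$method == method, , drop = FALSE]
  if (nrow(est) == 0L) stop("no cells for method ", method, call. = FALSE)
  n_doses <- length(unique(est$dose))
  expected <- 3L * 7L * n_doses
  if (length(unique(est$timecourse)) != 3L ||
      length(unique(est$ed50_true)) != 7L || nrow(est) != expected)
    stop(sprintf("incomplete grid: need 3 timecourses x 7 ED50 x %d doses (%d cells), have %d",
                 n_doses, expected, nrow(est)), call. = FALSE)
  est$band_pct <- unbiasedness_band_pct(est$n_reps_used, design$omega,
                                        design$sigma, design$n_per_arm)
  est$outside <- abs(est$relative_bias_pct) > est$band_pct
  list(count = sum(est$outside), total = nrow(est), cells = est)
}

#' @export
print.study_summary <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("Simulation study summary: %d scenario cells, methods: %s\n",
              nrow(e), paste(unique(e$method), collapse = ", ")))
  agg <- aggregate(cbind(rmse, relative_bias_pct) ~ method, data = e,
                   function(v) c(mean(v), max(abs(v))))
  cat("  per method: mean RMSE / max |relative bias| (% of max effect)\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %-7s %.4f / %.2f%%\n", agg$method[i],
                agg$rmse[i, 1], agg$relative_bias_pct[i, 2]))
  if (!is.null(x$failures) && any(x$failures$n_failed > 0)) {
    f <- x$failures[x$failures$n_failed > 0, ]
    cat(sprintf("  complete fit failures: %d (of %d fits attempted)\n",
                sum(f$n_failed), sum(x$failures$n_reps)))
  }
  invisible(x)
}

#' Write study outputs as CSV
#'
#' @param summary A \code{study_summary}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes \code{summary.csv},
#'   \code{params.csv}, \code{failures.csv} and, if retained,
#'   \code{raw_estimates.csv}.
#' @export
write_study_csv <- function(summary, dir) {
  stopifnot(inherits(summary, "study_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$estimates, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(summary$params))
    utils::write.csv(summary$params, file.path(dir, "params.csv"),
                     row.names = FALSE)
  utils::write.csv(summary$failures, file.path(dir, "failures.csv"),
                   row.names = FALSE)
  if (!is.null(summary$raw))
    utils::write.csv(summary$raw, file.path(dir, "raw_estimates.csv"),
                     row.names = FALSE)
  invisible(dir)
}
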