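#' Conventional MMRM analysis
#'
#' Saturated mixed model for repeated measures: one free mean parameter per
#' arm x visit cell, fitted by profiled GLS with a first-order autoregressive
#' residual correlation over visit positions ([fit_ar1_gls()]).  On a
#' balanced complete panel the cell estimates equal the cell sample means for
#' any working correlation; the AR(1) estimate feeds the model-based standard
#' errors.  The placebo-adjusted change (the treatment effect) at dose d and
#' visit t is \code{cellmean(d, t) - cellmean(0, t)}, with the covariance
#' cross-term included in its SE (zero here, as arms share no subjects).
#'
#' @param trial A \code{trial_data} data.frame ([simulate_trial()] or
#'   [read_trial_csv()]).
#' @param criterion \code{"reml"} (default) or \code{"ml"}.
#' @return An object of class \code{method_fit} with \code{method = "mmrm"}:
#'   \code{estimates} is a data.frame (dose, week, estimate, se, ci_low,
#'   ci_high) covering every nonzero dose x visit; \code{rho_hat},
#'   \code{sigma_hat}, \code{converged} record the covariance fit.  95%
#'   confidence limits use the normal quantile 1.96.
#' @export
fit_mmrm <- function(trial, criterion = c("reml", "ml")) {
  criterion <- match.arg(criterion)
  trial <- .sort_trial(trial)
  weeks <- sort(unique(trial$week))
  doses <- sort(unique(trial$dose))
  cell <- interaction(factor(trial$dose, levels = doses),
                      factor(trial$week, levels = weeks), drop = FALSE)
  X <- stats::model.matrix(~ 0 + cell)
  fit <- fit_ar1_gls(X, trial$duacr, trial$subject, criterion = criterion)
  # cell order: dose varies fastest within week
  idx <- function(d, w) match(d, doses) + (match(w, weeks) - 1L) * length(doses)
  grid <- expand.grid(dose = setdiff(doses, 0), week = weeks,
                      KEEP.OUT.ATTRS = FALSE)
  i1 <- idx(grid$dose, grid$week)
  i0 <- idx(rep(0, nrow(grid)), grid$week)
  est <- fit$beta[i1] - fit$beta[i0]
  se <- sqrt(fit$beta_cov[cbind(i1, i1)] + fit$beta_cov[cbind(i0, i0)] -
               2 * fit$beta_cov[cbind(i1, i0)])
  z <- qnorm(0.975)
  method_fit("mmrm",
             estimates = data.frame(dose = grid$dose, week = grid$week,
                                    estimate = est, se = se,
                                    ci_low = est - z * se,
                                    ci_high = est + z * se),
             params = NULL, converged = fit$converged,
             rho_hat = fit$rho_hat, sigma_hat = fit$sigma_hat)
}

.sort_trial <- function(trial) {
  stopifnot(is.data.frame(trial),
            all(c("subject", "dose", "visit", "week", "duacr") %in% names(trial)))
  trial[order(match(trial$subject, unique(trial$subject)), trial$visit), ,
        drop = FALSE]
}

# common container for the three analysis methods
method_fit <- function(method, estimates, params, converged, ...) {
  structure(c(list(method = method, estimates = estimates, params = params,
                   converged = converged), list(...)),
            class = "method_fit")
}

#' @export
print.method_fit <- function(x, ...) {
  cat(sprintf("<%s fit>%s\n", toupper(x$method),
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$params) && !is.null(x$params$ed50_hat))
    cat(sprintf("  ED50 = %.3g mg%s\n", x$params$ed50_hat,
                if (isTRUE(x$params$ed50_at_bound)) " (at bound)" else ""))
  if (!is.null(x$estimates)) {
    cat("  placebo-adjusted estimates (last visit):\n")
    last <- x$estimates[x$estimates$week == max(x$estimates$week), ]
    print(format(last, digits = 4), row.names = FALSE)
  }
  invisible(x)
}
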