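#' Dose-response MMRM, one reference-dose parameterization
#'
#' Fits the longitudinal Emax mixed model for repeated measures: each visit t
#' has its own placebo response \code{Plc_t} and drug-effect parameter, all
#' visits share one \code{ED50}, and residuals within subject follow an AR(1)
#' correlation.  The model is expressed in the reference-dose ("E_dose")
#' parameterization
#' \deqn{y = Plc_t + E_{dose,t} \frac{d}{ED50 + d} \frac{ED50 + dose_m}{dose_m},}
#' which collapses to \code{y = Plc_t + E_dose_t} when \code{d = dose_m}, so
#' the placebo-adjusted effect at the reference arm and its standard error
#' are read directly off the fit.
#'
#' Numerically, the linear parameters (the per-visit placebo and effect
#' coefficients) are profiled out by closed-form GLS at each candidate
#' \code{(ED50, rho)}, and the outer criterion is maximized by bounded
#' two-dimensional quasi-Newton search over \code{(log ED50, atanh rho)} with
#' multi-start over ED50.  The default outer criterion is the profiled
#' maximum likelihood, the convention for nonlinear generalized least
#' squares: it depends on the fitted mean only through its column space, so
#' the estimated ED50 (and the implied Emax) is identical whichever arm is
#' used as reference; the parameterizations differ only in which linear
#' coefficients and standard errors are reported.  (Restricted likelihood is
#' available, but for a mean that is nonlinear in ED50 its adjustment term
#' depends on the column scaling, anchoring the criterion to the chosen
#' reference dose; the ED50 estimate can then differ slightly across
#' parameterizations.)  Standard errors come from the Jacobian of the mean
#' function in the \code{(Plc_t, E_dose_t, ED50)} parameterization, weighted
#' by the fitted AR(1) covariance, so ED50 uncertainty propagates into the
#' per-visit effect SEs.
#'
#' @param trial A \code{trial_data} data.frame.
#' @param dose_m Reference dose in mg; must be one of the trial's nonzero
#'   doses.
#' @param criterion \code{"ml"} (default; reparameterization-invariant) or
#'   \code{"reml"} (anchored to \code{dose_m}, see Details).
#' @param ed50_bounds ED50 search bounds in mg; default \code{c(0.01, 1e4)}.
#' @param ed50_starts Multi-start ED50 initial values; default
#'   \code{c(1, 10, 30, 100, 300)}. The two best starts under the criterion
#'   are polished to convergence.
#' @param optim_control Control list passed to [stats::optim()]
#'   (\code{"L-BFGS-B"}).
#' @return An object of class \code{drmmrm_single}: per-visit
#'   \code{visits} data.frame (week, plc, e_dose, se), \code{ed50_hat},
#'   \code{ed50_se}, \code{emax_hat} (per-visit, back-calculated),
#'   \code{rho_hat}, \code{sigma_hat}, \code{loglik}, \code{converged},
#'   \code{ed50_at_bound}, \code{dose_m}.
#' @export
fit_drmmrm_single <- function(trial, dose_m, criterion = c("ml", "reml"),
                              ed50_bounds = c(0.01, 1e4),
                              ed50_starts = c(1, 10, 30, 100, 300),
                              optim_control = list(factr = 1e7)) {
  criterion <- match.arg(criterion)
  trial <- .sort_trial(trial)
  doses_nz <- sort(unique(trial$dose[trial$dose > 0]))
  if (!dose_m %in% doses_nz)
    stop("'dose_m' must be one of the trial's nonzero doses", call. = FALSE)
  weeks <- sort(unique(trial$week))
  m <- length(weeks)
  subj <- trial$subject
  y <- trial$duacr
  d <- trial$dose
  Ivis <- stats::model.matrix(~ 0 + factor(week, levels = weeks), trial)
  colnames(Ivis) <- paste0("w", weeks)

  dims <- .check_panel(cbind(y), y, subj)
  n_sub <- dims$n
  Y <- matrix(y, nrow = m)                  # visits x subjects
  d_sub <- d[seq(1, length(d), by = m)]     # one dose per subject
  # E_dose design: effect column is 1 at the reference dose for any ED50.
  # Per-subject blocks are [I_m, g_i I_m], so the GLS crossproducts have
  # Kronecker form K (x) W with K the 2x2 moment matrix of g; the inner
  # solve is closed-form in O(n m^2).
  g_sub <- function(ed50)
    (d_sub / (ed50 + d_sub)) * ((ed50 + dose_m) / dose_m)
  edose_solve <- function(ed50, rho) {
    gs <- g_sub(ed50)
    W <- ar1_corr_inverse(rho, m)
    K <- matrix(c(n_sub, sum(gs), sum(gs), sum(gs^2)), 2)
    detK <- K[1, 1] * K[2, 2] - K[1, 2]^2
    if (!is.finite(detK) || detK <= 1e-12 * K[1, 1] * K[2, 2]) return(NULL)
    s1 <- rowSums(Y)
    s2 <- drop(Y %*% gs)
    b_plc <- (K[2, 2] * s1 - K[1, 2] * s2) / detK
    b_e <- (K[1, 1] * s2 - K[1, 2] * s1) / detK
    R <- Y - b_plc - tcrossprod(b_e, gs)
    rss <- sum(R * (W %*% R))
    M <- n_sub * m; p <- 2L * m
    df <- if (criterion == "reml") M - p else M
    sigma2 <- rss / df
    ll <- -0.5 * (df * (log(2 * pi * sigma2) + 1) +
                    n_sub * ar1_logdet(rho, m))
    if (criterion == "reml")
      ll <- ll - 0.5 * (m * log(detK) - 2 * ar1_logdet(rho, m))
    list(beta = c(b_plc, b_e), sigma_hat = sqrt(sigma2), loglik = ll,
         rss_w = rss, n = n_sub, m = m, p = p)
  }
  neg_ll <- function(par) {
    sol <- edose_solve(exp(par[1]), tanh(par[2]))
    if (is.null(sol) || !is.finite(sol$loglik)) return(1e10)
    -sol$loglik
  }

  lb <- log(ed50_bounds)
  # start rho at the sample lag-1 autocorrelation of cell-demeaned residuals
  rho_z0 <- atanh(min(max(.lag1_autocorr(trial), -0.9), 0.9))
  starts <- pmin(pmax(log(ed50_starts), lb[1]), lb[2])
  screen <- vapply(starts, function(s) neg_ll(c(s, rho_z0)), numeric(1))
  keep <- order(screen)[seq_len(min(2L, length(starts)))]
  ctrl <- utils::modifyList(list(factr = 1e7, ndeps = c(1e-5, 1e-5)),
                            optim_control)
  best <- NULL
  for (s in starts[keep]) {
    op <- tryCatch(
      optim(c(s, rho_z0), neg_ll, method = "L-BFGS-B",
            lower = c(lb[1], atanh(-0.999)), upper = c(lb[2], atanh(0.999)),
            control = ctrl),
      error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  # derivative-free polish: the quasi-Newton step size limits accuracy near
  # the optimum, and downstream checks compare log-likelihoods to 1e-6
  if (!is.null(best) && best$par[1] > lb[1] + 1e-8 &&
      best$par[1] < lb[2] - 1e-8) {
    pol <- tryCatch(
      optim(best$par, neg_ll, method = "Nelder-Mead",
            control = list(reltol = 1e-13, maxit = 400)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value) {
      pol$convergence <- best$convergence
      pol$par <- pmin(pmax(pol$par, c(lb[1], atanh(-0.999))),
                      c(lb[2], atanh(0.999)))
      best <- pol
    }
  }
  fail <- function() structure(list(converged = FALSE, dose_m = dose_m),
                               class = "drmmrm_single")
  if (is.null(best)) return(fail())
  ed50 <- exp(best$par[1])
  rho <- tanh(best$par[2])
  sol <- edose_solve(ed50, rho)
  if (is.null(sol)) return(fail())

  plc <- sol$beta[seq_len(m)]
  e_dose <- sol$beta[m + seq_len(m)]
  shrink <- dose_m / (ed50 + dose_m)
  emax_t <- e_dose / shrink

  # Jacobian in the (Plc_t, E_dose_t, ED50) parameterization
  h <- (d / (ed50 + d)) / shrink
  dh <- d * (d - dose_m) / (dose_m * (ed50 + d)^2)
  ed_col <- e_dose[match(trial$week, weeks)] * dh
  J <- cbind(Ivis, Ivis * h, ed50_col = ed_col)
  W <- ar1_corr_inverse(rho, m)
  JtWJ <- .gls_crossprods(J, y, sol$n, m, W)$XtWX
  covJ <- sol$sigma_hat^2 *
    tryCatch(chol2inv(chol(JtWJ)), error = function(e) .pinv(JtWJ))
  se_edose <- sqrt(pmax(diag(covJ)[m + seq_len(m)], 0))
  se_plc <- sqrt(pmax(diag(covJ)[seq_len(m)], 0))
  ed50_se <- sqrt(max(diag(covJ)[2 * m + 1L], 0))

  at_bound <- min(abs(ed50 / ed50_bounds - 1)) < 1e-3
  structure(list(
    visits = data.frame(week = weeks, plc = plc, plc_se = se_plc,
                        e_dose = e_dose, se = se_edose),
    ed50_hat = ed50, ed50_se = ed50_se, emax_hat = emax_t,
    rho_hat = rho, sigma_hat = sol$sigma_hat, loglik = -best$value,
    converged = best$convergence == 0, ed50_at_bound = at_bound,
    dose_m = dose_m, criterion = criterion),
    class = "drmmrm_single")
}

# sample lag-1 autocorrelation of arm-by-visit cell-demeaned residuals,
# used as the optimizer's starting value for the working correlation
.lag1_autocorr <- function(trial) {
  res <- trial$duacr - stats::ave(trial$duacr, trial$dose, trial$visit)
  m <- length(unique(trial$visit))
  R <- matrix(res, nrow = m)
  num <- mean(R[-m, , drop = FALSE] * R[-1, , drop = FALSE])
  den <- mean(R^2)
  if (!is.finite(num / den)) 0 else num / den
}

#' Dose-response MMRM analysis (all arms)
#'
#' Runs [fit_drmmrm_single()] once per nonzero dose arm (fitting the same
#' data 3 or 4 times) and assembles the per-arm placebo-adjusted estimates:
#' for each arm, the estimate and SE are taken from the parameterization
#' where that arm is the reference dose.  The shared ED50 (identical across
#' parameterizations up to optimizer tolerance) and the back-calculated
#' per-visit Emax are recorded from the converged parameterization with the
#' highest criterion value.  A complete convergence failure is declared only
#' when every parameterization fails; partially failed studies keep the
#' estimates of the surviving parameterizations.
#'
#' @inheritParams fit_drmmrm_single
#' @return A \code{method_fit} with \code{method = "drmmrm"}:
#'   \code{estimates} has one row per nonzero dose x visit (the Emax-model
#'   constrained placebo-adjusted effects), \code{params} holds
#'   \code{ed50_hat}, \code{ed50_se}, per-visit \code{emax_hat}, boundary
#'   flags and the per-parameterization record \code{by_arm}.
#' @export
fit_drmmrm <- function(trial, criterion = c("ml", "reml"),
                       ed50_bounds = c(0.01, 1e4),
                       ed50_starts = c(1, 10, 30, 100, 300),
                       optim_control = list(factr = 1e7)) {
  criterion <- match.arg(criterion)
  doses_nz <- sort(unique(trial$dose[trial$dose > 0]))
  if (length(doses_nz) < 3L)
    stop("DR-MMRM needs at least three nonzero dose arms", call. = FALSE)
  fits <- lapply(doses_nz, function(dm)
    fit_drmmrm_single(trial, dm, criterion = criterion,
                      ed50_bounds = ed50_bounds, ed50_starts = ed50_starts,
                      optim_control = optim_control))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  conv_rec <- data.frame(dose_m = doses_nz, converged = ok,
                         ed50_hat = vapply(fits, function(f)
                           if (isTRUE(f$converged)) f$ed50_hat else NA_real_,
                           numeric(1)))
  if (!any(ok))
    return(method_fit("drmmrm", estimates = NULL, params = NULL,
                      converged = FALSE, by_arm = conv_rec))
  z <- qnorm(0.975)
  est <- do.call(rbind, lapply(which(ok), function(i) {
    f <- fits[[i]]
    data.frame(dose = f$dose_m, week = f$visits$week,
               estimate = f$visits$e_dose, se = f$visits$se,
               ci_low = f$visits$e_dose - z * f$visits$se,
               ci_high = f$visits$e_dose + z * f$visits$se)
  }))
  ref <- fits[[which(ok)[which.max(vapply(which(ok), function(i)
    fits[[i]]$loglik, numeric(1)))]]]
  method_fit("drmmrm", estimates = est,
             params = list(ed50_hat = ref$ed50_hat, ed50_se = ref$ed50_se,
                           emax_hat = ref$emax_hat,
                           plc_hat = ref$visits$plc,
                           ed50_at_bound = ref$ed50_at_bound,
                           weeks = ref$visits$week),
             converged = TRUE, by_arm = conv_rec,
             rho_hat = ref$rho_hat, sigma_hat = ref$sigma_hat)
}
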