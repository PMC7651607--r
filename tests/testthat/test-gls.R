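test_that("Gaussian log-likelihood matches a dense brute-force evaluation", {
  pan <- make_panel(n = 5, m = 4, p = 3, rho = 0.4, sigma = 0.7, seed = 11)
  for (rho in c(-0.5, 0, 0.226, 0.8)) {
    ll <- ar1_loglik(pan$X, pan$y, pan$subject, pan$beta, 0.7, rho)
    ll_dense <- dense_loglik(pan$X, pan$y, pan$m, pan$beta, 0.7, rho)
    expect_equal(ll, ll_dense, tolerance = 1e-10)
  }
})

test_that("closed-form AR(1) inverse agrees with dense solve", {
  for (rho in c(-0.7, 0.1, 0.9)) {
    R <- ar1_correlation(rho, 7)
    expect_equal(drmmrm:::ar1_corr_inverse(rho, 7), solve(R),
                 tolerance = 1e-10)
    expect_equal(drmmrm:::ar1_logdet(rho, 7),
                 as.numeric(determinant(R)$modulus), tolerance = 1e-10)
  }
})

test_that("saturated balanced GLS returns cell means for any working rho", {
  tr <- make_mini_trial(n_per_arm = 6, omega = 0.3, sigma = 0.5, rho = 0.3,
                        seed = 21)
  cellmeans <- tapply(tr$duacr, list(tr$dose, tr$week), mean)
  weeks <- sort(unique(tr$week)); doses <- sort(unique(tr$dose))
  cell <- interaction(factor(tr$dose, doses), factor(tr$week, weeks))
  X <- model.matrix(~ 0 + cell)
  for (rho in c(0, 0.226, -0.4, 0.85)) {
    sol <- gls_solve_given_rho(X, tr$duacr, tr$subject, rho)
    est <- matrix(sol$beta, nrow = length(doses))
    expect_equal(unname(est), unname(cellmeans), tolerance = 1e-10)
  }
})

test_that("profiled ML fit equals brute-force joint maximization", {
  pan <- make_panel(n = 8, m = 3, p = 2, rho = 0.35, sigma = 0.5, seed = 31)
  fit <- fit_ar1_gls(pan$X, pan$y, pan$subject, criterion = "ml")
  nll <- function(th) -dense_loglik(pan$X, pan$y, pan$m,
                                    th[1:2], exp(th[3]), tanh(th[4]))
  bf <- nlminb(c(fit$beta, log(fit$sigma_hat), atanh(fit$rho_hat)) * 0.9 + 0.01,
               nll, control = list(rel.tol = 1e-14, iter.max = 500))
  expect_lt(abs(fit$loglik - (-bf$objective)), 1e-6)
  expect_equal(fit$beta, bf$par[1:2], tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(fit$rho_hat, tanh(bf$par[4]), tolerance = 1e-3)
})

test_that("REML fit matches nlme::gls with AR(1) correlation", {
  skip_if_not_installed("nlme")
  tr <- make_mini_trial(n_per_arm = 15, omega = 0, sigma = 0.5, rho = 0.35,
                        seed = 41)
  weeks <- sort(unique(tr$week)); doses <- sort(unique(tr$dose))
  cell <- interaction(factor(tr$dose, doses), factor(tr$week, weeks))
  X <- model.matrix(~ 0 + cell)
  fit <- fit_ar1_gls(X, tr$duacr, tr$subject, criterion = "reml")
  gd <- data.frame(y = tr$duacr, cell = cell, visit = tr$visit,
                   subject = tr$subject)
  gfit <- nlme::gls(y ~ 0 + cell, data = gd,
                    correlation = nlme::corAR1(form = ~ visit | subject),
                    method = "REML")
  expect_equal(unname(fit$beta), unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$rho_hat,
               as.numeric(coef(gfit$modelStruct$corStruct,
                               unconstrained = FALSE)), tolerance = 1e-4)
  expect_equal(fit$sigma_hat, gfit$sigma, tolerance = 1e-4)
  expect_equal(sqrt(diag(fit$beta_cov)),
               unname(sqrt(diag(vcov(gfit)))), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("variance parameters are recovered at large n", {
  pan <- make_panel(n = 1200, m = 6, p = 2, rho = 0.226, sigma = 0.5,
                    seed = 51)
  fit <- fit_ar1_gls(pan$X, pan$y, pan$subject)
  expect_equal(fit$rho_hat, 0.226, tolerance = 0.06)
  expect_equal(fit$sigma_hat, 0.5, tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("degenerate single-visit panels fall back to rho = 0", {
  pan <- make_panel(n = 30, m = 1, p = 2, rho = 0, sigma = 0.5, seed = 61)
  fit <- fit_ar1_gls(pan$X, pan$y, pan$subject)
  expect_identical(fit$rho_hat, 0)
  expect_false(fit$rho_estimable)
  # beta covariance at rho = 0 on a saturated one-cell design is sigma^2/n
  X1 <- matrix(1, 30, 1)
  f1 <- fit_ar1_gls(X1, pan$y[seq_len(30)], seq_len(30))
  expect_equal(f1$beta_cov[1, 1], f1$sigma_hat^2 / 30, tolerance = 1e-10)
})

test_that("rank-deficient designs raise a singular-design error", {
  pan <- make_panel(n = 6, m = 3, p = 2, seed = 71)
  Xbad <- cbind(pan$X, pan$X[, 1])
  expect_error(gls_solve_given_rho(Xbad, pan$y, pan$subject, 0.2), "singular")
  expect_error(gls_solve_given_rho(pan$X, pan$y, pan$subject, 1.5), "rho")
  interleaved <- rep(seq_len(6), times = 3)
  expect_error(gls_solve_given_rho(pan$X, pan$y, interleaved, 0),
               "contiguous")
})
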