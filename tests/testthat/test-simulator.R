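test_that("AR(1) correlation matrix has the right entries", {
  R <- ar1_correlation(0.226, 9)
  expect_equal(R[1, 2], 0.226)
  expect_equal(R[1, 3], 0.051076, tolerance = 1e-6)
  expect_equal(R, t(R))
  expect_true(all(eigen(R, only.values = TRUE)$values > 0))
  expect_equal(ar1_correlation(0, 5), diag(5))
  expect_error(ar1_correlation(1, 5), "rho")
})

test_that("simulation is bit-reproducible and balanced", {
  sc <- mini_scenario(n_reps = 3, seed = 202)
  d <- uacr_design()
  t1 <- simulate_trial(sc, d, 2)
  t2 <- simulate_trial(sc, d, 2)
  expect_identical(t1$duacr, t2$duacr)
  t3 <- simulate_trial(sc, d, 3)
  expect_false(identical(t1$duacr, t3$duacr))
  # complete balanced panel: every subject exactly once per visit
  tab <- table(t1$subject, t1$visit)
  expect_true(all(tab == 1L))
  expect_identical(nrow(t1), 5L * 39L * 9L)
  expect_setequal(unique(t1$dose), c(0, 3, 10, 30, 100))
  tt <- simulate_trial(mini_scenario(arm_config = "three_dose", seed = 203), d, 1)
  expect_identical(nrow(tt), 4L * 39L * 9L)
})

test_that("simulated moments match the generative variance model", {
  # inflate n for tight Monte-Carlo error; one placebo-like scenario so the
  # mean structure is flat
  d <- uacr_design(n_per_arm = 4000, arm_config = "three_dose")
  sc <- mini_scenario(ed50 = 32, timecourse = "direct", n_reps = 1, seed = 303,
                      arm_config = "three_dose")
  tr <- simulate_trial(sc, d, 1)
  plc <- tr[tr$dose == 0, ]
  Y <- matrix(plc$duacr, ncol = 9, byrow = TRUE)
  S <- cov(Y)
  expect_equal(mean(diag(S)), 0.3716^2 + 0.50^2, tolerance = 0.02)
  # between-visit covariance omega^2 + sigma^2 rho^|lag|
  lag1 <- mean(S[cbind(1:8, 2:9)])
  lag3 <- mean(S[cbind(1:6, 4:9)])
  expect_equal(lag1, 0.3716^2 + 0.50^2 * 0.226, tolerance = 0.02)
  expect_equal(lag3, 0.3716^2 + 0.50^2 * 0.226^3, tolerance = 0.02)
  # implied residual lag-1 autocorrelation after removing the subject level
  rho_hat <- (lag1 - 0.3716^2) / 0.50^2
  expect_equal(rho_hat, 0.226, tolerance = 0.05)
})

test_that("noise-free simulation equals the true effect exactly", {
  d <- uacr_design(omega = 0, sigma = 1e-12, n_per_arm = 2)
  sc <- mini_scenario(ed50 = 16, timecourse = "exponential", seed = 7)
  tr <- simulate_trial(sc, d, 1)
  tp <- truth_params(16, "exponential")
  expect_equal(tr$duacr, true_effect(tp, tr$dose, tr$week), tolerance = 1e-9)
})

test_that("last-visit placebo-adjusted arm-mean difference has SD near 0.141", {
  d <- uacr_design()
  sc <- mini_scenario(ed50 = 32, timecourse = "linear", n_reps = 1000,
                      seed = 404)
  diffs <- vapply(seq_len(1000), function(r) {
    tr <- simulate_trial(sc, d, r)
    last <- tr[tr$week == 16, ]
    mean(last$duacr[last$dose == 100]) - mean(last$duacr[last$dose == 0])
  }, numeric(1))
  # Monte-Carlo SE of an SD over 1000 replicates is ~2.2%; allow ~3.5 SE
  expect_equal(sd(diffs), theoretical_rmse(0.3716, 0.50, 39), tolerance = 0.08)
  expect_equal(sd(diffs), 0.141, tolerance = 0.08)
})

test_that("absolute-scale export round-trips and centers on baseline 5.63", {
  d <- uacr_design(n_per_arm = 150)
  sc <- mini_scenario(seed = 505)
  tr <- simulate_trial(sc, d, 1)
  abs_tab <- export_absolute_scale(tr, d)
  expect_identical(nrow(abs_tab), nrow(tr) + 3L * length(unique(tr$subject)))
  base <- abs_tab[abs_tab$week < 2, ]
  expect_equal(mean(base$log_uacr), 5.63, tolerance = 0.05)
  rt <- derive_change_from_baseline(abs_tab)
  expect_identical(nrow(rt), nrow(tr))
  ord <- order(match(rt$subject, unique(tr$subject)), rt$week)
  expect_equal(rt$duacr[ord], tr$duacr, tolerance = 1e-12)
  # placebo arm mean change near zero
  expect_equal(mean(rt$duacr[rt$dose == 0]), 0, tolerance = 0.1)
})

test_that("trial CSV round trip is bit-exact", {
  d <- uacr_design(n_per_arm = 5)
  tr <- simulate_trial(mini_scenario(seed = 606), d, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, f)
  rt <- read_trial_csv(f)
  expect_identical(rt$duacr, tr$duacr)
  expect_identical(rt$subject, tr$subject)
  expect_identical(rt$dose, tr$dose)
  # schema errors are informative
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,arm,dose\nS001,placebo,0", bad)
  expect_error(read_trial_csv(bad), "missing columns")
})
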