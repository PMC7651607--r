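# Independent oracles and small fixture builders used across the suite.

# Brute-force Gaussian log-density of a stacked AR(1) panel, assembled as a
# dense covariance matrix and evaluated with generic solve()/determinant().
# Deliberately ignorant of the closed-form tridiagonal machinery.
dense_loglik <- function(X, y, m, beta, sigma, rho) {
  n <- length(y) / m
  R <- outer(seq_len(m), seq_len(m), function(i, j) rho^abs(i - j))
  V <- sigma^2 * kronecker(diag(n), R)
  r <- y - drop(X %*% beta)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + drop(crossprod(r, solve(V, r))))
}

# random balanced panel with AR(1) + intercept-shift errors
make_panel <- function(n, m, p, rho = 0.3, sigma = 0.6, omega = 0,
                       beta = NULL, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * m * (p - 1)), n * m, p - 1))
  if (is.null(beta)) beta <- rnorm(p)
  R <- outer(seq_len(m), seq_len(m), function(i, j) rho^abs(i - j))
  L <- chol(R)
  eps <- sigma * (matrix(rnorm(n * m), n, m) %*% L)
  eta <- rnorm(n, 0, omega)
  y <- drop(X %*% beta) + as.vector(t(eps + eta))
  list(X = X, y = y, subject = rep(seq_len(n), each = m),
       beta = beta, n = n, m = m)
}

# small custom trial: arbitrary doses/weeks/subjects-per-arm, exact truth
# plus optional noise; used for tiny brute-force instances
make_mini_trial <- function(doses = c(0, 10, 30, 100), weeks = c(4, 10, 16),
                            n_per_arm = 2, ed50 = 20,
                            timecourse = "direct", omega = 0, sigma = 0,
                            rho = 0, seed = 1) {
  set.seed(seed)
  tp <- truth_params(ed50, timecourse)
  m <- length(weeks)
  n_tot <- length(doses) * n_per_arm
  R <- outer(seq_len(m), seq_len(m), function(i, j) rho^abs(i - j))
  L <- chol(R)
  dose_s <- rep(doses, each = n_per_arm)
  y <- outer(dose_s, weeks, function(d, t) true_effect(tp, d, t)) +
    rnorm(n_tot, 0, omega) +
    sigma * (matrix(rnorm(n_tot * m), n_tot, m) %*% L)
  structure(data.frame(
    subject = rep(sprintf("M%02d", seq_len(n_tot)), each = m),
    arm = rep(ifelse(dose_s == 0, "placebo", paste0(dose_s, "mg")), each = m),
    dose = rep(dose_s, each = m),
    visit = rep(seq_len(m), n_tot),
    week = rep(weeks, n_tot),
    duacr = as.vector(t(y)), stringsAsFactors = FALSE),
    class = c("trial_data", "data.frame"))
}

# single-scenario shorthand
mini_scenario <- function(ed50 = 32, timecourse = "linear", n_reps = 10,
                          seed = 101, arm_config = "four_dose") {
  list(scenario_id = sprintf("test_%g_%s", ed50, timecourse),
       ed50_true = ed50, timecourse = timecourse, n_reps = n_reps,
       seed = seed, arm_config = arm_config)
}
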