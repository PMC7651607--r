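#' AR(1) correlation matrix over visit positions
#'
#' Entry (i, j) is \code{rho^|i-j|}, counting lag in visit positions (not
#' weeks), so the closely spaced week-14/15/16 visits correlate as strongly
#' as the 2-week-spaced ones.
#'
#' @param rho Lag-1 correlation, |rho| < 1.
#' @param m Number of visits (>= 1).
#' @return An m x m symmetric positive-definite correlation matrix.
#' @export
ar1_correlation <- function(rho, m) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            m >= 1, m == round(m))
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  idx <- seq_len(m)
  rho^abs(outer(idx, idx, "-"))
}

# rep-level seeds for one scenario, derived deterministically from its
# sub-seed so any single replicate can be re-simulated in isolation
.rep_seeds <- function(scenario_seed, n_reps) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

.as_scenario_row <- function(scenario) {
  if (inherits(scenario, "data.frame")) {
    stopifnot(nrow(scenario) == 1L)
    as.list(scenario)
  } else as.list(scenario)
}

#' Simulate one trial replicate
#'
#' Generates the long-format panel of log-scale UACR changes from baseline:
#' for subject i in the arm with dose d,
#' \code{duacr[i, t] = true_effect(d, t) + eta_i + eps[i, t]}, with
#' \code{eta_i ~ N(0, omega^2)} a subject-level shift and
#' \code{eps[i, ]} multivariate normal with covariance
#' \code{sigma^2 * ar1_correlation(rho, 9)}.  The placebo response is exactly
#' zero in expectation: all evaluated quantities are placebo-adjusted, so a
#' common placebo drift would cancel.  The panel is complete and balanced
#' (no dropout is simulated).
#'
#' @param scenario One row of a [scenario_grid()] (or an equivalent list with
#'   \code{ed50_true, timecourse, n_reps, seed}, optionally
#'   \code{arm_config, scenario_id}).
#' @param design A [uacr_design()]. Its arm configuration is overridden by
#'   the scenario's, if present.
#' @param rep Replicate index in \code{1..n_reps}.
#' @return A data.frame of class \code{trial_data} with columns
#'   \code{subject, arm, dose, visit, week, duacr}, rows ordered by subject
#'   then visit, and attributes \code{scenario_id, rep, seed, design}.
#' @export
simulate_trial <- function(scenario, design = uacr_design(), rep = 1L) {
  sc <- .as_scenario_row(scenario)
  stopifnot(inherits(design, "uacr_design"), rep >= 1, rep <= sc$n_reps)
  if (!is.null(sc$arm_config) && sc$arm_config != design$arm_config)
    design <- uacr_design(n_per_arm = design$n_per_arm, omega = design$omega,
                          sigma = design$sigma, rho = design$rho,
                          baseline_mean = design$baseline_mean,
                          visit_weeks = design$visit_weeks,
                          baseline_weeks = design$baseline_weeks,
                          arm_config = sc$arm_config)
  seed <- .rep_seeds(sc$seed, sc$n_reps)[rep]

  weeks <- design$visit_weeks
  m <- length(weeks)
  arms <- design$arms
  n <- design$n_per_arm
  n_tot <- nrow(arms) * n
  tp <- truth_params(sc$ed50_true, sc$timecourse)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eta <- rnorm(n_tot, 0, design$omega)
  L <- chol(ar1_correlation(design$rho, m))         # R = L'L, L upper
  eps <- design$sigma * (matrix(rnorm(n_tot * m), n_tot, m) %*% L)

  dose_s <- rep(arms$dose, each = n)
  truth <- outer(dose_s, weeks, function(d, t) true_effect(tp, d, t))
  y <- truth + eta + eps                            # n_tot x m

  out <- data.frame(
    subject = rep(sprintf("S%03d", seq_len(n_tot)), each = m),
    arm = rep(rep(arms$arm, each = n), each = m),
    dose = rep(dose_s, each = m),
    visit = rep(seq_len(m), times = n_tot),
    week = rep(weeks, times = n_tot),
    duacr = as.vector(t(y)),
    stringsAsFactors = FALSE)
  structure(out,
            scenario_id = if (!is.null(sc$scenario_id)) sc$scenario_id else
              sprintf("%s_ed50-%g_%s", design$arm_config, sc$ed50_true, sc$timecourse),
            rep = as.integer(rep), seed = seed, design = design,
            class = c("trial_data", "data.frame"))
}

#' Export a trial on the absolute log-UACR scale
#'
#' Demonstration plumbing for round-tripping with absolute-scale data sets:
#' draws per-subject baseline values around \code{baseline_mean} at the
#' baseline weeks (-2, -1, 0) and emits post-baseline absolute values as
#' (mean of the subject's baseline samples) + duacr, so that re-deriving
#' change from mean baseline recovers the simulated panel exactly.
#'
#' @param trial A [simulate_trial()] result.
#' @param design The [uacr_design()] used (defaults to the one recorded on
#'   the trial).
#' @param seed Seed for the baseline draws; default derived from the trial's
#'   own seed.
#' @return A data.frame with columns \code{subject, arm, dose, week,
#'   log_uacr}; baseline rows have \code{week < 2}.
#' @export
export_absolute_scale <- function(trial, design = attr(trial, "design"),
                                  seed = attr(trial, "seed") + 1L) {
  stopifnot(inherits(trial, "trial_data"), inherits(design, "uacr_design"))
  subs <- unique(trial$subject)
  n_tot <- length(subs)
  bw <- design$baseline_weeks
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  b_subj <- rnorm(n_tot, design$baseline_mean, design$omega)
  b_vals <- rep(b_subj, each = length(bw)) +
    rnorm(n_tot * length(bw), 0, design$sigma)
  first <- !duplicated(trial$subject)
  base <- data.frame(
    subject = rep(subs, each = length(bw)),
    arm = rep(trial$arm[first], each = length(bw)),
    dose = rep(trial$dose[first], each = length(bw)),
    week = rep(bw, times = n_tot),
    log_uacr = b_vals, stringsAsFactors = FALSE)
  b_mean <- tapply(base$log_uacr, base$subject, mean)
  post <- data.frame(
    subject = trial$subject, arm = trial$arm, dose = trial$dose,
    week = trial$week,
    log_uacr = trial$duacr + as.vector(b_mean[trial$subject]),
    stringsAsFactors = FALSE)
  out <- rbind(base, post)
  out[order(match(out$subject, subs), out$week), , drop = FALSE]
}

#' Re-derive the change-from-baseline panel from an absolute-scale table
#'
#' Inverse of [export_absolute_scale()]: subtracts each subject's mean
#' baseline (weeks < first post-baseline visit) from the post-baseline rows.
#'
#' @param abs_table A data.frame as produced by [export_absolute_scale()].
#' @param first_post_week First post-baseline week; default 2.
#' @return A data.frame with columns \code{subject, arm, dose, week, duacr}.
#' @export
derive_change_from_baseline <- function(abs_table, first_post_week = 2) {
  is_base <- abs_table$week < first_post_week
  b_mean <- tapply(abs_table$log_uacr[is_base], abs_table$subject[is_base], mean)
  post <- abs_table[!is_base, , drop = FALSE]
  post$duacr <- post$log_uacr - as.vector(b_mean[post$subject])
  post$log_uacr <- NULL
  rownames(post) <- NULL
  post
}

#' Read/write trial data as CSV
#'
#' Long-format CSV with header
#' \code{subject,arm,dose,visit,week,duacr,scenario,rep}. The response is
#' written with 17 significant digits so the round trip is bit-exact.
#'
#' @param trial A \code{trial_data} data.frame.
#' @param path File path.
#' @return \code{write_trial_csv} returns \code{path} invisibly;
#'   \code{read_trial_csv} returns a \code{trial_data} data.frame.
#' @export
write_trial_csv <- function(trial, path) {
  out <- data.frame(
    subject = trial$subject, arm = trial$arm, dose = trial$dose,
    visit = trial$visit, week = trial$week,
    duacr = sprintf("%.17g", trial$duacr),
    scenario = attr(trial, "scenario_id") %||% NA_character_,
    rep = attr(trial, "rep") %||% NA_integer_,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  classes <- c(subject = "character", arm = "character", duacr = "character",
               dose = "numeric", week = "numeric", visit = "integer")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = classes[intersect(names(classes), header)])
  need <- c("subject", "arm", "dose", "visit", "week", "duacr")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trial CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$duacr <- as.numeric(d$duacr)
  if (anyNA(d$duacr) || anyNA(d$dose) || anyNA(d$visit))
    stop("trial CSV contains non-numeric dose/visit/duacr values",
         call. = FALSE)
  out <- d[, need]
  structure(out,
            scenario_id = if ("scenario" %in% names(d)) d$scenario[1] else NA,
            rep = if ("rep" %in% names(d)) d$rep[1] else NA,
            class = c("trial_data", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
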