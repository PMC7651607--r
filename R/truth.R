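#' True dose-response effect model
#'
#' The simulated drug effect on log UACR follows an Emax curve in dose whose
#' asymptote is anchored so that the 100 mg dose produces exactly a 40%
#' reduction (a change of log(0.6) on the log scale) at full effect, for any
#' ED50.  The effect develops over time according to one of three
#' time-courses: immediate ("direct"), first-order onset with a 1.75-week
#' half-life ("exponential"), or a linear ramp reaching full effect at week 16
#' ("linear").
#'
#' @param ed50 Dose (mg) producing half the maximal effect; must be positive.
#' @param timecourse One of "direct", "exponential", "linear".
#' @param half_life_weeks Onset half-life (weeks) of the exponential
#'   time-course. Default 1.75.
#' @param ramp_end_weeks Week at which the linear ramp reaches full effect.
#'   Default 16 (the last scheduled visit).
#' @param target_reduction Multiplicative UACR ratio attained by the 100 mg
#'   dose at full effect. Default 0.6 (a 40% reduction).
#' @return An object of class \code{truth_params}.
#' @seealso [true_effect()], [emax_for_ed50()]
#' @examples
#' tp <- truth_params(32, "linear")
#' true_effect(tp, dose = 10, t = 16)
#' @export
truth_params <- function(ed50, timecourse = c("direct", "exponential", "linear"),
                         half_life_weeks = 1.75, ramp_end_weeks = 16,
                         target_reduction = 0.6) {
  timecourse <- match.arg(timecourse)
  stopifnot(is.numeric(ed50), length(ed50) == 1L, is.finite(ed50),
            half_life_weeks > 0, ramp_end_weeks > 0,
            target_reduction > 0, target_reduction < 1)
  if (ed50 <= 0) stop("'ed50' must be positive", call. = FALSE)
  structure(list(ed50 = ed50, timecourse = timecourse,
                 half_life_weeks = half_life_weeks,
                 ramp_end_weeks = ramp_end_weeks,
                 target_reduction = target_reduction),
            class = "truth_params")
}

#' Maximal effect implied by an ED50
#'
#' The Emax parameter is back-calculated from the design anchor: the top dose
#' (100 mg) must achieve \code{log(0.6)} at full effect, so
#' \code{Emax = log(0.6) * (100 + ED50) / 100}.
#'
#' @param ed50 Positive dose in mg.
#' @param target_reduction UACR ratio at the anchor; default 0.6.
#' @param anchor_dose Dose (mg) at which the target reduction is anchored;
#'   default 100.
#' @return Emax on the log change-from-baseline scale (negative: a reduction).
#' @export
emax_for_ed50 <- function(ed50, target_reduction = 0.6, anchor_dose = 100) {
  if (!is.numeric(ed50) || any(!is.finite(ed50)) || any(ed50 <= 0))
    stop("'ed50' must be a positive finite number", call. = FALSE)
  log(target_reduction) * (anchor_dose + ed50) / anchor_dose
}

#' Fraction of the full drug effect present at time t
#'
#' @param timecourse One of "direct", "exponential", "linear".
#' @param t Time in weeks since start of treatment (nonnegative); vectorized.
#' @param half_life_weeks Exponential onset half-life; default 1.75 weeks.
#' @param ramp_end_weeks End of the linear ramp; default week 16 (capped at 1
#'   beyond it).
#' @return Multiplier in \[0, 1\].
#' @export
timecourse_multiplier <- function(timecourse, t, half_life_weeks = 1.75,
                                  ramp_end_weeks = 16) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be nonnegative and finite", call. = FALSE)
  switch(match.arg(timecourse, c("direct", "exponential", "linear")),
         direct = rep(1, length(t)),
         exponential = 1 - exp(-(log(2) / half_life_weeks) * t),
         linear = pmin(t / ramp_end_weeks, 1))
}

#' True log-scale drug effect at a dose and visit
#'
#' Combines the Emax dose-response with the effect time-course:
#' \code{effect(d, t) = Emax(ED50) * m(t) * d / (ED50 + d)}, with 0 for
#' placebo (dose 0).
#'
#' @param params A [truth_params()] object.
#' @param dose Dose in mg (nonnegative); vectorized.
#' @param t Weeks since start of treatment (nonnegative); vectorized
#'   (recycled against \code{dose}).
#' @return True change from baseline in log UACR attributable to drug.
#' @export
true_effect <- function(params, dose, t) {
  stopifnot(inherits(params, "truth_params"))
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("'dose' must be nonnegative and finite", call. = FALSE)
  emax <- emax_for_ed50(params$ed50, params$target_reduction)
  mult <- timecourse_multiplier(params$timecourse, t,
                                params$half_life_weeks, params$ramp_end_weeks)
  emax * mult * dose / (params$ed50 + dose)
}
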