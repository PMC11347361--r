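# Outcome proportion above which an outcome is treated as "common" and the
# OR/HR rare-outcome shortcuts no longer apply.
COMMON_OUTCOME_THRESHOLD <- 0.15

#' Convert an odds ratio to a risk ratio
#'
#' Applies the baseline-risk correction `RR = OR / (1 - p0 + p0 * OR)`, where
#' `p0` is the outcome risk in the unexposed (reference) group. As `p0 -> 0`
#' the odds ratio approaches the risk ratio (the rare-outcome limit); for a
#' common outcome the odds ratio overstates the risk ratio and the correction
#' shrinks it towards the null.
#'
#' @param or Odds ratio, a positive number (vectorised).
#' @param p0 Baseline (unexposed) outcome risk, strictly in (0, 1).
#' @return Risk ratio on the same side of the null as `or`.
#' @examples
#' or_to_rr(2.0, 0.5)   # 1.333...
#' or_to_rr(1.44, 0.08) # ~1.39
#' @export
or_to_rr <- function(or, p0) {
  if (!is.numeric(or) || any(!is.finite(or)) || any(or <= 0)) {
    stop("`or` must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(p0) || any(!is.finite(p0)) || any(p0 <= 0) || any(p0 >= 1)) {
    stop("`p0` must lie strictly in (0, 1)", call. = FALSE)
  }
  or / (1 - p0 + p0 * or)
}

#' Convert a hazard ratio to a risk ratio
#'
#' For a rare outcome the hazard ratio is used directly as a risk ratio. For a
#' common outcome (more than ~15% of participants experience the event by end
#' of follow-up) the standard approximation
#' `RR = (1 - 0.5^sqrt(HR)) / (1 - 0.5^sqrt(1/HR))` is applied, which maps the
#' null to the null and is symmetric under `HR -> 1/HR`.
#'
#' @param hr Hazard ratio, a positive number (vectorised).
#' @param rare_outcome Logical; if `TRUE` the hazard ratio is returned
#'   unchanged.
#' @return Risk ratio.
#' @examples
#' hr_to_rr(1.2, rare_outcome = TRUE)  # 1.2
#' hr_to_rr(1.2, rare_outcome = FALSE) # ~1.135
#' @export
hr_to_rr <- function(hr, rare_outcome = FALSE) {
  if (!is.numeric(hr) || any(!is.finite(hr)) || any(hr <= 0)) {
    stop("`hr` must be a positive finite number", call. = FALSE)
  }
  if (isTRUE(rare_outcome)) {
    return(hr)
  }
  ifelse(hr == 1, 1, (1 - 0.5^sqrt(hr)) / (1 - 0.5^sqrt(1 / hr)))
}

#' Convert a correlation coefficient to an odds ratio
#'
#' Uses the standardised-mean-difference chain: `d = 2r / sqrt(1 - r^2)`,
#' then `log OR = pi * d / sqrt(3)`. The sign of the log odds ratio matches
#' the sign of `r`, and `r_to_or(-r) = 1 / r_to_or(r)`.
#'
#' @param r Pearson correlation, strictly in (-1, 1) (vectorised).
#' @return Odds ratio.
#' @examples
#' r_to_or(0.28) # ~2.88
#' @export
r_to_or <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("`r` must lie strictly in (-1, 1)", call. = FALSE)
  }
  d <- 2 * r / sqrt(1 - r^2)
  exp(pi * d / sqrt(3))
}

#' Standard error of a log effect from its confidence interval
#'
#' Recovers the log-scale Wald standard error from a ratio-scale confidence
#' interval: `(log(upper) - log(lower)) / (2 * z)` with `z` the standard
#' normal quantile for the interval's coverage. The z quantile is computed at
#' full precision (1.959964... for 95%), not rounded to 1.96.
#'
#' @param ci_lower,ci_upper Positive confidence limits with
#'   `ci_lower < ci_upper`.
#' @param level Coverage of the interval, default 0.95.
#' @return Standard error of the log effect estimate.
#' @examples
#' se_from_ci(1.10, 1.19) # ~0.0201
#' @export
se_from_ci <- function(ci_lower, ci_upper, level = 0.95) {
  if (!is.numeric(ci_lower) || !is.numeric(ci_upper) ||
      any(ci_lower <= 0) || any(ci_upper <= ci_lower)) {
    stop("confidence limits must be positive with ci_lower < ci_upper",
         call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  (log(ci_upper) - log(ci_lower)) / (2 * z)
}

#' Construct an effect estimate on a relative scale
#'
#' Bundles a point estimate, its confidence interval, the effect measure
#' (risk ratio, odds ratio or hazard ratio) and, where relevant for
#' conversion, the baseline outcome prevalence or a rare-outcome flag.
#'
#' @param point Point estimate, positive.
#' @param ci_lower,ci_upper Confidence limits, `0 < ci_lower <= point <=
#'   ci_upper`.
#' @param measure One of `"RR"`, `"OR"`, `"HR"`.
#' @param outcome_prevalence Optional outcome proportion in (0, 1); used as
#'   the baseline risk `p0` for OR conversion and to classify the outcome as
#'   rare or common.
#' @param rare_outcome Optional logical; when `outcome_prevalence` is given
#'   it is derived from the 15% common-outcome threshold instead.
#' @param level Coverage of the interval, default 0.95.
#' @return An object of class `effect_estimate`.
#' @examples
#' effect_estimate(1.14, 1.10, 1.19, measure = "RR")
#' @export
effect_estimate <- function(point, ci_lower, ci_upper,
                            measure = c("RR", "OR", "HR"),
                            outcome_prevalence = NULL, rare_outcome = NULL,
                            level = 0.95) {
  measure <- match.arg(measure)
  if (!is.numeric(point) || length(point) != 1 || point <= 0) {
    stop("`point` must be a single positive number", call. = FALSE)
  }
  if (ci_lower <= 0 || ci_lower > point || point > ci_upper) {
    stop("need 0 < ci_lower <= point <= ci_upper", call. = FALSE)
  }
  if (!is.null(outcome_prevalence)) {
    if (outcome_prevalence <= 0 || outcome_prevalence >= 1) {
      stop("`outcome_prevalence` must lie strictly in (0, 1)", call. = FALSE)
    }
    rare_outcome <- outcome_prevalence <= COMMON_OUTCOME_THRESHOLD
  }
  structure(
    list(measure = measure, point = point,
         ci_lower = ci_lower, ci_upper = ci_upper,
         outcome_prevalence = outcome_prevalence,
         rare_outcome = rare_outcome, level = level),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s %.2f (%d%% CI %.2f, %.2f)\n", x$measure,
              round(x$point, digits), round(100 * x$level),
              round(x$ci_lower, digits), round(x$ci_upper, digits)))
  if (!is.null(x$outcome_prevalence)) {
    cat(sprintf("  outcome prevalence %.3f (%s outcome)\n",
                x$outcome_prevalence,
                if (isTRUE(x$rare_outcome)) "rare" else "common"))
  }
  invisible(x)
}

#' Convert an effect estimate to the risk-ratio scale
#'
#' Applies the measure-appropriate conversion to the point estimate and both
#' confidence limits. Risk-ratio inputs are returned unchanged. Odds ratios
#' with a rare outcome pass through (the rare-outcome limit of the
#' baseline-risk correction); otherwise the outcome prevalence is required as
#' `p0`. Hazard ratios pass through for rare outcomes and use the
#' common-outcome approximation otherwise.
#'
#' @param estimate An [effect_estimate()].
#' @return An `effect_estimate` with `measure = "RR"`.
#' @export
to_rr_scale <- function(estimate) {
  if (!inherits(estimate, "effect_estimate")) {
    stop("`estimate` must be an effect_estimate", call. = FALSE)
  }
  if (estimate$measure == "RR") {
    return(estimate)
  }
  rare <- estimate$rare_outcome
  p0 <- estimate$outcome_prevalence
  if (is.null(rare) && is.null(p0)) {
    stop(sprintf(
      "%s estimate needs `outcome_prevalence` (baseline risk p0) or an explicit `rare_outcome` flag for conversion to the risk-ratio scale",
      estimate$measure), call. = FALSE)
  }
  conv <- if (estimate$measure == "HR") {
    function(x) hr_to_rr(x, rare_outcome = isTRUE(rare))
  } else if (isTRUE(rare)) {
    identity # OR ~ RR when the outcome is rare
  } else {
    if (is.null(p0)) {
      stop("common-outcome OR conversion needs `outcome_prevalence` (p0)",
           call. = FALSE)
    }
    function(x) or_to_rr(x, p0)
  }
  effect_estimate(conv(estimate$point), conv(estimate$ci_lower),
                  conv(estimate$ci_upper), measure = "RR",
                  outcome_prevalence = p0, rare_outcome = rare,
                  level = estimate$level)
}
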