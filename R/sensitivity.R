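#' E-value of a risk ratio
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both the exposure and
#' the outcome to fully explain away an observed association:
#' `E = RR + sqrt(RR * (RR - 1))` for `RR >= 1`. Protective estimates
#' (`RR < 1`) are oriented by taking the reciprocal before applying the
#' formula, so the result is always on the `>= 1` side.
#'
#' @param rr Observed risk ratio, positive (vectorised).
#' @return E-value, `>= 1`; equal to 1 exactly when `rr = 1`.
#' @examples
#' evalue_point(1.41) # 2.17 to 2 dp
#' evalue_point(0.80) # same as evalue_point(1.25)
#' @export
evalue_point <- function(rr) {
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0)) {
    stop("`rr` must be a positive finite number", call. = FALSE)
  }
  rr <- ifelse(rr < 1, 1 / rr, rr)
  rr + sqrt(rr * (rr - 1))
}

#' Risk ratio whose E-value equals a given value
#'
#' Inverts the E-value formula in closed form: `RR = E^2 / (2E - 1)`.
#' Round-trips with [evalue_point()] on the `>= 1` side.
#'
#' @param e E-value, `>= 1` (vectorised).
#' @return The risk ratio `>= 1` with that E-value.
#' @examples
#' invert_evalue(2.00) # 4/3
#' @export
invert_evalue <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 1)) {
    stop("`e` must be >= 1", call. = FALSE)
  }
  e^2 / (2 * e - 1)
}

#' E-value of the confidence limit closer to the null
#'
#' For a harmful estimate (`rr_point >= 1`) the lower confidence limit is
#' used; for a protective estimate the upper limit (reciprocated). When the
#' interval contains the null no confounding at all is needed to explain a
#' non-significant result, so the E-value is exactly 1.
#'
#' @param rr_point Point estimate on the risk-ratio scale.
#' @param ci_lower,ci_upper Confidence limits with
#'   `ci_lower <= rr_point <= ci_upper`.
#' @return E-value of the limit closer to the null, `>= 1`.
#' @examples
#' evalue_ci(1.14, 1.10, 1.19) # 1.43 to 2 dp
#' evalue_ci(1.14, 0.95, 1.30) # 1: interval spans the null
#' @export
evalue_ci <- function(rr_point, ci_lower, ci_upper) {
  if (ci_lower > rr_point || rr_point > ci_upper) {
    stop("need ci_lower <= rr_point <= ci_upper", call. = FALSE)
  }
  if (ci_lower <= 1 && ci_upper >= 1) {
    return(1)
  }
  if (rr_point >= 1) evalue_point(ci_lower) else evalue_point(ci_upper)
}

#' Joint bounding factor of an unmeasured confounder
#'
#' The maximum multiplicative bias in an observed risk ratio that a
#' confounder with confounder-outcome association `rr_ud` and
#' confounder-exposure association `rr_eu` (both on the risk-ratio scale,
#' oriented `>= 1`) can produce:
#' `B = (rr_ud * rr_eu) / (rr_ud + rr_eu - 1)`. `B` is symmetric in its
#' arguments and never exceeds the smaller of the two.
#'
#' @param rr_ud Confounder-outcome risk ratio, `>= 1` (vectorised).
#' @param rr_eu Confounder-exposure risk ratio, `>= 1` (vectorised).
#' @return Bounding factor `B >= 1`.
#' @examples
#' bounding_factor(1.48, 1.39) # 1.10 to 2 dp
#' @export
bounding_factor <- function(rr_ud, rr_eu) {
  if (any(!is.finite(rr_ud)) || any(rr_ud < 1) ||
      any(!is.finite(rr_eu)) || any(rr_eu < 1)) {
    stop("`rr_ud` and `rr_eu` must be >= 1 (orient scenarios first)",
         call. = FALSE)
  }
  (rr_ud * rr_eu) / (rr_ud + rr_eu - 1)
}

#' Proportion of an observed effect explainable by a bounding factor
#'
#' Computed on the excess-relative-risk scale:
#' `100 * (B - 1) / (RR - 1)`, capped at 100. A bounding factor as large as
#' the observed risk ratio can explain the entire excess risk ("total"
#' confounding); a smaller one explains only part of it.
#'
#' @param rr_obs Observed risk ratio, `> 1` for a non-trivial answer.
#' @param b Bounding factor, `>= 1`.
#' @return Percentage in `[0, 100]`. If `rr_obs <= 1` there is no excess
#'   risk to explain and 0 is returned with a warning.
#' @examples
#' proportion_explained(1.14, bounding_factor(1.48, 1.39)) # ~71.5
#' proportion_explained(1.10, bounding_factor(1.48, 1.39)) # 100 (capped)
#' @export
proportion_explained <- function(rr_obs, b) {
  if (any(!is.finite(b)) || any(b < 1)) {
    stop("`b` must be >= 1", call. = FALSE)
  }
  if (rr_obs <= 1) {
    warning("observed RR <= 1: nothing on the harmful side to explain",
            call. = FALSE)
    return(0)
  }
  pmin(100, 100 * (b - 1) / (rr_obs - 1))
}

#' Complementary confounder association needed for total confounding
#'
#' Given one known confounder association `rr_known`, solves
#' `B(rr_known, x) = rr_obs_target` for the other association in closed
#' form: `x = rr_obs_target * (rr_known - 1) / (rr_known - rr_obs_target)`.
#' Because the bounding factor never exceeds the smaller of its two
#' arguments, no finite complement exists when
#' `rr_known <= rr_obs_target`; `NA` is returned (unattainable).
#'
#' @param rr_known Known association (either side), `>= 1`.
#' @param rr_obs_target Observed risk ratio the bound must reach, `> 1`.
#' @return The complementary risk ratio, or `NA_real_` when the target bound
#'   is unattainable.
#' @examples
#' required_complementary_rr(3.00, 4/3) # 1.60 exactly
#' required_complementary_rr(1.10, 1.14) # NA: unattainable
#' @export
required_complementary_rr <- function(rr_known, rr_obs_target) {
  if (!is.finite(rr_obs_target) || rr_obs_target <= 1) {
    stop("`rr_obs_target` must be > 1", call. = FALSE)
  }
  if (!is.finite(rr_known) || rr_known < 1) {
    stop("`rr_known` must be >= 1", call. = FALSE)
  }
  if (rr_known <= rr_obs_target) {
    return(NA_real_)
  }
  rr_obs_target * (rr_known - 1) / (rr_known - rr_obs_target)
}

#' Define a confounder scenario
#'
#' A named hypothetical confounder with its exposure-side and outcome-side
#' associations on the risk-ratio scale, both oriented to the `>= 1` side.
#'
#' @param name Scenario label.
#' @param rr_eu Confounder-exposure risk ratio, `>= 1`.
#' @param rr_ud Confounder-outcome risk ratio, `>= 1`.
#' @param provenance Optional free text recording where the association
#'   strengths come from.
#' @return An object of class `confounder_scenario`.
#' @export
confounder_scenario <- function(name, rr_eu, rr_ud, provenance = "") {
  if (!is.finite(rr_eu) || rr_eu < 1 || !is.finite(rr_ud) || rr_ud < 1) {
    stop("scenario associations must be >= 1 (orient before constructing)",
         call. = FALSE)
  }
  structure(list(name = as.character(name), rr_eu = rr_eu, rr_ud = rr_ud,
                 provenance = provenance),
            class = "confounder_scenario")
}

#' @export
print.confounder_scenario <- function(x, ...) {
  cat(sprintf("Confounder scenario '%s': RR_EU = %.2f, RR_UD = %.2f\n",
              x$name, x$rr_eu, x$rr_ud))
  invisible(x)
}

# Extract (point RR, closer-to-null CI limit) from a rema fit, an
# effect_estimate, or a numeric c(point, lower, upper).
observed_rr <- function(x) {
  if (inherits(x, "rema")) {
    list(point = x$rr, lower = x$ci_lower, upper = x$ci_upper)
  } else if (inherits(x, "effect_estimate")) {
    if (x$measure != "RR") x <- to_rr_scale(x)
    list(point = x$point, lower = x$ci_lower, upper = x$ci_upper)
  } else if (is.numeric(x) && length(x) == 3) {
    list(point = x[1], lower = x[2], upper = x[3])
  } else {
    stop("expected a rema fit, an effect_estimate, or c(point, lower, upper)",
         call. = FALSE)
  }
}

#' Bounding analysis of a confounder scenario against an observed estimate
#'
#' Computes the scenario's joint bounding factor and the proportion of the
#' observed excess risk it could explain, both against the point estimate and
#' against the confidence limit closer to the null, together with
#' total-confounding flags (`B >=` the corresponding observed risk ratio) and
#' the complementary exposure-side association that would be needed for
#' total confounding given the scenario's outcome-side association.
#'
#' @param scenario A [confounder_scenario()].
#' @param observed The observed association: a [rema()] fit, an
#'   [effect_estimate()], or a numeric vector `c(point, lower, upper)` on the
#'   risk-ratio scale.
#' @return An object of class `bounding_result`.
#' @examples
#' sc <- confounder_scenario("depression", rr_eu = 1.39, rr_ud = 1.48)
#' analyse_scenario(sc, c(1.14, 1.10, 1.19))
#' @export
analyse_scenario <- function(scenario, observed) {
  if (!inherits(scenario, "confounder_scenario")) {
    stop("`scenario` must be a confounder_scenario", call. = FALSE)
  }
  obs <- observed_rr(observed)
  b <- bounding_factor(scenario$rr_ud, scenario$rr_eu)
  # limit closer to the null, on the harmful side
  limit <- if (obs$point >= 1) obs$lower else 1 / obs$upper
  point <- if (obs$point >= 1) obs$point else 1 / obs$point

  if (point <= 1) {
    warning("observed point estimate is null: proportions set to 0",
            call. = FALSE)
    prop_point <- 0
    prop_limit <- 0
  } else {
    prop_point <- proportion_explained(point, b)
    prop_limit <- if (limit > 1) proportion_explained(limit, b) else 100
  }

  structure(
    list(name = scenario$name, rr_eu = scenario$rr_eu,
         rr_ud = scenario$rr_ud, b = b,
         rr_point = point, rr_lower_ci = limit,
         proportion_explained_point = prop_point,
         proportion_explained_lower_ci = prop_limit,
         fully_explains_point = b >= point,
         fully_explains_lower_ci = b >= limit,
         required_rr_eu = if (point > 1) {
           required_complementary_rr(scenario$rr_ud, point)
         } else NA_real_),
    class = "bounding_result"
  )
}

#' @export
print.bounding_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (RR_EU = %.2f, RR_UD = %.2f)\n",
              x$name, x$rr_eu, x$rr_ud))
  cat(sprintf("  joint bounding factor B = %.2f\n", round(x$b, 2)))
  cat(sprintf("  explains %.0f%% of the point estimate (RR %.2f)%s\n",
              round(x$proportion_explained_point),
              x$rr_point,
              if (x$fully_explains_point) " [total confounding]" else ""))
  cat(sprintf("  explains %.0f%% of the closer CI limit (RR %.2f)%s\n",
              round(x$proportion_explained_lower_ci),
              x$rr_lower_ci,
              if (x$fully_explains_lower_ci) " [total confounding]" else ""))
  if (!is.na(x$required_rr_eu)) {
    cat(sprintf(
      "  RR_EU needed for total confounding at RR_UD = %.2f: %.2f\n",
      x$rr_ud, round(x$required_rr_eu, 2)))
  } else if (x$rr_point > 1) {
    cat(sprintf(
      "  RR_EU needed for total confounding at RR_UD = %.2f: unattainable\n",
      x$rr_ud))
  }
  invisible(x)
}

#' Contour of constant joint bounding factor
#'
#' Emits coordinate pairs `(rr_ud, rr_eu)` on the curve
#' `B(rr_ud, rr_eu) = target_b`: every combination of confounder strengths on
#' the curve produces the same maximum bias. `rr_ud` is log-spaced on
#' `(target_b, rr_ud_max]` — dense near the asymptote at `rr_ud = target_b`,
#' where the required `rr_eu` diverges — and `rr_eu` is obtained from
#' [required_complementary_rr()]. The curve passes through the symmetric
#' point `rr_ud = rr_eu = E`, where `E` is the E-value of the risk ratio
#' whose total-confounding bound is `target_b`.
#'
#' @param target_b The bounding-factor level of the contour, `> 1`.
#' @param n_points Number of coordinate pairs, default 200.
#' @param rr_ud_max Largest `rr_ud` sampled, default `10 * target_b`.
#' @return An object of class `bounding_curve`: a data frame with columns
#'   `rr_ud`, `rr_eu` and attribute `target_b`.
#' @examples
#' crv <- bounding_curve(4/3)
#' head(crv)
#' @export
bounding_curve <- function(target_b, n_points = 200,
                           rr_ud_max = 10 * target_b) {
  if (!is.finite(target_b) || target_b <= 1) {
    stop("`target_b` must be > 1", call. = FALSE)
  }
  if (rr_ud_max <= target_b) {
    stop("`rr_ud_max` must exceed `target_b`", call. = FALSE)
  }
  if (n_points < 2) stop("`n_points` must be at least 2", call. = FALSE)
  # open at target_b (asymptote), closed at rr_ud_max
  lg <- seq(log(target_b), log(rr_ud_max), length.out = n_points + 1)[-1]
  rr_ud <- exp(lg)
  rr_eu <- vapply(rr_ud, required_complementary_rr, numeric(1),
                  rr_obs_target = target_b)
  structure(data.frame(rr_ud = rr_ud, rr_eu = rr_eu),
            target_b = target_b,
            class = c("bounding_curve", "data.frame"))
}
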