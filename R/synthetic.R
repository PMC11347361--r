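# Run expr with a locally seeded RNG, restoring any pre-existing global
# RNG state afterwards so the generators have no side effects.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Simulate study-level meta-analysis inputs
#'
#' Draws from the normal-normal random-effects generative model assumed by
#' [rema()]: per-study standard errors uniform on `se_range`, study-specific
#' true effects `N(theta, tau2)`, and observed log risk ratios normal around
#' the study effect with the study's standard error. Identical seeds give
#' bit-identical output.
#'
#' @param k Number of studies, `>= 1`.
#' @param theta True pooled log risk ratio.
#' @param tau2 True between-study variance, `>= 0`.
#' @param se_range Length-2 positive increasing interval the per-study
#'   standard errors are drawn from.
#' @param seed Integer seed (required; the generators keep no global state).
#' @return A data frame with columns `log_rr` and `se`.
#' @examples
#' sim <- simulate_meta_sample(k = 5, theta = log(1.14), tau2 = 0.01,
#'                             seed = 42)
#' rema(sim$log_rr, sim$se)
#' @export
simulate_meta_sample <- function(k, theta, tau2, se_range = c(0.05, 0.3),
                                 seed) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (!is.finite(tau2) || tau2 < 0) stop("`tau2` must be >= 0", call. = FALSE)
  if (length(se_range) != 2 || any(se_range <= 0) ||
      se_range[1] > se_range[2]) {
    stop("`se_range` must be positive and ordered", call. = FALSE)
  }
  with_local_seed(seed, {
    se <- stats::runif(k, se_range[1], se_range[2])
    mu <- stats::rnorm(k, theta, sqrt(tau2))
    data.frame(log_rr = stats::rnorm(k, mu, se), se = se)
  })
}

#' Simulate a cohort with a binary unmeasured confounder
#'
#' Generates `n` participants under a log-linear (risk-ratio) model, so the
#' generative parameters are exactly the risk ratios the bounding factor
#' consumes: confounder `U ~ Bernoulli(p_u)`; exposure
#' `Bernoulli(p_exposure_base * rr_eu^U)`; outcome
#' `Bernoulli(p_outcome_base * rr_ud^U * true_rr^exposure)`. With
#' `true_rr = 1` and `rr_eu, rr_ud > 1`, the crude (U-collapsed) risk ratio
#' is biased upward, but never beyond `bounding_factor(rr_ud, rr_eu)`.
#'
#' @param n Cohort size.
#' @param p_u Prevalence of the confounder, in (0, 1). Default 0.2.
#' @param rr_eu Exposure risk ratio for the confounder, `>= 1`.
#' @param rr_ud Outcome risk ratio for the confounder, `>= 1`.
#' @param true_rr Causal exposure-outcome risk ratio.
#' @param p_exposure_base Exposure probability at `U = 0`. Default 0.2.
#' @param p_outcome_base Outcome probability at `U = 0`, unexposed.
#'   Default 0.1.
#' @param seed Integer seed.
#' @return An object of class `synthetic_cohort`: a 2x2x2 count array
#'   indexed (u, exposed, outcome) plus the generating configuration.
#' @examples
#' coh <- simulate_confounded_cohort(10000, rr_eu = 1.39, rr_ud = 1.48,
#'                                   true_rr = 1, seed = 7)
#' crude_rr(coh)
#' @export
simulate_confounded_cohort <- function(n, p_u = 0.2, rr_eu = 1, rr_ud = 1,
                                       true_rr = 1, p_exposure_base = 0.2,
                                       p_outcome_base = 0.1, seed) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (p_u <= 0 || p_u >= 1) stop("`p_u` must be in (0, 1)", call. = FALSE)
  if (rr_eu < 1 || rr_ud < 1) {
    stop("`rr_eu` and `rr_ud` must be >= 1", call. = FALSE)
  }
  if (true_rr <= 0) stop("`true_rr` must be positive", call. = FALSE)
  p_exp_max <- p_exposure_base * rr_eu
  if (p_exp_max >= 1) {
    stop(sprintf("exposure probability overflow: p_exposure_base * rr_eu = %g >= 1",
                 p_exp_max), call. = FALSE)
  }
  p_out_max <- p_outcome_base * rr_ud * max(true_rr, 1)
  if (p_out_max >= 1) {
    stop(sprintf("outcome probability overflow: p_outcome_base * rr_ud * true_rr = %g >= 1",
                 p_out_max), call. = FALSE)
  }
  counts <- with_local_seed(seed, {
    u <- stats::rbinom(n, 1, p_u)
    e <- stats::rbinom(n, 1, p_exposure_base * rr_eu^u)
    y <- stats::rbinom(n, 1, p_outcome_base * rr_ud^u * true_rr^e)
    array(tabulate(1 + y * 4 + e * 2 + u, nbins = 8), dim = c(2, 2, 2),
          dimnames = list(u = c("0", "1"), exposed = c("0", "1"),
                          outcome = c("0", "1")))
  })
  structure(
    list(counts = counts,
         config = list(n = n, p_u = p_u, rr_eu = rr_eu, rr_ud = rr_ud,
                       true_rr = true_rr, p_exposure_base = p_exposure_base,
                       p_outcome_base = p_outcome_base, seed = seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic confounded cohort, n = %d (rr_eu = %g, rr_ud = %g, true_rr = %g)\n",
    cfg$n, cfg$rr_eu, cfg$rr_ud, cfg$true_rr))
  print(x$counts)
  invisible(x)
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) {
  grid <- expand.grid(u = 0:1, exposed = 0:1, outcome = 0:1)
  grid$count <- as.vector(x$counts)
  grid
}

# Collapse a cohort (or accept c(a, b, c, d) = exposed-case, exposed-noncase,
# unexposed-case, unexposed-noncase) into a 2x2 count vector.
collapse_counts <- function(x) {
  if (inherits(x, "synthetic_cohort")) {
    tab <- apply(x$counts, c("exposed", "outcome"), sum)
    c(a = tab["1", "1"], b = tab["1", "0"],
      c = tab["0", "1"], d = tab["0", "0"])
  } else if (is.numeric(x) && length(x) == 4) {
    stats::setNames(x, c("a", "b", "c", "d"))
  } else {
    stop("expected a synthetic_cohort or counts c(a, b, c, d)", call. = FALSE)
  }
}

#' Crude risk ratio of a 2x2 table
#'
#' The risk ratio of the exposure-outcome table collapsed over the
#' confounder: `RR = [a/(a+b)] / [c/(c+d)]` with cells a = exposed cases,
#' b = exposed non-cases, c = unexposed cases, d = unexposed non-cases. The
#' Wald confidence interval uses
#' `se(log RR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. A zero case cell
#' triggers a 0.5 continuity correction of all four cells, with a warning and
#' a `continuity_corrected` attribute — never silently.
#'
#' @param x A `synthetic_cohort` or a numeric count vector `c(a, b, c, d)`.
#' @param level Confidence level, default 0.95.
#' @return An [effect_estimate()] with `measure = "RR"` and attributes
#'   `se_log_rr` and `continuity_corrected`.
#' @examples
#' crude_rr(c(10, 90, 5, 95)) # RR = 2
#' @export
crude_rr <- function(x, level = 0.95) {
  n <- collapse_counts(x)
  if (n["a"] + n["b"] == 0 || n["c"] + n["d"] == 0) {
    stop("an exposure margin is empty; no risk ratio is defined",
         call. = FALSE)
  }
  corrected <- FALSE
  if (n["a"] == 0 || n["c"] == 0) {
    warning("zero case cell: applying 0.5 continuity correction",
            call. = FALSE)
    n <- n + 0.5
    corrected <- TRUE
  }
  rr <- (n["a"] / (n["a"] + n["b"])) / (n["c"] / (n["c"] + n["d"]))
  se <- sqrt(1 / n["a"] - 1 / (n["a"] + n["b"]) +
               1 / n["c"] - 1 / (n["c"] + n["d"]))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- effect_estimate(unname(rr), unname(exp(log(rr) - z * se)),
                         unname(exp(log(rr) + z * se)), measure = "RR",
                         level = level)
  attr(est, "se_log_rr") <- unname(se)
  attr(est, "continuity_corrected") <- corrected
  est
}

#' Risk ratio within each confounder stratum
#'
#' The crude risk ratio computed separately at `U = 0` and `U = 1`. Under the
#' generative model of [simulate_confounded_cohort()] both stratum-specific
#' risk ratios converge to `true_rr` as the cohort grows, so they serve as an
#' oracle for the causal effect the collapsed table distorts.
#'
#' @param cohort A `synthetic_cohort`.
#' @param level Confidence level, default 0.95.
#' @return A list with elements `u0` and `u1`, each an [effect_estimate()]
#'   or `NULL` (with a warning) for a degenerate stratum.
#' @export
stratified_rr <- function(cohort, level = 0.95) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must be a synthetic_cohort", call. = FALSE)
  }
  one <- function(u) {
    tab <- cohort$counts[u, , ]
    counts <- c(tab["1", "1"], tab["1", "0"], tab["0", "1"], tab["0", "0"])
    if (counts[1] + counts[2] == 0 || counts[3] + counts[4] == 0) {
      warning("degenerate stratum U = ", u, " omitted", call. = FALSE)
      return(NULL)
    }
    crude_rr(counts, level = level)
  }
  list(u0 = one("0"), u1 = one("1"))
}
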