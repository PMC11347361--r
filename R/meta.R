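# Restricted log-likelihood of the normal-normal random-effects model,
# profiled over the pooled mean. Constant terms dropped.
reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  theta <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - theta)^2))
}

#' Random-effects meta-analysis by restricted maximum likelihood
#'
#' Fits the normal-normal random-effects model to study-level log risk
#' ratios: each observed `yi` is `N(mu_i, sei^2)` with study-specific true
#' effects `mu_i ~ N(theta, tau2)`. The between-study variance `tau2` is
#' estimated by maximising the restricted log-likelihood over `[0, Inf)` with
#' bounded derivative-free scalar optimisation (search interval
#' `[0, 10 * max(sei^2)]`, convergence tolerance 1e-10), which is robust at
#' the `tau2 = 0` boundary. The pooled effect is the inverse-variance
#' weighted mean with weights `1/(sei^2 + tau2)`, with a Wald confidence
#' interval on the log scale. Cochran's Q (from fixed-effect weights) and
#' `I^2 = max(0, (Q - (k-1))/Q)` are reported as heterogeneity diagnostics.
#'
#' @param yi Numeric vector of study log risk ratios.
#' @param sei Positive numeric vector of their standard errors.
#' @param level Confidence level for the pooled interval, default 0.95.
#' @param data Optional data frame (or the output of
#'   [simulate_meta_sample()]) in which `yi` and `sei` are looked up.
#' @param tau2 Optional non-negative value at which to fix the between-study
#'   variance instead of estimating it (e.g. `tau2 = 0` for a common-effect
#'   fit). Default `NULL`: estimate by REML.
#' @return An object of class `rema`: a list with the study data, `k`,
#'   `tau2`, the pooled log risk ratio `theta` with `se`, risk-ratio-scale
#'   confidence limits, `q_stat`, `i2` and the confidence `level`.
#' @examples
#' fit <- rema(c(0.10, 0.15, 0.12), c(0.05, 0.08, 0.06))
#' summary(fit)
#' coef(fit)
#' @seealso [pool_by_quantile()] for pooling a study table per exposure
#'   quantile.
#' @export
rema <- function(yi, sei, level = 0.95, data = NULL, tau2 = NULL) {
  if (!is.null(data)) {
    yi <- eval(substitute(yi), data, parent.frame())
    sei <- eval(substitute(sei), data, parent.frame())
  }
  if (length(yi) == 0) stop("no studies to pool", call. = FALSE)
  if (length(yi) != length(sei)) {
    stop("`yi` and `sei` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(yi)) || any(!is.finite(sei)) || any(sei <= 0)) {
    stop("`yi` must be finite and `sei` strictly positive", call. = FALSE)
  }
  k <- length(yi)
  vi <- sei^2

  if (!is.null(tau2)) {
    if (!is.finite(tau2) || tau2 < 0) {
      stop("fixed `tau2` must be >= 0", call. = FALSE)
    }
  } else if (k == 1) {
    warning("only one study: returning it unchanged with tau2 = 0",
            call. = FALSE)
    tau2 <- 0
  } else {
    upper <- 10 * max(vi)
    opt <- stats::optimize(reml_loglik, interval = c(0, upper),
                           yi = yi, vi = vi, maximum = TRUE, tol = 1e-10)
    # optimize never returns an exact endpoint; take the boundary when it wins
    tau2 <- if (reml_loglik(0, yi, vi) >= opt$objective) 0 else opt$maximum
  }

  w <- 1 / (vi + tau2)
  theta <- sum(w * yi) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)

  w_fe <- 1 / vi
  theta_fe <- sum(w_fe * yi) / sum(w_fe)
  q_stat <- sum(w_fe * (yi - theta_fe)^2)
  i2 <- if (q_stat > 0) max(0, (q_stat - (k - 1)) / q_stat) else 0

  structure(
    list(yi = yi, sei = sei, k = k, tau2 = tau2,
         theta = theta, se = se,
         rr = exp(theta), ci_lower = exp(theta - z * se),
         ci_upper = exp(theta + z * se),
         q_stat = q_stat, i2 = i2, level = level),
    class = "rema"
  )
}

#' @export
print.rema <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects meta-analysis (REML), k = %d\n", x$k))
  cat(sprintf("Pooled RR %s (%d%% CI %s, %s)   tau2 = %s\n",
              format(round(x$rr, digits)), round(100 * x$level),
              format(round(x$ci_lower, digits)),
              format(round(x$ci_upper, digits)),
              format(round(x$tau2, 4))))
  invisible(x)
}

#' @export
summary.rema <- function(object, ...) {
  structure(list(fit = object), class = "summary.rema")
}

#' @export
print.summary.rema <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("log RR %s (se %s)\n",
              format(round(f$theta, 4)), format(round(f$se, 4))))
  cat(sprintf("Heterogeneity: Q = %s on %d df, I2 = %s%%\n",
              format(round(f$q_stat, 2)), f$k - 1,
              format(round(100 * f$i2, 1))))
  invisible(x)
}

#' @export
coef.rema <- function(object, ...) {
  c(log_rr = object$theta)
}

#' @export
vcov.rema <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("log_rr", "log_rr"))
}

#' @export
confint.rema <- function(object, parm, level = NULL, ...) {
  level <- if (is.null(level)) object$level else level
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(object$theta + c(-1, 1) * z * object$se, 1, 2)
  dimnames(out) <- list("log_rr",
                        sprintf("%g %%", 100 * c((1 - level) / 2,
                                                 1 - (1 - level) / 2)))
  out
}

#' Pooled estimate and prediction interval on the risk-ratio scale
#'
#' The prediction interval widens the pooled Wald interval by the
#' between-study variance, `exp(theta +/- z * sqrt(se^2 + tau2))`, and
#' describes where a new study's true risk ratio is expected to fall.
#'
#' @param object A fitted [rema()] object.
#' @param ... Unused.
#' @return A one-row data frame with pooled RR, confidence limits and
#'   prediction limits.
#' @export
predict.rema <- function(object, ...) {
  z <- stats::qnorm(1 - (1 - object$level) / 2)
  s <- sqrt(object$se^2 + object$tau2)
  data.frame(rr = object$rr,
             ci_lower = object$ci_lower, ci_upper = object$ci_upper,
             pi_lower = exp(object$theta - z * s),
             pi_upper = exp(object$theta + z * s))
}

#' Read and validate a study-estimate table
#'
#' Expected CSV columns: `study_id`, `quantile`, `measure` (one of
#' `rr`/`or`/`hr`, case-insensitive), `point`, `ci_lower`, `ci_upper`, and
#' optionally `outcome_prevalence`, `rare_outcome` (logical) and a free-text
#' `tag` used for subset analyses. Validation failures report the offending
#' rows.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("study table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "quantile", "measure", "point",
                "ci_lower", "ci_upper")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("study table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) stop("study table has no rows", call. = FALSE)
  tab$measure <- toupper(tab$measure)
  problems <- character(0)
  bad_measure <- which(!tab$measure %in% c("RR", "OR", "HR"))
  if (length(bad_measure)) {
    problems <- c(problems, sprintf("row %d: unknown measure '%s'",
                                    bad_measure, tab$measure[bad_measure]))
  }
  bad_point <- which(!is.finite(tab$point) | tab$point <= 0 |
                       !is.finite(tab$ci_lower) | tab$ci_lower <= 0 |
                       !is.finite(tab$ci_upper) |
                       tab$ci_lower > tab$point | tab$point > tab$ci_upper)
  if (length(bad_point)) {
    problems <- c(problems,
                  sprintf("row %d: need 0 < ci_lower <= point <= ci_upper",
                          bad_point))
  }
  if ("outcome_prevalence" %in% names(tab)) {
    bad_p0 <- which(!is.na(tab$outcome_prevalence) &
                      (tab$outcome_prevalence <= 0 |
                         tab$outcome_prevalence >= 1))
    if (length(bad_p0)) {
      problems <- c(problems,
                    sprintf("row %d: outcome_prevalence outside (0, 1)",
                            bad_p0))
    }
  }
  if (length(problems)) {
    stop("invalid study table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  tab
}

# One study-table row -> effect_estimate
row_to_estimate <- function(row, level = 0.95) {
  p0 <- NULL
  if (!is.null(row$outcome_prevalence) && !is.na(row$outcome_prevalence)) {
    p0 <- row$outcome_prevalence
  }
  rare <- NULL
  if (!is.null(row$rare_outcome) && !is.na(row$rare_outcome)) {
    rare <- as.logical(row$rare_outcome)
  }
  effect_estimate(row$point, row$ci_lower, row$ci_upper,
                  measure = row$measure, outcome_prevalence = p0,
                  rare_outcome = rare, level = level)
}

#' Pool a study table per exposure quantile
#'
#' Converts every study estimate to the risk-ratio scale (via
#' [to_rr_scale()]), extracts the log risk ratio and its standard error from
#' the confidence interval, and fits one random-effects meta-analysis per
#' non-reference quantile. Hazard- and odds-ratio studies are converted
#' before pooling, not pooled on their native scale.
#'
#' @param table A study-estimate data frame as returned by
#'   [read_study_table()].
#' @param reference Label of the reference quantile, excluded from pooling
#'   (default `"Q1"`).
#' @param level Confidence level, default 0.95.
#' @return A named list of [rema()] fits, one per non-reference quantile
#'   (alphabetical order). Quantiles with no studies are omitted.
#' @export
pool_by_quantile <- function(table, reference = "Q1", level = 0.95) {
  if (!reference %in% table$quantile) {
    warning("reference quantile '", reference,
            "' does not appear in the table", call. = FALSE)
  }
  dup <- duplicated(table[c("study_id", "quantile")])
  if (any(dup)) {
    stop("each study may contribute at most one estimate per quantile; ",
         "duplicated: ",
         paste(unique(sprintf("%s/%s", table$study_id[dup],
                              table$quantile[dup])), collapse = ", "),
         call. = FALSE)
  }
  quantiles <- setdiff(sort(unique(table$quantile)), reference)
  fits <- list()
  for (q in quantiles) {
    rows <- table[table$quantile == q, , drop = FALSE]
    if (nrow(rows) == 0) {
      warning("quantile '", q, "' has no studies; omitted", call. = FALSE)
      next
    }
    est <- lapply(seq_len(nrow(rows)), function(i) {
      to_rr_scale(row_to_estimate(as.list(rows[i, , drop = FALSE]),
                                  level = level))
    })
    yi <- vapply(est, function(e) log(e$point), numeric(1))
    sei <- vapply(est, function(e) se_from_ci(e$ci_lower, e$ci_upper, level),
                  numeric(1))
    fits[[q]] <- rema(yi, sei, level = level)
  }
  fits
}
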