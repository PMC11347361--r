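# Dense grid-search oracle for the restricted likelihood: evaluates the
# profiled restricted log-likelihood on a tau2 grid and returns the argmax.
# Independent of the optimiser used by rema(). After the coarse pass, one
# brute-force refinement pass around the argmax sharpens tau2 (and hence the
# pooled estimate) well past the coarse step.
reml_grid_oracle <- function(yi, sei, tau2_max = 1, step = 1e-5,
                             refine = TRUE) {
  vi <- sei^2
  k <- length(yi)
  scan <- function(grid) {
    m <- length(grid)
    V <- outer(grid, vi, "+")      # m x k
    W <- 1 / V
    rs <- rowSums(W)
    theta <- as.vector(W %*% yi) / rs
    resid2 <- (matrix(yi, m, k, byrow = TRUE) - theta)^2
    ll <- -0.5 * (rowSums(log(V)) + log(rs) + rowSums(W * resid2))
    i <- which.max(ll)
    list(tau2 = grid[i], theta = theta[i], loglik = ll[i], i = i,
         grid = grid)
  }
  coarse <- scan(seq(0, tau2_max, by = step))
  if (!refine) {
    return(coarse[c("tau2", "theta", "loglik")])
  }
  lo <- max(0, coarse$tau2 - step)
  hi <- min(tau2_max, coarse$tau2 + step)
  fine <- scan(seq(lo, hi, length.out = 20001))
  fine[c("tau2", "theta", "loglik")]
}

# Write a small synthetic study-estimate table: `k` studies, quantiles
# Q2..Q4 vs reference Q1, generated from the normal-normal model at the
# given per-quantile true log RRs. Mixes measures: one HR (rare) study and
# one OR study with known prevalence, so pooling exercises the conversions.
write_study_csv <- function(path, k = 5, theta_by_q = c(Q2 = log(1.04),
                                                        Q3 = log(1.09),
                                                        Q4 = log(1.14)),
                            tau2 = 0, seed = 101) {
  rows <- list()
  z <- qnorm(0.975)
  for (q in names(theta_by_q)) {
    sim <- simulate_meta_sample(k, theta_by_q[[q]], tau2,
                                se_range = c(0.03, 0.10),
                                seed = seed + match(q, names(theta_by_q)))
    for (i in seq_len(k)) {
      rr <- exp(sim$log_rr[i])
      lo <- exp(sim$log_rr[i] - z * sim$se[i])
      hi <- exp(sim$log_rr[i] + z * sim$se[i])
      measure <- "rr"
      prevalence <- NA
      rare <- NA
      if (i == 1) {          # study 1 reports hazard ratios, rare outcome
        measure <- "hr"
        rare <- TRUE
      } else if (i == 2) {   # study 2 reports odds ratios, rare outcome
        measure <- "or"
        prevalence <- 0.05
      }
      rows[[length(rows) + 1]] <- data.frame(
        study_id = sprintf("study%02d", i), quantile = q, measure = measure,
        point = rr, ci_lower = lo, ci_upper = hi,
        outcome_prevalence = prevalence, rare_outcome = rare,
        tag = if (i <= 3) "owob" else "weightgain")
    }
  }
  for (i in seq_len(k)) {    # reference rows, not pooled
    rows[[length(rows) + 1]] <- data.frame(
      study_id = sprintf("study%02d", i), quantile = "Q1", measure = "rr",
      point = 1, ci_lower = 1, ci_upper = 1,
      outcome_prevalence = NA, rare_outcome = NA,
      tag = if (i <= 3) "owob" else "weightgain")
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# Scenario table exercising all three association types on the exposure side.
write_scenario_csv <- function(path) {
  tab <- data.frame(
    name = c("depression", "food_insecurity", "overeating"),
    exposure_assoc_type = c("or", "rr", "r"),
    exposure_assoc_value = c(1.44, 1.60, 0.28),
    exposure_p0 = c(0.08, NA, 0.5),
    outcome_assoc_type = c("or", "or", "or"),
    outcome_assoc_value = c(1.58, 1.53, 1.58),
    outcome_p0 = c(0.5, 0.5, 0.5))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
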