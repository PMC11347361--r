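test_that("single-study input passes through with tau2 = 0 and a warning", {
  expect_warning(fit <- rema(log(1.2), 0.1), "one study")
  expect_equal(fit$rr, 1.2, tolerance = 1e-12)
  expect_identical(fit$tau2, 0)
  expect_equal(fit$se, 0.1, tolerance = 1e-12)
})

test_that("identical studies pool to themselves with no heterogeneity", {
  fit <- rema(rep(log(1.5), 3), rep(0.2, 3))
  expect_equal(fit$rr, 1.5, tolerance = 1e-9)
  expect_equal(fit$tau2, 0, tolerance = 1e-10)
  expect_equal(fit$se, 0.2 / sqrt(3), tolerance = 1e-9)
  expect_equal(fit$q_stat, 0, tolerance = 1e-12)
  expect_identical(fit$i2, 0)
})

test_that("REML estimate matches the dense grid-search oracle on a fixture", {
  yi <- c(0.05, 0.25, -0.02, 0.18, 0.40)
  sei <- c(0.08, 0.12, 0.10, 0.05, 0.15)
  fit <- rema(yi, sei)
  oracle <- reml_grid_oracle(yi, sei, tau2_max = 1, step = 1e-5)
  expect_lt(abs(fit$tau2 - oracle$tau2), 1e-4)
  expect_lt(abs(fit$theta - oracle$theta), 1e-6)
  # heterogeneous fixture should have tau2 > 0
  expect_gt(fit$tau2, 0)
})

test_that("REML estimate agrees with an independent reference fit", {
  library(metafor)
  yi <- c(0.05, 0.25, -0.02, 0.18, 0.40)
  sei <- c(0.08, 0.12, 0.10, 0.05, 0.15)
  fit <- rema(yi, sei)
  # run the reference fitter to a comparable convergence threshold
  ref <- metafor::rma(yi = yi, sei = sei, method = "REML",
                      control = list(threshold = 1e-10))
  expect_equal(fit$tau2, ref$tau2, tolerance = 1e-7)
  expect_equal(fit$theta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(fit$se, ref$se, tolerance = 1e-8)
  expect_equal(fit$q_stat, ref$QE, tolerance = 1e-8)
})

test_that("pooled estimate is invariant to study ordering and stays in range", {
  sim <- simulate_meta_sample(8, log(1.2), 0.02, seed = 5)
  fit <- rema(sim$log_rr, sim$se)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  fit2 <- rema(sim$log_rr[perm], sim$se[perm])
  expect_equal(fit$theta, fit2$theta, tolerance = 1e-9)
  expect_equal(fit$tau2, fit2$tau2, tolerance = 1e-9)
  # pooled RR lies within the span of the study estimates
  expect_gte(fit$rr, min(exp(sim$log_rr)))
  expect_lte(fit$rr, max(exp(sim$log_rr)))
  expect_true(fit$ci_lower <= fit$rr && fit$rr <= fit$ci_upper)
})

test_that("with tau2 fixed at 0, rescaling all se leaves the point and scales the CI", {
  yi <- c(0.1, 0.3, -0.05, 0.2)
  sei <- c(0.08, 0.12, 0.10, 0.05)
  f1 <- rema(yi, sei, tau2 = 0)
  f3 <- rema(yi, 3 * sei, tau2 = 0)
  expect_equal(f1$theta, f3$theta, tolerance = 1e-12)
  expect_equal(f3$se, 3 * f1$se, tolerance = 1e-12)
  expect_equal(log(f3$ci_upper / f3$ci_lower),
               3 * log(f1$ci_upper / f1$ci_lower), tolerance = 1e-10)
})

test_that("REML optimiser matches the grid oracle on random small instances", {
  set.seed(2024)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    sei <- runif(k, 0.08, 0.4)
    yi <- rnorm(k, 0.1, sqrt(sei^2 + 0.03))
    fit <- rema(yi, sei)
    oracle <- reml_grid_oracle(yi, sei, tau2_max = min(2, 10 * max(sei^2)),
                               step = 1e-5)
    expect_lt(abs(fit$tau2 - oracle$tau2), 1e-4)
    expect_lt(abs(fit$theta - oracle$theta), 1e-6)
  }
})

test_that("rema rejects degenerate inputs", {
  expect_error(rema(numeric(0), numeric(0)), "no studies")
  expect_error(rema(c(0.1, 0.2), 0.1), "same length")
  expect_error(rema(c(0.1, 0.2), c(0.1, -0.1)), "positive")
})

test_that("rema methods expose the fit consistently", {
  sim <- simulate_meta_sample(6, log(1.3), 0.01, seed = 9)
  fit <- rema(sim$log_rr, sim$se)
  expect_equal(unname(coef(fit)), fit$theta)
  expect_equal(unname(vcov(fit)[1, 1]), fit$se^2)
  ci <- confint(fit)
  expect_equal(unname(exp(ci[1, ])), c(fit$ci_lower, fit$ci_upper),
               tolerance = 1e-12)
  pred <- predict(fit)
  expect_lte(pred$pi_lower, pred$ci_lower)
  expect_gte(pred$pi_upper, pred$ci_upper)
  expect_output(print(summary(fit)), "Heterogeneity")
})

test_that("pool_by_quantile pools per quantile after RR conversion", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(path, k = 5, tau2 = 0, seed = 31)
  tab <- read_study_table(path)
  fits <- pool_by_quantile(tab, reference = "Q1")
  expect_named(fits, c("Q2", "Q3", "Q4"))
  expect_true(all(vapply(fits, function(f) f$k, numeric(1)) == 5))
  # generated at theta = log 1.14 with tight ses: pooled Q4 RR close to 1.14
  expect_equal(fits$Q4$rr, 1.14, tolerance = 0.05)
  # pooling is on the log-RR scale regardless of the reported measure
  expect_true(all(vapply(fits, function(f) f$tau2 >= 0, logical(1))))
})

test_that("pool_by_quantile handles edge tables", {
  only_ref <- data.frame(study_id = c("s1", "s2"), quantile = "Q1",
                         measure = "RR", point = c(1, 1),
                         ci_lower = c(1, 1), ci_upper = c(1, 1))
  expect_length(pool_by_quantile(only_ref, reference = "Q1"), 0)

  dup <- data.frame(study_id = "s1", quantile = c("Q2", "Q2"),
                    measure = "RR", point = c(1.2, 1.3),
                    ci_lower = c(1.1, 1.2), ci_upper = c(1.3, 1.4))
  # no Q1 rows either: the reference warning fires before the error
  expect_error(suppressWarnings(pool_by_quantile(dup)),
               "at most one estimate")
})

test_that("study-table validation itemises offending rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- data.frame(study_id = c("s1", "s2"), quantile = c("Q2", "Q2"),
                    measure = c("RR", "banana"), point = c(1.2, 1.1),
                    ci_lower = c(1.3, 1.0), ci_upper = c(1.4, 1.2))
  write.csv(bad, path, row.names = FALSE)
  err <- tryCatch(read_study_table(path), error = conditionMessage)
  expect_match(err, "row 2: unknown measure")
  expect_match(err, "row 1: need 0 < ci_lower")
  expect_error(read_study_table(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("pooling recovers the generating effect across simulated meta-analyses", {
  # 50 replicates at k = 20: mean pooled log RR within Monte-Carlo error
  theta <- log(1.14)
  est <- vapply(1:50, function(i) {
    sim <- simulate_meta_sample(20, theta, 0.01, seed = 7000 + i)
    rema(sim$log_rr, sim$se)$theta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - theta), 2 * mc_se + 0.005)
})
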