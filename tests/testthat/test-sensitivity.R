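test_that("E-value formula reproduces worked values", {
  expect_equal(evalue_point(1.41), 2.17032887621, tolerance = 1e-10)
  expect_equal(evalue_point(1.10), 1.43166247904, tolerance = 1e-10)
  expect_equal(evalue_point(1.14), 1.53949968711, tolerance = 1e-10)
  expect_identical(evalue_point(1), 1)
  expect_error(evalue_point(0), "positive")
  expect_error(evalue_point(-2), "positive")
})

test_that("protective estimates are oriented by reciprocal before the E-value", {
  for (rr in c(0.2, 0.5, 0.8, 0.99)) {
    expect_equal(evalue_point(rr), evalue_point(1 / rr), tolerance = 1e-12)
  }
  # E >= RR on the harmful side, with equality only at the null
  for (rr in c(1.01, 1.5, 3)) {
    expect_gt(evalue_point(rr), rr)
  }
})

test_that("inverse E-value is the closed form E^2/(2E - 1)", {
  expect_equal(invert_evalue(2.00), 4 / 3, tolerance = 1e-12)
  expect_identical(invert_evalue(1), 1)
  expect_equal(invert_evalue(1.55), 1.14404761905, tolerance = 1e-10)
  expect_error(invert_evalue(0.9), ">= 1")
})

test_that("invert_evalue round-trips with evalue_point", {
  for (rr in c(1.001, 1.14, 1.33, 2, 4.7)) {
    expect_equal(invert_evalue(evalue_point(rr)), rr, tolerance = 1e-12)
  }
  for (e in c(1, 1.2, 2, 5)) {
    expect_equal(evalue_point(invert_evalue(e)), e, tolerance = 1e-12)
  }
})

test_that("CI E-value uses the limit closer to the null", {
  expect_equal(round(evalue_ci(1.14, 1.10, 1.19), 2), 1.43)
  expect_identical(evalue_ci(1.14, 0.95, 1.30), 1)
  # protective estimate: upper limit, reciprocated
  expect_equal(evalue_ci(0.80, 0.70, 0.91), 1.42857142857, tolerance = 1e-10)
  expect_error(evalue_ci(1.14, 1.20, 1.30), "ci_lower <= rr_point")
})

test_that("bounding factor reproduces worked values and basic properties", {
  expect_equal(round(bounding_factor(1.48, 1.39), 2), 1.10)
  expect_equal(bounding_factor(3.00, 1.60), 4 / 3, tolerance = 1e-12)
  for (x in c(1, 1.5, 4)) {
    expect_identical(bounding_factor(1, x), 1)
  }
  expect_error(bounding_factor(0.9, 2), ">= 1")
})

test_that("bounding factor is symmetric, capped by its smaller argument, and monotone", {
  grid <- c(1.1, 1.5, 2, 3, 6)
  for (a in grid) {
    for (b in grid) {
      expect_equal(bounding_factor(a, b), bounding_factor(b, a),
                   tolerance = 1e-12)
      expect_lte(bounding_factor(a, b), min(a, b) + 1e-12)
    }
    # strictly increasing in each argument (away from the null)
    if (a > 1) {
      expect_gt(bounding_factor(a, 2.5), bounding_factor(a, 2))
    }
  }
})

test_that("the bounding factor at (E, E) recovers the observed risk ratio", {
  for (rr in seq(1.01, 5, length.out = 60)) {
    e <- evalue_point(rr)
    expect_equal(bounding_factor(e, e), rr, tolerance = 1e-9)
  }
})

test_that("proportion explained uses the excess-relative-risk scale with a cap", {
  b <- bounding_factor(1.48, 1.39)
  expect_equal(proportion_explained(1.14, b), 71.50497, tolerance = 1e-4)
  expect_identical(proportion_explained(1.10, b), 100)
  expect_identical(proportion_explained(1.5, 1.0), 0)
  expect_identical(proportion_explained(1.10, 1.10), 100)
  expect_warning(out <- proportion_explained(0.9, 1.2), "nothing")
  expect_identical(out, 0)
  # monotone in b, equal to 100 exactly at b = rr
  props <- vapply(c(1.02, 1.05, 1.08, 1.14), proportion_explained,
                  numeric(1), rr_obs = 1.14)
  expect_true(all(diff(props) > 0))
  expect_identical(props[4], 100)
})

test_that("required complementary association solves the bound in closed form", {
  expect_equal(required_complementary_rr(3.00, 4 / 3), 1.60,
               tolerance = 1e-12)
  expect_equal(required_complementary_rr(1.49, 1.14), 1.596,
               tolerance = 1e-10)
  expect_identical(required_complementary_rr(1.10, 1.14), NA_real_)
  expect_identical(required_complementary_rr(1.14, 1.14), NA_real_)
  expect_error(required_complementary_rr(2, 1), "> 1")
})

test_that("required complementary association round-trips through the bound", {
  for (a in c(1.5, 2, 3, 8)) {
    for (t in c(1.1, 1.33, 1.45)) {
      if (a > t) {
        x <- required_complementary_rr(a, t)
        expect_equal(bounding_factor(a, x), t, tolerance = 1e-9)
      }
    }
  }
})

test_that("scenario analysis composes bound, proportions, and flags", {
  dep <- confounder_scenario("depression", rr_eu = 1.39, rr_ud = 1.48)
  res <- analyse_scenario(dep, c(1.14, 1.10, 1.19))
  expect_equal(res$b, bounding_factor(1.48, 1.39), tolerance = 1e-12)
  expect_equal(res$proportion_explained_point, 71.50497, tolerance = 1e-4)
  expect_identical(res$proportion_explained_lower_ci, 100)
  expect_false(res$fully_explains_point)   # B = 1.100 < 1.14
  expect_true(res$fully_explains_lower_ci) # B = 1.100 >= 1.10
  expect_equal(res$required_rr_eu, required_complementary_rr(1.48, 1.14),
               tolerance = 1e-12)

  food <- confounder_scenario("food insecurity", rr_eu = 1.60, rr_ud = 1.42)
  res <- analyse_scenario(food, c(1.14, 1.10, 1.19))
  expect_equal(res$b, 1.12475247525, tolerance = 1e-10)
  expect_equal(res$proportion_explained_point, 89.1089108911,
               tolerance = 1e-8)
  expect_identical(res$proportion_explained_lower_ci, 100)
})

test_that("degenerate scenarios and null estimates are handled explicitly", {
  null_sc <- confounder_scenario("nothing", rr_eu = 1, rr_ud = 1)
  res <- analyse_scenario(null_sc, c(1.14, 1.10, 1.19))
  expect_identical(res$b, 1)
  expect_identical(res$proportion_explained_point, 0)
  expect_false(res$fully_explains_point)

  expect_warning(
    res <- analyse_scenario(confounder_scenario("x", 1.5, 1.5),
                            c(1.0, 0.9, 1.1)),
    "null")
  expect_identical(res$proportion_explained_point, 0)
  expect_error(confounder_scenario("bad", 0.8, 1.5), ">= 1")
})

test_that("scenario analysis accepts a fitted meta-analysis as the observed effect", {
  fit <- rema(rep(log(1.2), 3), rep(0.05, 3))
  sc <- confounder_scenario("u", rr_eu = 1.5, rr_ud = 1.5)
  res <- analyse_scenario(sc, fit)
  expect_equal(res$rr_point, fit$rr, tolerance = 1e-12)
  expect_equal(res$b, bounding_factor(1.5, 1.5), tolerance = 1e-12)
})

test_that("bounding curve lies on the contour and passes the symmetric point", {
  crv <- bounding_curve(4 / 3, n_points = 150, rr_ud_max = 12)
  expect_true(all(abs(bounding_factor(crv$rr_ud, crv$rr_eu) - 4 / 3) < 1e-9))
  # rr_eu decreases as rr_ud grows
  expect_true(all(diff(crv$rr_eu) < 0))
  # symmetric point: at rr_ud = 2 (the E-value of 4/3) the complement is 2
  expect_equal(required_complementary_rr(2, 4 / 3), 2, tolerance = 1e-12)
  expect_equal(evalue_point(4 / 3), 2, tolerance = 1e-12)
  # generic symmetric-point identity on another contour
  e <- evalue_point(1.14)
  expect_equal(required_complementary_rr(e, 1.14), e, tolerance = 1e-9)
  expect_error(bounding_curve(1.0), "> 1")
  expect_error(bounding_curve(1.5, rr_ud_max = 1.4), "exceed")
})
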