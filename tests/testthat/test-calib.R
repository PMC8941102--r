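quad_mass <- function(spec, lower, upper) {
  integrate(function(t) calibration_density(t, spec), lower, upper,
            rel.tol = 1e-9, abs.tol = 1e-12)$value
}

test_that("soft-bounded uniform densities integrate to 1 with stated tails", {
  spec <- calibration_spec("crown", "uniform", tL = 4.25, tU = 5.33,
                           pL = 0.025, pU = 0.025)
  expect_equal(quad_mass(spec, 1e-12, Inf), 1, tolerance = 1e-6)
  expect_equal(quad_mass(spec, 1e-12, 4.25), 0.025, tolerance = 1e-6)
  expect_equal(quad_mass(spec, 5.33, Inf), 0.025, tolerance = 1e-6)
  # continuity at the bounds
  h <- (1 - 0.05) / (5.33 - 4.25)
  expect_equal(uniform_soft_density(4.25 - 1e-9, spec), h, tolerance = 1e-4)
  expect_equal(uniform_soft_density(5.33 + 1e-9, spec), h, tolerance = 1e-4)
})

test_that("a 1e-300 tail mass is a hard bound", {
  spec <- calibration_spec("root", "uniform", tL = 10, tU = 18.91,
                           pL = 1e-300, pU = 0.025)
  expect_equal(uniform_soft_density(10 - 1e-9, spec), 0)
  expect_equal(uniform_soft_density(5, spec), 0)
  expect_gt(uniform_soft_density(10 + 1e-9, spec), 0)
  expect_equal(quad_mass(spec, 1e-12, Inf), 1, tolerance = 1e-6)
  expect_equal(quad_mass(spec, 18.91, Inf), 0.025, tolerance = 1e-6)
})

test_that("uniform quantiles hit the bounds at the tail masses", {
  spec <- calibration_spec("crown", "uniform", tL = 4.07, tU = 5.17,
                           pL = 0.025, pU = 0.025)
  expect_equal(calibration_quantile(0.025, spec), 4.07, tolerance = 1e-6)
  expect_equal(calibration_quantile(1 - 0.025, spec), 5.17, tolerance = 1e-6)
  # cdf/quantile round trip across all three pieces
  for (q in c(0.001, 0.01, 0.3, 0.9, 0.99, 0.9999)) {
    expect_equal(calibration_cdf(calibration_quantile(q, spec), spec), q,
                 tolerance = 1e-9)
  }
})

test_that("the truncated Cauchy peaks at tL(1+p) and normalizes", {
  spec <- calibration_spec("clado_stem", "cauchy_min", tL = 10,
                           pL = 1e-300, p = 0.1, c = 1)
  grid <- seq(10.001, 60, by = 0.001)
  d <- cauchy_min_density(grid, spec)
  expect_equal(grid[which.max(d)], 11.0, tolerance = 1e-3)
  expect_equal(quad_mass(spec, 10, Inf), 1, tolerance = 1e-6)
  expect_equal(cauchy_min_density(c(9, 10), spec), c(0, 0))
})

test_that("calibration sampling reproduces the tail masses", {
  spec <- calibration_spec("crown", "uniform", tL = 4.25, tU = 5.33,
                           pL = 0.025, pU = 0.025)
  n <- 1e5
  draws <- sample_calibration(spec, n, seed = 1)
  se <- sqrt(0.025 * 0.975 / n)
  expect_lt(abs(mean(draws > 5.33) - 0.025), 3 * se)
  expect_lt(abs(mean(draws < 4.25) - 0.025), 3 * se)
  expect_identical(draws, sample_calibration(spec, n, seed = 1))

  cm <- calibration_spec("stem", "cauchy_min", tL = 10, pL = 1e-300)
  cd <- sample_calibration(cm, 1e4, seed = 2)
  expect_gt(min(cd), 10)
})

test_that("the rate hyperprior follows distance / age", {
  pr <- derive_rate_prior(0.3581, 10, shape = 2)
  expect_equal(pr$shape, 2)
  expect_equal(pr$rate, 55.85, tolerance = 1e-4)
  expect_equal(pr$mean, 0.03581)

  pr2 <- derive_rate_prior(0.2, 10, shape = 2)
  expect_equal(pr2$mean, 0.02)
  expect_equal(pr2$rate, 100)

  pr3 <- derive_rate_prior(0.1, 10, shape = 1)  # exponential case
  expect_equal(pr3$rate, 100)
  expect_equal(pr3$mean, 0.01)
  expect_error(derive_rate_prior(-1, 10), "positive")

  expect_equal(gamma_prior(1, 10)$mean, 0.1)
})

test_that("sampling fraction is a plain proportion with guarded inputs", {
  expect_equal(sampling_fraction(65, 6478), 65 / 6478)
  expect_equal(sampling_fraction(65, 6478), 0.010034, tolerance = 1e-4)
  expect_equal(sampling_fraction(10, 10), 1)
  expect_equal(sampling_fraction(1, 100), 0.01)
  expect_error(sampling_fraction(0, 10), "n_ingroup")
  expect_error(sampling_fraction(11, 10), "n_ingroup")
})

test_that("the bundled calibration table encodes the three strategies", {
  s1 <- load_calibration_table(strategy = 1)
  s2 <- load_calibration_table(strategy = 2)
  s3 <- load_calibration_table(strategy = 3)
  expect_length(s1, 8)
  expect_length(s2, 8)
  expect_length(s3, 7)
  n1 <- vapply(s1, function(s) s$node, character(1))
  n2 <- vapply(s2, function(s) s$node, character(1))
  n3 <- vapply(s3, function(s) s$node, character(1))
  expect_true("6-1" %in% n1 && !"6-2" %in% n1)
  expect_true("6-2" %in% n2 && !"6-1" %in% n2)
  expect_false(any(grepl("^6", n3)))
  # strategies 1 and 2 differ only in the attachment of the min-1000 record
  shared1 <- s1[n1 != "6-1"]
  shared2 <- s2[n2 != "6-2"]
  expect_equal(shared1, shared2)
  deep1 <- s1[[which(n1 == "6-1")]]
  deep2 <- s2[[which(n2 == "6-2")]]
  expect_equal(deep1$tL, 10)
  expect_equal(deep2$tL, 10)
  expect_equal(deep1$family, "cauchy_min")
  # the root calibration spans 1000-1891 My in 100-My units
  root <- s1[[which(n1 == "1")]]
  expect_equal(c(root$tL, root$tU), c(10.00, 18.91))
  expect_error(load_calibration_table(strategy = 5), "strategy")
})

test_that("every bundled density is non-negative and integrates to 1", {
  for (spec in load_calibration_table(strategy = 1)) {
    lower <- if (spec$family == "cauchy_min") spec$tL else 1e-12
    expect_equal(quad_mass(spec, lower, Inf), 1, tolerance = 1e-6)
    grid <- seq(spec$tL * 0.5 + 1e-9, spec$tL * 3, length.out = 200)
    expect_true(all(calibration_density(grid, spec) >= 0))
  }
})
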