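test_that("indeterminacy-adjusted density reduces to and scales the classical pdf", {
  # exponential special case: (1/alpha) exp(-1) at x = alpha, shape 1
  expect_equal(dweibull_ind(0.1880, scale = 0.1880, shape = 1),
               (1 / 0.1880) * exp(-1), tolerance = 1e-12)
  xs <- c(0.05, 0.1880, 0.4, 1.3)
  expect_equal(dweibull_ind(xs, 0.1880, 2.2222),
               dweibull(xs, shape = 2.2222, scale = 0.1880), tolerance = 1e-14)
  expect_equal(dweibull_ind(xs, 0.1880, 2.2222, indeterminacy = 0.04),
               1.04 * dweibull_ind(xs, 0.1880, 2.2222), tolerance = 1e-14)
  expect_error(dweibull_ind(0.1, scale = -1, shape = 2), "scale")
})

test_that("indeterminacy-adjusted cdf has the printed raw form", {
  expect_equal(pweibull_ind(0, 1, 2, indeterminacy = 0.05), 0)
  expect_equal(pweibull_ind(1, scale = 1, shape = 1), 1 - exp(-1),
               tolerance = 1e-14)
  # raw form tends to 1 + I, deliberately unclamped at this layer
  expect_equal(pweibull_ind(1e6, 1, 1, indeterminacy = 0.04), 1.04,
               tolerance = 1e-12)
  xs <- c(0.1, 0.5, 2)
  expect_equal(pweibull_ind(xs, 0.7, 3),
               pweibull(xs, shape = 3, scale = 0.7), tolerance = 1e-12)
})

test_that("distribution mean matches closed forms", {
  expect_equal(mean_weibull_ind(1, 1), 1, tolerance = 1e-14)
  expect_equal(mean_weibull_ind(1, 2, indeterminacy = 0.05),
               1.05 * sqrt(pi) / 2, tolerance = 1e-13)
  expect_equal(mean_weibull_ind(0.1880, 2.2222), 0.1665, tolerance = 5e-4)
})

test_that("Gamma(1 + 1/b) and Gamma(1/b)/b evaluation routes agree", {
  for (b in c(0.5, 1, 2, 2.2222, 3)) {
    expect_equal(mean_weibull_ind(1, b), gamma(1 / b) / b,
                 tolerance = 1e-12)
  }
})

test_that("failure fractions match direct evaluation and clamp out-of-range values", {
  expect_equal(failure_fraction(0.5, shape = 1, mean_ratio = 2),
               1 - exp(-0.25), tolerance = 1e-12)
  expect_equal(failure_fraction(0.5, shape = 1), 1 - exp(-0.5),
               tolerance = 1e-12)
  expect_equal(failure_fraction(1, shape = 2), 1 - exp(-pi / 4),
               tolerance = 1e-12)
  # at indeterminacy 0 the fraction is the classical Weibull cdf at
  # t0 = a * mu0 with mu0 = alpha Gamma(1 + 1/beta)
  a <- 0.8; b <- 2.5; scale <- 1.7
  mu0 <- mean_weibull_ind(scale, b)
  expect_equal(failure_fraction(a, b),
               pweibull(a * mu0, shape = b, scale = scale), tolerance = 1e-12)
  # large indeterminacy pushes the raw value above 1; clamped with warning
  expect_warning(p <- failure_fraction(3, shape = 3, indeterminacy = 0.5),
                 "clamped")
  expect_identical(p, 1)
  expect_gt(failure_fraction(3, shape = 3, indeterminacy = 0.5,
                             clamp = FALSE), 1)
})

test_that("AQL fraction decreases in the mean ratio and never exceeds the LQL fraction", {
  for (b in c(1, 2.2222)) {
    for (a in c(0.5, 1.0)) {
      for (I in c(0, 0.04)) {
        ratios <- c(1, 1.1, 1.3, 1.7, 2.5, 5, 50)
        ps <- vapply(ratios, function(r) {
          aql_fraction(design_setting(0.10, 0.10, a, b, r, I))
        }, numeric(1))
        expect_true(all(diff(ps) < 0))
        s1 <- design_setting(0.10, 0.10, a, b, 1.4, I)
        expect_lte(aql_fraction(s1), lql_fraction(s1))
        # ratio = 1: the two quality levels coincide
        s0 <- design_setting(0.10, 0.10, a, b, 1, I)
        expect_equal(aql_fraction(s0), lql_fraction(s0))
      }
    }
  }
  # as the ratio grows without bound the AQL fraction vanishes (I = 0)
  expect_lt(aql_fraction(design_setting(0.1, 0.1, 0.5, 1, 1e6, 0)), 1e-6)
})

test_that("design setting and indeterminacy interval validate their domains", {
  expect_error(design_setting(0, 0.1, 1, 2), "producer_risk")
  expect_error(design_setting(0.1, 1, 1, 2), "consumer_risk")
  expect_error(design_setting(0.1, 0.1, -1, 2), "termination_ratio")
  expect_error(design_setting(0.1, 0.1, 1, 2, mean_ratio = 0.9), "mean_ratio")
  ii <- indeterminacy_interval(0, 0.04)
  expect_identical(unname(ii[1]), 0)
  expect_error(indeterminacy_interval(0.05, 0.02), "lower <= upper")
  # degenerate interval: the form the design tables are indexed by
  expect_identical(unname(indeterminacy_interval(0.05)[2]), 0.05)
})
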