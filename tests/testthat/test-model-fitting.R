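test_that("Weibull MLE recovers known parameters on simulated data", {
  x <- simulate_lifetimes(5000, scale = 0.188, shape = 2.22, seed = 101)
  fit <- fit_weibull_mle(x)
  expect_equal(unname(fit$estimates[["shape"]]), 2.22, tolerance = 0.05)
  expect_equal(unname(fit$estimates[["scale"]]), 0.188, tolerance = 0.05)
  expect_true(all(is.finite(fit$standard_errors)))
  expect_error(fit_weibull_mle(c(1, -2)), "positive")
})

test_that("information criteria satisfy their definitional identities", {
  x <- covid_italy_ratios()
  for (model in c("WD", "ENHD", "NHD")) {
    fit <- fit_lifetime_model(x, model)
    expect_true(fit$converged)
    expect_equal(fit$aic, fit$neg2_loglik + 2 * fit$k, tolerance = 1e-10)
    expect_equal(fit$bic, fit$neg2_loglik + fit$k * log(fit$m),
                 tolerance = 1e-10)
  }
})

test_that("fixture fits reproduce the reference goodness-of-fit table", {
  x <- covid_italy_ratios()
  wd <- fit_weibull_mle(x)
  expect_equal(unname(wd$estimates[["shape"]]), 2.2222, tolerance = 1e-3)
  expect_equal(unname(wd$estimates[["scale"]]), 0.1880, tolerance = 1e-3)
  expect_equal(wd$aic, -253.1131, tolerance = 1e-3)
  expect_equal(wd$ks_stat, 0.0684, tolerance = 1e-2)
  expect_equal(wd$ks_pvalue, 0.6766, tolerance = 0.01)
  expect_equal(unname(wd$standard_errors[["shape"]]), 0.1596, tolerance = 0.05)
  expect_equal(unname(wd$standard_errors[["scale"]]), 0.00845, tolerance = 0.05)
  enhd <- fit_lifetime_model(x, "ENHD")
  expect_equal(enhd$aic, -250.9344, tolerance = 1e-2)
  nhd <- fit_lifetime_model(x, "NHD")
  expect_equal(nhd$aic, -217.1095, tolerance = 0.5)
  owd <- fit_lifetime_model(x, "OWD")
  expect_equal(owd$aic, -252.5084, tolerance = 1e-2)
})

test_that("competitor distributions reduce to their special cases", {
  q <- c(0.05, 0.2, 0.7, 1.5)
  # NHD at alpha = 1 is exponential(rate = lambda)
  expect_equal(pnhd(q, alpha = 1, lambda = 3), pexp(q, rate = 3),
               tolerance = 1e-13)
  # ENHD at theta = 1 is the NHD, on density and cdf
  expect_equal(penhd(q, 2.5, 1.3, theta = 1), pnhd(q, 2.5, 1.3),
               tolerance = 1e-13)
  x <- simulate_lifetimes(200, 1, 2, seed = 5)
  expect_equal(sum(log(denhd(x, 2.5, 1.3, 1))),
               sum(log(dnhd(x, 2.5, 1.3))), tolerance = 1e-10)
  # densities integrate-consistently with their cdfs (finite differences)
  h <- 1e-6
  expect_equal((powd(0.5 + h, 1.8, 1.3, 0.19) - powd(0.5 - h, 1.8, 1.3, 0.19)) / (2 * h),
               dowd(0.5, 1.8, 1.3, 0.19), tolerance = 1e-4)
})

test_that("the returned MLE is a local optimum of the likelihood", {
  x <- covid_italy_ratios()
  fit <- fit_weibull_mle(x)
  ll_hat <- fit$loglik
  set.seed(77)
  for (i in 1:64) {
    pert <- fit$estimates * exp(runif(2, -0.1, 0.1))
    ll <- sum(dweibull(x, shape = pert[["shape"]], scale = pert[["scale"]],
                       log = TRUE))
    expect_lte(ll, ll_hat + 1e-8)
  }
})

test_that("KS statistic by the sorted-sample formula matches a brute-force scan", {
  x <- covid_italy_ratios()
  fit <- fit_weibull_mle(x)
  ks <- ks_statistic(x, fit$cdf)
  xs <- sort(x)
  grid <- sort(c(seq(0, max(x) * 1.1, length.out = 5000), xs, xs - 1e-12))
  fn <- ecdf(x)
  d_scan <- max(abs(fn(grid) - fit$cdf(grid)))
  expect_equal(ks$statistic, d_scan, tolerance = 1e-9)
  # data drawn from the hypothesized model: D small, p comfortable
  y <- simulate_lifetimes(10000, 1, 2, seed = 303)
  ks2 <- ks_statistic(y, function(q) pweibull(q, 2, 1))
  expect_lt(ks2$statistic, 0.02)
  expect_gt(ks2$p.value, 0.01)
  # degenerate single observation: D is the larger one-sided gap
  ks3 <- ks_statistic(0.5, function(q) pweibull(q, 2, 1))
  f <- pweibull(0.5, 2, 1)
  expect_equal(ks3$statistic, max(1 - f, f), tolerance = 1e-12)
})

test_that("model comparison flags the Weibull as AIC-minimal on the fixture", {
  x <- covid_italy_ratios()
  tab <- model_comparison_table(x)
  expect_equal(nrow(tab), 4L)
  expect_true(tab$best[tab$model == "WD"])
  expect_equal(sum(tab$best), 1L)
  expect_true(all(tab$converged))
  # model-recovery: on large simulated Weibull data, WD wins again
  y <- simulate_lifetimes(2000, 0.188, 2.2222, seed = 13)
  tab2 <- model_comparison_table(y, models = c("WD", "NHD"))
  expect_true(tab2$best[tab2$model == "WD"])
})

test_that("indeterminacy-adjusted shape estimate scales linearly", {
  expect_equal(neutrosophic_shape_adjust(2.2222, 0.04), 2.311088,
               tolerance = 1e-6)
  expect_equal(neutrosophic_shape_adjust(3.1, 0), 3.1)
  expect_equal(neutrosophic_shape_adjust(1.0, 0.05), 1.05)
})
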