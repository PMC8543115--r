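test_that("structured search equals exhaustive enumeration within small bounds", {
  settings <- list(
    design_setting(0.10, 0.25, 1.0, 2, 1.5, 0),
    design_setting(0.10, 0.10, 1.0, 2, 2.0, 0.02),
    design_setting(0.10, 0.05, 1.0, 3, 1.8, 0.05),
    design_setting(0.05, 0.25, 0.5, 1, 2.0, 0)
  )
  for (s in settings) {
    got <- design_repetitive_plan(s, n_max = 60, c_max = 60, asn_max = Inf)
    want <- exhaustive_design_oracle(s, n_max = 60, c_max = 60)
    expect_identical(is.null(want), !got$feasible)
    if (!is.null(want)) {
      expect_equal(got$plan$n, want$n)
      expect_equal(got$plan$c1, want$c1)
      expect_equal(got$plan$c2, want$c2)
      expect_equal(got$asn, want$asn, tolerance = 1e-12)
    }
  }
})

test_that("returned plans satisfy both risk constraints", {
  for (s in list(design_setting(0.10, 0.10, 1.0, 2.2222, 1.1, 0.04),
                 design_setting(0.10, 0.25, 0.5, 2, 1.2, 0),
                 design_setting(0.10, 0.01, 1.0, 3, 1.5, 0.02))) {
    d <- design_repetitive_plan(s)
    expect_true(d$feasible)
    chk <- check_feasibility(d$plan, s)
    expect_true(chk$feasible)
    expect_gte(d$oc_aql, 1 - s$producer_risk)
    expect_lte(d$oc_lql, s$consumer_risk)
    expect_gte(d$asn, d$plan$n)
  }
})

test_that("feasibility checker flags violated constraints", {
  s <- design_setting(0.10, 0.01, 1.0, 2.2222, 1.1, 0)
  chk <- check_feasibility(attribute_plan(1, 0, 0), s)
  expect_false(chk$feasible)
  # c1 = c2 = n accepts everything: the consumer constraint must fail
  chk2 <- check_feasibility(attribute_plan(30, 30, 30),
                            design_setting(0.10, 0.25, 1.0, 2, 1.5, 0))
  expect_equal(chk2$oc_aql, 1)
  expect_equal(chk2$oc_lql, 1)
  expect_false(chk2$consumer_ok)
  expect_true(chk2$producer_ok)
})

test_that("single-plan design minimizes n with c1 = c2 and ASN = n", {
  s <- design_setting(0.10, 0.25, 0.5, 2, 1.1, 0.02)
  d <- design_single_plan(s)
  expect_true(d$feasible)
  expect_equal(d$plan$c1, d$plan$c2)
  expect_equal(d$asn, d$plan$n)
  expect_gte(accept_probability(d$plan, aql_fraction(s)), 0.90)
  expect_lte(accept_probability(d$plan, lql_fraction(s)), 0.25)
  # no smaller n admits any c: check n - 1 exhaustively
  n1 <- d$plan$n - 1L
  cs <- 0:n1
  feas <- pbinom(cs, n1, aql_fraction(s)) >= 0.90 &
    pbinom(cs, n1, lql_fraction(s)) <= 0.25
  expect_false(any(feas))
})

test_that("single-plan design handles a slack consumer constraint", {
  s <- design_setting(0.10, 0.97, 0.5, 1, 1, 0)
  d <- design_single_plan(s)
  expect_true(d$feasible)
  expect_lte(d$plan$n, 10)
})

test_that("repetitive design is never costlier than the single plan", {
  for (s in list(design_setting(0.10, 0.25, 0.5, 2, 1.1, 0.02),
                 design_setting(0.10, 0.10, 1.0, 2, 1.5, 0),
                 design_setting(0.10, 0.05, 1.0, 2.2222, 1.3, 0.04))) {
    rep_d <- design_repetitive_plan(s)
    single_d <- design_single_plan(s)
    expect_true(rep_d$feasible && single_d$feasible)
    expect_lte(rep_d$asn, single_d$plan$n + 1e-9)
  }
})

test_that("higher indeterminacy mostly lowers the minimal ASN", {
  tab <- generate_design_table(c(0.25, 0.10), c(1.2, 1.4, 1.8),
                               c(0, 0.05), termination_ratio = 1.0,
                               shape = 2)
  w0 <- tab[tab$I == 0, ]
  w5 <- tab[tab$I == 0.05, ]
  ok <- is.finite(w0$ASN) & is.finite(w5$ASN)
  expect_gte(sum(ok), 5)
  expect_gte(mean(w5$ASN[ok] <= w0$ASN[ok]), 0.8)
})

test_that("design table layout is deterministic and consistent with single designs", {
  tab <- generate_design_table(0.10, 1.1, c(0, 0.04),
                               termination_ratio = 1.0, shape = 2.2222)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$I, c(0, 0.04))
  cell <- design_repetitive_plan(
    design_setting(0.10, 0.10, 1.0, 2.2222, 1.1, 0.04))
  expect_equal(tab$n[tab$I == 0.04], cell$plan$n)
  expect_equal(tab$ASN[tab$I == 0.04], cell$asn, tolerance = 1e-12)
})

test_that("ill-separated quality levels are reported as having no usable plan", {
  # here every formally feasible plan resamples almost surely, so the
  # expected inspection volume explodes past the usability ceiling
  d <- design_repetitive_plan(design_setting(0.10, 0.10, 0.5, 1, 1.1, 0))
  expect_false(d$feasible)
  expect_null(d$plan)
  expect_true(is.na(d$asn))
  tab <- generate_design_table(0.10, 1.1, 0, termination_ratio = 0.5,
                               shape = 1)
  expect_true(is.na(tab$n[1]) && is.na(tab$ASN[1]))
})
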