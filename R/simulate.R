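#' Simulate Weibull lifetimes
#'
#' Draws i.i.d. classical Weibull lifetimes by the inverse-cdf transform
#' \eqn{x = \alpha(-\log(1-u))^{1/\beta}}; with a fixed seed the stream is
#' reproducible bitwise.
#'
#' @param n number of draws.
#' @param scale,shape Weibull parameters, `> 0`.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` non-negative lifetimes.
#' @examples
#' simulate_lifetimes(5, scale = 0.188, shape = 2.2222, seed = 1)
#' @export
simulate_lifetimes <- function(n, scale, shape, seed = NULL) {
  check_weibull_params(scale, shape)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  scale * (-log1p(-u))^(1 / shape)
}

#' Monte-Carlo verification of OC and ASN
#'
#' Empirical counterpart of the analytic operating characteristic and
#' average sample number: repeatedly runs the repetitive procedure (draw a
#' binomial failure count at failure fraction `p`, accept / reject /
#' resample until a terminal decision) and reports the acceptance fraction
#' and mean total items inspected. Per-stage failure counts are binomial
#' because each item fails before `t0` independently with probability
#' `p = F(t0)`.
#'
#' @param plan an [attribute_plan()].
#' @param p true failure fraction in `[0, 1]`.
#' @param replications number of independent runs of the procedure.
#' @param seed integer seed (all randomness is governed by it).
#' @param max_stages cap on resampling stages per replication; hitting it
#'   raises a warning (a diagnostic for pathological plans) and counts the
#'   replication as unresolved (excluded from the acceptance rate).
#' @return List with `accept_rate`, `mean_samples_used`, `replications`,
#'   and their analytic counterparts `oc` and `asn` for convenience.
#' @examples
#' mc <- monte_carlo_oc(attribute_plan(5, 0, 1), p = 0.2,
#'                      replications = 10000, seed = 7)
#' mc$accept_rate  # close to oc_value(attribute_plan(5, 0, 1), 0.2)
#' @export
monte_carlo_oc <- function(plan, p, replications = 200000L, seed = NULL,
                           max_stages = 10000L) {
  stopifnot(inherits(plan, "attribute_plan"))
  check_prob(p)
  if (replications < 1) stop("'replications' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  active <- rep.int(TRUE, replications)
  accepted <- logical(replications)
  resolved <- logical(replications)
  stages <- integer(replications)
  stage <- 0L
  while (any(active) && stage < max_stages) {
    stage <- stage + 1L
    idx <- which(active)
    d <- stats::rbinom(length(idx), plan$n, p)
    stages[idx] <- stage
    acc <- d <= plan$c1
    rej <- d > plan$c2
    done <- acc | rej
    accepted[idx[acc]] <- TRUE
    resolved[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }
  if (any(active)) {
    warning(sprintf("%d replication(s) unresolved after %d stages",
                    sum(active), max_stages), call. = FALSE)
  }
  list(
    accept_rate = sum(accepted) / sum(resolved),
    mean_samples_used = mean(as.numeric(stages) * plan$n),
    replications = replications,
    oc = oc_value(plan, p),
    asn = average_sample_number(plan, p)
  )
}

#' Synthetic stand-in for the Italy death-ratio data
#'
#' Generates a lifetime-like dataset emulating the packaged worked-example
#' data: Weibull draws with scale 0.188 and shape 2.2222 (the parameters
#' the real ratios are well fitted by). Useful for tests that must not
#' depend on the real fixture.
#'
#' @param n number of values (default 111, the fixture's length).
#' @param seed integer seed.
#' @return Numeric vector of positive values with a `"label"` attribute
#'   marking it as synthetic.
#' @examples
#' x <- generate_covid_like_dataset(seed = 42)
#' @export
generate_covid_like_dataset <- function(n = 111L, seed = NULL) {
  x <- simulate_lifetimes(n, scale = 0.188, shape = 2.2222, seed = seed)
  attr(x, "label") <- "synthetic Weibull(0.188, 2.2222) ratios"
  x
}
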