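#' Count failures in a truncated life test
#'
#' In a type-I time-truncated life test an item "fails" when its lifetime
#' (or lifetime-like ratio) does not exceed the truncation time, so the
#' failure count among `n` items is binomial with `p = F(t0)`.
#'
#' @param values non-negative lifetime/ratio observations.
#' @param t0 truncation time, on the scale of `values`.
#' @return Integer count of observations `<= t0`.
#' @examples
#' count_failures(covid_italy_ratios(), t0 = 0.1665)
#' @export
count_failures <- function(values, t0) {
  if (!is.numeric(values) || !length(values)) {
    stop("'values' must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(values < 0)) stop("'values' must be non-negative", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || t0 <= 0) {
    stop("'t0' must be a single positive number", call. = FALSE)
  }
  sum(values <= t0)
}

#' Repetitive-plan decision from a failure count
#'
#' Applies the repetitive counting rule: accept when `failures <= c1`,
#' reject when `failures > c2`, otherwise draw a fresh sample
#' (`"resample"`). Both boundaries are inclusive on the accept side,
#' consistent with the binomial accept/reject probabilities
#' (`Pa` sums to `c1` inclusive, `Pr` is the complement beyond `c2`).
#'
#' @param failures observed failure count, `0 <= failures <= n`.
#' @param plan an [attribute_plan()].
#' @param t0 optional truncation time recorded in the outcome.
#' @return An object of class `"test_outcome"`: list with `decision`
#'   (one of `"accept"`, `"reject"`, `"resample"`), `failures`,
#'   `truncation_time` and `plan`.
#' @examples
#' repetitive_decision(58, attribute_plan(114, 58, 66))  # accept
#' repetitive_decision(67, attribute_plan(114, 58, 66))  # reject
#' @export
repetitive_decision <- function(failures, plan, t0 = NA_real_) {
  stopifnot(inherits(plan, "attribute_plan"))
  if (!is.numeric(failures) || length(failures) != 1L ||
      failures != round(failures)) {
    stop("'failures' must be a single integer", call. = FALSE)
  }
  if (failures < 0 || failures > plan$n) {
    stop("'failures' must lie in 0..n", call. = FALSE)
  }
  decision <- if (failures <= plan$c1) {
    "accept"
  } else if (failures > plan$c2) {
    "reject"
  } else {
    "resample"
  }
  structure(
    list(decision = decision, failures = as.integer(failures),
         truncation_time = t0, plan = plan),
    class = "test_outcome"
  )
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("truncated life test: %d failures", x$failures))
  if (is.finite(x$truncation_time)) cat(sprintf(" at t0 = %g", x$truncation_time))
  cat(sprintf(" under plan (n = %d, c1 = %d, c2 = %d)\n",
              x$plan$n, x$plan$c1, x$plan$c2))
  cat("decision:", toupper(x$decision), "\n")
  invisible(x)
}

#' Apply a plan to observed data
#'
#' Runs one stage of the truncated life test on observed data: takes the
#' first `n` observations (or a seed-controlled random subsample), counts
#' failures at `t0` and returns the repetitive decision. If fewer than `n`
#' observations are available, all of them are used, with a warning.
#'
#' @param values non-negative observations.
#' @param plan an [attribute_plan()].
#' @param t0 truncation time on the data scale.
#' @param subsample `"first"` (default: first `n` values in file order) or
#'   `"random"` (seeded random subsample).
#' @param seed RNG seed used when `subsample = "random"`.
#' @return A `"test_outcome"` (see [repetitive_decision()]).
#' @export
apply_plan <- function(values, plan, t0, subsample = c("first", "random"),
                       seed = NULL) {
  stopifnot(inherits(plan, "attribute_plan"))
  subsample <- match.arg(subsample)
  if (length(values) < plan$n) {
    warning(sprintf("only %d observations available for a plan with n = %d; using all",
                    length(values), plan$n), call. = FALSE)
    sub <- values
  } else if (subsample == "first") {
    sub <- values[seq_len(plan$n)]
  } else {
    if (!is.null(seed)) set.seed(seed)
    sub <- sample(values, plan$n)
  }
  repetitive_decision(count_failures(sub, t0), plan, t0 = t0)
}

#' Worked example: COVID-19 daily death ratios, Italy 2020
#'
#' End-to-end illustration on the packaged dataset of 111 daily
#' death-to-new-case ratios (Italy, 1 April - 20 July 2020): fit the
#' Weibull model by maximum likelihood, take the fitted mean (rounded to
#' 4 decimals, as the specified mean \eqn{\mu_0} of the hypothesis
#' H0: \eqn{\mu = \mu_0}) and the fitted shape (rounded to 4 decimals, as
#' the specified shape), design the minimal-ASN repetitive plan at
#' producer risk 0.10, consumer risk 0.10, termination ratio 1.0,
#' mean ratio 1.1 and indeterminacy 0.04, and apply it to the data at
#' `t0 = a * mu0`.
#'
#' @param verbose print a report? Default `TRUE`.
#' @return (Invisibly) a list with the `fit`, `mu0`, `setting`, `design`,
#'   `failures` and `outcome`.
#' @examples
#' \donttest{
#' run_worked_example(verbose = FALSE)$design$plan
#' }
#' @export
run_worked_example <- function(verbose = TRUE) {
  x <- covid_italy_ratios()
  fit <- fit_weibull_mle(x)
  shape0 <- round(fit$estimates[["shape"]], 4)
  mu0 <- round(fit$mean, 4)
  setting <- design_setting(producer_risk = 0.10, consumer_risk = 0.10,
                            termination_ratio = 1.0, shape = shape0,
                            mean_ratio = 1.1, indeterminacy = 0.04)
  design <- design_repetitive_plan(setting, n_max = 2000L)
  t0 <- setting$termination_ratio * mu0
  failures <- count_failures(x, t0)
  outcome <- suppressWarnings(apply_plan(x, design$plan, t0))
  if (verbose) {
    cat("Worked example: daily death ratios, Italy, 1 Apr - 20 Jul 2020\n")
    cat(sprintf("  Weibull MLE: shape = %.4f, scale = %.4f; fitted mean mu0 = %.4f\n",
                fit$estimates[["shape"]], fit$estimates[["scale"]], mu0))
    cat(sprintf("  design at (alpha~ = 0.10, beta~ = 0.10, a = 1.0, ratio = 1.1, I = 0.04):\n"))
    cat(sprintf("    plan n = %d, c1 = %d, c2 = %d, ASN = %.2f\n",
                design$plan$n, design$plan$c1, design$plan$c2, design$asn))
    cat(sprintf("  truncated life test at t0 = %.4f: %d of %d ratios at or below t0\n",
                t0, failures, length(x)))
    cat(sprintf("  decision: %s\n", toupper(outcome$decision)))
  }
  invisible(list(fit = fit, mu0 = mu0, setting = setting, design = design,
                 failures = failures, outcome = outcome))
}
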