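#' Neutrosophic Weibull density
#'
#' Density of the Weibull distribution under neutrosophic indeterminacy.
#' The indeterminate form scales the classical density by `(1 + I)`, where
#' `I` is the indeterminacy level; `I = 0` recovers the classical Weibull
#' density exactly.
#'
#' @param x vector of non-negative quantiles.
#' @param scale Weibull scale parameter \eqn{\alpha > 0} (same units as `x`).
#' @param shape Weibull shape parameter \eqn{\beta > 0} (dimensionless).
#' @param indeterminacy indeterminacy level \eqn{I \ge 0}; may be a vector,
#'   e.g. the two endpoints of an indeterminacy interval
#'   (see [indeterminacy_interval()]).
#'
#' @return Numeric vector of densities, recycled over `x` and `indeterminacy`.
#' @seealso [pweibull_ind()], [mean_weibull_ind()]
#' @examples
#' dweibull_ind(0.188, scale = 0.188, shape = 1)          # (1/alpha) exp(-1)
#' dweibull_ind(0.1, scale = 0.188, shape = 2.2222, indeterminacy = 0.04)
#' @export
dweibull_ind <- function(x, scale, shape, indeterminacy = 0) {
  check_weibull_params(scale, shape)
  check_indeterminacy(indeterminacy)
  if (any(x < 0)) stop("'x' must be non-negative", call. = FALSE)
  stats::dweibull(x, shape = shape, scale = scale) * (1 + indeterminacy)
}

#' Neutrosophic Weibull cumulative distribution function
#'
#' Distribution function of the Weibull model under indeterminacy,
#' \deqn{F(x) = 1 - e^{-(x/\alpha)^\beta}(1 + I) + I.}
#' The value is returned in this raw form: for \eqn{I > 0} it exceeds the
#' classical cdf and tends to \eqn{1 + I} as \eqn{x \to \infty}. No clamping
#' is applied at this layer; quantities fed to binomial probabilities
#' (see [failure_fraction()]) are clamped there.
#'
#' @inheritParams dweibull_ind
#' @param q vector of non-negative quantiles.
#' @return Numeric vector; equals the classical Weibull cdf when
#'   `indeterminacy = 0`, and is exactly 0 at `q = 0` for any `I`.
#' @examples
#' pweibull_ind(0.188, scale = 0.188, shape = 1)   # 1 - exp(-1)
#' pweibull_ind(0, scale = 1, shape = 2, indeterminacy = 0.05)  # exactly 0
#' @export
pweibull_ind <- function(q, scale, shape, indeterminacy = 0) {
  check_weibull_params(scale, shape)
  check_indeterminacy(indeterminacy)
  if (any(q < 0)) stop("'q' must be non-negative", call. = FALSE)
  1 - exp(-(q / scale)^shape) * (1 + indeterminacy) + indeterminacy
}

#' Neutrosophic Weibull mean
#'
#' Mean of the Weibull distribution under indeterminacy,
#' \eqn{\mu = \alpha \Gamma(1 + 1/\beta)(1 + I)}.
#'
#' @inheritParams dweibull_ind
#' @return Positive numeric vector.
#' @examples
#' mean_weibull_ind(0.1880, 2.2222)           # ~0.1665
#' mean_weibull_ind(1, 2, indeterminacy = 0.05)  # 1.05 * sqrt(pi)/2
#' @export
mean_weibull_ind <- function(scale, shape, indeterminacy = 0) {
  check_weibull_params(scale, shape)
  check_indeterminacy(indeterminacy)
  scale * gamma_one_plus_inv(shape) * (1 + indeterminacy)
}

# Gamma(1 + 1/beta) through the log-gamma route; identical to
# Gamma(1/beta)/beta by the recurrence Gamma(z + 1) = z Gamma(z).
gamma_one_plus_inv <- function(shape) {
  exp(lgamma(1 + 1 / shape))
}

#' Indeterminacy interval
#'
#' A neutrosophic indeterminacy level is an interval `[lower, upper]` with
#' `0 <= lower <= upper`. A degenerate interval (`lower == upper`) represents
#' a single specified level, the form under which design tables are indexed;
#' `c(0, 0)` recovers classical statistics.
#'
#' @param lower,upper interval endpoints, `0 <= lower <= upper`.
#' @return A length-2 numeric vector of class `"indeterminacy_interval"`.
#' @examples
#' indeterminacy_interval(0, 0.04)
#' indeterminacy_interval(0.05)     # degenerate: the tables' I_U form
#' @export
indeterminacy_interval <- function(lower, upper = lower) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L) {
    stop("'lower' and 'upper' must be single numbers", call. = FALSE)
  }
  if (lower < 0 || upper < lower) {
    stop("need 0 <= lower <= upper", call. = FALSE)
  }
  structure(c(lower = lower, upper = upper), class = "indeterminacy_interval")
}

#' @export
print.indeterminacy_interval <- function(x, ...) {
  cat(sprintf("indeterminacy interval [%g, %g]\n", x[["lower"]], x[["upper"]]))
  invisible(x)
}

#' Design setting for a truncated-life-test sampling plan
#'
#' Bundles the quantities that define a two-point plan design: producer and
#' consumer risks, termination ratio, Weibull shape, mean ratio and the
#' indeterminacy level.
#'
#' The truncation time is `t0 = termination_ratio * mu0`, where `mu0` is the
#' specified mean. The producer's constraint binds at the acceptable quality
#' level (failure fraction at `mean_ratio`), the consumer's at the limiting
#' quality level (`mean_ratio = 1`, i.e. the null hypothesis point).
#'
#' @param producer_risk maximum probability of rejecting a good lot,
#'   \eqn{\tilde\alpha \in (0,1)}.
#' @param consumer_risk maximum probability of accepting a bad lot,
#'   \eqn{\tilde\beta \in (0,1)}.
#' @param termination_ratio truncation time as a multiple of the specified
#'   mean, `a > 0`.
#' @param shape Weibull shape parameter \eqn{\beta > 0}.
#' @param mean_ratio ratio of true to specified mean, \eqn{\mu/\mu_0 \ge 1};
#'   `1` defines the limiting quality level.
#' @param indeterminacy single indeterminacy level \eqn{I \ge 0} (design
#'   tables are indexed by the interval's upper endpoint).
#'
#' @return An object of class `"design_setting"`.
#' @examples
#' design_setting(0.10, 0.10, termination_ratio = 1.0, shape = 2.2222,
#'                mean_ratio = 1.1, indeterminacy = 0.04)
#' @export
design_setting <- function(producer_risk, consumer_risk, termination_ratio,
                           shape, mean_ratio = 1, indeterminacy = 0) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
    v
  }
  producer_risk <- num1(producer_risk, "producer_risk")
  consumer_risk <- num1(consumer_risk, "consumer_risk")
  termination_ratio <- num1(termination_ratio, "termination_ratio")
  shape <- num1(shape, "shape")
  mean_ratio <- num1(mean_ratio, "mean_ratio")
  indeterminacy <- num1(indeterminacy, "indeterminacy")
  if (producer_risk <= 0 || producer_risk >= 1) {
    stop("'producer_risk' must lie in (0, 1)", call. = FALSE)
  }
  if (consumer_risk <= 0 || consumer_risk >= 1) {
    stop("'consumer_risk' must lie in (0, 1)", call. = FALSE)
  }
  if (termination_ratio <= 0) stop("'termination_ratio' must be > 0", call. = FALSE)
  if (shape <= 0) stop("'shape' must be > 0", call. = FALSE)
  if (mean_ratio < 1) stop("'mean_ratio' must be >= 1", call. = FALSE)
  if (indeterminacy < 0) stop("'indeterminacy' must be >= 0", call. = FALSE)
  structure(
    list(producer_risk = producer_risk, consumer_risk = consumer_risk,
         termination_ratio = termination_ratio, shape = shape,
         mean_ratio = mean_ratio, indeterminacy = indeterminacy),
    class = "design_setting"
  )
}

#' @export
print.design_setting <- function(x, ...) {
  cat("Design setting (time-truncated life test)\n")
  cat(sprintf("  producer risk: %g   consumer risk: %g\n",
              x$producer_risk, x$consumer_risk))
  cat(sprintf("  termination ratio a: %g   Weibull shape: %g\n",
              x$termination_ratio, x$shape))
  cat(sprintf("  mean ratio: %g   indeterminacy: %g\n",
              x$mean_ratio, x$indeterminacy))
  cat(sprintf("  failure fractions: p1 = %.6f (AQL), p2 = %.6f (LQL)\n",
              aql_fraction(x), lql_fraction(x)))
  invisible(x)
}

#' Failure fraction of a truncated life test
#'
#' Probability that an item fails before the truncation time
#' `t0 = a * mu0` when lifetimes are Weibull with mean `mean_ratio * mu0`
#' under indeterminacy `I`:
#' \deqn{p = 1 - \exp\{-a^\beta (\mu/\mu_0)^{-\beta}
#'       \Gamma(1+1/\beta)^\beta (1+I)^\beta\}(1+I) + I.}
#' Because of the additive `I` term the raw expression can exceed 1; since
#' the fraction feeds a binomial failure count it is clamped into
#' \eqn{[0, 1]} (with a warning) when `clamp = TRUE`.
#'
#' @param termination_ratio truncation time as a multiple of the specified
#'   mean.
#' @param shape Weibull shape.
#' @param mean_ratio ratio of true to specified mean (`1` at the limiting
#'   quality level).
#' @param indeterminacy indeterminacy level `I >= 0`.
#' @param clamp clamp the result into `[0, 1]`? Default `TRUE`.
#' @return The failure fraction (a probability when `clamp = TRUE`).
#' @seealso [aql_fraction()], [lql_fraction()]
#' @examples
#' failure_fraction(0.5, shape = 1, mean_ratio = 2)   # 1 - exp(-0.25)
#' failure_fraction(1, shape = 2)                     # 1 - exp(-pi/4)
#' @export
failure_fraction <- function(termination_ratio, shape, mean_ratio = 1,
                             indeterminacy = 0, clamp = TRUE) {
  if (termination_ratio <= 0 || shape <= 0) {
    stop("'termination_ratio' and 'shape' must be > 0", call. = FALSE)
  }
  check_indeterminacy(indeterminacy)
  g <- gamma_one_plus_inv(shape)
  p <- 1 - exp(-termination_ratio^shape * mean_ratio^(-shape) *
                 g^shape * (1 + indeterminacy)^shape) *
    (1 + indeterminacy) + indeterminacy
  if (clamp) {
    out <- pmin(pmax(p, 0), 1)
    if (any(out != p)) {
      warning("failure fraction outside [0, 1] clamped", call. = FALSE)
    }
    out
  } else {
    p
  }
}

#' Failure fraction at the acceptable quality level (AQL)
#'
#' The failure fraction `p1` at the setting's `mean_ratio`, i.e. the point
#' at which the producer's risk constraint binds.
#'
#' @param setting a [design_setting()].
#' @return A probability (clamped into `[0, 1]`).
#' @export
aql_fraction <- function(setting) {
  stopifnot(inherits(setting, "design_setting"))
  failure_fraction(setting$termination_ratio, setting$shape,
                   setting$mean_ratio, setting$indeterminacy)
}

#' Failure fraction at the limiting quality level (LQL)
#'
#' The failure fraction `p2` at `mean_ratio = 1` (the null hypothesis
#' point), where the consumer's risk constraint binds.
#'
#' @inheritParams aql_fraction
#' @return A probability (clamped into `[0, 1]`).
#' @export
lql_fraction <- function(setting) {
  stopifnot(inherits(setting, "design_setting"))
  failure_fraction(setting$termination_ratio, setting$shape,
                   1, setting$indeterminacy)
}

# -- internal parameter checks ---------------------------------------------

check_weibull_params <- function(scale, shape) {
  if (any(scale <= 0) || any(shape <= 0)) {
    stop("Weibull 'scale' and 'shape' must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

check_indeterminacy <- function(indeterminacy) {
  if (!is.numeric(indeterminacy) || any(indeterminacy < 0)) {
    stop("'indeterminacy' must be numeric and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}
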