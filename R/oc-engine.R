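#' Attribute plan for repetitive sampling
#'
#' The triple `(n, c1, c2)` defining a repetitive acceptance sampling plan:
#' draw `n` items, count failures `d` in the truncated life test; accept the
#' lot if `d <= c1`, reject if `d > c2`, otherwise draw a fresh sample and
#' repeat. `c1 == c2` reduces the scheme to a single sampling plan.
#'
#' @param n sample size per stage (positive integer).
#' @param c1 acceptance number, `0 <= c1`.
#' @param c2 rejection threshold, `c1 <= c2 <= n`.
#' @return An object of class `"attribute_plan"`.
#' @examples
#' attribute_plan(114, 58, 66)
#' attribute_plan(5, 2, 2)   # single sampling plan
#' @export
attribute_plan <- function(n, c1, c2 = c1) {
  int1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v)) {
      stop(sprintf("'%s' must be a single integer", nm), call. = FALSE)
    }
    as.integer(v)
  }
  n <- int1(n, "n"); c1 <- int1(c1, "c1"); c2 <- int1(c2, "c2")
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (c1 < 0L || c1 > c2 || c2 > n) {
    stop("need 0 <= c1 <= c2 <= n", call. = FALSE)
  }
  structure(list(n = n, c1 = c1, c2 = c2), class = "attribute_plan")
}

#' @export
print.attribute_plan <- function(x, ...) {
  kind <- if (x$c1 == x$c2) "single sampling plan" else "repetitive sampling plan"
  cat(sprintf("%s: n = %d, c1 = %d, c2 = %d\n", kind, x$n, x$c1, x$c2))
  invisible(x)
}

check_prob <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("'p' must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Stage acceptance probability
#'
#' Probability that a single stage of the plan accepts outright:
#' \eqn{P_a(p) = P(X \le c_1)} for \eqn{X \sim Binomial(n, p)}.
#' Binomial tails are computed by [stats::pbinom()] (the regularized
#' incomplete beta function), stable for `n` in the hundreds.
#'
#' @param plan an [attribute_plan()].
#' @param p failure fraction(s) in `[0, 1]`.
#' @return Probability vector.
#' @examples
#' accept_probability(attribute_plan(5, 0, 1), 0.2)  # 0.8^5
#' @export
accept_probability <- function(plan, p) {
  stopifnot(inherits(plan, "attribute_plan"))
  check_prob(p)
  stats::pbinom(plan$c1, plan$n, p)
}

#' Stage rejection probability
#'
#' Probability that a single stage rejects outright:
#' \eqn{P_r(p) = 1 - P(X \le c_2)}.
#'
#' @inheritParams accept_probability
#' @return Probability vector.
#' @export
reject_probability <- function(plan, p) {
  stopifnot(inherits(plan, "attribute_plan"))
  check_prob(p)
  stats::pbinom(plan$c2, plan$n, p, lower.tail = FALSE)
}

#' Operating characteristic of a repetitive plan
#'
#' Probability that a lot with failure fraction `p` is ultimately accepted:
#' \deqn{L(p) = \frac{P_a(p)}{P_a(p) + P_r(p)},}
#' the terminal acceptance probability of the resampling scheme. At the
#' endpoints, `L(0) = 1` and (for `c1 < n`) `L(1) = 0` by limit. When
#' `c1 == c2` the denominator is 1 and `L(p) = accept_probability(plan, p)`.
#'
#' @inheritParams accept_probability
#' @return Probability vector.
#' @examples
#' oc_value(attribute_plan(5, 0, 1), 0.2)  # ~0.555014
#' @export
oc_value <- function(plan, p) {
  pa <- accept_probability(plan, p)
  pr <- reject_probability(plan, p)
  tot <- pa + pr
  out <- ifelse(tot > 0, pa / tot, NA_real_)
  # p = 1 with c1 < n <= c2 would give 0/0; the plan then never terminates
  if (anyNA(out)) {
    stop("OC undefined: accept and reject probabilities are both zero",
         call. = FALSE)
  }
  out
}

#' Average sample number of a repetitive plan
#'
#' Expected total number of items inspected before a terminal decision:
#' \eqn{ASN(p) = n / (P_a(p) + P_r(p))}. Always at least `n`, with equality
#' exactly when every stage terminates (`Pa + Pr = 1`, in particular for any
#' single sampling plan `c1 == c2`).
#'
#' @inheritParams accept_probability
#' @return Numeric vector, `>= n`.
#' @examples
#' average_sample_number(attribute_plan(5, 0, 1), 0.2)  # ~8.4688
#' @export
average_sample_number <- function(plan, p) {
  pa <- accept_probability(plan, p)
  pr <- reject_probability(plan, p)
  tot <- pa + pr
  if (any(tot <= 0)) {
    stop("ASN undefined: accept and reject probabilities are both zero",
         call. = FALSE)
  }
  plan$n / tot
}

#' Evaluate a plan at one failure fraction
#'
#' Convenience wrapper returning the stage probabilities, OC and ASN of a
#' plan at a failure fraction.
#'
#' @inheritParams accept_probability
#' @return A one-row `data.frame` with columns `p`, `accept_prob`,
#'   `reject_prob`, `oc`, `asn` (one row per element of `p`).
#' @export
oc_evaluation <- function(plan, p) {
  data.frame(
    p = p,
    accept_prob = accept_probability(plan, p),
    reject_prob = reject_probability(plan, p),
    oc = oc_value(plan, p),
    asn = average_sample_number(plan, p)
  )
}
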