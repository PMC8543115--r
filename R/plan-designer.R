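#' Design a minimal-ASN repetitive sampling plan
#'
#' Solves the constrained integer program
#' \deqn{\min_{n, c_1, c_2} ASN \quad \text{s.t.}\quad
#'   L(p_1) \ge 1 - \tilde\alpha,\; L(p_2) \le \tilde\beta,\;
#'   0 \le c_1 \le c_2 \le n,}
#' where `p1`/`p2` are the failure fractions at the acceptable and limiting
#' quality levels of `setting`, by exact enumeration. The ASN objective is
#' evaluated, by default, at the limiting quality level (`mean_ratio = 1`,
#' the null-hypothesis operating point) — the convention under which the
#' package's design tables are reported; `objective = "aql"` evaluates it at
#' the acceptable quality level instead.
#'
#' The search enumerates `n` ascending and exploits two monotonicities: for
#' fixed `(n, c1)` the feasible `c2` form an interval and the ASN is
#' increasing in `c2`, so only the smallest feasible `c2` is a candidate;
#' and `ASN >= n` always, so the scan stops once `n` exceeds the best ASN
#' found (or `asn_max`). The result is the exact global optimum within the
#' bounds, with ties broken by smaller `n`, then smaller `c1`.
#'
#' A setting is reported infeasible when no plan with `ASN <= asn_max`
#' exists within `n <= n_max`: for ill-separated quality levels formally
#' feasible plans exist whose accept and reject probabilities are both
#' nearly zero, so the scheme resamples almost every stage and the expected
#' inspection volume explodes; such plans are not usable designs.
#'
#' @param setting a [design_setting()].
#' @param n_max largest stage sample size searched (default 500).
#' @param c_max largest acceptance/rejection number searched (default
#'   `min(n, n_max)`).
#' @param asn_max usability ceiling on the expected sample number
#'   (default 1150).
#' @param objective quality level at which the ASN objective is evaluated:
#'   `"lql"` (default) or `"aql"`.
#' @return An object of class `"design_result"`: a list with the `plan`
#'   (an [attribute_plan()], or `NULL` if infeasible), `feasible`, `asn`
#'   (at the objective level), `asn_aql`, `asn_lql`, `oc_aql`, `oc_lql`,
#'   `p_aql`, `p_lql`, the `setting` and the `search_bounds`.
#' @examples
#' s <- design_setting(0.10, 0.10, 1.0, 2.2222, 1.1, 0.04)
#' design_repetitive_plan(s)   # n = 114, c1 = 58, c2 = 66, ASN = 191.67
#' @export
design_repetitive_plan <- function(setting, n_max = 500L, c_max = n_max,
                                   asn_max = 1150,
                                   objective = c("lql", "aql")) {
  stopifnot(inherits(setting, "design_setting"))
  objective <- match.arg(objective)
  if (n_max < 1L) stop("'n_max' must be >= 1", call. = FALSE)
  p1 <- aql_fraction(setting)
  p2 <- lql_fraction(setting)
  pr <- setting$producer_risk
  cr <- setting$consumer_risk
  # L(p1) >= 1 - pr  <=>  Pr(p1) <= Pa(p1) * pr / (1 - pr)
  # L(p2) <= cr      <=>  Pr(p2) >= Pa(p2) * (1 - cr) / cr
  r_acc <- pr / (1 - pr)
  r_rej <- (1 - cr) / cr

  best <- NULL
  best_asn <- Inf
  for (n in seq_len(n_max)) {
    if (n > min(best_asn, asn_max)) break
    cm <- min(n, c_max)
    idx <- 0:cm
    pa1 <- stats::pbinom(idx, n, p1)
    pr1 <- stats::pbinom(idx, n, p1, lower.tail = FALSE)
    pa2 <- stats::pbinom(idx, n, p2)
    pr2 <- stats::pbinom(idx, n, p2, lower.tail = FALSE)
    # smallest c2 with pr1[c2] <= pa1[c1] * r_acc   (pr1 non-increasing)
    c2_lo <- cm + 1L - findInterval(pa1 * r_acc, rev(pr1))
    # largest c2 with pr2[c2] >= pa2[c1] * r_rej
    c2_hi <- cm - findInterval(pa2 * r_rej, rev(pr2), left.open = TRUE)
    c2_cand <- pmax(c2_lo, idx)
    feas <- c2_lo <= cm & c2_cand <= c2_hi
    if (!any(feas)) next
    c1f <- idx[feas]
    c2f <- c2_cand[feas]
    asn <- if (objective == "lql") {
      n / (pa2[feas] + pr2[c2f + 1L])
    } else {
      n / (pa1[feas] + pr1[c2f + 1L])
    }
    asn[asn > asn_max] <- Inf
    j <- which.min(asn)
    if (asn[j] < best_asn) {
      best_asn <- asn[j]
      best <- c(n, c1f[j], c2f[j])
    }
  }

  bounds <- c(n_max = as.integer(n_max), c_max = as.integer(c_max),
              asn_max = asn_max)
  if (is.null(best)) {
    return(structure(
      list(plan = NULL, feasible = FALSE, asn = NA_real_,
           asn_aql = NA_real_, asn_lql = NA_real_,
           oc_aql = NA_real_, oc_lql = NA_real_,
           p_aql = p1, p_lql = p2, objective = objective,
           setting = setting, search_bounds = bounds),
      class = "design_result"
    ))
  }
  plan <- attribute_plan(best[1], best[2], best[3])
  structure(
    list(plan = plan, feasible = TRUE, asn = best_asn,
         asn_aql = average_sample_number(plan, p1),
         asn_lql = average_sample_number(plan, p2),
         oc_aql = oc_value(plan, p1),
         oc_lql = oc_value(plan, p2),
         p_aql = p1, p_lql = p2, objective = objective,
         setting = setting, search_bounds = bounds),
    class = "design_result"
  )
}

#' Design a minimal-n single sampling plan
#'
#' The special case `c1 == c2 == c` of the repetitive scheme: every stage
#' terminates, the OC reduces to the binomial acceptance probability and
#' `ASN = n`, so the plan minimizing the expected sample number is the one
#' with the smallest `n` satisfying
#' `Pa(p1) >= 1 - producer_risk` and `Pa(p2) <= consumer_risk`.
#'
#' @inheritParams design_repetitive_plan
#' @param n_max largest sample size searched (default 2000).
#' @return A `"design_result"` (with `asn == n` when feasible).
#' @examples
#' s <- design_setting(0.10, 0.25, 0.5, 2, 1.1, 0.02)
#' design_single_plan(s)$plan$n
#' @export
design_single_plan <- function(setting, n_max = 2000L) {
  stopifnot(inherits(setting, "design_setting"))
  p1 <- aql_fraction(setting)
  p2 <- lql_fraction(setting)
  pr <- setting$producer_risk
  cr <- setting$consumer_risk
  for (n in seq_len(n_max)) {
    cs <- 0:n
    ok <- stats::pbinom(cs, n, p1) >= 1 - pr &
      stats::pbinom(cs, n, p2) <= cr
    if (any(ok)) {
      plan <- attribute_plan(n, cs[which(ok)[1L]])
      return(structure(
        list(plan = plan, feasible = TRUE, asn = as.numeric(n),
             asn_aql = as.numeric(n), asn_lql = as.numeric(n),
             oc_aql = oc_value(plan, p1), oc_lql = oc_value(plan, p2),
             p_aql = p1, p_lql = p2, objective = "lql",
             setting = setting,
             search_bounds = c(n_max = as.integer(n_max),
                               c_max = as.integer(n_max),
                               asn_max = as.numeric(n_max))),
        class = "design_result"
      ))
    }
  }
  structure(
    list(plan = NULL, feasible = FALSE, asn = NA_real_,
         asn_aql = NA_real_, asn_lql = NA_real_,
         oc_aql = NA_real_, oc_lql = NA_real_,
         p_aql = p1, p_lql = p2, objective = "lql", setting = setting,
         search_bounds = c(n_max = as.integer(n_max),
                           c_max = as.integer(n_max),
                           asn_max = as.numeric(n_max))),
    class = "design_result"
  )
}

#' @export
print.design_result <- function(x, ...) {
  if (!x$feasible) {
    cat("No usable plan found within search bounds (n_max =",
        x$search_bounds[["n_max"]], ", asn_max =",
        x$search_bounds[["asn_max"]], ")\n")
    return(invisible(x))
  }
  print(x$plan)
  cat(sprintf("  ASN = %.2f (objective at %s), OC: L(p1) = %.4f, L(p2) = %.4f\n",
              x$asn, toupper(x$objective), x$oc_aql, x$oc_lql))
  cat(sprintf("  failure fractions: p1 = %.6f, p2 = %.6f\n",
              x$p_aql, x$p_lql))
  invisible(x)
}

#' Check a plan against the two-point risk constraints
#'
#' Evaluates the OC of `plan` at the setting's acceptable and limiting
#' quality levels and compares against `1 - producer_risk` and
#' `consumer_risk`.
#'
#' @param plan an [attribute_plan()].
#' @param setting a [design_setting()].
#' @return A list with `oc_aql`, `oc_lql`, `producer_ok`, `consumer_ok`
#'   and `feasible` (both constraints hold).
#' @examples
#' s <- design_setting(0.10, 0.10, 1.0, 2.2222, 1.1, 0.04)
#' check_feasibility(attribute_plan(114, 58, 66), s)
#' @export
check_feasibility <- function(plan, setting) {
  stopifnot(inherits(plan, "attribute_plan"),
            inherits(setting, "design_setting"))
  l1 <- oc_value(plan, aql_fraction(setting))
  l2 <- oc_value(plan, lql_fraction(setting))
  producer_ok <- l1 >= 1 - setting$producer_risk
  consumer_ok <- l2 <= setting$consumer_risk
  list(oc_aql = l1, oc_lql = l2,
       producer_ok = producer_ok, consumer_ok = consumer_ok,
       feasible = producer_ok && consumer_ok)
}

#' Generate a grid of plan designs
#'
#' Designs one repetitive plan per combination of consumer risk, mean ratio
#' and indeterminacy level at fixed producer risk, termination ratio and
#' shape — the layout of the package's design tables (consumer risk varies
#' slowest, then mean ratio; one block of columns per indeterminacy level
#' is obtained by filtering the long format returned here).
#'
#' @param consumer_risks vector of consumer risks.
#' @param mean_ratios vector of mean ratios (each `>= 1`).
#' @param indeterminacies vector of indeterminacy levels.
#' @param producer_risk single producer risk (default 0.10).
#' @param termination_ratio termination ratio `a`.
#' @param shape Weibull shape.
#' @inheritParams design_repetitive_plan
#' @return A `data.frame` with columns `beta_risk`, `ratio`, `I`, `n`,
#'   `c1`, `c2`, `ASN`; infeasible cells carry `NA` in the plan columns.
#' @examples
#' generate_design_table(0.10, 1.1, c(0, 0.04),
#'                       termination_ratio = 1.0, shape = 2.2222)
#' @export
generate_design_table <- function(consumer_risks, mean_ratios,
                                  indeterminacies,
                                  producer_risk = 0.10,
                                  termination_ratio, shape,
                                  n_max = 500L, c_max = n_max,
                                  asn_max = 1150,
                                  objective = c("lql", "aql")) {
  objective <- match.arg(objective)
  if (!length(consumer_risks) || !length(mean_ratios) ||
      !length(indeterminacies)) {
    stop("all grids must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(I = indeterminacies, ratio = mean_ratios,
                      beta_risk = consumer_risks,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("beta_risk", "ratio", "I")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- design_setting(producer_risk, grid$beta_risk[i],
                        termination_ratio, shape,
                        grid$ratio[i], grid$I[i])
    d <- design_repetitive_plan(s, n_max = n_max, c_max = c_max,
                                asn_max = asn_max, objective = objective)
    if (d$feasible) {
      data.frame(beta_risk = grid$beta_risk[i], ratio = grid$ratio[i],
                 I = grid$I[i], n = d$plan$n, c1 = d$plan$c1,
                 c2 = d$plan$c2, ASN = d$asn)
    } else {
      data.frame(beta_risk = grid$beta_risk[i], ratio = grid$ratio[i],
                 I = grid$I[i], n = NA_integer_, c1 = NA_integer_,
                 c2 = NA_integer_, ASN = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
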