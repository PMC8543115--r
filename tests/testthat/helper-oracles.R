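# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: binomial tails by direct summation of the
# pmf written out with choose(), and plan search by exhaustive enumeration.

binom_pmf_oracle <- function(i, n, p) {
  choose(n, i) * p^i * (1 - p)^(n - i)
}

accept_oracle <- function(n, c1, p) {
  sum(binom_pmf_oracle(0:c1, n, p))
}

reject_oracle <- function(n, c2, p) {
  if (c2 >= n) 0 else sum(binom_pmf_oracle((c2 + 1):n, n, p))
}

oc_oracle <- function(n, c1, c2, p) {
  pa <- accept_oracle(n, c1, p)
  pr <- reject_oracle(n, c2, p)
  pa / (pa + pr)
}

asn_oracle <- function(n, c1, c2, p) {
  n / (accept_oracle(n, c1, p) + reject_oracle(n, c2, p))
}

# Exhaustive enumeration over all (n, c1, c2) within bounds; objective is
# the ASN at the limiting quality level, ties broken by the enumeration
# order (n, then c1, then c2 ascending) under strict improvement.
exhaustive_design_oracle <- function(setting, n_max, c_max = n_max,
                                     asn_max = Inf) {
  p1 <- aql_fraction(setting)
  p2 <- lql_fraction(setting)
  best <- NULL
  best_asn <- Inf
  for (n in 1:n_max) {
    cm <- min(n, c_max)
    pmf1 <- binom_pmf_oracle(0:n, n, p1)
    pmf2 <- binom_pmf_oracle(0:n, n, p2)
    cdf1 <- cumsum(pmf1)
    cdf2 <- cumsum(pmf2)
    # upper tails by direct summation (avoids 1 - cdf cancellation)
    up1 <- rev(cumsum(rev(pmf1)))
    up2 <- rev(cumsum(rev(pmf2)))
    tail1 <- function(c2) if (c2 >= n) 0 else up1[c2 + 2]
    tail2 <- function(c2) if (c2 >= n) 0 else up2[c2 + 2]
    for (c1 in 0:cm) {
      for (c2 in c1:cm) {
        l1 <- cdf1[c1 + 1] / (cdf1[c1 + 1] + tail1(c2))
        l2 <- cdf2[c1 + 1] / (cdf2[c1 + 1] + tail2(c2))
        if (l1 >= 1 - setting$producer_risk && l2 <= setting$consumer_risk) {
          asn <- n / (cdf2[c1 + 1] + tail2(c2))
          if (asn <= asn_max && asn < best_asn) {
            best_asn <- asn
            best <- list(n = n, c1 = c1, c2 = c2, asn = asn)
          }
        }
      }
    }
  }
  best
}
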