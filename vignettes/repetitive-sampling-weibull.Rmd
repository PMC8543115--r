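---
title: "Repetitive acceptance sampling for Weibull lifetimes under indeterminacy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repetitive acceptance sampling for Weibull lifetimes under indeterminacy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raspweib)
```

## The testing problem

A monitor — a health administrator tracking daily death-to-case ratios, or
a reliability engineer testing components — wants to decide whether the mean
$\mu$ of a lifetime-like quantity equals a specified value $\mu_0$, using as
few observations as possible. Observations are expensive, so instead of
estimating $\mu$ precisely, each sampled item is watched only until a fixed
truncation time $t_0 = a\mu_0$ (the *termination ratio* $a$ expresses $t_0$
in units of the specified mean) and we record only whether it "failed"
(value $\le t_0$) or not. If lifetimes follow a known distribution, each
item fails independently with probability $p = F(t_0)$, so the number of
failures among $n$ items is Binomial$(n, p)$ and the whole decision problem
reduces to an attribute sampling plan.

The repetitive scheme uses a triple $(n, c_1, c_2)$ with
$0 \le c_1 \le c_2 \le n$: draw $n$ items, count failures $d$;
accept $H_0$ if $d \le c_1$, reject if $d > c_2$, and otherwise discard the
sample and repeat with a fresh one. With stage-wise accept and reject
probabilities
$$P_a(p) = \sum_{i=0}^{c_1} \binom{n}{i} p^i (1-p)^{n-i}, \qquad
  P_r(p) = 1 - \sum_{i=0}^{c_2} \binom{n}{i} p^i (1-p)^{n-i},$$
the probability of *ultimately* accepting is the operating characteristic
$$L(p) = \frac{P_a(p)}{P_a(p) + P_r(p)},$$
and since the number of stages is geometric with success probability
$P_a + P_r$, the expected total inspection effort is the average sample
number
$$ASN(p) = \frac{n}{P_a(p) + P_r(p)} \ \ge\ n .$$
When $c_1 = c_2$ every stage terminates, $L(p) = P_a(p)$ and $ASN = n$: the
classical single sampling plan is the degenerate special case. The appeal
of the repetitive scheme is that the indecision band $(c_1, c_2]$ lets a
much smaller $n$ achieve the same discrimination, at the price of
occasional resampling.

## Indeterminacy

Recorded epidemic (and reliability) data are often imprecise — uncertain
case counts, reporting lags — and neutrosophic statistics quantifies this
through an indeterminacy level $I \in [I_L, I_U]$. The package uses the
indeterminacy-scaled Weibull family: density
$f_N(x) = (1 + I)\, f(x)$ where $f$ is the classical Weibull
pdf with scale $\alpha$ and shape $\beta$, cdf
$$F_N(x) = 1 - e^{-(x/\alpha)^\beta}(1 + I) + I ,$$
and mean $\mu_N = \alpha\,\Gamma(1 + 1/\beta)\,(1 + I)$. At $I = 0$
everything reduces to classical statistics. Two numerical points deserve
note:

* As printed, $F_N(x) \to 1 + I$ as $x \to \infty$: the indeterminate cdf
  is not a normalized probability. `pweibull_ind()` reports this raw form
  faithfully; the *failure fractions* fed into binomial probabilities are
  clamped into $[0,1]$ (with a warning) by `failure_fraction()`, because a
  binomial argument must be a probability. For the tabulated parameter
  ranges ($I \le 0.05$, $a \le 1$) the clamp never activates.
* $\Gamma(1/\beta)/\beta$ and $\Gamma(1+1/\beta)$ are the same quantity by
  the Gamma recurrence; the package evaluates it once, through the
  log-gamma route for stability, and the test suite checks both routes
  agree to $10^{-12}$.

Under $H_1$ the true mean is $\mu = r \mu_0$ for a mean ratio $r \ge 1$,
and substituting $t_0 = a \mu_0$ into $F_N$ gives the two operating points
of the design:
$$p_1 = 1 - \exp\{-a^\beta r^{-\beta}\,\Gamma(1{+}1/\beta)^\beta
        (1{+}I)^\beta\}(1{+}I) + I
  \quad\text{(acceptable quality level, AQL)},$$
with $p_2$ the same expression at $r = 1$ (the limiting quality level,
LQL — the null-hypothesis point). Since $p$ is decreasing in $r$,
$p_1 \le p_2$ always.

## Plan design

Given producer risk $\tilde\alpha$ and consumer risk $\tilde\beta$, a valid
plan must accept good lots reliably and bad lots rarely:
$$L(p_1) \ge 1 - \tilde\alpha, \qquad L(p_2) \le \tilde\beta .$$
`design_repetitive_plan()` minimizes the ASN over all integer triples
subject to these constraints. Two design choices here were genuinely open:

**Where the ASN objective is evaluated.** The ASN depends on the true
failure fraction. The package evaluates (and reports) it at the *limiting*
quality level $p_2$ — the null-hypothesis operating point, i.e. the regime
in which the monitor actually runs the procedure while $H_0$ stands. Both
values are exposed in the result (`asn_lql`, `asn_aql`), and
`objective = "aql"` switches the optimization target.

**How the search works.** The optimum is found by exact enumeration, not
heuristics. Two monotonicities make this cheap: (i) for fixed $(n, c_1)$
the feasible $c_2$ form an interval — raising $c_2$ raises $L$ at both
operating points and raises the ASN — so only the smallest feasible $c_2$
can be optimal and it is found by a binary search on the binomial tail;
(ii) $ASN \ge n$, so the scan over ascending $n$ stops as soon as $n$
exceeds the best ASN found. The result is the certified global optimum
within the bounds; ties are broken toward smaller $n$, then smaller $c_1$.
The test suite checks the structured search against brute-force
enumeration of every triple up to $n = 60$. Constraints are compared with
exact floating-point inequalities (no epsilon slack), as a grid search
over exact binomial tails warrants.

**When no plan is reported.** For ill-separated operating points (e.g.
$\beta = 1$, $a = 0.5$, $r = 1.1$: $p_1 = 0.365$ vs $p_2 = 0.393$) formally
feasible triples exist, but only with $P_a + P_r$ so small that the scheme
resamples almost every stage: the cheapest such design already needs an
expected inspection volume in the thousands. A plan like that is not a
usable design, so the search reports "no usable plan" when nothing with
$ASN \le$ `asn_max` (default 1150, roughly an order of magnitude above a
typical single-plan sample size) exists within $n \le$ `n_max` (default
500). Both ceilings are arguments, so a caller who genuinely wants a
14,000-sample resampling scheme can raise them.

Defaults for the tunable parameters, and why:

| parameter | default | meaning |
|---|---|---|
| `producer_risk` | 0.10 (conventional) | max P(reject) at the AQL |
| `consumer_risk` | — | max P(accept) at the LQL |
| `termination_ratio` a | — | $t_0/\mu_0$; larger $a$ = longer test, fewer samples |
| `n_max` | 500 | search bound on the stage size |
| `asn_max` | 1150 | usability ceiling on expected inspection volume |

`design_single_plan()` solves the $c_1 = c_2$ case by minimal $n$; because
single plans are a subset of the repetitive feasible set with $ASN = n$,
the repetitive optimum's ASN can never exceed the single-plan $n$ — the
economy property, asserted per-setting in the tests.

## Executing a plan

`count_failures()` counts observations $\le t_0$ — the truncated-life-test
census; `repetitive_decision()` applies accept iff $d \le c_1$, reject iff
$d > c_2$, consistent with the binomial tail definitions of $P_a$ and
$P_r$ (the boundary conventions follow the probability model, which is
unambiguous even where verbal descriptions of such procedures often are
not). `run_worked_example()` chains the whole pipeline on the packaged
Italian COVID-19 ratios: the Weibull fit gives mean $0.1665$ and shape
$2.2222$ (both rounded to the 4 decimals at which the hypothesis is
stated, then treated as the *specified* $\mu_0$ and $\beta$), the design
at $(\tilde\alpha, \tilde\beta, a, r, I) = (0.10, 0.10, 1.0, 1.1, 0.04)$
returns $(n, c_1, c_2) = (114, 58, 66)$ with $ASN = 191.67$, and 58 of the
111 ratios lie at or below $t_0 = 0.1665$, so the lot is accepted exactly
at the boundary ($d = c_1$). The dataset is 3 observations short of the
plan's $n = 114$; `apply_plan()` then uses all available observations and
says so — with 58 failures already at most $c_1$, the 3 missing
observations could not change the acceptance.

## Model choice for the data layer

Which lifetime family feeds the design is an empirical question.
`model_comparison_table()` fits four candidates by maximum likelihood —
Weibull (WD), odds Weibull (OWD), Nadarajah–Haghighi (NHD) and its
exponentiated extension (ENHD) — and ranks them by AIC, with BIC and the
one-sample Kolmogorov–Smirnov distance reported alongside. Numerical
choices:

* The Weibull fit goes through `fitdistrplus::fitdist()`; standard errors
  come from the inverse observed information.
* The other three models have awkward likelihood surfaces (the NHD has a
  flat ridge $\alpha \to \infty$, $\lambda \to 0$ along which gradient
  methods stall or overflow), so they are fitted by a derivative-free
  simplex search on log-parameters — which enforces positivity without
  constraints — from eight deterministic starting points, keeping the best
  converged optimum; a simplex restart at the optimum polishes ridge
  solutions. All parameters are constrained positive, including the OWD
  exponent $\alpha$ (its fitted value on real data is comfortably
  positive).
* The KS statistic uses the sorted-sample formula
  $D = \max_i\{i/m - F(x_{(i)}),\, F(x_{(i)}) - (i-1)/m\}$ and the
  asymptotic Kolmogorov p-value *without* correction for estimated
  parameters; with parameters estimated the p-value is anti-conservative
  and should be read as descriptive — the ranking surface is AIC, not the
  KS p.
* `neutrosophic_shape_adjust()` maps a classical shape estimate to its
  indeterminate counterpart, $(1 + I_U)\hat\beta$.

## What the simulator emulates — and what it does not

`simulate_lifetimes()` draws classical Weibull lifetimes by inverse-cdf
transform; `generate_covid_like_dataset()` uses scale 0.188 and shape
2.2222, the values the real ratios are well fitted by, so tests of the
fitting layer need not touch the packaged data. `monte_carlo_oc()` is the
end-to-end empirical check of the analytic OC and ASN: it plays the
repetitive procedure forward with binomial stage counts and compares the
empirical acceptance rate and mean inspection volume against $L(p)$ and
$ASN(p)$ — agreement within three Monte-Carlo standard errors at
$2 \times 10^5$ replications is asserted in the tests. A stage cap
(default $10^4$) guards pathological plans and raises a diagnostic rather
than spinning.

The generator emulates *only* the distributional assumption: i.i.d.
Weibull draws. Real daily ratios are serially dependent (epidemic
dynamics), truncated by reporting practices, and rounded to four decimals
with ties; none of that is modelled, deliberately — the sampling theory
treats observations as exchangeable lifetime-like draws, and the package
follows that contract. Passing tests therefore validate the sampling
mathematics and the fitting machinery, not the epidemiological adequacy of
the i.i.d. assumption for any particular surveillance stream.

## Problem sizes and numerical conventions

The default test run uses desk-scale problems: exhaustive-search
cross-checks to $n_{\max} = 60$, binomial-identity checks to $n = 50$ at
$10^{-12}$, Monte-Carlo verification at $2\times 10^5$ replications,
parameter recovery at $n = 5000$, and one full 112-cell design-table
regeneration (about two seconds). Binomial tails always go through
`stats::pbinom` — the regularized incomplete beta — never through naive
summation, which is reserved for test oracles; upper tails use
`lower.tail = FALSE` to avoid cancellation.

## Known limitations

* Published reference tables for this plan family were evidently produced
  with a non-exhaustive search: for some settings they list feasible but
  suboptimal triples. The exact optimizer here will then legitimately
  return a *different* plan with a strictly smaller ASN; the package
  guarantees optimality within bounds, not replication of any particular
  historical table cell.
* The indeterminate cdf is unnormalized by construction; consumers who
  need a probability must use the clamped failure fractions.
* Type-I (time) censoring only; no curtailment within a stage, no group or
  multiple-dependent-state extensions.
* The KS p-values ignore parameter estimation (see above).
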