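---
title: "Rank-difference tests for monotone ordered alternatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-difference tests for monotone ordered alternatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendrank)
```

## The problem

Dose-response and toxicity studies often ask a sharper question than
"do these k groups differ?": do responses *increase* with dose? With
groups indexed by the hypothesized ordering, the model is k independent
continuous samples differing only in location,
F_i(x) = F(x − θ_i), and the hypotheses are

* H0: θ_1 = θ_2 = ... = θ_k
* H1: θ_1 ≤ θ_2 ≤ ... ≤ θ_k, with at least one strict inequality.

Classical rank tests for this problem reduce each cross-group
comparison to a sign. The Jonckheere–Terpstra (JT) statistic counts,
over all group pairs i < j, the cross-pairs whose later-group
observation is larger (the Mann–Whitney count U_ij); the modified JT
(MJT) weights U_ij by the group distance (j − i); the Cuzick (CU)
statistic is the rank-sum of each group weighted by its index; and the
Terpstra–Magel (TM) statistic counts k-tuplets — one observation per
group — in strictly increasing order.

The rank-difference statistic implemented here keeps the *magnitude*
of each comparison as well as its sign. With R_iu the rank of
observation u of group i in the pooled sample of size N,

S = Σ_{i<j} Σ_{u,v} (R_jv − R_iu)⁺,

the sum over every cross-group pair of the positive part of the rank
difference. A concordant pair far apart in rank contributes more than a
marginally concordant one, which is exactly the information the sign-only
tests discard, and is where the statistic's power advantage over JT
comes from.

## Exact null moments

Under H0 the pooled ranks are a uniformly random permutation of 1..N,
so the distribution of S depends only on the composition
(n_1, ..., n_k). With P = Σ_{i<j} n_i n_j cross pairs and every pair
term having expectation (N+1)/6,

E(S) = P (N + 1) / 6.

The variance comes from a covariance decomposition over pairs of pair
terms, classified by how many observations they share and where the
shared observation sits. For distinct ranks drawn without replacement
from {1..N} the exact mixed moments are polynomial in N:

| term | value |
|---|---|
| E[(b−a)⁺] | (N+1)/6 |
| E[((b−a)⁺)²] | N(N+1)/12 |
| shared end observation, E[(b−a)⁺(c−a)⁺] | (N+1)(3N+1)/60 |
| shared middle observation, E[(b−a)⁺(c−b)⁺] | (N+1)(N+2)/120 |
| disjoint, E[(b−a)⁺(d−c)⁺] | (N+1)(5N+4)/180 |

Counting the ordered pairs of pair terms in each class from the
composition (via the cumulative sizes before and after each group) and
assembling gives the closed form in `rd_null_variance()`. One point
deserves emphasis: the disjoint-observation covariance is
−(N+1)/180 per ordered pair, *not* zero — ranks sampled without
replacement are negatively dependent even across disjoint index sets.
Because typeset formulas are easy to mistranscribe, the package treats
exhaustive enumeration as the arbiter: the test suite verifies the
closed forms against the full null distribution for **every**
composition with N ≤ 8 and k ∈ {2, 3, 4} at 10⁻¹⁰ relative error, and
`exact_null_distribution()` provides the same enumeration route at run
time.

The standardized statistic z = (S − E S)/√Var S is asymptotically
standard normal as group sizes grow proportionally;
`cdf_diagnostic()` quantifies the finite-sample quality of that
approximation by the Kolmogorov–Smirnov distance between the simulated
null CDF of z and Φ. At sizes (10,10,10) with 20,000 replicates the
distance is below 0.03.

## Inference routes and ties

`trend_test()` exposes three routes:

* **asymptotic** (rank-difference test only): z and the one-sided
  upper-tail normal p-value, no continuity correction. Refused for
  tied data: the variance above assumes continuity, and a midrank
  plug-in would silently use the wrong null scale.
* **permutation**: the pooled (mid)ranks are permuted `n_perm` times;
  p = (1 + b)/(B + 1) where b counts permuted statistics ≥ the observed
  one. The add-one convention keeps Monte-Carlo p-values valid (never
  zero). Available for all five statistics, and the recommended route
  for tied data.
* **exact**: full enumeration of assignments of ranks 1..N to groups,
  capped (default 200,000 arrangements) with an error directing large
  problems to the permutation route.

Tie conventions follow the field's conventions per statistic: midranks
everywhere; JT/MJT credit tied cross-pairs 1/2; TM counts strictly
increasing tuplets only; the rank-difference statistic takes positive
parts of midrank differences (a tied pair contributes 0). A
`side = "decreasing"` alternative is implemented by reversing the group
order, so the one-sided increasing machinery serves both directions.

## The MJT–CU identity

The simulation tables always show identical power for MJT and CU. That
is not a coincidence: writing the two-sample Mann–Whitney count at each
cut m (groups 1..m pooled versus m+1..k pooled) in terms of pooled rank
sums gives

MJT = CU − N(N+1)/2 − Σ_{m=1}^{k−1} n_{>m}(n_{>m}+1)/2,

an exact affine identity at fixed sizes (n_{>m} is the total size after
cut m). The two statistics therefore induce the same ordering of
datasets, the same permutation p-values, and the same calibrated
rejection decisions. The test suite asserts the identity exactly,
including under ties.

## The simulation engine and what it emulates

`power_study()` reproduces the shared-draw calibration protocol of the
published study this package re-implements:

1. draw `b_null` null datasets once; set each test's cutpoint at the
   empirical 95th percentile (the ⌈0.95 B⌉-th order statistic) of its
   own statistic over those *same* datasets;
2. draw `b_alt` datasets per alternative; the rejection rate of a test
   is the fraction of its statistics strictly above its cutpoint.

Every test sees identical datasets (common random numbers): generation
never consumes RNG state conditional on the test list, which the suite
checks by re-running with different test subsets. Rejecting strictly
above an order-statistic cutpoint is slightly conservative for discrete
statistics, matching the slightly-below-nominal sizes in the published
tables. Defaults are the published replication levels, B_null = 20,000
and B_alt = 10,000; reduced levels (B = 2,000) are used in the test
suite with a correspondingly widened tolerance (±0.04 instead of
±0.02).

The scenario families are those of the published study: normal with
stated means and standard deviations (unit unless stated, e.g. the
unequal-variance scenario uses sd 3, 2, 1); location-shifted t with
3 df; exponential parameterized by its mean; and mixed designs with
normal early groups and exponential later groups. Two interpretation
choices were open and are fixed here: mixed-design normal components
use unit variance, and mixed-design cutpoints are calibrated from
exchangeable *standard normal* nulls while their size rows are
estimated under the (non-exchangeable) mixed null — that mismatch, not
an implementation artifact, is what makes the mixed-table sizes
conservative (≈0.015–0.03 at nominal 0.05). For the pure-family tables
the calibration family matches the table's family; since all five
statistics are rank-based, any exchangeable continuous null yields the
same cutpoint distribution, and the empirical sizes sit near 0.05
either way.

What a green simulation test establishes: that the engine reproduces
the published Monte-Carlo cells within the stated Monte-Carlo
tolerance under the stated families. What it does not establish:
behaviour under tied/ordinal data (out of scope here: only the
permutation route covers ties), umbrella or tree alternatives, or
non-location alternatives.

## Numerical choices

* Cutpoints and tail probabilities compare on a half-integer grid; a
  1e−9 fuzz guards the ≥ comparisons against binary representation
  error.
* Enumeration is capped at 200,000 arrangements by default; beyond it
  the error message points to permutation inference.
* Per-configuration seeds are derived deterministically from the base
  seed and kept below 2³¹; identical seeds reproduce byte-identical
  power tables.
* The null-moment formulas are evaluated in double precision; the
  largest intermediate (P² terms at N = 80) is far below 2⁵³, so the
  closed forms are exact.

## Known limitations

* Asymptotic inference for JT/MJT/TM/CU is deliberately not provided;
  the package's scope ties asymptotics to the rank-difference statistic
  whose exact moments it owns. The permutation route covers the rest.
* The exact route enumerates rather than using network algorithms, so
  it is a small-N tool by design.
* Tied-data *asymptotic* theory (midrank variance) is not implemented;
  tied data are directed to permutation inference.
* The null law of S is invariant under reversing the composition, but
  it is not symmetric about its mean for unequal (or even equal) group
  sizes; small-sample inference should therefore use the exact or
  permutation routes rather than a symmetry argument.
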