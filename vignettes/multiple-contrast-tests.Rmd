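---
title: "Multiple contrast tests for censored survival data: models, procedures, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple contrast tests for censored survival data: models, procedures, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survMCTP)
```

## The statistical model

We observe $k \ge 2$ independent groups of right-censored time-to-event
data: for subject $i$ of group $j$, an event time $T_{ji} \sim F_j$ and a
censoring time $C_{ji} \sim G_j$ (both continuous), of which only
$X_{ji} = \min(T_{ji}, C_{ji})$ and the indicator
$\delta_{ji} = I(X_{ji} = T_{ji})$ are observed.  Group differences are
expressed through the cumulative hazard functions $A_j(t)$: the local null
hypothesis for a pair $(j_1, j_2)$ is $A_{j_1} \equiv A_{j_2}$, which is
equivalent to equality of the survival distributions.  A contrast matrix
$H \in \mathbb{R}^{q \times k}$ with $H \mathbf{1}_k = \mathbf{0}_q$ encodes
the family of comparisons; this package supports the pairwise rows
($-1$ at $j_1$, $+1$ at $j_2$) of the Dunnett (many-to-one, $q = k - 1$) and
Tukey (all pairs, $q = k(k-1)/2$) types plus user-supplied pair lists.
General non-pairwise rows are accepted by the `contrast_set` container but
rejected by the procedures with an explicit error, because the two-sample
statistics below are only defined for pairs.

The inferential building block is the weighted log-rank statistic
$$
T_{j_1,j_2}(w) \;=\; \sqrt{\tfrac{n}{n_{j_1} n_{j_2}}} \int_0^\infty
w\{\hat F_{j_1,j_2}(t-)\}\,
\frac{Y_{j_1}(t)\,Y_{j_2}(t)}{Y_{j_1}(t) + Y_{j_2}(t)}\,
\{\mathrm d\hat A_{j_2}(t) - \mathrm d\hat A_{j_1}(t)\},
$$
with $Y_j$ the at-risk process, $\hat A_j$ the Nelson–Aalen estimator,
$\hat F_{j_1,j_2}$ the pair-pooled Kaplan–Meier CDF, and
$n = n_{j_1} + n_{j_2}$.  The weight family shipped is Fleming–Harrington
$w(x) = x^r (1-x)^g$ (the log-rank test at $r = g = 0$) plus the crossing
weight $w(x) = 1 - 2x$, which changes sign at the pooled median and is
sensitive to crossing hazards.  The default weight set everywhere is
$\{1,\; 1 - 2x\}$, a pairing that has proved robust against both
stochastic-ordering and crossing alternatives; more weights can be attached
(`parse_weights("fh:1,1")` etc.) provided they remain linearly independent
(`check_linear_independence()`).

## The four procedures

**Adjusted log-rank** (`adjusted_logrank_test`): for each pair, the
chi-square statistic $T^2/\hat\sigma^2$ is referred to $\chi^2_1$; local
p-values are compared with the Bonferroni level $\alpha/q$ and the global
decision uses the minimum p-value.  This is the reference method: optimal
under proportional hazards, fragile under crossing hazards.

**Adjusted mdir** (`adjusted_mdir_test`): for each pair, $m$ weighted
statistics are combined in the studentized quadratic form
$Z = T^\top \hat\Sigma^{-} T$ with $\hat\Sigma$ the plug-in covariance
(integrating weight products against the pair-pooled Nelson–Aalen
increments) and $\hat\Sigma^-$ its Moore–Penrose inverse.  Calibration is by
permutation of group labels within the pair, which is exact under the
exchangeable local null; the asymptotic $\chi^2_m$ reference is available
(`calibrate = "chisq"`) but the permutation path is the default because the
asymptotic version is anti-conservative in moderate samples.  Local
p-values use the add-one estimator $(1 + \#\{Z^* \ge Z\})/(B+1)$ and the
Bonferroni level $\alpha/q$; when $1/(B+1) \ge \alpha/q$ no rejection is
achievable and the procedure warns rather than errors, since the
descriptive p-values remain useful.

**MultiWeightedLR** (`multiweightedlr_test`): all $m\cdot q$ statistics are
kept separate.  Each is studentized by its own estimated standard
deviation, the global statistic is the maximum absolute standardized entry,
and the critical value is the equicoordinate $(1-\alpha)$-quantile of a
centered multivariate normal with the estimated correlation matrix — the
standard simultaneous-inference construction, which exploits the
correlation between the statistics instead of a Bonferroni bound.  The
statistics are *not* unit-variance as defined, so studentization is a
necessary design choice for the Gaussian comparison to make sense; it is
the same choice made by classical multiple-contrast procedures for means
and relative effects.

The joint covariance needs cross-contrast blocks for which no closed-form
plug-in is standard.  Each two-sample statistic decomposes into per-group
martingale integrals $\pm\int H_{a,p}(t)\, \mathrm dM_j(t)/Y_j(t)$, so the
covariance between statistics of two contrasts sharing group $j$ is
estimated by the optional-variation plug-in
$\sum_t H_{a,p}(t) H_{b,s}(t)\, \mathrm dN_j(t)/Y_j(t)^2$, with sign
$\varepsilon_a(j)\varepsilon_b(j)$ tracking whether $j$ enters each
contrast positively or negatively; blocks of disjoint contrasts are zero by
independence.  Two independent checks back this estimator: agreement with
the empirical covariance of the statistic vector over thousands of null
replicates (tested entrywise within three Monte-Carlo standard deviations)
and with a wild-bootstrap covariance estimate
(`joint_covariance(method = "wild")`).

**multiCASANOVA** (`multicasanova_test`): the pooled-quantity variant.  The
per-contrast statistic $\tilde T_{j_1,j_2}(w)$ replaces the pair-pooled CDF
and at-risk denominator by their *all-group* pooled versions, weights are
combined per contrast in a Wald form $C_{j_1,j_2}$ (Moore–Penrose inverse
again), and the global statistic is $C_{\max}$ — no maximum over weights,
since the quadratic form already absorbs them.  Calibration is by the wild
bootstrap for counting processes: each subject's counting-process increment
is multiplied by an i.i.d. mean-zero, unit-variance multiplier $G_{ji}$
(Rademacher by default, centered Poisson(1) as an alternative — discrete
laws, matching the discreteness of the processes), giving bootstrap
Nelson–Aalen increments and hence bootstrap statistics $C^*_{\max}$.  Three
implementation decisions matter:

* the data-based covariance $\widehat{\mathrm{Cov}}$ is computed once and
  reused in every draw — only the hazard-difference increments are
  bootstrapped;
* one multiplier per subject, shared across all contrasts within a draw, so
  the joint dependence among contrasts is preserved in the bootstrap
  distribution of the maximum;
* the critical value is the empirical $(1-\alpha)$-quantile of the
  $C^*_{\max}$ sample, taken with the add-one convention as the order
  statistic at $\lceil (1-\alpha)(B+1) \rceil$; the seemingly natural index
  $\lceil (1-\alpha) B \rceil$ is anti-conservative — if the observed
  statistic were exchangeable with the $B$ bootstrap draws, comparing
  against the 475th of 500 draws rejects with probability
  $26/501 \approx 5.2\% > \alpha$, while the add-one index 476 gives
  $25/501 \le \alpha$, a difference confirmed empirically in null
  simulations.  Both the global and all local decisions compare against
  this single shared quantile.

## Numerical conventions

* **Ties.** The model assumes continuous distributions, but simulated
  double-precision data can tie.  At a tied time, events are counted in
  $\mathrm dN$ while censored records remain in the risk set — the standard
  Nelson–Aalen/Kaplan–Meier convention.
* **Integrals** are finite sums over the sorted unique observed times of
  the relevant (pair or all-group) sample; grid points where an at-risk
  product vanishes contribute zero.
* **Left limits.** $\hat F(t-)$ is the estimate at the largest grid point
  strictly below $t$, zero before the first event.
* **Pseudo-inverse.** Singular values below
  $m\,\sqrt{\varepsilon_{\mathrm{mach}}}\,s_{\max}$ are treated as zero, so
  quadratic forms on singular covariance matrices (e.g. proportional
  weights) are well-defined and reproducible.
* **Equicoordinate quantile.** Rectangle probabilities come from the
  Genz–Bretz randomized-lattice algorithm at a fixed integration seed;
  the quantile is located by bisection on a bracket starting at $[1, 6]$
  (expanded when needed) to an absolute tolerance of $10^{-3}$.  The
  estimated correlation matrix is repaired to positive semidefiniteness
  beforehand by clipping negative eigenvalues at zero and rescaling to unit
  diagonal, since finite-sample plug-in blocks need not be jointly PSD.
  Coordinates with zero estimated variance (a pair without any events) are
  dropped with a warning.
* **Seeds.** Every resampling procedure takes a master seed; per-contrast
  and per-run sub-seeds are derived deterministically (a counter scheme,
  kept below $2^{31}$), so multi-contrast and multi-run results are
  reproducible and independent of execution order.

## The scenario generator

`scenario()` encodes four named hazard configurations for $k = 4$ groups of
100 subjects each, covering the qualitative regimes that matter for
log-rank-type tests:

| name | laws (per group) | hazard relationship |
|------|------------------|---------------------|
| `Prop`  | Exponential, rates 1.2, 1.8, 2.3, 2.9 | proportional |
| `NProp` | Lognormal (2.2, 1.7), (2.6, 1.6), (3.5, 1.7), (4.5, 1.6) | non-proportional, non-crossing |
| `Cross` | Weibull shapes 1.5, 2.5, 3.5, 4.5, scale 5 | pairwise crossing |
| `Mix`   | Lognormal (2.3, 1.7); Exponential 0.05; Weibull (2.4, 11.7); Lognormal (3, 1.6) | mixed |

Parameter conventions are the standard R ones — Exponential(rate),
Lognormal(meanlog, sdlog), Weibull(shape, scale) — stated here prominently
because parameter roles are a common source of irreproducibility.
Censoring is Uniform$(0, u_j)$ with $u_j$ calibrated per group by numeric
root-finding so that $P(C < T)$ hits the requested target (0–30% is the
studied range); calibration is per group so each group attains the target
marginally.  Custom scenarios take arbitrary law lists, group sizes and
targets.

`run_study()` is the Monte-Carlo harness: a contrast is a true null exactly
when its two groups follow identical laws, the family-wise error rate
(FWER) is the fraction of runs with at least one rejection among true-null
contrasts, and local power is the per-contrast rejection rate among
false-null contrasts.  Reports carry the binomial precision band
$\alpha \pm z_{0.975}\sqrt{\alpha(1-\alpha)/\text{runs}}$ — at 10,000 runs
and $\alpha = 5\%$ this is $[4.57\%, 5.43\%]$.

The generator emulates independent, identically distributed groups with
non-informative uniform censoring.  It does not emulate covariate-driven
censoring, dependent observations, left truncation or staggered accrual,
so passing tests demonstrate calibration and power behaviour under the
stated sampling model, not robustness to those real-data complications.

## Problem sizes used by the shipped checks

The package's own Monte-Carlo checks use sizes chosen to give informative
binomial precision while remaining routine on a single CPU: 10,000 runs for
the non-resampling FWER check of the adjusted log-rank, 10,000 runs at
$B = 500$ bootstrap draws for the multiCASANOVA FWER check, 1,000 runs at
$B = 500$ for the crossing-hazards power ordering, 5,000 replicates for the
empirical joint-covariance validation, and 1,000 replications at $B = 199$
for the permutation-uniformity check.  Full-scale studies (e.g. $B = 1000$
everywhere, more scenario/censoring combinations) use the same code paths
through `run_study()`.

## Known limitations

* Only pairwise contrasts: average- or trend-type rows, and factorial
  main-effect/interaction contrasts, are out of scope.
* The maximum test relies on the multivariate normal approximation; with
  small groups (around $n_j = 50$) it can be anti-conservative, and no
  small-sample correction is applied.
* Simultaneous intervals are reported on the standardized-statistic scale
  only; the weighted log-rank statistics are not effect estimators, so no
  hazard-difference effect scale is offered.
* The wild bootstrap keeps the data-based covariance
  $\widehat{\mathrm{Cov}}$ fixed across draws (by construction), so it
  cannot reflect the sampling variability of that covariance estimate; the
  observed quadratic form's null tail is correspondingly a little heavier
  than the bootstrap distribution at moderate group sizes, and in
  exchangeable null scenarios at $n_j = 100$ the package's own Monte-Carlo
  check measures a family-wise error rate a few tenths of a percentage
  point above the nominal 5%, at the edge of the 10,000-run binomial band.
* The local decisions of the wild-bootstrap procedure share a single global
  bootstrap quantile; per-contrast quantiles would be a different (closed
  testing-flavoured) procedure and are not implemented.
* No Holm or closed-testing sharpening of the Bonferroni-adjusted
  procedures.
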