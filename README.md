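# survMCTP

Multiple contrast test procedures (MCTPs) for right-censored k-sample
survival data that stay powerful when hazards are non-proportional or
crossing.

## The problem

Multi-arm time-to-event trials ask *which* arms differ, not merely whether
any do. The standard answer — pairwise log-rank tests with a Bonferroni
correction — inherits the log-rank test's fragility: under late effects or
crossing hazards its power collapses, and the Bonferroni bound ignores the
correlation between the pairwise statistics. This package implements four
procedures for simultaneous pairwise inference on the cumulative hazards
$A_j(t)$ of $k$ groups, for contrast families of Dunnett (many-to-one) or
Tukey (all-pairs) type:

1. **Adjusted log-rank** — pairwise weighted log-rank statistics
   $T_{j_1,j_2}(w)$ referred to $\chi^2_1$, Bonferroni level $\alpha/q$
   (the clinical-practice reference method);
2. **Adjusted mdir** — per pair, several weights
   ($w \equiv 1$ and the crossing weight $1-2x$ by default) combined in the
   studentized quadratic form $Z = T^\top \hat\Sigma^- T$, calibrated by
   permutation within the pair, Bonferroni level $\alpha/q$;
3. **MultiWeightedLR** — all $m\cdot q$ studentized statistics compared
   simultaneously with the equicoordinate $(1-\alpha)$-quantile of the
   fitted multivariate normal, so the correlation between contrasts and
   weights replaces the Bonferroni penalty;
4. **multiCASANOVA** — per-contrast Wald statistics
   $C_{j_1,j_2} = \tilde T^\top \widehat{\mathrm{Cov}}^- \tilde T$ built
   from all-group pooled quantities, global statistic
   $C_{\max}$, calibrated by a wild bootstrap with Rademacher or centered
   Poisson multipliers on the counting-process increments.

A scenario generator and Monte-Carlo harness (`scenario()`, `run_study()`)
reproduce family-wise error rate (FWER) and power studies under
proportional, non-proportional, crossing and mixed hazard configurations
with calibrated uniform censoring.

See `vignettes/multiple-contrast-tests.Rmd` for the full model, estimator
definitions and numerical conventions.

## Worked example

```r
library(survMCTP)

# four groups with crossing hazards (Weibull shapes 1.5..4.5, scale 5),
# n = 100 per group, 10% uniform censoring
d <- sample_scenario(scenario("Cross", n = 100, censoring = 0.1), seed = 42)

res <- mctp_test(d,
                 methods   = c("adjusted_logrank", "multicasanova_rademacher"),
                 contrasts = "dunnett", B = 1000, seed = 1)
res$adjusted_logrank
#> Bonferroni-adjusted weighted log-rank test
#> Global decision: do not reject at alpha = 0.05
#>   alpha_bonferroni: 0.01667
#>  contrast statistic p_value reject
#>    1 vs 2   0.01496  0.9027  FALSE
#>    1 vs 3   0.06542  0.7981  FALSE
#>    1 vs 4   1.22400  0.2686  FALSE

res$multicasanova_rademacher
#> multiCASANOVA wild-bootstrap test (rademacher multipliers)
#> Global decision: reject at alpha = 0.05
#>   bootstrap_quantile: 6.156
#>  contrast statistic critical    p_adj reject
#>    1 vs 2     20.73    6.156 0.000999   TRUE
#>    1 vs 3     28.19    6.156 0.000999   TRUE
#>    1 vs 4     46.86    6.156 0.000999   TRUE
```

Group 1 (Weibull shape 1.5) has a hazard that crosses those of the other
groups, so early and late hazard differences cancel inside the classical
log-rank integral: the adjusted log-rank sees nothing ($p \ge 0.27$
everywhere). The crossing-weight-aware multiCASANOVA statistics (20.7 to
46.9) clear their shared bootstrap critical value (6.2) for every
comparison. `statistic` is the $\chi^2_1$ value for the adjusted
log-rank and the Wald quadratic form $C_{j_1,j_2}$ for multiCASANOVA;
`p_adj` is the add-one share of bootstrap $C^*_{\max}$ draws at or above
each local statistic.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/survmctp.R simulate --scenario Cross --n 100 --seed 42 --emit-data --out d.csv
Rscript inst/cli/survmctp.R test --input d.csv --method adjusted_logrank --contrasts dunnett --out res.csv
```

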