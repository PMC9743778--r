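# prrda

Differential-abundance testing for microbiome count tables with the
**permutation of regressor residuals (PRR) test** applied to likelihood-based
count-regression models.

## Why

Per-taxon regression is the standard way to test whether microbial counts
are associated with a covariate of interest (diet group, exposure, age)
while adjusting for other covariates. But real 16S/metagenomic counts are
overdispersed and zero-inflated, and when the fitted distribution is wrong,
the likelihood-ratio test's false positive rate can explode — misspecified
Poisson or binomial models reject well over 90% of truly null taxa at a
nominal 5% threshold. Plain permutation tests stay calibrated but cannot
adjust for covariates without stratification.

The PRR test keeps both properties. Partition the count-component design as
$X = (X^*, X^\dagger)$ and the zero-component design as $Z = (Z^*, Z^\dagger)$,
starred blocks holding the covariate(s) of interest. Then:

1. replace $X^*$ by its least-squares residual
   $\tilde X = X^* - X^\dagger\hat\Sigma$ (and likewise $\tilde Z$); the
   maximized likelihood is unchanged, but $\tilde X$ is orthogonal to the
   nuisance covariates;
2. for each of $B$ iterations, permute the rows of $\tilde X$ and $\tilde Z$
   (one shared index set), refit, and compute the full-vs-reduced
   likelihood-ratio p-value $p_b$ from the $\chi^2_{p+s}$ tail
   ($p$, $s$ = interest columns of the two components);
3. report both the standard LRT p-value $\hat p$ and the permutation p-value
   $p = \frac{1}{B}\sum_b \mathbb{1}(p_b < \hat p)$.

Because the observed pivotal is exchangeable with the permuted ones under
the null, $p$ holds the nominal false positive rate *whatever* the count
model — the model only shapes power.

Eight families are supported — {Poisson, negative binomial, binomial,
beta-binomial} × {plain, zero-inflated} — with library-size exposure as a
log offset (Poisson type) or the number of trials (binomial type), and
simultaneous testing of count and zero components. The package also ships
the simulation framework used to validate the test: a zero-inflated
negative-binomial base-table generator, signal injection into counts and/or
zeros (with optionally confounded urbanization/age covariates), and
FPR / power@0.05 / partial-AUC metrics.

## Worked example

```r
library(prrda)

cfg <- simulation_config(n_samples = 100, n_taxa = 50,
                         signal_mode = "counts_zeros", effect_size = 2, seed = 1)
sim <- build_experiment(cfg)           # counts + covariates + known truth
tab <- prr_test_table(sim$counts, sim$covariates, interest = "diet",
                      families = c("Poisson", "ZINegativeBinomial"),
                      zero_formula = ~diet, B = 200, seed = 1)
head(tab[tab$family == "ZINegativeBinomial",
         c("taxon_id", "family", "df", "p_lrt", "p_perm")])
#>     taxon_id             family df     p_lrt p_perm
#> 2  taxon0001 ZINegativeBinomial  6 0.5427272  0.630
#> 4  taxon0002 ZINegativeBinomial  6 0.5524072  0.680
#> 6  taxon0003 ZINegativeBinomial  6 0.4333939  0.505
#> 8  taxon0004 ZINegativeBinomial  6 0.1319333  0.200
#> 10 taxon0005 ZINegativeBinomial  6 0.8284367  0.815
#> 12 taxon0006 ZINegativeBinomial  6 0.8054196  0.745
```

`df = 6` because the 4-level diet factor contributes 3 treatment-coded
columns to each of the count and zero components, tested jointly. Comparing
the two p-value columns against the simulation truth:

```r
truth <- da_truth(sim, "diet")
for (f in c("Poisson", "ZINegativeBinomial")) {
  sub <- tab[tab$family == f, ]
  sub <- sub[match(sim$counts$taxon_ids, sub$taxon_id), ]
  cat(f, "loglik:", round(fpr_tpr(sub$p_lrt, truth), 3),
      " llperm:", round(fpr_tpr(sub$p_perm, truth), 3), "\n")
}
#> Poisson loglik: 0.794 1  llperm: 0.059 0.312
#> ZINegativeBinomial loglik: 0.029 0.188  llperm: 0 0.188
```

Each pair is (FPR, TPR) at the 0.05 threshold: the misspecified Poisson LRT
rejects 79% of null taxa, while its PRR version sits at the nominal rate
(0.059 here, with only ~45 null taxa) and still detects 31% of the true
signals. The zero-inflated negative binomial is near-calibrated either way
on this small table — the PRR construction is insurance for the models that
are not.

A thin CLI over the same functions is installed at
`system.file("scripts/prrda", package = "prrda")` with subcommands
`simulate`, `test`, `evaluate`, and `replicate` (the scaled-down
model-comparison harness).

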