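---
title: "Permutation of regressor residuals for microbiome differential abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation of regressor residuals for microbiome differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrda)
```

## The problem

Differential-abundance (DA) testing asks, taxon by taxon, whether the counts
in a sample-by-taxon table are associated with a covariate of interest (a
diet group, an exposure gradient) after adjusting for nuisance covariates.
Microbiome count tables make this hard for parametric tests: counts are
strongly overdispersed (a taxon with mean 30 can have variance above 1000),
zero-inflated, and only interpretable relative to the per-sample sequencing
depth ("library size" $s_i = \sum_j Y_{ij}$). When the fitted model is wrong
in either the tail or the zero mass, the likelihood-ratio test (LRT) can
reject the null for the bulk of truly null taxa — false positive rates above
90% are realistic, not pathological.

Plain permutation tests fix the calibration but cannot adjust for covariates
without stratification, which small studies cannot afford. The permutation of
regressor residuals (PRR) test keeps the regression structure and the
permutation guarantee at once.

## The test

Write the count-component model matrix as $X = (X^*, X^\dagger)$ and the
zero-component matrix as $Z = (Z^*, Z^\dagger)$, where the starred blocks
hold the columns generated by the covariate(s) of interest (a categorical
covariate with $m$ levels contributes $m-1$ treatment-coded columns) and the
daggered blocks hold everything else, including the intercept. The null
hypothesis is that all starred coefficients vanish in both components.

1. **Residualize.** Solve the least-squares problem
   $\hat\Sigma = \arg\min_\Sigma \lVert X^* - X^\dagger\Sigma \rVert^2$ and
   replace $X^*$ by $\tilde X = X^* - X^\dagger\hat\Sigma$ (same for $Z$).
   Because $(\tilde X, X^\dagger)$ spans the same column space as
   $(X^*, X^\dagger)$, the maximized likelihood is unchanged — the package
   asserts this identity in its test suite for all eight families — but
   $\tilde X$ is exactly orthogonal to the nuisance block, which is what
   makes permuting it meaningful.
2. **Permute.** For $b = 1, \dots, B$ draw a random permutation of the row
   indices and apply the *same* permutation to the rows of $\tilde X$ and
   $\tilde Z$. Refit the full model on the permuted design and form the
   full-versus-reduced likelihood-ratio pivotal
   $2(\ell_b - \ell_\text{reduced})$, with p-value $p_b$ from the
   $\chi^2_{p+s}$ upper tail, where $p$ and $s$ are the interest-column
   counts of $X$ and $Z$ (degrees of freedom add across components because
   both are tested jointly).
3. **Compare.** The observed LRT p-value is $\hat p$ from
   $2(\ell_0 - \ell_\text{reduced})$; the permutation p-value is
   $p = \frac{1}{B}\sum_b \mathbb{1}(p_b < \hat p)$, with strict inequality.
   An add-one smoothed variant $(1 + \#\{p_b \le \hat p\})/(1+B)$ is
   available behind `smooth = TRUE` for downstream FDR procedures that
   dislike exact zeros, but it is not the default.

Under the null the observed pivotal is exchangeable with the permuted ones,
so $p$ is calibrated regardless of whether the count model fits — the chi-squared
reference only serves as a monotone transform. That is the entire point: the
LRT p-value `p_lrt` inherits every model misspecification, the permutation
p-value `p_perm` does not.

## The eight families

`prr_families()` enumerates the 2 × 2 × 2 grid {Poisson, negative binomial,
binomial, beta-binomial} × {plain, zero-inflated}:

* **Poisson type** models the mean on a log link with an additive
  $\log s_i$ offset.
* **Binomial type** treats $Y_{ij}$ as successes out of $s_i$ trials on a
  logit link.
* **Overdispersion** enters as the negative-binomial size $\theta$
  (variance $\mu + \mu^2/\theta$) or the beta-binomial intra-class
  correlation $\rho \in (0,1)$ (via $a = p\gamma$, $b = (1-p)\gamma$,
  $\gamma = (1-\rho)/\rho$).
* **Zero inflation** mixes a point mass at zero with weight
  $\pi_i = \mathrm{logit}^{-1}(z_i'\beta)$ into the base density. Count and
  zero components are tested simultaneously.

Auxiliary parameters are optimized on unconstrained internal scales
($\log\theta$, $\mathrm{logit}\,\rho$) so the quasi-Newton optimizer never
collides with a hard boundary.

## Fitting and the honest convergence flag

Maximization uses BFGS with analytic gradients (a compiled kernel mirrored
by a plain-R reference implementation that the test suite compares it
against). Starting values matter — the beta-binomial likelihood can be
unevaluable far from its optimum — so the package uses an IRLS pass for the
mean coefficients, the logit of the observed zero excess for the zero
intercept, and method-of-moments dispersion. The two plain GLM families
(Poisson, binomial) delegate the inner optimization to `stats::glm.fit`,
then verify the result against the package's own gradient.

A fit is reported `converged = TRUE` only if the optimizer terminated below
its iteration cap (200, with one deterministic perturbed restart), the
gradient norm satisfies $\lVert g \rVert \le 10^{-6}(1 + |\ell|)$, and no
auxiliary parameter sits at its internal boundary ($|\cdot| > 15$). The
tolerance is scaled by the log-likelihood magnitude because an absolute
$10^{-6}$ is below attainable floating-point accuracy when $|\ell|$ is in
the hundreds. Two refinements keep the flag honest without being vacuous:

* an iteration-cap hit is first polished by a re-run from the endpoint with
  a terminating tolerance; the cap only counts if the polish also hits it;
* when the zero component vanishes ($\max_i \pi_i < 10^{-4}$ — common when a
  ZI family is fitted to a taxon that is not zero-inflated), the supremum
  lies at the coefficient boundary and the gradient along the vanished
  component cannot reach zero; the check then covers the identified
  directions only, and a formally non-zero gradient is accepted when a
  Cauchy-step bound shows the attainable log-likelihood gain is below
  $10^{-7}(1 + |\ell|)$.

Permutation refits are warm-started from the reduced-model solution with the
interest coefficients at zero (under permutation the interest effect is near
null, so this is both faster and less prone to bad local optima than
starting from the observed fit) and use a looser stopping rule
(`reltol` $10^{-9}$, gradient tolerance $10^{-4}$-scaled), since only the LR
statistic at about $10^{-4}$ precision feeds the pivotal. Non-converged
permutation refits are dropped and counted in `n_failed`; if more than 10%
of the $B$ iterations fail, the taxon is failed outright rather than
silently renormalized. All-zero taxa are skipped: no family extracts
information from them.

## The simulation framework

`simulation_config()` + `build_experiment()` generate tables with known
ground truth. The defaults encode the study conditions the package's
evaluation uses: 149 samples × 531 taxa, four diet groups assigned uniformly,
10% of taxa differentially abundant per factor, effect sizes from the
multiplier grid {1.25, 1.5, 2, 3, 5}, and in the confounded design
urbanization (×3 effect, its own 10% of taxa per group) plus an age effect
ramping linearly from ×1 at age 20 to ×5 at age 69. Confounding follows
fixed joint/conditional tables (e.g. 80% of meateaters are low-urbanization;
no vegan is 60 or older), so diet, urbanization and age are entangled the
way real cohort covariates are.

The base table is a zero-inflated negative binomial: per-taxon means
log-uniform on 1–100, dispersions uniform on 0.1–2, structural-zero
probabilities uniform on 0–0.6, scaled by log-normal per-sample library-size
factors (sdlog 0.5). These ranges put the bulk of taxa in the overdispersed,
zero-inflated regime of real 16S data (a taxon with mean 30 and dispersion
0.8 has variance above 1100) while still spanning nearly-Poisson taxa. What
the generator does *not* emulate: compositional coupling between taxa
(columns are independent given the library-size factor), phylogenetic
correlation, and batch structure. Calibration results on it therefore speak
to marginal count behavior, not to compositionality-induced artifacts.

Signal injection follows two mechanisms, separately or combined:

* **counts**: non-zero counts of affected samples are multiplied and rounded
  half-to-even (unbiased for fractional multipliers such as 1.25); zeros are
  untouched.
* **zeros**: the taxon's baseline odds of a non-zero observation
  (#nonzero/#zero) is multiplied for affected samples, every sample's
  non-zero status is redrawn, and non-zero draws consume the original
  non-zero values without replacement (in sample order) until the pool
  depletes — the non-zero multiset is conserved, only reshuffled toward
  affected samples.

In combined mode the zero shuffle runs first and the count multiplication
second, so the conservation property stays checkable before values change.
Library sizes are recomputed after injection, since they are row sums by
definition.

## Evaluation metrics

For a p-value vector against known truth: FPR and TPR at a fixed threshold
(strict `<`), `power_at_fpr()` (TPR at the largest achievable threshold
whose empirical FPR stays at or below the target; ties break toward the
smaller threshold so the constraint binds exactly), and `auc_at_fpr()`
(trapezoidal partial ROC area up to FPR 0.10). Two normalizations of the
partial area are offered because "normalized by the maximum attainable
area" is ambiguous: the default divides by `max_fpr` (chance level 0.05);
`standardized = TRUE` applies the McClish transformation (chance level 0.5).
Neither is privileged by the package's own validation, which asserts only
closed-form extremes, the chance level, invariance under monotone p-value
transforms, and agreement with an independent ROC implementation.

## Problem sizes used in validation

The packaged validation runs desk-scale versions of the full design:
n = 100 samples, m = 100 taxa (50 for the slower zero-inflated families),
B = 200 permutations, 5 repetitions, effect ×2. At these sizes the
PRR test's empirical FPR at the 0.05 threshold lands within ±0.02 of
nominal for Poisson, ZI negative binomial and ZI beta-binomial families,
while the plain Poisson/binomial LRT rejects over 90% of null taxa on
strongly overdispersed zero-inflated data — the misspecification failure
the PRR construction exists to fix. Null uniformity of `p_perm` is checked
by Kolmogorov–Smirnov across 500 null taxa. Repetition seeds derive
deterministically from the master seed (`seed + r`; per-taxon seeds are
pre-assigned from the master seed and the taxon index), so every run —
including multi-worker runs — is exactly reproducible.

One consequence of recomputing library sizes deserves emphasis. Injection
increases the row sums of affected samples, so after recomputation the
*relative* abundance of every untouched taxon is genuinely lower in affected
samples: "null" taxa acquire a real, compositionally induced association
with the grouping covariate. A perfectly calibrated test will therefore
reject somewhat more than the nominal fraction of per-taxon-null hypotheses
when the injected mass is a large share of the table — which happens at
small taxon counts with strong counts-and-zeros effects, where 10% of taxa
can carry an appreciable share of all reads. This is a property of the
simulation design (and of compositional count data generally), not of the
test: on pure-null tables, where no such leakage exists, the validation
suite checks that the PRR p-values are uniform and the false positive rate
sits at its nominal level.

## Known limitations

* Permutation resolution is $1/B$; with the default strict-inequality
  p-value, B = 1000 gives a finest attainable p of 0.001 and exact zeros
  occur. Use `smooth = TRUE` before Benjamini–Hochberg if that matters.
* The beta-binomial families are the slowest and most numerically delicate;
  a small fraction of permutation refits may be dropped (reported in
  `n_failed`).
* The ZI families' zero component is logistic by construction; other link
  choices are out of scope.
* Hurdle (truncated) models, random effects, moderated dispersion shrinkage
  and score/Wald test variants are deliberately not implemented.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_samples = 100, n_taxa = 50,
                         signal_mode = "counts_zeros", effect_size = 2,
                         seed = 1)
sim <- build_experiment(cfg)
tab <- prr_test_table(sim$counts, sim$covariates, interest = "diet",
                      families = c("Poisson", "ZINegativeBinomial"),
                      zero_formula = ~diet, B = 200, seed = 1)
truth <- da_truth(sim, "diet")
ord <- match(sim$counts$taxon_ids, tab$taxon_id[tab$family == "Poisson"])
fpr_tpr(tab$p_perm[tab$family == "Poisson"][ord], truth)
```
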