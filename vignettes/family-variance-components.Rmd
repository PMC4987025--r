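---
title: "Family-based variance components, genetic correlations and polygenic scores"
author: "famvc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variance components, genetic correlations and polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvc)
```

## The problem

Complex traits such as chronic pain cluster in families for two
confounded reasons: relatives share alleles, and they share
environments — most strongly a spouse or partner, but also a sibship
and a household. `famvc` implements the family-based mixed-model
toolkit used to separate these sources on a population pedigree
cohort: pedigree-derived covariance structures, univariate variance
decomposition on ordinal (Chronic Pain Grade, 0–4) and binary (major
depressive disorder) traits, the bivariate model that partitions the
pain–depression covariance into genetic and spouse-environment parts,
and polygenic risk-score profiling with relatedness-aware association.
Because the motivating cohorts are managed-access, the package ships a
gene-dropping simulator that generates family cohorts with known
ground truth, and every inferential stage is validated against it.

## Model

For individual $i$ with phenotype $y_i$ the working model is the
animal model with shared-environment terms

$$ y = X\beta + a + c_{sp} + c_{sib} + c_{hh} + e, $$

where $a \sim N(0, \sigma^2_A A)$ with $A$ the additive (numerator)
relationship matrix, each shared-environment term is
$N(0, \sigma^2_c C)$ with $C$ the 0/1 block covariance of the couple,
sibship or household partition, and $e \sim N(0, \sigma^2_E I)$. Fixed
effects are sex, age and age$^2$ throughout. The heritability and
shared-environment proportions are each component's share of the
summed variance.

### Relationship structures

`additive_relationship_matrix()` runs the tabular method in
topological order: $A_{ii} = 1 + \tfrac12 A_{fm}$ and
$A_{ij} = \tfrac12 (A_{jf} + A_{jm})$, a missing parent contributing
zero (an individual with one known parent is treated as having a
unique non-inbred phantom founder for the other slot — the standard
convention). The recursion runs dense inside each connected family
component and is assembled sparse, so cohorts of $10^4$–$10^5$
individuals stay linear in total size. The matrix equals twice the
kinship matrix; the test suite checks it exactly against an
independent recursive-coancestry oracle on random pedigrees.
`additive_relationship_inverse()` assembles $A^{-1}$ directly from
Henderson's rules with inbreeding, which the Gibbs backend uses as the
prior precision of the genetic effects.

Group structures (`group_covariance_matrix()`) are deliberately coded
0/1 and not group-size normalised: the entry is 1 exactly when two
individuals share the group, which is the covariance implied by one
shared deviate per group and keeps the variance-component
interpretation clean. Individuals outside every group are singleton
blocks, so the diagonal is always 1 and every individual carries the
same total variance. Couples default to parent pairs with at least one
common offspring when no couples file is supplied — the only
pedigree-internal signal of partnership; an explicit couples file
overrides this. Household variables can be supplied as one or two
separate files, each producing its own structure, since household
semantics vary between cohorts.

## Estimation backends

### AI-REML

`fit_reml()` maximises the restricted likelihood of any model that is
*linear in its variance parameters*, $V(\theta) = \sum_k \theta_k
G_k$, by average-information updates. The engine exploits that $V$ is
block diagonal over the connected components of the combined
covariance pattern — independent families — so each iteration costs
the sum of small dense factorizations rather than one $n^3$ solve; the
inner loop is compiled (RcppArmadillo). Safeguards: a trust region on
the Newton step (the average-information matrix is singular at
perfectly correlated boundaries), step halving, a multiplicative
fixed-point fallback for variance parameters, a damped gradient step
as a last resort, and clamping of variances at a small positive floor.
Convergence is declared when the restricted log-likelihood changes by
less than $10^{-6}$. Standard errors come from the inverse
average-information matrix and proportion intervals from the delta
method.

Ordinal grades are fitted by this backend as numeric 0–4 working
scores. That is a declared approximation: categorisation attenuates
observed-scale variance shares relative to the liability scale, so
REML proportions from the raw grades are systematically smaller than
the generative liability-scale shares. Parameter-recovery validation
therefore uses Gaussian-scale traits, while analyses of real ordinal
data should read the REML output as observed-scale decompositions (the
likelihood-ratio machinery, which only compares nested fits on the
same working scale, is unaffected). Correlations are much less
affected: attenuation factors cancel to first order in the ratio
$\mathrm{cov}/\sqrt{v_1 v_2}$, which is why the bivariate genetic
correlation is estimated on working scales without liability
conversion — matching the convention of the motivating analysis,
which reported unconverted coefficients.

### Probit threshold Gibbs sampler

`fit_gibbs_ordinal()` fits ordinal and binary traits on the liability
scale: a latent Gaussian liability cut at thresholds. Two design
choices matter and both exist for mixing, not convenience:

* **Partial collapsing.** With one genetic effect per individual, the
  textbook sampler (liabilities given effects, effects given
  liabilities) is a random walk with effective sample sizes in the
  single digits, because each liability is almost determined by "its"
  effect. The sampler therefore updates liabilities and fixed effects
  under the per-family *marginal* covariance
  $V_b = \sum_c \sigma^2_c K_{cb} + \sigma^2_E I$ with the random
  effects integrated out, then redraws the effects exactly from their
  full conditional before anything else uses them, and finally draws
  the variances from their scaled inverse-chi-squared conditionals.
  This is a valid partially collapsed Gibbs scheme and raises the ESS
  by two orders of magnitude at identical cost.
* **Identification.** Binary traits fix the threshold at 0 and the
  residual at 1 (ordinary probit). For ordinal traits the classic
  device of sampling interior cutpoints uniformly between adjacent
  order statistics mixes glacially at cohort size — the cutpoint gap
  shrinks as $1/n$ while the scale information lives in the cutpoints.
  Instead all cutpoints are fixed at the normal quantiles of the
  observed category frequencies and the residual variance is freed.
  Under a threshold-generating process this pins the same quantities
  (location and scale of the liability) without the random walk; the
  restriction it adds — cutpoint spacing consistent with a normal
  marginal — holds by construction for threshold data and was verified
  on model-exact simulations (posterior proportion 0.497 for a truth
  of 0.5).

Priors on the genetic and shared-environment variances are scaled
inverse-chi-squared with scale 1 and df 0.002 — the conventional
weakly-informative variance prior of Bayesian animal models, nearly
flat on the log scale. A df-1 prior was rejected for these components
because it places essentially no mass below $\sigma^2 \approx 0.1$ and
cannot recover null components. The *residual* variance (free in the
ordinal parameterisation) instead takes a proper scaled
inverse-chi-squared prior with df 1 and scale 1: with one genetic
effect per individual the ordinal likelihood remains positive as
$\sigma^2_E \to 0$, so a near-flat prior's $\sigma^{-1}$ spike at the
origin becomes an absorbing corner of the posterior (chains observed
stuck at residual share 0.003); the proper prior's
$e^{-1/(2\sigma^2)}$ factor removes that singularity at the cost of a
single pseudo-observation. Defaults
mirror long production chains (85,000 iterations, 15,000 burn-in,
thinning 50, three chains — `mcmc_profile("paper")`), with a short
profile (5,000/1,000/5) for desk-scale runs; convergence is flagged
through per-component effective sample sizes (threshold 100) and a
cross-chain discrepancy check.

DIC is computed as mean deviance plus the effective parameter count
$p_D$ (mean deviance minus deviance at the posterior means). The
deviance is the *marginal* family-level likelihood — the probability
of each family's observed category vector with all random effects and
the residual integrated out, estimated by the GHK
sequential-conditioning sampler on a thinned subsample of draws, with
a fixed uniform-deviate panel shared across competing models (common
random numbers). The conditional deviance (given the realised random
effects), which is what falls out of the chain for free, was evaluated
and rejected for model comparison: every group-share structure assigns
singleton individuals a private effect, and a conditional deviance
rewards any model that merely adds such a private noise channel —
spurious components produced large spurious DIC improvements. With the
marginal deviance a spurious component raises DIC (by roughly its
added parameter count), as it should.

### Model selection

`stepwise_model_selection()` reproduces the forward procedure: start
from the additive-only model, add each candidate shared environment in
turn, keep the best addition if it improves the criterion, then try to
add one more, stopping when nothing improves. Under `"LRT"` a
candidate improves the fit when its one-degree-of-freedom test is
significant at $\alpha = 0.05$ (plain $\chi^2_1$ by default; the
boundary-corrected half-mixture is available, since testing a variance
on its boundary makes the plain test conservative). Under `"DIC"` an
addition must lower DIC by more than a small tolerance (0.1), which
also implements the declared tie-break: equal criteria favour fewer
components. The full trace of every fitted model is retained.

## Bivariate model

`fit_bivariate_reml()` stacks two traits and gives every component —
additive, retained shared environment, residual — an unstructured
2×2 covariance block. The model includes additive + spouse + residual
by default, i.e. the univariate winner's shape, not all four
components. Missingness is pairwise-complete: an individual missing
one trait still contributes to the other. Correlations are
off-diagonals over geometric-mean variances with delta-method SEs.
Nulls for the significance tests (`constrained_fit()`) pin exactly one
off-diagonal at zero, giving one degree of freedom; the full model is
warm-started from the better-fitting null so the comparison stays
nested even when the full fit sits in a flat corner of the parameter
space. The adjusted phenotypic correlation is the summed-component
cross-covariance over the total variances, tested as estimate/SE
against a standard normal (two-tailed); the raw Pearson correlation is
reported alongside, since either convention may be wanted and the two
differ in how fixed effects and relatedness are handled.

## Polygenic scoring

Scores follow the thresholding construction: at each discovery
p-value cutoff $p_T \in \{0.01, 0.05, 0.1, 0.5\}$ the score is the
dosage-weighted sum of aligned effect sizes. Allele alignment is
PRSice-style — matching orientation keeps the weight, swapped alleles
flip its sign, strand-ambiguous (A/T, C/G) SNPs are excluded by
default, the reverse-complement orientation is tried before declaring
a mismatch, and every exclusion is reported with a reason. Missing
dosages are imputed at twice the counted-allele sample frequency
(zero-variance contribution); SNPs with no observed dosage are dropped
rather than imputed. Scores are standardised before association so the
coefficient is a per-SD effect. No LD clumping is applied by default
because the simulated panel is LD-free.

`prs_mixed_association()` fits the score as a fixed effect in a mixed
model with the additive relationship structure (REML Wald inference,
or the Gibbs backend's posterior summaries), optionally adjusted by
`ancestry_components()` — the top eigenvectors of the standardised
genotype covariance, which play the same adjustment role as
multidimensional-scaling components and default to four. Passing
`structure = NULL` gives the unrelated-cohort analysis without a
relationship matrix. Variance explained is
$\beta^2 \mathrm{Var}(\text{score})/\mathrm{Var}(y)$ — the variance of
the fitted score contribution over the phenotype variance.

## The synthetic cohort

The generator is first-class, tested code, and its defaults *are* the
study conditions used throughout validation:

* families of three generations; sibship sizes Poisson(2.2); 60% of
  middle-generation offspring partner with immigrant founders;
  households are each couple plus its never-partnered offspring;
* liability shares: additive 0.4, spouse 0.2, residual 0.4 (sibship
  and household available but 0 by default); cross-trait genetic
  correlation 0.5 and spouse-environment correlation 0.5;
* grade frequencies (0.55, 0.15, 0.12, 0.10, 0.08) for grades 0–4 — a
  majority-no-pain population shape; disease prevalence 0.12. Neither
  is published for the motivating subsample, so these are declared
  assumptions, fixed once;
* ages uniform 18–90 with coefficients (sex 0.3, age 0.02,
  age² −10⁻⁴); sex balanced. These exist to exercise the fixed-effect
  machinery, not for demographic realism;
* genetic values by gene dropping: founders drawn at the additive
  variance, non-founders as the parental mean plus a Mendelian
  deviate of variance $\tfrac12\sigma^2_A(1 - (F_f + F_m)/2)$ — exact
  for arbitrary pedigrees in linear time, with the matrix-factorization
  construction retained in tests as the oracle;
* genotypes by Hardy–Weinberg founder draws and Mendelian
  transmission; an independent unrelated training sample (never the
  target pedigree) yields marginal-regression summary statistics for
  scoring.

What it does **not** emulate: linkage disequilibrium, assortative
mating, population stratification (a two-population construction is
used only to test the ancestry components), age structure, or
informative missingness. Passing tests demonstrate that the estimators
recover the truth under the stated generative model — not that real
cohort data meet those assumptions.

## Validation scale

The packaged checks run at sizes chosen to give stable Monte-Carlo
behaviour on a single core: relationship-matrix oracle equivalence on
50 random pedigrees; gene-dropping covariance against $\sigma^2_A A$
with 10,000 replicates on a 10-member pedigree; univariate recovery on
20 cohorts of ≈6,000 individuals (mean ĥ² 0.398, spouse share 0.197,
20/20 interval coverage in the development runs); stepwise-selection
fidelity over 20 seeds per criterion on cohorts of ≈2,500 (a size set
by a power analysis of the grade-scale spouse signal: the deviance
gain of the true model clears the DIC decision margin on essentially
every seed); bivariate recovery at n ≈ 6,000 with 200 reduced-size
(n ≈ 1,500) null replicates for LRT calibration; PRS power at
n_train = 20,000, n_target ≈ 2,000 on panels of 1,000–2,000
independent SNPs, with the target trait carrying the scored panel at
0.8% of its variance — the weak-prediction regime in which
cross-cohort pain scores operate, giving variance explained under 1%
with detectable association. `scripts/acceptance.R` re-runs these end
to end from a seed.

## Known limitations

* REML on raw ordinal scores is an observed-scale analysis; no
  liability transformation of univariate proportions is applied.
* The Gibbs backend's fixed-cutpoint identification assumes the
  marginal liability is approximately normal; gross violations (e.g.
  dominant fixed effects with wild covariate distributions) would bias
  the scale.
* Delta-method SEs for correlations degrade near |r| = 1; the PSD
  repair caps |cov| marginally inside the boundary, so reported
  correlations never exceed 1 − 10⁻⁵ in magnitude.
* The LRT for a variance component on its boundary is conservative in
  its plain-χ² form; the boundary mixture option is provided but is
  not the default, which follows the stated analysis procedure.
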