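---
title: "Moderated twin variance components with an item response measurement model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated twin variance components with an item response measurement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acemirt)
```

## The problem

Classical twin designs decompose phenotypic variance into additive genetic
(A), common environmental (C) and unique environmental (E) parts by
contrasting monozygotic (MZ) and dizygotic (DZ) pair covariances.
Interaction with a measured moderator — family socio-economic status being
the motivating example — asks whether those variance components themselves
change with the moderator (ACE × M). Behavioural phenotypes, however, are
usually test or questionnaire *sum scores*, and a sum score is a nonlinearly
compressed version of the underlying trait: hard tests compress the low end
(floor), easy tests the high end (ceiling). Because moderation analysis is a
statement about variances *conditional* on the moderator, any
trait-dependent compression that correlates with the moderator manufactures
interaction effects that are pure scale artefacts. `acemirt` implements the
remedy: fit the biometric moderation model and a Rasch item response model
*jointly*, so the analysis happens on the latent-trait scale where
measurement error is modelled rather than baked into the phenotype.

## The model

For family $i$ with moderator $M_i$ (shared by both twins — individual-level
moderators are rejected at validation), each variance component is moderated
on the log scale:

$$\sigma^2_{Ai} = \exp(\beta_{0a} + \beta_{1a} M_i), \quad
  \sigma^2_{Ci} = \exp(\beta_{0c} + \beta_{1c} M_i), \quad
  \sigma^2_{Ei} = \exp(\beta_{0e} + \beta_{1e} M_i).$$

The log link keeps every variance positive and makes the map from
coefficients to variances one-to-one. The older path-moderation approach
(loadings $\beta_0 + \beta_1 M$, variance their square) is *not* identified:
`purcell_equivalent_solutions()` enumerates, for a binary moderator, the
four coefficient pairs with identical fit, which is why confidence
statements about path-moderation coefficients are not interpretable. This
identified reparametrization buys a restriction: moderation is monotone in
$M$, so a U-shaped (parabolic) moderation pattern cannot be represented.

Twin $j$'s latent trait is $\theta_{ij}$ with
$E(\theta_{ij}) = \mu + \beta_{1m} M_i$. Integrating the familial effects
out, a pair is bivariate normal with common variance
$\sigma^2_{Ai} + \sigma^2_{Ci} + \sigma^2_{Ei}$ and cross-covariance
$\sigma^2_{Ai} + \sigma^2_{Ci}$ (MZ) or
$\tfrac12\sigma^2_{Ai} + \sigma^2_{Ci}$ (DZ). The measurement layer is a
Rasch model with known difficulties $b_k$ and fixed discriminations $a_k$
(1 for pure Rasch):
$P(Y_{ijk} = 1 \mid \theta_{ij}) = \mathrm{logistic}(a_k(\theta_{ij} - b_k))$.
Fixing the item parameters anchors the latent scale; estimating them jointly
is out of scope. Missing item responses drop out of the likelihood; a twin
with missing items keeps a usable latent trait through the remaining items.

Heritability is reported at the moderator reference level,
$h^2 = \exp(\beta_{0a}) / (\exp(\beta_{0a}) + \exp(\beta_{0c}) +
\exp(\beta_{0e}))$.

## Estimation

Inference is fully Bayesian. Priors (all config-exposed through
`prior_spec()`): Normal(0, 10²) on $\mu$ and $\beta_{1m}$; Normal(0, 2²) on
the six log-variance coefficients — weakly informative on the log scale,
which also stops $\exp$ overflow; Beta(1, 1) on the moderator probabilities
$\pi_{mz}, \pi_{dz}$ used for imputation. Families with a missing moderator
are kept: their $M_i$ is a latent Bernoulli($\pi_{zygosity}$) variable
updated inside the chain (`moderator_policy = "impute"`), with
`"complete_cases"` available as the traditional comparison.

The sampler is an adaptive Metropolis-within-Gibbs scheme written for this
model:

* The family-level latent effects (familial effect for MZ; common
  environment, family genetic value and Mendelian terms for DZ) are
  marginalized analytically into the exact bivariate normal above. This
  shrinks the latent space to $\theta$ alone and removes a layer of
  posterior coupling.
* $(\mu, \beta_{1m})$ are conditionally Gaussian and drawn exactly.
* The six log-variance coefficients move by a joint adaptive Metropolis step
  (empirical-covariance proposal, target acceptance 0.234, adaptation frozen
  after burn-in so kept draws come from a fixed kernel).
* In the joint IRT model a second, *non-centered* variance move is
  interweaved: each pair's $\theta$ is re-expressed as standardized
  residuals, the variance coefficients are proposed jointly while $\theta$
  is rescaled along, and the move is accepted on item likelihood plus prior.
  Centered and non-centered updates mix along complementary directions of
  the posterior; their composition removes most of the notorious slow mixing
  of hierarchical variance parameters.
* $\theta_{ij}$ updates by per-twin random-walk Metropolis against its
  conditional-normal prior given the co-twin, with per-twin step sizes tuned
  to ~44% acceptance during warm-up. The likelihood kernel is in C++.

Correctness of the stationary distribution is asserted by tests rather than
assumed: the mean-parameter posterior matches deterministic grid quadrature
on small instances (both the phenotype-only and the joint IRT model), and
the full posterior matches an independently coded Gibbs implementation of
the augmented hierarchy (JAGS) within Monte Carlo error. Convergence should
be checked per run with `convergence_report()` (split-chain $\hat R$,
effective sample size); `mcmc_config()` defaults mirror the reference
protocol (5,000 adaptation / 50,000 burn-in / 25,000 kept draws), while the
test suite and the acceptance script use much shorter chains that the
diagnostics support at their problem sizes.

Initialization: $\theta$ starts at a shifted empirical logit of each twin's
proportion correct; variance intercepts split the observed phenotypic
variance 25/25/50; slopes start at 0 with small per-chain jitter. Draws of
structural coefficients whose proposals would overflow ($\exp$ beyond double
range) are rejected by the $-\infty$ log-likelihood rule rather than
clamped, keeping the kernel exact. A "structurally absent" component is
represented by a very negative intercept, not a special flag, so the
parameter space stays unconstrained.

## The simulator

`simulate_twin_data()` generates the full hierarchy: the MZ path draws a
familial effect with variance $\sigma^2_A + \sigma^2_C$ shared by the pair;
the DZ path draws a family genetic value $A1_i$ and per-twin Mendelian terms
$A2_{ij}$, combined as $\sqrt{\tfrac12}A1_i + \sqrt{\tfrac12}A2_{ij}$ and
scaled by $\sigma_A(M_i)$ — the unique weighting with marginal variance
$\sigma^2_A$ and co-twin genetic correlation 0.5. Item responses are
independent Bernoulli draws given $\theta$. The MZ count is fixed at
`round(prop_mz * n_pairs)` rather than binomially drawn, matching a design
with a fixed MZ percentage. Seeds determine everything: the same
configuration reproduces bit-identical datasets, and replication $r$ uses a
substream seed derived from the scenario seed.

The two benchmark scenarios use 2,000 pairs (28% MZ), 40 items, ACE
variances (0.25, 0.25, 0.5), a Bernoulli(0.5) family moderator with main
effect $\beta_{1m} = 0.7$ — which explains
$0.1225/1.1225 \approx 10.9\%$ of phenotypic variance
(`moderator_variance_explained()`) — and *zero* true interactions. Scenario
1 draws item difficulties from Normal(+1, 1): mostly hard items, a floor
effect, positively skewed sum scores. Scenario 2 mirrors it with
Normal(−1, 1). The presets set $\mu = -\beta_{1m} \cdot P(M{=}1) = -0.35$ so
the *population* latent mean sits at zero: with the phenotypic population
mean anchored at zero the two scenarios are exact mirror images of one
another, and the moderator's mean effect does not shift the whole cohort
relative to the item bank. Under this calibration the pooled DZ sum-score
skewness concentrates near ±0.55; note that any single 2,000-pair dataset
carries a skewness sampling spread of roughly ±0.1 around that (item-bank
draw plus sampling noise), so one-dataset skewness figures are only
reproducible to that accuracy.

What the simulator does *not* emulate: ordinal items, individual-specific
moderators, non-normal latent effects, local item dependence, or
missing-data mechanisms beyond missing-completely-at-random masking of the
moderator. Passing tests therefore demonstrate correctness of the method
under its own generative assumptions, not robustness to their violation.

## The sum-score comparison

`fit_acem_sumscore()` is the analysis the package exists to warn about: per
twin, count correct responses; divide every score by the standard deviation
of the scores of all twins (both zygosities pooled) whose family has
moderator value 1 — so that group's scaled SD is exactly 1, putting the
sum-score and latent-trait analyses on comparable scales; then fit the same
biometric kernel (`fit_acem_phenotype()`, literally the same code path)
treating the scaled score as the observed phenotype, with its own free mean
parameters since the scale differs. A twin with *any* missing item gets a
missing phenotype rather than a partial sum, because a partial sum measures
something else; such twins drop out of the phenotype likelihood only.

On floor-effect data this analysis produces spuriously *positive*
interaction estimates — the moderator-1 group sits further from the floor,
so its observed-score variance is inflated relative to the moderator-0
group — and on ceiling-effect data the mirror-image negative ones, with the
E × M coefficient the most reliably distorted. The joint IRT fit on the same
datasets keeps interaction posteriors centred near zero and
highest-posterior-density exclusion rates near the nominal 5%. At the
package's test scale (20 replications) the floor-scenario sum-score E × M
posterior mean averages around +0.2 with an across-replication SD near
0.09.

## Evaluation utilities

`hpd_interval()` finds the shortest interval containing the target
probability by scanning a fixed-length window over the sorted draws (checked
against an exhaustive window search and against `coda`). Intervals are
computed on pooled chains at 0.95 by default. `power_from_replications()`
counts intervals excluding zero; the same number is power under a nonzero
truth and the false-positive rate under a zero truth. For variance
components, which are bounded below by zero, HPD exclusion of zero is not a
significance test and replication summaries should not read it as one.
`skewness_joanes_gill()` returns the moment estimator $g_1$ and the two
bias-adjusted variants $b_1$ and $G_1$ (cross-checked against `e1071`);
for samples of a few thousand the three agree to three decimals.
`convergence_report()` computes split-chain $\hat R$ (each chain halved, so
it works for single-chain runs) and effective sample sizes, flagging
parameters above a 1.1 threshold.

## Problem sizes used by the tests

The replication suites run at sizes chosen to exercise the full pipeline
while keeping the suite practical on a single core: sum-score skewness on 30
replications of 2,000 pairs per scenario; false-positive control of the IRT
model on 25 replications of 200 pairs × 20 items; the sum-score bias
protocol at its benchmark size (20 replications of 2,000 pairs × 40 items);
and parameter recovery on 20 replications of 1,000 pairs × 20 items — the
item-information design, where 20 items with known parameters are indeed
enough to recover all eight structural coefficients within 3 empirical
standard errors. At a few hundred pairs the variance-coefficient posteriors
are wide and their posterior means sit visibly inside the prior's pull
(Bayesian shrinkage), which is why the recovery suite uses the 1,000-pair
design rather than something smaller.

## Known limitations

No dominance (D) component, sex limitation, or bivariate moderation of
phenotype and moderator jointly; discriminations are fixed constants, never
estimated; moderation is monotone by construction; the moderator measurement
itself is assumed error-free. The HPD-based "significance" convention
inherits the usual caveats for bounded parameters. Paper-scale MCMC runs
(2,000 pairs × 40 items at the default chain lengths) take on the order of
tens of minutes; the defaults exist for final analyses, not exploration.
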