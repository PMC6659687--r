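---
title: "Models and methods: reproductive mode, sexual selection, and diversification"
author: "viviphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viviphy)
```

## The scientific problem

In live-bearing fishes and other viviparous lineages, females differ in
*when* they provision their offspring.  Lecithotrophic females load the
egg with yolk before fertilization; placentotrophic females transfer
resources across a placenta throughout gestation.  The timing of
provisioning is predicted to reshape sexual selection: a female who has
already invested heavily in an egg benefits from choosing her mate
before copulation (favouring ornaments, courtship, dichromatism),
whereas a female with cheap eggs and post-fertilization control over
allocation can shift mate screening after copulation, relaxing selection
on male display traits.  Both regimes carry predictions about
speciation: pre-copulatory sexual selection should accelerate the origin
of pre-zygotic isolation, while the rapid antagonistic coevolution of
placental provisioning should accelerate post-zygotic isolation.

`viviphy` implements the comparative-phylogenetics toolchain needed to
test these predictions on a time-calibrated phylogeny with species-level
trait data: trait scoring and binarization, ancestral state
reconstruction, correlated evolution of male/female trait pairs,
trait-dependent diversification models, and two safeguards against the
known false-positive behaviour of state-dependent diversification
methods.  Every stage is also exercisable on synthetic data with known
ground truth, which is how the package validates itself.

## Trait scoring

**Matrotrophy index (MI).**  MI is the ratio of offspring dry mass at
birth to egg dry mass at fertilization.  Under exponential growth or
loss of embryo mass across the 0–50 developmental staging scale, a
species with overall mass ratio MI follows a linear regression of
ln(dry mass) on stage with slope ln(MI)/50.  This gives the package's
one analytic anchor: MI = 0.7 corresponds to a slope of
`ln(0.7)/50 = -0.00713`, i.e. −0.0071 at four decimals.  Natural
logarithms are essential here; base-10 does not reproduce that value.

**Placentotrophy calls are conservative.**  A species is scored
placentotrophic only when its pooled collection is *trustworthy* (more
than 7 broods and a pooled stage range wider than 25 units) and either

1. some population's slope is significantly greater than 0 (one-sided
   *t* test, n − 2 df, p < 0.05), or
2. at least two populations have an estimated MI above 1 with slopes
   significantly above the MI = 0.7 reference slope (−0.0071).

Anything else scores 0.  Insufficient data therefore defaults to
lecithotrophy — false positives are treated as worse than false
negatives.  The trustworthiness thresholds apply to the pooled
species-level collection by default (`pooled = TRUE`); a per-population
variant is available.  No multiplicity correction is applied to the
p < 0.05 rules; they are fixed decision thresholds, not inference.

**Binarization.**  Continuous male traits (relative gonopodium length,
size-dimorphism index) are split at the median: the lowest ⌈n/2⌉
species score 0, the rest 1.  Values tied with the boundary all score 0
— with discrete ties the "bottom 50%" is taken literally, and the choice
is deterministic.  The sexual-selection index is the plain sum of the
courtship, dichromatism and ornamentation indicators (0–3), missing if
any component is missing.

## Mk models and ancestral states

Binary (and multi-state) characters evolve by a continuous-time Markov
chain with generator Q; the likelihood on the tree is computed by
Felsenstein pruning with per-branch matrix exponentials and per-node
rescaling.  ER (one rate) and ARD (k(k−1) rates) models are fitted by
bounded maximum likelihood and compared by AIC.  Ancestral states are
exact per-node marginal posteriors from a two-pass (inside/outside)
algorithm; stochastic character maps draw joint node states exactly and
then fill in branch histories by rejection sampling, falling back to
uniformization after 10^4 rejections so termination is guaranteed.

Design choices worth knowing:

* The default root prior for ancestral-state work is **uniform**,
  matching the long-standing default of the standard `ace`-style
  implementations; FitzJohn weighting is available for consistency
  experiments with the diversification models.
* Optimiser bounds are [1e-8, 1e3] per unit branch length, with the ER
  solution used as one ARD start plus log-uniform restarts under a fixed
  seed.
* Origin/loss counts from an ML reconstruction assign each node its
  maximum-probability state with ties broken toward absence (the
  conservative direction); a stochastic-map counter (posterior mean
  gains/losses) is provided alongside, since either convention is
  defensible.

## Correlated evolution of trait pairs

Two binary traits are encoded as a four-state joint chain
((0,0), (0,1), (1,0), (1,1)).  The *independent* model has four rates
(gain/loss of each trait, shared across backgrounds); the *dependent*
model has eight (every single-trait transition rate may depend on the
other trait's state).  Dual transitions — both traits changing in the
same instant — are fixed at zero, the standard Discrete formulation.

**Reversible-jump MCMC.**  Each rate is either in the zero bin or free;
free rates carry an exponential prior whose mean is itself uniform on
(0, 20) and is sampled as part of the chain (hierarchical treatment —
the alternative reading, re-drawing a fixed mean once per chain, is
available via `hyper = FALSE`).  Moves are multiplicative rate updates,
zero-bin toggles whose birth proposals draw from the prior (so the prior
density cancels and detailed balance is immediate), and an independence
update of the hyperprior mean.  The sampler deliberately omits
shared-positive-bin moves that would let two rates be constrained equal:
per-rate zero/free toggles are a valid reversible move set, keep the
Z-score semantics exact, and avoid the delicate bookkeeping of
bin-merging proposals.  The model prior places probability 0.5 on each
rate being zero, independently.

The **Z-score** of a rate is the percentage of posterior samples in
which it is exactly zero; rates with Z below 5% are flagged as supported
evolutionary pathways.

**Marginal likelihoods** come from stepping-stone sampling along a
power posterior with Beta(0.3, 1)-quantile spacing (the spacing
concentrates stones near the prior, where the integrand changes
fastest); per-stone expectations are combined in log space with an
ESS-adjusted Monte-Carlo standard error.  Bayes factors are
2 × Δ log marginal likelihood with the conventional labels: ≤ 2 none,
(2, 5] positive, (5, 10] strong, > 10 very strong.  Stepping-stone runs
default to a fixed exponential prior mean so that the estimate targets a
well-defined model; the hierarchical hyperprior can be included
explicitly.

Chain-length defaults are desk-scale: 2 × 10^5 iterations with 2 × 10^4
burn-in, thinning 100, three replicate chains; production-scale settings
(hundreds of millions of iterations, 200 stones × 2 × 10^5 iterations)
are reachable through the same arguments when hardware allows.  Before
running chains, rescale the tree with `scale_branch_lengths()` (default
target mean edge 0.1) so rates are of order one; any constant works
because rates back-transform by the recorded factor.

## Trait-dependent diversification

BiSSE couples a binary character to state-dependent speciation and
extinction: along each branch the extinction and data vectors obey

    E_i' = mu_i - (lambda_i + mu_i + sum_j q_ij) E_i + lambda_i E_i^2 + sum_j q_ij E_j
    D_i' = -(lambda_i + mu_i + sum_j q_ij) D_i + 2 lambda_i E_i D_i + sum_j q_ij D_j

integrated tipward-to-rootward with a Cash–Karp 4(5) adaptive stepper
(absolute and relative tolerances 1e-8, extinction probabilities clamped
to [0, 1], per-node log rescaling).  Tips start at `D = f × indicator`
and `E = 1 − f`, where f is the global sampling fraction (scored species
over described species).  At nodes, `D = lambda × D_left × D_right`.
The root uses FitzJohn weighting (each state weighted by its share of
the data likelihood) and conditions on survival of both root lineages;
equal weights and fixed-root options exist.  The six-parameter BiSSE,
the 20-parameter four-state MuSSE (all 12 transitions free), and the
ten-parameter two-trait main-effects model
(`lambda(a,b) = lambda0 + a·lambdaA + b·lambdaB`, likewise for mu, with
an independent four-rate character model) share this one kernel; the
main-effects model is an exact reparameterisation of a constrained
four-state MuSSE and is checked as such.

**ML fitting** uses a derivative-free Nelder–Mead search on log rates
(signed main effects on their natural scale), restarted from its own
solution, with equality constraints expressed as strings
(`"lambda1==lambda0"`, `"mu1==0"`).  Rates are boxed above by 100
expected events per mean edge — far beyond anything identifiable — which
keeps the simplex out of numerically stiff regimes.  A `fast` mode
(single start, shorter search, 1e-6 tolerances) exists for simulation
loops where thousands of fits are needed and procedure-consistency, not
ultimate precision, is what matters.  Nested models are compared by
likelihood-ratio chi-square and AIC.

**Bayesian runs** use univariate slice sampling under independent
Exp(rate 1/(2r)) priors — mean 2r, with r the character-independent net
diversification rate — starting from the ML estimates, 10,000
generations by default with the first 10% discarded.  Signed main
effects, which must admit negative values, receive a Laplace(0, 2r)
prior of matching scale.  Net diversification d = λ − μ is summarised
per state with 95% credibility intervals, and both posterior means and
medians are reported wherever a rate ratio is quoted, since the two can
differ in skewed posteriors.

## Safeguards against SSE false positives

State-dependent diversification tests are known to reject neutral nulls
too often.  Two checks are built in:

* **Tip-rate (FiSSE-style) test.**  Each tip's equal-splits statistic
  `ES = sum_j l_j / 2^(j-1)` (j = 1 at the terminal edge) yields an
  inverse-ES speciation-rate proxy; the observed state-1 minus state-0
  difference in mean 1/ES is compared with a null built by re-simulating
  the character on the same tree under its fitted equal-rates Mk model.
  The two-tailed p doubles the smaller tail with the +1 small-sample
  correction, capped at 1.  Equal-rates simulation is used because ER is
  typically the AIC-preferred reconstruction model for these characters;
  tips on zero-length terminal edges are excluded from group means.
* **Parametric-bootstrap calibration.**  The character is re-simulated
  (default 100 times) on the fixed tree under its fitted transition
  rates, starting from the reconstructed ancestral state (absence); each
  replicate gets the same equal-rates versus free-rates LRT as the real
  data, and the empirical 5th percentile of the null p values — nearest
  rank, i.e. the 5th smallest of 100 — becomes the significance cutoff.
  Because observed and simulated traits pass through the identical
  fitting procedure, the calibrated decision depends only on the rank of
  the observed p value, which makes its size exact under the null even
  when individual fits are numerically imperfect.  Monomorphic simulated
  traits are redrawn (with the count reported) so the replicate count
  stays fixed; the full fitted two-rate chain is used by default, with a
  gains-only switch.

## The synthetic-data generators

The generators define the package's study conditions and are first-class
tested code:

* `simulate_bd_tree()` / `simulate_bisse_tree()`: forward Gillespie
  simulation from two crown lineages with state-dependent birth, death
  and character transitions; extinct lineages are pruned so outputs are
  ultrametric.  Stopping is at a crown age or at the moment the extant
  count first reaches n, with the present placed uniformly between that
  birth and the next event.  This simple forward-stop rule (rather than
  a general sampling algorithm) slightly biases tree age at small n; the
  suite always compares like with like, so the bias cancels out of every
  check that uses it.
* `simulate_mk_trait()` / `simulate_dependent_traits()`: exponential
  waiting times down every edge with full change histories recorded.
* `simulate_brood_data()`: stages uniform over a configurable span
  centred on the 0–50 scale midpoint, ln-mass linear in stage with slope
  ln(MI)/50 plus Gaussian noise.  Defaults (12 broods, stage range 40,
  ln-mass SD 0.15) represent a well-sampled museum collection; real
  collections are messier (unbalanced stages, brood-level correlation),
  so passing recovery tests show correctness of the scoring rules, not
  robustness to field sampling artefacts.

Everything is reproducible bit-for-bit from (generator, parameters,
seed); records carry the full latent history.

## Validation strategy and problem sizes

The test suite checks every likelihood kernel against an independent
oracle: state-enumeration sums on trees of up to 6 tips (100 random Mk
and 80 joint-chain parameterisations), a closed-form constant-rate
birth–death solution for the factorisation limit
(SSE = birth–death × Mk when rates are state-homogeneous), fine-grid
`deSolve` integration for BiSSE/MuSSE on trees of up to 10 tips, and
numeric quadrature for stepping-stone marginals and posterior means.
Samplers are additionally validated by prior recovery with the
likelihood switched off.

Simulation studies run at desk scale: 30 replicates of 200-tip trees for
BiSSE parameter recovery (true λ1/λ0 = 2; the sign of d1 − d0 and the
median ratio are the targets), 15 outer replicates of the end-to-end
LRT calibration with 16 inner simulations on 40-tip trees, and 60 trees
for the tip-rate type-I check — sizes chosen so the whole suite runs on
one desktop core in well under half an hour while leaving the acceptance
thresholds (≥ 85% sign recovery, median ratio in [1.5, 2.7], binomial
CIs containing 5%) statistically meaningful.  One classification
property deserves a note: brood data generated at MI = 1.0 sit exactly
on the rule-1 null, so the one-sided t test fires in 5% of replicates by
construction; the suite therefore tests "correct in ≥ 95%" as a
one-sided binomial hypothesis at level 0.05 rather than as a hard cut on
the realised proportion.

## Known limitations

* Likelihood kernels assume binary, rooted, (near-)ultrametric trees;
  polytomies are resolved deterministically with zero-length edges, and
  dating error beyond a relative 1e-6 in tip depths is tolerated with a
  warning for Mk work but rejected for SSE models.
* The reversible-jump model space omits shared-positive-bin moves (rates
  constrained equal but nonzero); model averaging is over zero/free
  configurations only.
* Incomplete sampling is handled by a single global sampling fraction;
  clade-level unresolved-tip corrections, hidden-state (HiSSE-type)
  models, continuous-trait (QuaSSE-type) diversification and
  phylogenetic regression are out of scope.
* The Gillespie n-tip stopping rule is not a uniform draw from the
  conditioned birth–death distribution; do not use these trees to test
  tree-prior calibration itself.
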