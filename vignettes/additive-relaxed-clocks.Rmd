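---
title: "Additive relaxed clock models for dating pathogen phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive relaxed clock models for dating pathogen phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcdating)
```

## The problem

A dated (time-scaled) phylogeny places every node of a rooted tree on a
calendar axis: tips at their known sampling dates, internal nodes at the
estimated times their ancestors existed. In the two-step approach to dating,
a substitution-scaled tree is estimated first by standard phylogenetics, and
the dates of its nodes are then inferred under a *molecular clock model*
that links the duration $l_i$ of branch $i$ (in years) to the number of
substitutions $x_i$ observed on it.

`arcdating` implements six clock models, Bayesian MCMC dating of a fixed
rooted topology with heterochronous (serially sampled) tips, a coalescent
simulator, DIC and reversible-jump model comparison, and two
temporal-signal utilities (root-to-tip regression and the
date-randomization test).

## The six clock models

Writing $\mu$ for the mean substitution rate (substitutions per genome per
year), the discrete models give integer counts and the continuous models
give real-valued branch lengths:

| model  | branch law                                                   | $E(x_i)$ | $V(x_i)$                  | additive |
|--------|--------------------------------------------------------------|----------|---------------------------|----------|
| `sc`   | $\mathrm{Poisson}(\mu l_i)$                                  | $\mu l_i$ | $\mu l_i$                | yes      |
| `rc`   | $\mathrm{NegBin}(k,\; \theta l_i/(1+\theta l_i))$            | $\mu l_i$ | $\mu l_i + \sigma^2 l_i^2$ | no      |
| `arc`  | $\mathrm{NegBin}(\mu l_i/\omega,\; \omega/(1+\omega))$       | $\mu l_i$ | $\mu l_i (1+\omega)$      | yes      |
| `csc`  | $\Gamma(\mu l_i,\, 1)$                                       | $\mu l_i$ | $\mu l_i$                 | yes      |
| `crc`  | $\Gamma\!\big(\tfrac{\mu^2 l_i}{\mu+\sigma^2 l_i},\, 1+\tfrac{\sigma^2 l_i}{\mu}\big)$ | $\mu l_i$ | $\mu l_i + \sigma^2 l_i^2$ | no |
| `carc` | $\Gamma(\mu l_i/(1+\omega),\, 1+\omega)$                     | $\mu l_i$ | $\mu l_i (1+\omega)$      | yes      |

All gamma distributions are shape–scale. Our negative binomial convention
is $\mathrm{NegBin}(r, p)$ with pmf $\binom{x+r-1}{x} p^x (1-p)^r$ and mean
$rp/(1-p)$; `stats::dnbinom`'s `prob` argument is $1-p$ under this
convention. The classical uncorrelated relaxed clock (`rc`, `crc`) draws an
independent, *identically distributed* gamma rate
$m_i \sim \Gamma(k, \theta)$ per branch, with $k = \mu^2/\sigma^2$ and
$\theta = \sigma^2/\mu$. The additive relaxed clock (`arc`) instead lets the
per-branch rate variance shrink with duration,
$m_i \sim \Gamma(\mu l_i/\omega,\, \omega/l_i)$ so $V(m_i)=\mu\omega/l_i$,
which after Poisson mixing yields the negative-binomial law above.

**Additivity** means that the substitution count on two abutting branches,
summed, follows the same law as the count on a single branch of the summed
duration — equivalently, the branch law is infinitely divisible in $l$
(a Lévy process: Poisson, negative-binomial, or gamma process). The
classical relaxed clock violates it: merging branches of lengths $l_1, l_2$
inflates the variance by exactly $2\sigma^2 l_1 l_2$. In practice this means
dating results under `rc`/`crc` are sensitive to which genomes are included,
because adding or removing genomes splits or merges branches.
`additivityGap()` quantifies both effects:

```{r additivity}
additivityGap(clockModel("arc", mu = 5, omega = 2), l1 = 1, l2 = 3)
additivityGap(clockModel("rc", mu = 5, sigma2 = 2), l1 = 1, l2 = 3)
```

With $\omega = 0$ (or $\sigma^2 = 0$ in the continuous family) every
relaxed model collapses to its strict counterpart; the continuous strict
clock is nested in both `crc` and `carc`, which is what the reversible-jump
comparison exploits.

## Bayesian dating on a fixed tree

`runMcmc()` samples the internal-node dates, $\mu$, the relaxation
parameter, and the coalescent parameter $\alpha$ by Metropolis–Hastings,
holding the topology and tip dates fixed:

* one uniform-window proposal per internal-node date (the window respects no
  hard bounds; ordering violations simply receive zero likelihood),
* multiplicative scale moves for $\mu$, the relaxation parameter, and
  $\alpha$,
* proposal widths adapted during the first 20% of iterations towards ~25%
  acceptance, then frozen so the chain after the adaptation phase is a
  valid Markov chain; summaries discard the first 50% by default.

### Tree prior

The default prior on node dates is the constant-size heterochronous
coalescent with pairwise coalescence rate $1/\alpha$ ($\alpha = N_e g$):
going forward in time over the sorted node events,
$\log p = -(n-1)\log\alpha - \tfrac{1}{\alpha}\int \binom{k(t)}{2} dt$,
with $k(t)$ the number of extant lineages. $\alpha$ gets an
Exponential(mean 10 years) hyperprior and its own scale move. A uniform
prior over valid date configurations is available with
`treePrior = "uniform"` (used, e.g., when checking conjugate posteriors).

### Parameter priors, and why the two relaxation priors differ

* $\mu \sim \Gamma(0.001, 1000)$ (shape–scale): essentially flat on the
  scales of interest, mean 1.
* $\omega \sim \Gamma(0.1, 1)$: a conservative prior with mean and variance
  0.1. $\omega$ is a dimensionless variance-inflation factor, so "small
  relative to 1" is a meaningful default scepticism.
* $\sigma^2$: improper flat on $(0,\infty)$ by default. This is deliberate
  and *not* symmetric with $\omega$: $\sigma^2$ is a squared rate, and for
  data with mean rate $\mu$ and typical branch duration $\bar l$ it must
  reach roughly $\mu\omega/\bar l$ — tens, for epidemic-scale trees — to
  express the same relaxation that a small $\omega$ expresses. A
  $\Gamma(0.1,1)$ prior on $\sigma^2$ has essentially no mass there; in our
  experiments it forced the classical relaxed clock into a biased,
  spuriously overconfident fit (rate estimates ~20% low with credible
  intervals missing the truth) even when the node dates were fixed at their
  true values. With the flat prior the likelihood alone drives $\sigma^2$
  and the classical model behaves as reported in the literature: unbiased
  but imprecise. Any proper gamma prior can be supplied via
  `priors = list(relax = c(shape, scale))`.

### Numerical choices

* Likelihoods are computed in log space throughout. The negative-binomial
  log pmf is parametrised by $\log p$ and $\log(1-p)$ (`log1p` forms), and
  its binomial coefficient as $-\log(x+r) - \mathrm{lbeta}(x+1, r)$. Both
  choices matter in the tails the sampler actually visits: `prob`
  $= 1/(1+\omega)$ rounds to exactly 1 once $\omega < 2\cdot10^{-16}$, and
  $\log\Gamma(x+r) - \log\Gamma(r)$ cancels catastrophically once
  $r = \mu l/\omega \gtrsim 10^9$.
* Below $\omega$ (or $\sigma^2$) $= 10^{-10}$ the negative binomial is
  evaluated as its Poisson limit; the interpreted and compiled
  implementations use the same switch point and agree to ~$10^{-13}$,
  which the test suite checks state by state against recorded traces.
* Zero-duration branches carry a point mass at zero substitutions under
  every model; the per-branch rate of the discrete additive clock is
  undefined at $l=0$ and `sampleRate()` refuses rather than guesses.
* Continuous observations below $10^{-9}$ are floored at $10^{-9}$ before
  likelihood evaluation (gamma densities with shape < 1 diverge at the
  origin, and reconstructed trees routinely contain zero-length branches);
  a warning is emitted.
* Per-genome conversion (`toGenomeUnits`) rounds half away from zero, so a
  0.5-substitution branch becomes 1; discrete likelihoods require this
  rounding, continuous ones take fractional lengths as-is.
* Polytomies are resolved into binary nodes joined by zero-length branches
  on input (with a notice). Under additive models the likelihood is
  provably unchanged by the resolution — one of the test suite's checks.
* The MCMC core is compiled (Rcpp), drawing from R's RNG so that a single
  `set.seed` makes entire analyses bit-reproducible.

## Model comparison

`dic()` reports $\mathrm{DIC} = \bar D + p_D$ with $D = -2\log L$,
$\bar D$ the posterior mean deviance and $p_D = \mathrm{Var}(D)/2$, the
half-variance estimator of the effective number of parameters. We use the
half-variance form rather than the plug-in $\bar D - D(\bar\theta)$
deliberately: with ~100 node-date parameters, the plug-in state of a
heavily relaxed classical clock lies on a likelihood ridge that is nearly
flat in the dates, biasing its $p_D$ towards zero; in simulations where
the additive model fit better on mean deviance in 10/10 data sets, the
plug-in variant still inverted 3 comparisons while the half-variance
variant inverted none. Both estimators are standard; only their robustness
differs here.

`runRjMcmc()` compares the nested continuous pair (`csc` at $\omega = 0$
inside `carc`) by reversible jump: the trans-model move proposes
$\omega^\ast$ from its $\Gamma(0.1,1)$ prior, so the proposal density and
prior cancel and the acceptance ratio is a bare likelihood ratio. With
model prior odds 1:1 the Bayes factor is the posterior odds of the
indicator. The discrete strict clock is not nested in the discrete relaxed
models, so no discrete reversible jump is offered.

## The simulator and what the tests can claim

`simulateStudy()` generates the package's reference study design: 100
genomes of 10,000 bp sampled at regular intervals (equally spaced,
endpoints included) between 2010 and 2020, a heterochronous coalescent
genealogy with $\alpha = 5$ years, and per-branch substitution counts from
the discrete additive clock with $\mu = 5$ substitutions per genome per
year and a chosen $\omega$; the two-stage mechanism (gamma rate, then
Poisson count) is used for the additive clock so the latent per-branch
rates are also exercised. `sampleCoalescentTree()` matches the closed-form
expected TMRCA depths ($\alpha$ for two contemporaneous tips,
$2\alpha(1-1/n)$ for $n$) to Monte-Carlo accuracy at $10^5$ replicates.

The observed tree handed to the sampler is the *true* topology with branch
lengths drawn from the clock law — an error-free-reconstruction mode.
Real pipelines reconstruct the tree from sequences first, which adds
branch-length noise (a Jukes–Cantor alignment simulator,
`simulateAlignment()`, is provided for users who want to interpose their
own tree estimator). Consequently the package's simulation studies measure
the clock models under ideal reconstruction: credible intervals come out
somewhat *shorter* than a full pipeline would give — visibly so for the
classical clock's TMRCA intervals — and passing tests say nothing about
robustness to topology error. Scale choices in the test suite (20
simulated data sets at $2\times10^4$ MCMC iterations for the
interval-length comparison; 10 data sets for the DIC comparison; 4 seeds
per $\omega$ for the relaxation-recovery check) were made so the whole
suite completes on one CPU in minutes while keeping Monte-Carlo error well
inside the tolerances asserted.

What the headline comparison shows, on data simulated under the additive
clock across $\omega \in [0, 10]$: both models' credible intervals cover
the true $\mu$ and TMRCA at near-nominal rates, but the additive model's
intervals are systematically shorter — markedly so for the TMRCA — and the
posterior mean of $\omega$ tracks the simulated value monotonically. That
reproduces the qualitative and (within a ±35% band) quantitative pattern
of the study this package re-implements.

## Temporal signal

`rttRegression()` fits the ordinary least-squares root-to-tip regression;
its slope estimates the rate only under a strict clock, and its $R^2$ is a
weak signal measure because root-to-tip paths share branches.
`dateRandomizationTest()` is the stronger test: the dating analysis is
re-run with tip dates permuted uniformly among tips, and temporal signal
is declared significant only when the credible interval for $\mu$ on the
real dates overlaps *none* of the permuted-date intervals.

## Known limitations

* The topology is fixed: no joint tree-and-dates inference, and no
  within-alignment (pruning-algorithm) likelihood.
* Constant-size coalescent prior only; no skyline or exponential-growth
  variants, no internal-node calibration priors.
* Split-$\hat R$ is reported for two or more chains; for two *identical*
  chains it equals 1 only up to $O(1/\sqrt n)$ because the halves of one
  chain differ.
* Uncorrelated clocks only; autocorrelated rate models are out of scope.
* The date-randomization test re-runs the full MCMC per permutation;
  at the published scale (100 permutations, $10^5$ iterations) it is the
  most expensive operation in the package.
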