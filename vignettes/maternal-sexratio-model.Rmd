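---
title: "Decomposing brood sex-ratio variation into maternally inherited and residual components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing brood sex-ratio variation into maternally inherited and residual components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(matriline)
library(dplyr)
```

## The scientific problem

Maternally inherited endosymbionts (*Wolbachia*, *Rickettsia*, *Cardinium*,
...) can bias the sex ratio of their arthropod hosts' broods, for example
by killing male embryos or by feminizing genetic males. Because the
bacteria pass only from mother to offspring, an endosymbiont-driven
sex-ratio distortion should itself be maternally inherited: a female's
tendency to produce daughters should reappear in her daughters and
granddaughters, but not spread to unrelated lineages.

`matriline` implements the statistical machinery for testing exactly that
in multi-generation laboratory pedigrees of broods ("clutches") whose
offspring are sexed at adulthood:

1. a hierarchical Bayesian "maternal animal model" that splits among-female
   variance in clutch sex ratio into a maternally inherited component and a
   residual dam-level component;
2. the downstream endosymbiont statistics (prevalence contrasts, exact
   tests, the expected-infected-male algebra, and a clutch-size diagnostic
   that separates male killing from feminization);
3. a forward-time pedigree simulator that realises the model generatively,
   with maternal endosymbiont transmission and configurable distortion
   mechanisms, so that every inferential step can be validated without
   access to any particular breeding data set.

## The model

Let $Y_i \in \{0, 1\}$ be the sex of offspring $i$ (male = 1, so a "sex
ratio" is always a proportion of males) and let $d(i)$ denote its mother.
Each offspring is Bernoulli with dam-specific mean $\pi_d$,

$$\operatorname{logit}(\pi_d) \;=\; \mu + x_d^\top\beta + m_{d} + e_{d},$$

where $\mu$ is the population mean logit sex ratio, $x_d$ holds optional
fixed-effect covariates (infection status, antibiotic treatment,
population), $m_d$ is the **maternally inherited** effect and $e_d$ a
dam-level residual. The defining constraint is perfect maternal
transmission: a daughter inherits her mother's $m$ unchanged
($m_i = m_{d(i)}$), so $m$ is constant within a *matriline* — the set of
females tracing back to one founding female — and the model pools
information along maternal lineages. Founding females draw
$m \sim N(0, \sigma^2_m)$; every dam draws
$e \sim N(0, \sigma^2_e)$ independently. $\sigma^2_m$ measures heritable
(e.g. endosymbiont-borne) sex-ratio variation; $\sigma^2_e$ captures
among-dam variation that does *not* transmit (paternal effects, titer
fluctuation, loss of infection, ...).

Since all offspring of a dam share $\pi_d$, the per-offspring Bernoulli
likelihood collapses to a dam-level binomial — `total_male` successes out
of all sexed adults — which differs from the Bernoulli formulation only by
a data-dependent `log choose()` constant and is what the sampler
evaluates.

### Priors and their parameterization

$\mu$ and each $\beta$ get diffuse $N(0, 10^3)$ priors. The variance
components carry $\text{Gamma}(0.1, 0.1)$ priors placed, by default, on
the **precisions** $1/\sigma^2_m$ and $1/\sigma^2_e$ — the WinBUGS-style
convention for hierarchical logit models. Statements of this prior in the
applied literature are often ambiguous between precisions, variances and
standard deviations, so `maternal_model_spec(prior_on = "sd")` switches to
a gamma prior on $\sigma_m, \sigma_e$ for sensitivity analysis; the
precision remains the default because it admits a conjugate Gibbs update.

## Sampling scheme

`fit_maternal_model()` runs Metropolis-within-Gibbs chains with a fixed
update order per iteration:

1. all matriline effects $m_k$: random-walk Metropolis, proposed and
   accepted simultaneously (valid because the $m_k$ are conditionally
   independent given everything else); each acceptance uses all dam
   records of that matriline;
2. all dam effects $e_d$: likewise, one record each;
3. $\mu$, then each $\beta_j$: scalar random walks over the whole
   likelihood;
4. $\tau_m, \tau_e$: conjugate draws from
   $\text{Gamma}(a + k/2,\; b + \tfrac12\sum \text{effects}^2)$ (or a
   log-scale Metropolis step on $\sigma$ under `prior_on = "sd"`).

Defaults follow the two-chain, 12,000-iteration, 2,000-burn-in design the
model was built around. Proposal scales adapt every 50 iterations during
burn-in toward a 20–50% acceptance band and are frozen afterwards, so the
kernel used for inference satisfies detailed balance. Chains start
over-dispersed: $\mu$ at the empirical logit of the pooled sex ratio plus
chain-indexed jitter, effects jittered around zero, precisions at 1.
Within-block bookkeeping is sorted by id, and each chain derives its seed
deterministically from the master seed, so identical data + configuration
+ seed reproduce draws exactly.

Summaries (`posterior_summary()`, `tidy()`) report posterior means,
standard deviations and **equal-tailed** 95% credibility intervals
(type-7 quantiles), plus the classic (non-split) Gelman–Rubin potential
scale reduction factor. Variance-component summaries transform the
precision draws draw-wise ($\sigma^2 = 1/\tau$ per draw) — never
$1/\bar\tau$, which Jensen's inequality would bias.

### Identifiability

The likelihood is invariant to $(\mu + c,\; m - c)$; only the priors on
$m$ break this. The identifiable combination $\mu + \bar m$ is stable
across chains (a property test asserts this), and individual $m$ levels
should be interpreted only relative to one another. This is the usual
behaviour of random-intercept logit models and is harmless for the
quantities of interest, $\sigma^2_m$ and $\sigma^2_e$.

## What the simulator emulates — and what it does not

`simulate_pedigree()` is the model read generatively plus explicit
endosymbiont machinery:

* founders open matrilines and draw $m$; breeding dams draw $e$; offspring
  sexes are Bernoulli at `plogis(mu + m + e)` *before* manipulation;
* infection passes maternally with configurable `transmission_efficiency`
  (default 1, matching the observation that infected mothers in such
  systems typically produce only infected offspring);
* `male_killing(s)` removes each male embryo of an infected dam with
  probability `s` (broods shrink; hatched counts drop);
  `feminization(f)` relabels males female (brood size unchanged);
* clutch sizes are Poisson with mean 17, close to the observed control
  brood mean of 16.8 in the kind of breeding study this mirrors. The
  Poisson is a deliberate stand-in: real clutch-size distributions are
  substantially over-dispersed, and the mean is configurable while the
  family is fixed.

Default pedigree shape: 200 founders, two breeding generations, one
breeding daughter recruited per dam — about 200 matrilines, 400 breeding
dams and 6,800 sexed offspring, the same order as the pedigrees such
breeding designs produce. All hatched offspring are assumed to survive to
adulthood and be sexed; juvenile mortality, multiple cocoons per female
(records are pooled per dam anyway), cytoplasmic incompatibility,
parthenogenesis and multi-endosymbiont interactions are *not* modelled.
Consequently, passing tests demonstrate correctness of the machinery under
the model's own assumptions — they cannot certify robustness to
over-dispersion, sex-biased juvenile survival or imperfect detection in
real data.

An optional `couple_infection = TRUE` flag restricts nonzero $m$ to
infected matrilines (endosymbiont-caused distortion); the default keeps
the generator exactly congruent with the fitted model.

The master seed spawns one deterministic sub-seed per generation
(`seed + 77003 g mod 2^31-1`). Per-dam sub-streams were considered and
rejected: no supported operation re-simulates a single dam, and
generation-level streams already make outputs reproducible and cheap to
regenerate.

## Validation strategy

Three independent routes check the sampler:

* **Quadrature oracle.** `posterior_oracle_small()` integrates the
  unnormalised posterior on a dense tensor grid for instances with at most
  three free location parameters (precisions fixed, dam effects dropped).
  Riemann sums on these smooth, rapidly decaying integrands converge
  essentially spectrally; halving the step changes posterior means by
  under $10^{-4}$. Sampler means agree within three Monte-Carlo standard
  errors (batch-means estimate) on a battery of tiny fixed datasets. The
  oracle comparisons use a tighter-but-weak $N(0, 10)$ prior on $\mu$ in
  *both* routes so a fixed-width grid resolves the posterior; this choice
  is about grid efficiency, not inference.
* **Enumeration oracles.** `fisher_exact()` and `exact_binomial_test()`
  are swept against exhaustive hypergeometric/binomial enumeration over
  all small supports.
* **Recovery at scale.** Pedigrees generated at reference values
  $\sigma^2_m = 0.64$, $\sigma^2_e = 0.27$, $\mu = \operatorname{logit}(0.34)$
  are refit end-to-end; across ten seeded replicates both posterior means
  land inside the intervals [0.34, 1.05] and [0.12, 0.47] and their
  replicate averages sit within a few percent of the generating values.
  A 100-replicate study at smaller size checks that the 95% interval for
  $\sigma^2_m$ covers the generating value in at least 85% of replicates
  (the gamma prior exerts some pull at modest matriline counts, hence the
  slack below the nominal 95%).

## Numerical choices

* The binomial log likelihood is evaluated through the softplus kernel
  `y*eta - n*(max(eta,0) + log1p(exp(-|eta|)))`, finite for any `eta`, so
  extreme linear predictors cannot produce `log(0)`.
* Dams with clutches but no sexed adults are flagged `excluded` by
  `aggregate_dams()` and dropped (with a message) by the fitting
  functions; any dam with at least one sexed adult is retained.
* Degenerate inputs fail loudly with classed conditions
  (`matriline_*_error`): cyclic maternal links name the cycle, dangling
  dam references list the rows, a constant contrast covariate is a design
  error, and a 2×2 table with a zero margin returns p = 1 with a warning
  rather than an error.
* Two-sided exact tests default to the minimum-likelihood rule;
  `two_sided_rule = "double.tail"` is provided because published exact
  p-values rarely state their convention, and the two rules differ
  materially (for 11 successes in 18 trials against 0.37 they give 0.048
  and 0.065 — only the latter rounds to the conventionally quoted 0.07).
* Bootstrap intervals in `clutch_size_mechanism_diagnostic()` resample
  clutches (not offspring), percentile method, seeded.

## Worked example

A small end-to-end run (kept deliberately light; the defaults are
`n_chains = 2, n_iterations = 12000, burn_in = 2000`):

```{r example, eval = FALSE}
sim <- simulate_pedigree(sim_params(seed = 11))
records <- aggregate_dams(sim$pedigree)
fit <- fit_maternal_model(records, maternal_model_spec(), mcmc_config(seed = 2))
tidy(fit)
autoplot(fit, type = "density")

# mechanism diagnostics on the same pedigree
per_clutch <- tertiary_sex_ratio(
  aggregate_dams(sim$pedigree, per_clutch = TRUE) |>
    dplyr::filter(total_male + total_female > 0)
)
weighted_pearson(per_clutch, x = "n_hatched", y = "sex_ratio")
```

## Known limitations

* No additive-genetic (pedigree relatedness) component: a nuclear
  contribution to sex-ratio variation is absorbed partly by $m$ (via
  mother–daughter resemblance) and partly by $e$. Such extensions are
  notoriously hard to converge for binary traits at these sample sizes.
* Mixed-model F-tests with adjusted denominator degrees of freedom and
  Tukey-style post-hoc contrasts are intentionally out of scope; the
  Bayesian fixed-effect contrast (`group_sexratio_contrast()`) is the
  package's analogue.
* The sampler is plain random-walk Metropolis within Gibbs — adequate at
  the problem sizes the model targets (hundreds of matrilines), but no
  match for gradient-based samplers on much larger data.
* The per-clutch mode keeps clutch identity only for the size/sex-ratio
  correlation; the model itself treats the dam, not the clutch, as the
  residual unit.
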