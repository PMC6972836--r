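---
title: "Model-based unconstrained ordination with honest uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based unconstrained ordination with honest uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Community ecologists summarise a site-by-species matrix $y$ (presences,
counts, or ordinal cover classes) by placing the $n$ sample units in a
low-dimensional space whose axes are interpreted as compositional
gradients. `latentord` does this with a Bayesian latent factor model:

$$g(\mu_{ij}) = \alpha_i + \beta_j + z_i^\top \theta_j,$$

where $\alpha_i$ is a site effect (overall richness/abundance of site
$i$), $\beta_j$ a species effect (overall commonness of species $j$),
$z_i \in \mathbb{R}^q$ the latent factors of site $i$ — the ordination
coordinates, $q = 2$ by default — and $\theta_j$ the factor loadings of
species $j$. Four observation models share this linear predictor:

* **binary** (presence/absence): $y_{ij} \sim \mathrm{Bernoulli}(\Phi(\eta_{ij}))$, probit link;
* **poisson** (counts): $y_{ij} \sim \mathrm{Poisson}(e^{\eta_{ij}})$;
* **negbinomial** (overdispersed counts): mean $e^{\eta_{ij}}$, variance
  $\mu + \omega \mu^2$ — the mean/overdispersion parameterisation, *not*
  the trials/probability one;
* **ordinal** (cover classes $1,\dots,K$): cumulative probit — a latent
  $z^*_{ij} \sim N(\eta_{ij}, 1)$ is cut at ordered thresholds
  $c_1 < \dots < c_{K-1}$; the unit latent variance is fixed for
  identifiability.

Priors are $\alpha_i \sim N(\mu_\alpha, V_\alpha)$,
$\beta_j \sim N(\mu_\beta, V_\beta)$, $\theta_j \sim N(0, V_\theta)$,
$z_i \sim N(0, I)$, with defaults
$\mu_\alpha = \mu_\beta = 0$, $V_\alpha = V_\beta = 1$, $V_\theta = I$;
$\omega$ gets a half-Cauchy prior with scale $\sqrt{20}$ (a "spread of
20" on the squared scale; a Cauchy has no variance, so we read the usual
variance-20 phrasing as scale$^2 = 20$), and the cutoffs independent
standard normal priors subject to the ordering constraint. Because a
rotation of $(Z, \Theta)$ leaves the likelihood unchanged, the loading
matrix is constrained: upper triangle of its first $q$ rows zero and
diagonal positive ($\theta_{11} > 0$, $\theta_{12} = 0$,
$\theta_{22} > 0$ for $q = 2$), enforced in the sampler by
positive-truncated normal priors on the diagonal elements. (Some
descriptions of this constraint state the positive element as
$\theta_{21}$; the diagonal is what fixes the reflection of the second
axis, so that is what we constrain.)

## Sampling

Binary and ordinal families use an exact Gibbs sampler built on the
classic latent-normal data augmentation: given truncated-normal draws of
$z^*_{ij}$ consistent with the observed class, every other full
conditional is Gaussian (the constrained loading diagonals are
positive-truncated normals, drawn by exact scalar Gibbs within the row).
Truncated normals are drawn by inverse-CDF with log-space tail handling,
so the augmentation stays exact arbitrarily far into the tails. Ordinal
cutoffs are drawn from their standard-normal prior conditionals
truncated between the neighbouring classes' latents and cutoffs, which
preserves the ordering by construction. The two-class ordinal model with
its cutoff at zero has exactly the binary probit likelihood; in this
package the cutoff is sampled rather than fixed, so the equivalence is
at the likelihood (not chain-path) level.

The count families are not conjugate, and we use adaptive random-walk
Metropolis-within-Gibbs (compiled, in `src/`): all site effects, species
effects, factor rows and loading rows are conditionally independent
blocks given the rest of the state, so a sweep walks through them with
cached per-cell log-densities. Per-block proposal scales adapt by
Robbins-Monro toward acceptance 0.44 (scalar blocks) / 0.234 (rows)
during burn-in only and are frozen afterwards, so the retained draws
target the exact posterior. The overdispersion $\omega$ is updated by a
random walk on $\log \omega$. Defaults are 20,000 iterations, 10,000
burn-in, thinning 10; every fit is bit-reproducible given the seed in
`mcmc_control()`. Initialisation: effects and factors at zero, loading
diagonal at one, $\omega = 1$, cutoffs at the standard-normal quantiles
of the empirical class frequencies.

Poisson versus negative binomial fits to the same counts are compared
with `dic()` ($\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D -
D(\bar\vartheta)$). `mcmc_diagnostics()` reports split-$\hat R$ and an
autocorrelation-based effective sample size per parameter and warns
when $\hat R > 1.1$. Fitted objects are plain R lists and are saved and
restored exactly with `saveRDS()`/`readRDS()`.

## Summarising uncertainty: HPD widths, alignment, anchoring

The headline summary is the average width of the 95% highest posterior
density intervals of all $n \times q$ latent factor coordinates
(`hpd_widths()`). One-dimensional HPD intervals use the minimal-width
sorted-window algorithm (the narrowest window containing
$\lceil \gamma m \rceil$ order statistics; ties resolved to the smallest
lower endpoint); only the single minimal interval is reported, never
disjoint unions.

Two subtleties deserve emphasis:

**Rotation alignment.** The loading constraint ties the rotation of the
ordination to the first $q$ species only. When $p \gg q$ that tie is
weak: the posterior keeps a near-flat rotational ridge, chains drift
slowly around it, and *raw* per-coordinate interval widths grow with
chain length without ever stabilising — they conflate rotational
ambiguity with positional uncertainty. We therefore align every
retained draw to the posterior-mean configuration by orthogonal
Procrustes rotation before summarising (`align_factors()`, the default
in `hpd_widths()` and `plot_ordination()`). Aligned widths are stable in
chain length, and for small $p$ — where the constraint already pins the
rotation — alignment changes essentially nothing. `align = FALSE`
recovers the raw summary. We chose alignment over a stronger in-sampler
constraint because it leaves the posterior itself untouched (every
stored draw still satisfies the loading constraints exactly) and makes
the summary well-defined. Calibration is checked at two levels in the
test-suite: the sampler itself is validated on raw draws where chains
genuinely converge (a one-dimensional model, where the positivity
constraint fully pins the reflection: interval coverage of true factors
and simulation-based-calibration ranks are nominal), and the reported
two-dimensional summaries are validated on rotation-aligned draws
against the correspondingly aligned true configuration. Raw
two-dimensional marginals are *not* calibrated at practical chain
lengths — their coverage climbs from ~0.79 at 1,500 iterations to only
~0.91 at 40,000 as the chain slowly explores the rotational ridge —
which is precisely why the package does not report them.

**Anchoring.** Ordination is about relative positions, so
`anchor_factors()` translates every draw so a chosen reference site sits
at the origin; summaries of anchored draws measure uncertainty relative
to the anchor, and a common shift of the whole cloud cancels exactly.
Widths are reported on unanchored draws by default (`anchor_site`
switches). Anchoring (translation) and alignment (rotation) are
independent operations.

Two-dimensional 95% HPD regions for single sites
(`hpd_region_2d()`) are computed either from a Gaussian-kernel density
estimate (normal-reference bandwidth; threshold chosen so the stated
fraction of draws lies above it) — the default, because posterior
clouds are often visibly non-elliptical — or as the normal-theory
ellipse at the $\chi^2_2$ radius, which is faster. Rank-deficient draw
clouds fall back to a product of 1-D intervals with a warning.
`plot_ordination()` renders the point-estimate map, posterior point
clouds, HPD region boundaries, and anchored versions of each.

## The synthetic-community generator and the design tool

`ord_design()`/`sim_community()` generate communities from the model
itself: $\alpha_i \sim N(\mu_\alpha, \sigma_\alpha^2)$,
$\beta_j \sim N(\mu_\beta, \sigma_\beta^2)$, $Z$ and $\Theta$
elementwise standard normal with the loading constraints applied, and
responses drawn from the design's sampling distribution (for
`"negbinomial"` designs with design overdispersion `omega`, default 1;
ordinal designs cut a unit-variance latent normal at the design
cutoffs, by default standard-normal $K$-tiles). Replicate $r$ of a
design uses an RNG stream derived from `(seed, r)`, so replicates are
independent and each is bit-reproducible.

A design can append `p_rare` *rare species* whose effects are drawn
from $N(\mu_{rare}, \sigma_{rare}^2)$, default mean $-4$ and SD $0.5$:
strongly negative effects that make occurrences sparse. With standard
normal site effects these defaults give a marginal occurrence
probability of about 0.027 per site-species pair, and about two thirds
of simulated rare species are never observed across 20 sites
(`occurrence_summaries()` computes both by Monte Carlo, with standard
errors). Note the pair of published reference values often quoted for
this regime (occurrence 0.027, zero-occurrence 75%) cannot both hold
under one parameterisation of this generative family: the parameters
that give 0.027 give a zero-occurrence expectation of 0.655 (the
per-dataset median is 0.70, interquartile range 0.5–0.8), while
shrinking the site-effect SD to 0.5 gives 0.751 but occurrence 0.019.
We fix the parameterisation by the occurrence probability.

`hpd_width_design()` is the study-design tool: for each requested
(sites, species) cell it simulates `reps` communities, fits the matching
model, and averages the 95% HPD widths of the latent factors across
sites, dimensions and replicates — the expected precision of a planned
ordination study. Population parameters for a concrete community can be
plugged in from a pilot fit via `estimate_population_params()` (the
across-unit mean and SD, $n-1$ denominator, of the posterior-mean site
and species effects). Count designs default to 30,000 iterations per
fit (the Metropolis sampler needs longer runs before aligned widths
stabilise; the compiled sweep makes this cheap), binary/ordinal designs
to 5,000. Reference points this tool reproduces, with 50 replicates in
the original studies and 4–10 here: presence-absence surveys of 20
sites with common-species effect SD 0.5 give mean widths near 2.8, 2.2,
1.7 and 1.1 at 10, 20, 40 and 80 species; mixing 10 rare into 10 common
species gives ≈ 2.3 (more than 20 common, less than 10 common alone);
and at spider-like abundance parameters, 40 sites × 50 species gives
≈ 1.0 with fewer species being costlier than fewer sites. Abundance
designs beat their degraded presence counterparts throughout
(`degrade_to_presence()` maps any positive count to presence).

## Numerical and design choices

* Average width is taken over all $n \cdot q$ coordinates; the
  probability level defaults to $\gamma = 0.95$ everywhere.
* The linear predictor indexes sites by rows and species by columns;
  `read_community()` has a `transpose` flag for files stored the other
  way, auto-detects comma/tab delimiters, and reports the exact cell on
  validation failures.
* $K$ ordinal classes use $K - 1$ free cutoffs; class 1 is the region
  below $c_1$ and class $K$ the region above $c_{K-1}$.
* General $q \ge 1$ is supported; $q = 2$ is the sensible default for
  ordination graphics.
* Degenerate inputs: empty truncation regions cannot arise in the
  augmentation or cutoff updates by construction; count proposals that
  leave the positivity region are rejected by prior support; Metropolis
  acceptance rates outside $[0.1, 0.7]$ after burn-in trigger a warning.

## What the simulations do and do not show

The generator draws data from exactly the model that is then fitted, so
design-tool outputs are *best-case* precision estimates: real
communities have species interactions, zero inflation, covariate
structure and non-normal effect distributions that the model ignores.
Passing calibration on prior-predictive replicates validates the
sampler, not the model's adequacy for any particular data set. Raw
(unaligned) width summaries additionally depend on how strongly the
first $q$ species pin the rotation and on chain length, which is the
main reason otherwise comparable analyses can report substantially
different average widths for similar data; cross-study comparisons
should use aligned summaries. Known limitations: no missing data, no
covariates (unconstrained ordination only), no logistic-link
alternative, a single common overdispersion parameter across species,
and no selection of $q$ by information criteria.

## Problem sizes used in the test-suite and reproduction script

The bundled tests and the reproduction script rerun the simulation
studies at reduced scale — 4–10 replicates per design cell, 5,000
iterations for the Gibbs fits, 30,000 for the compiled count fits, 100
prior-predictive replicates for calibration — which keeps Monte Carlo
error within the widened tolerances asserted there.
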