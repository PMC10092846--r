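---
title: "Models and methods behind cupnest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cupnest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cupnest` implements a comparative-analysis workflow for the size of open
cup nests in passerine birds: from raw calliper measurements to volumes,
from range polygons to per-species climate and insularity covariates, and
from there to Bayesian phylogenetic mixed models (BPMMs) fitted across a
sample of candidate phylogenies. This vignette explains the models, the
choices that were genuinely open, and what the synthetic validation
suite does and does not demonstrate.

## Nest geometry

An open cup nest is modelled as half a spheroid. With mean outer diameter
$\bar D$ (up to four measurements around the rim) and mean outer height
$\bar H$ (up to two), the full nest volume is

$$V_{\mathrm{full}} = \tfrac{2}{3}\pi\left(\bar D/2\right)^2 \bar H,$$

the inner cup volume is the same form on $(\bar d, \bar h)$, and the
*outer* volume — the amount of structural material, the main response of
interest — is $V_{\mathrm{full}} - V_{\mathrm{inner}}$. Records with
fewer than the nominal number of replicate measurements are averaged
as-is rather than rejected, because literature sources often report a
single value per dimension. Records measured only internally (misshapen
or cavity-constrained specimens) carry an inner volume and no outer or
full volume.

Literature dimension tuples follow fixed conventions: unqualified values
refer to the external nest; values separated by "by" or a multiplication
sign are length and width (diameters $D_1$ and $D_3$), with a third value
read as height; an unqualified "depth" is the external height unless it
directly follows an inner-cup diameter description, in which case it is
the inner height. These rules operate on already-tokenised values —
free-text parsing is out of scope.

Digitised tables occasionally produce an inner volume a hair above the
full volume. Violations up to 0.5% are clamped to equality (treated as
measurement noise); anything larger raises an error, since it breaks the
subtraction semantics. Units are fixed to cm at ingest (`read_measurements`
converts mm); geometry functions never rescale.

## Range geography and climate

Range polygons carry integer attribute codes; only polygons with
seasonal code 1 (resident) or 2 (breeding season), origin 1 (native) or
2 (re-introduced) and presence 1 (extant) survive filtering. Retained
polygons are intersected with a 0.5° grid (0.25° for visualisation
matrices); a cell counts as occupied on *any* positive-area overlap,
matching the fraction-greater-than-zero rule used for islands. A
minimum-cover fraction is available for sensitivity analysis. Polygons
extending past 180° longitude are split at the antimeridian before
gridding. All geometry is planar in degrees, with no latitudinal area
weighting — cell means are averaged unweighted, mirroring the cell-based
averaging of the downstream statistics; an area-weighted variant would
be a straightforward extension but is deliberately not the default.

The range *midpoint* is not a standard construction; we use the
unweighted mean of occupied-cell centres, which is robust to polygon
digitisation detail and consistent with the cell-based climate
averaging. A midpoint exactly on the equator is assigned to the northern
hemisphere as a deterministic tie-break. Climate zones split at the
tropics: midpoints above 23.5°N are northern temperate and use
March–June climate layers; below 23.5°S, southern temperate,
September–December; otherwise tropical, using all twelve months. Per
species, the selected months are averaged within each occupied cell and
the cell values averaged across the range; cells lacking climate data
are dropped from the cell average.

Insularity uses a marine-island layer with areas: islands qualify when
strictly larger than 1 km² and strictly smaller than 2,000,000 km² (the
size of Greenland); a 2,000 km² upper bound is available to probe
small-island effects, and we read the alternative threshold as replacing
the *upper* bound. Island polygons are rasterised with the same
any-overlap rule; a species is insular when the insular share of its
occupied cells strictly exceeds 90%. A share of exactly 0.9 is therefore
*not* insular.

## Phylogenetic machinery

`bm_covariance` returns the Brownian-motion tip covariance (shared
root-to-MRCA path lengths); polytomies and zero-length internal branches
pass through the covariance untouched, with no arbitrary resolution.

**Pagel's λ** multiplies the off-diagonal covariance entries. The root
state and rate σ² are profiled out by GLS, leaving a one-dimensional
likelihood maximised over [0, 1] by bounded search with the boundary
values checked explicitly. We restrict to [0, 1] rather than the
tree-specific algebraic maximum because signal estimates are reported and
interpreted on that scale. ML (not REML) is used. A star tree makes the
likelihood constant in λ; the fit flags this (`flat_likelihood`) and
returns λ = 0 by convention rather than an arbitrary interior value.

**Ancestral states** are the joint maximum-likelihood reconstruction
under Brownian motion. Because the BM log-likelihood is a sum of squared
state changes weighted by inverse branch lengths, the ML states solve the
weighted graph-Laplacian system of the tree with tips fixed — equivalent
to the GLS/re-rooting estimator computed from the full covariance, and
the test suite verifies the equivalence to 1e-8 against a brute-force
GLS oracle. Node variances come from the inverse internal-node block of
the Laplacian scaled by the Brownian rate estimated with the unbiased
(n−1) divisor — the convention of the standard tool this mirrors — and
95% intervals are ±1.96 SD. Zero-length *terminal* pendant pairs make
the tip covariance singular and raise an error naming the node;
zero-length internal edges are floored at 1e-10 of tree depth, which
forces the adjoining states to coincide (the polytomy limit).

**Evolutionary correlation** between two traits is computed from the GLS
evolutionary covariance $R = (X - 1\hat a)^\top C^{-1}(X - 1\hat a)/(n-1)$
with $\hat a$ the GLS phylogenetic means. No derivation is fixed by
precedent for its p-value; we use $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$
degrees of freedom applied to the phylogenetically corrected $r$, which
reduces to the familiar test when the tree is a star.

Every estimator can be mapped over a tree sample with `over_trees`,
which prunes to the common tip set and reports per-tree values with
mean, min and max — estimates are reported as averages over the
topology distribution. Pruning tips without data before analysis never
changes estimates (tested property).

## The Bayesian phylogenetic mixed model

At measurement-record level the model for a (transformed) response $y$ is

$$y = X\beta + Z a + Z s + e,\qquad
a \sim N(0, \sigma^2_{p} A),\quad
s \sim N(0, \sigma^2_{s} I),\quad
e \sim N(0, \sigma^2_{e} I),$$

where $A$ is the BM covariance of the pruned tree scaled to unit
diagonal (a correlation matrix) and $Z$ maps records to species. The
species term absorbs between-species effects independent of phylogeny,
so the residual is within-species variability; models with one row per
species (the nestling-period model) drop it. Priors are diffuse normal
$N(0, 10^{10})$ on fixed effects and univariate inverse-Wishart
$(V = 1, \nu = 0.02)$ on each variance — implemented as
inverse-gamma(shape ν/2, scale νV/2), the standard equivalence.

Sampling is a conjugate Gibbs scheme: all location effects
$(\beta, a, s)$ are drawn *jointly* from their multivariate-normal full
conditional via the mixed-model equations (a fresh Cholesky per
iteration, since the variance ratios move), and each variance from its
inverse-gamma full conditional. The joint location update is what makes
the confounded $a$/$s$ pair mix acceptably. R's RNG drives everything,
so a seed fixes the draw sequence bitwise.

**Transforms and standardisation.** Nest dimensions, clutch size, body
mass, nest-site height and nestling period are log-transformed;
precipitation and absolute latitude square-root transformed; temperature
uses a signed square root $\mathrm{sign}(x)\sqrt{|x|}$ because
breeding-season means can be negative and a plain square root would be
undefined. Continuous predictors are then mean-centred and scaled to
unit SD, using the sample (n−1) SD — this reproduces the two-point
worked example $\log\{e, e^2\} \mapsto \{-0.707, 0.707\}$ and matches
the usual "units of standard deviation" reporting; the population
divisor is available by configuration. Reported effect sizes are
posterior means of coefficients on this standardized scale.

**Multi-tree pooling.** The published protocol runs short chains on each
of 1000 trees (2400 iterations, 400 burn-in, thinning 1000), retaining
2 draws per tree for 2000 pooled solutions; with three chains per tree
the arithmetic only works if a single chain feeds the pool, so chain 1
contributes the retained draws and further chains serve the
Gelman–Rubin diagnostic only. `paper_schedule()` encodes that protocol.
The package default is a desk-scale schedule — 100 trees, 5000
iterations, 1000 burn-in, thinning 20 — which pools many more draws per
tree at a fraction of the tree count; tree subsampling is seeded.

**Summaries and diagnostics.** pMCMC is
$2\min(\#\{>0\}, \#\{<0\})/N$ floored at $2/N$ so finite samples never
report exactly zero. Conditional $R^2$ is computed per draw as
$(V_{fix} + \sigma^2_p + \sigma^2_s)/(V_{fix} + \sigma^2_p + \sigma^2_s
+ \sigma^2_e)$ with $V_{fix}$ the variance of the fixed linear predictor
over records, and reported as the posterior mean. HPD intervals are
empirical shortest-window intervals (no external MCMC package is
required). PSRF follows Gelman–Rubin
$\sqrt{((n-1)/n\,W + B/n)/W}$; ESS is $N/(1 + 2\sum\rho_k)$ truncated
at the first non-positive autocorrelation, with the lag-1 value screened
against 0.1. Runs with PSRF ≥ 1.1 or ESS below the configured floor are
flagged non-converged in their summaries rather than silently accepted.
Repeatability — the between-species share of phenotypic variance in
replicated records — is estimated by an intercept-only mixed model
(`lme4`). VIF is $1/(1 - R^2_j)$ from regressing each predictor on the
rest; the suite asserts all values below 6 on assembled tables.

## The synthetic-data generator

Because the deposited specimen data, range maps and posterior trees are
external downloads, validation runs entirely on generated data with
known ground truth. `nest_scenario()` fixes the study conditions:

* Yule trees (birth rate 1), ultrametric, seeded.
* A phylogenetic species effect with covariance
  $\sigma^2_p A(\lambda)$, species effects iid, record-level residuals;
  defaults $\sigma^2_p = 0.5$, $\sigma^2_s = 0.2$, $\sigma^2_e = 0.3$,
  $\lambda = 0.9$ — signal in the range reported for log nest volume,
  and a conditional $R^2$ around 0.8.
* Standardized fixed effects defaulting to the headline magnitudes for
  nest volume: body mass 0.750, breeding-range temperature −0.145,
  insularity 0.209 (Bernoulli dummy, p = 0.25).
* Record counts 1 + truncated Poisson(0.3), i.e. mean ≈ 1.3 records per
  species, max 14 — the empirical record-replication regime; a fixed
  count is available (the recovery benchmark uses 2).
* A literature-vs-museum source offset of +0.2 on the log response for
  literature records, encoding that museum specimens measure smaller;
  the magnitude is a round, plausible shrinkage-scale choice.
* A toy geography: rectangular ranges on a 0.5° regional grid, eight
  islands with stated areas spanning both insularity thresholds,
  monthly temperature $T = 30 - 0.5\,|lat| + 8\cos(2\pi(m -
  m_{peak})/12)$ with the warm peak in July north of the equator and
  January south of it (the sinusoid cancels exactly in annual means),
  and uniform precipitation.

Everything is a pure function of (scenario, seed). What the generator
does *not* emulate: real coastlines and island archipelago geometry,
spatially structured precipitation, heteroscedastic or spatially biased
sampling of specimens, taxonomic mismatch between data and trees, and
non-Brownian trait evolution. Passing tests therefore demonstrate that
the estimators recover the truth *under the model's own assumptions* —
they do not certify behaviour under model misspecification.

## Validation problem sizes

The test suite checks, among other things: exact geometry closed forms
and additivity on 1000 random dimension sets; ancestral states against a
brute-force GLS oracle on 100 random 5-tip trees (1e-8); λ recovery at
generating values {0, 0.5, 0.9, 1} as the median of 100 fits on 200-tip
trees (±0.05); 95% HPD coverage of the benchmark effects in at least
17/20 seeded replicates of the 200-species × 2-record recovery scenario,
with variance components within 3 posterior SDs; pMCMC calibration for a
null predictor over 50 replicates at 100 species (binomial 95% bounds
around 5%); diagnostic closed forms; the geospatial rule table; and
repeatability 0.8 ± 0.05 from a generative 4:1 variance split over 100
species × 3 records. These sizes are the package's chosen validation
conditions; the sampler schedules used in tests retain a few hundred
draws per fit, which the diagnostics show is ample for posterior means
at these sizes.

## Known limitations

* The Gibbs sampler handles Gaussian responses only; no multi-response
  or non-Gaussian families, and no DIC/model selection.
* The λ search is ML over [0, 1]; no REML, no OU or early-burst models.
* Geospatial computations are planar in degrees; ranges touching the
  poles or requiring equal-area projection are outside the design.
* The species and phylogenetic effects are confounded at species level;
  with a single record per species their separation rests entirely on
  the prior and tree structure, which is why the one-record-per-species
  models drop the species term.
* The evolutionary-correlation p-value rests on a t-approximation whose
  derivation is a package decision, not an established identity.
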