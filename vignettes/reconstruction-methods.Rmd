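---
title: "Reconstructing small-area case counts from privacy-perturbed tabulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing small-area case counts from privacy-perturbed tabulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censrecon)
```

## The statistical problem

Census tabulations of a rare binary health item are published through a
privacy mechanism: every cell receives symmetric integer noise and small
counts are suppressed.  At the finest areal level — units of a few hundred
residents, where a condition at 2–5 cases per 1000 produces true counts of
0, 1 or 2 — the published values are nearly uninformative one cell at a
time.  But the same latent counts are published repeatedly: aggregated to
every coarser level of a nested areal hierarchy, and along socioeconomic
and remoteness margins.  Each published cell is an independent noisy view
of a *sum* of the latent fine counts, so jointly the tables constrain the
latent vector far more tightly than any single table.

`censrecon` treats the fine-unit case counts as latent variables and
couples their reconstruction to a small-area prevalence model, so that
units borrow strength both from arithmetic consistency with the published
aggregates and from spatial and covariate smoothing.

## The observation model

For a published cell with true (latent) aggregate $y$, the mechanism draws
$\varepsilon$ from a symmetric pmf on $\{-d,\dots,d\}$, floors the noisy
value at zero, and suppresses results at or below the threshold $\tau$:

$$o = \begin{cases} 0 & \max(0, y+\varepsilon) \le \tau \\
\max(0, y+\varepsilon) & \text{otherwise,} \end{cases}$$

with true zeros published as exact zeros (`zero_fixed`).  The exact
likelihood $P(o \mid y)$, including the aggregated mass at $o = 0$, is
implemented in `perturbation_loglik()` and verified in the tests to
normalise to $1$ within $10^{-12}$ by enumeration.  Defaults are $d = 2$,
pmf $(0.1, 0.2, 0.4, 0.2, 0.1)$, $\tau = 2$: strong enough that published
zeros regularly hide true counts of 1–2 (which the reconstruction must
recover), while large counts pass through nearly unchanged.  Perturbations
are independent across all published cells; real mechanisms repeat the same
perturbation for identical cells, so independence gives the reconstruction
*less* information than reality and is conservative.  Suppressed cells are
modelled as published zeros (not as missing), since that is how public
tables render them.

Public register maps use a different rule — counts below 20 are censored
and the rest rounded to the nearest ten (`ndss_censor_round()`, ties round
up; the real tool's tie rule is undocumented).

## The prevalence model

Let $i$ index fine units and $j \in \{$0–9, 10–14, 15–19$\}$ age groups.
Case counts are binomial in the stated-response denominators,
$y_{ij} \sim \mathrm{Bin}(n_{ij}, p_{ij})$, with

$$\operatorname{logit} p_{ij} = \beta_{0j} + \beta_{\mathrm{ses}}
(\mathrm{ses}_i - 5.5) + \gamma_{r(i)} + u_i .$$

* $\beta_{0,\text{young}}$ and $\beta_{0,\text{old}}$ are free intercepts;
  the middle age group uses the logit-scale mixture
  $\eta_{\text{mid}} = w\,\eta_{\text{young}} + (1-w)\,\eta_{\text{old}}$
  with $w \in (0,1)$ learned from the data.  Mixing on the logit scale
  keeps $p_{\text{mid}}$ between the two endpoint models and makes $w$
  identifiable from counts alone; mixing on the probability or model-index
  scale would be near-indistinguishable at these prevalences but is not
  continuously parameterised.
* The socioeconomic effect is linear in the decile (1 = most
  disadvantaged), centred at 5.5 so the intercepts retain their
  interpretation.
* The five remoteness effects $\gamma$ are sum-to-zero by construction
  (four free coordinates).
* $u$ is a zero-mean Gaussian field over unit centroids with exponential
  covariance $\sigma_u^2 \exp(-\|s_i - s_j\|/\rho)$ (distances in km, a
  $10^{-8}\sigma_u^2$ diagonal jitter for Cholesky stability).  The
  exponential kernel — Matérn with smoothness 1/2 — is the conventional
  robust choice for areal centroid smoothing and needs no mesh machinery.

The binomial denominator is the stated-response count, not the population:
prevalence is defined among respondents, and non-response bias is a known
limitation of the underlying instrument rather than something the model
attempts to correct.

**Priors** (`prior_spec()`): $N(0, 2^2)$ on the intercepts, slope and the
free remoteness coordinates — weakly informative on the logit scale;
$N(\log 1, 1^2)$ on $\log \sigma_u$ (field amplitudes from 0.14 to 7 within
two prior sds); $N(\log 50\,\mathrm{km}, 1^2)$ on $\log \rho$ (ranges from
a few km to several hundred on the 500 km synthetic domain); uniform on
$w$.

**Identifiability.** The fitted field carries a sum-to-zero constraint
(the intercepts absorb the level), as in ICAR/BYM-style areal models.
Without it the field mean and the intercepts trade off along a direction
the data cannot resolve, and the field hyperparameters inflate to
accommodate the drift.  The constraint changes the interpretation of the
intercept only by the generating field's sample mean, which is an order of
magnitude smaller than the intercept's posterior spread at the default
study scale.

## The blocked Gibbs sampler

`run_chain()` cycles three blocks:

1. **Latent counts** (`update_counts()`): a Metropolis sweep over every
   fine unit and age group.  Proposals are $y \pm k$ with
   $k \sim 1 + \mathrm{Geom}$, rejected outside $[0, n_{ij}]$.  The
   acceptance ratio combines the perturbation likelihood of *every*
   published cell containing the unit — the fine cell, each coarser spatial
   cell, and the two margin cells — with the binomial model term.
   Aggregates are maintained incrementally (adding $y'-y$ along the unit's
   membership chain) and recomputed from scratch every 1000 iterations with
   an exact integer equality check.
2. **Spatial field** (`update_field()`): elliptical slice sampling under
   the Gaussian prior and the binomial likelihood; always accepts a valid
   state and needs no tuning.
3. **Scalars** (`update_scalars()`): coordinate-wise adaptive random-walk
   Metropolis on the intercepts, slope, free remoteness coordinates and
   $\operatorname{logit} w$ (binomial likelihood plus priors), and on
   $\log \sigma_u, \log \rho$ (which move the field through its whitened
   representation, so the likelihood informs them directly).  Proposal
   scales adapt towards a 0.35 acceptance rate during burn-in only, so the
   post-burn-in chain is a fixed-kernel Markov chain with the correct
   stationary distribution.

Two numerical choices deserve note.  First, the sampler holds the field in
whitened (non-centred) form, $u = \mathrm{centre}(\sigma_u L^\top z)$ with
$z \sim N(0, I)$ and $L$ the Cholesky factor of the correlation matrix:
with weak unit-level data the centred parameterisation mixes poorly because
$u$ and $\sigma_u$ are strongly coupled under the prior.  Second, inside
the count sweeps infeasible (cell, candidate) pairs receive a steep linear
penalty ($-100$ log-units per integer of infeasibility) instead of
$-\infty$.  The initial state — published fine counts clipped to their
denominators — is generically inconsistent with the coarser published
cells, and single-cell moves cannot cross hard zero-likelihood barriers;
the penalty turns initialisation into a short hill-climb while leaving the
stationary distribution on the support unchanged to $e^{-100}$ relative
mass.  The exported `perturbation_loglik()` is exact; the tests verify the
sweep kernel's stationary distribution against exact enumeration posteriors
(total variation below 0.02 on a single-cell system, and a three-unit joint
system with a coupled state-level cell).

Latent state is fine-level only; every coarser observed cell is a
deterministic sum.  Denominators $n_{ij}$ are treated as known — taken from
the synthetic truth in simulation studies, or from the published fine-level
positives-plus-negatives otherwise — because their relative perturbation is
negligible at denominator scale; reconstructing them jointly would roughly
double the latent dimension for no measurable gain at these prevalences.

Initial values: counts at the clipped published values, scalars at prior
means, $w$ at 0.5, field at zero.  Defaults (`mcmc_config()`): 2 chains of
6000 iterations, 2000 burn-in, thinning 4.  Convergence is monitored by
rank-normalised split-$\widehat R$ and bulk effective sample size
(`mcmc_diagnostics()`), validated in the tests against white-noise and
AR(1) oracles.

## The synthetic census generator

`simulate_truth()` draws a complete ground truth with the structure the
analysis assumes: centroids uniform on a square (planar km; geodesy is
irrelevant at desk scale), a nested hierarchy built by recursive spatial
slicing so coarse units are contiguous, socioeconomic deciles with
block-level autocorrelation, remoteness as distance-from-centre quintiles
of whole blocks, the Gaussian field, per-unit response rates (uniform on
0.88–0.95, around the instrument's real-world response rate), and binomial
denominators and case counts.  `publish_tables()` then pushes every true
aggregate through the perturbation mechanism, and `emulate_registers()`
produces a near-complete hospital-register table (binomial thinning at
capture 0.999, the published completeness estimate for the hospital
register it emulates) and a community-register table (capture 0.85, the
middle of the published 80–90% range; censored below 20 and rounded to
tens) on an external partition deliberately not nested in the hierarchy.

Default scale: 400 fine units with 30–120 residents per age group
(fine census units hold roughly 200–800 people across all ages), intercepts
at $\operatorname{logit}(0.0018)$ and $\operatorname{logit}(0.0052)$ —
prevalence anchors of 1.8 and 5.2 per 1000 for the youngest and oldest
groups — slope $-0.05$ per decile, remoteness effects
$(-0.2, -0.1, 0, 0.1, 0.2)$ increasing towards very remote, field
$\sigma_u = 0.3$, $\rho = 50$ km, and mixing weight $w = 0.9$.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: deterministic repeated perturbation of identical
cells, differential non-response correlated with the outcome, population
sizes spanning two orders of magnitude, double registration across regions,
and boundary/correspondence error between address bases.  The simulation
study validates the *inference machinery*, not the epidemiology.

## Reported summaries

`prevalence_summary()` offers two per-unit prevalence definitions.  The
count-based definition divides grouped latent count draws by grouped
denominators — faithful to the reconstruction, but dominated by
discreteness at realistic scales (most units have posterior median count
0).  The model-based definition evaluates the fitted surface
$\operatorname{expit}(\eta)$ per draw and is what maps and national
summaries should use; the 0–9 and 10–14 groups are combined with
stated-response weights into a 0–14 product.  Units are classed as
`"higher"` confidence when the posterior sd is below 25% of the posterior
median prevalence.  National summaries report the median and IQR across
units of the per-unit posterior median, per 1000.  Quantiles use linear
interpolation of order statistics throughout (no convention is fixed by the
products being emulated).

Calibration is assessed as coverage of the *generating latent prevalence*
by the model-based 95% credible intervals, pooled over simulation
replicates.  The count-based intervals are not used for this: discrete
point-mass intervals cover realised counts mechanically (measured ~99%),
which tests discreteness rather than calibration.  The mixing-weight
recovery check compares the replicate-averaged posterior median of $w$ to
the generating value: at the default study scale a single replicate
identifies $w$ with a sampling sd of roughly 0.15 (it is a ratio of three
intercept-scale contrasts estimated from ~50–150 cases each), so averaging
over the ten replicates is the meaningful precision.

## Problem sizes

The shipped tests run the single-cell stationarity check at $10^5$ sweeps
(total variation below 0.02 against exact enumeration), a three-unit joint
check at $10^5$ sweeps, and a ten-replicate recovery study at the full
default scale of 400 fine units with one 3000-iteration chain per
replicate — enough for split-$\widehat R$ near 1.05 on the key scalars, as
the acceptance script's two-chain run confirms.  Longer chains sharpen the
field-hyperparameter effective sample sizes but do not move the reported
summaries.

## Known limitations

* Whole-unit external correspondence only (no population-weighted splits).
* The perturbation mechanism is a stand-in with matched qualitative
  behaviour; the real mechanism's pmf and repetition rules are not public.
* Denominators are conditioned on, not reconstructed.
* A single spatial field is shared across age groups; age-specific fields
  would need either stronger data or informative priors.
* The exponential kernel is fixed (config-switchable in principle); no
  anisotropy.
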