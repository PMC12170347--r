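# censrecon

Bayesian reconstruction of small-area case counts from privacy-perturbed
census tabulations, with a geospatial prevalence model.

## The problem

National statistical agencies release census tabulations through privacy
mechanisms: symmetric integer noise is injected into every published cell
and small counts are suppressed (published as zero).  For a rare condition
— such as diabetes among children, with a prevalence of a few cases per
1000 — the counts at the finest areal units are small enough that the
perturbation destroys most of the unit-level signal.  The same tabulations
are, however, published at every level of a nested areal hierarchy
(fine units up to the state total) and along socioeconomic and remoteness
margins, and those redundant noisy views of the same underlying counts can
be combined: a latent fine-unit count vector must be simultaneously
consistent with *all* published aggregates, which constrains it far more
than any single table does.

`censrecon` implements this reconstruction for epidemiologists and
biostatisticians working with perturbed tabulations.  It jointly infers

* the true fine-unit case counts `y_ij` (unit `i`, age group `j`), and
* a small-area prevalence model on the logit scale,

      logit p_ij = beta0_j + beta_ses (ses_i - 5.5) + gamma[rem_i] + u_i

  with a per-age-model intercept, a linear socioeconomic-decile gradient,
  five sum-to-zero remoteness effects, and a Gaussian spatial random field
  `u` with exponential covariance `sigma_u^2 exp(-d/rho)`.  The youngest
  (0–9) and oldest (15–19) age groups have their own intercepts; the middle
  group (10–14) is a logit-scale mixture `w eta_young + (1-w) eta_old` with
  the mixing weight `w` learned from the data.

Inference is by a blocked Gibbs sampler: Metropolis sweeps over the latent
integer counts (the acceptance ratio combines the exact perturbation
likelihood of every published cell containing the unit with the binomial
model term), elliptical slice sampling of the spatial field, and adaptive
random-walk updates of the scalar parameters.  Because real unit-level
extracts cannot be redistributed, the package ships a synthetic-census
generator that reproduces the full data structure — three response
categories (case / non-case / not stated), the nested hierarchy with
socioeconomic and remoteness margins, the noise-plus-suppression
mechanism, and register publication rules (censoring below 20, rounding to
the nearest ten) — so every stage is testable end to end.

## Worked example

```r
library(censrecon)

# a synthetic world at the default study scale: 400 fine units,
# prevalence anchors 1.8 and 5.2 per 1000, mixing weight 0.9
sim  <- simulate_truth(sim_config(seed = 1))
h    <- sim$hierarchy
tabs <- publish_tables(h, sim$truth, perturb_config(), seed = 101)
nst  <- truth_matrices(h, sim$truth)$n_stated

fit <- fit_reconstruction(tabs, h, n_stated = nst,
                          mcfg = mcmc_config(n_iter = 3000, n_burn = 1000,
                                             thin = 4, n_chains = 2,
                                             seed = 11))
summary(fit)
```

```
Scalar parameter posteriors:
             median     mean       sd    q2.5    q97.5
beta0_young -6.3671  -6.3729   0.1243 -6.6322  -6.1316
beta0_old   -5.3896  -5.3909   0.0964 -5.5892  -5.2119
beta_ses    -0.0120  -0.0111   0.0307 -0.0668   0.0489
...
sigma_u      0.4112   0.4257   0.1477  0.1644   0.7591
w            0.8735   0.8563   0.1042  0.6248   0.9939

National small-area prevalence, median [IQR] per 1000:
  age0_14: 1.79 [1.61-2.24]
  age15_19: 4.43 [3.95-5.49]
```

The intercept posteriors recover the generating values (`qlogis(0.0018)
= -6.32`, `qlogis(0.0052) = -5.26`), the field scale and mixing weight
concentrate near their generating values (0.3 and 0.9), and the national
prevalence summaries sit at the generator's anchors of roughly 1.8 and 5.2
cases per 1000.  Downstream:

```r
ps  <- prevalence_summary(fit, type = "model")   # per-unit estimates,
                                                 # 95% CrIs, confidence class
agg <- aggregate_posterior(fit, aggregation_matrix(h, "L3"),
                           ages = "age0_9")      # posterior coarse counts
reg <- emulate_registers(h, sim$truth, seed = 201)
compare_register(agg, reg$hospital[reg$hospital$age_group == "age0_9",
                                   c("unit_id", "count")])
#> Register comparison over 20 units: 0 outlier(s) outside the 95% CrI (0.0%)
#> Pearson correlation (register vs posterior median): 0.9
```

`prevalence_summary` classifies a unit as `"higher"` confidence when the
posterior standard deviation is below 25% of the posterior median
prevalence, and `compare_register` flags units whose register count falls
outside the reconstruction's 95% credible interval.

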