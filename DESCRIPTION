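Package: censrecon
Title: Reconstruction of Privacy-Perturbed Census Counts and Small-Area
    Prevalence Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian statistical reconstruction of true small-area case
    counts from privacy-perturbed nested census tabulations, coupled with a
    geospatial logit prevalence model.  A blocked Gibbs sampler jointly
    explores latent fine-unit counts consistent with noise-injected,
    low-count-suppressed tables published at every level of a nested areal
    hierarchy (and socioeconomic/remoteness margins), with feedback against
    a binomial smoothing model whose linear predictor combines an intercept,
    a socioeconomic gradient, remoteness effects and a Gaussian spatial
    random field.  Includes a synthetic-census generator emulating the
    perturbation mechanism and register publication rules (censoring below
    20, rounding to the nearest ten), posterior summaries with confidence
    classification, and register-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
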