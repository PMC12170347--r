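#' Model parameters for the geospatial prevalence model
#'
#' The expected proportion positive in each fine unit is modelled on the
#' logit scale, separately for the youngest and oldest age groups, as
#' intercept + socioeconomic effect + remoteness effect + spatial random
#' field; the middle age group's logit prevalence is the convex combination
#' `w * young + (1 - w) * old`.  The five remoteness effects are sum-to-zero
#' by construction (four free coordinates), and the field hyperparameters
#' and mixing weight are held on unconstrained scales.
#'
#' @param beta0_young,beta0_old Intercepts (logit scale).
#' @param beta_ses Socioeconomic slope per decile unit (deciles centred at
#'   5.5).
#' @param gfree Four free remoteness coordinates; the fifth is minus their
#'   sum.
#' @param log_sigma_u,log_rho Log field standard deviation and log range
#'   (km).
#' @param logit_w Mixing weight on the logit scale.
#' @param u Spatial field values per fine unit (may be `NULL` until bound to
#'   a hierarchy).
#' @return An object of class `model_params`.
#' @export
model_params <- function(beta0_young, beta0_old, beta_ses = 0,
                         gfree = rep(0, 4), log_sigma_u = 0,
                         log_rho = log(50), logit_w = 0, u = NULL) {
  stopifnot(length(gfree) == 4L)
  structure(list(beta0_young = beta0_young, beta0_old = beta0_old,
                 beta_ses = beta_ses, gfree = as.numeric(gfree),
                 log_sigma_u = log_sigma_u, log_rho = log_rho,
                 logit_w = logit_w, u = u),
            class = "model_params")
}

#' Derived quantities of a parameter set
#'
#' @param params A [model_params()].
#' @return `gamma_full`: the five sum-to-zero remoteness effects.
#' @export
gamma_full <- function(params) c(params$gfree, -sum(params$gfree))

#' Prior specification
#'
#' Independent normal priors on the unconstrained scalars and a uniform
#' prior on the mixing weight (equivalently a standard logistic prior on its
#' logit).  Defaults: N(0, 2^2) on intercepts, slope and remoteness
#' coordinates (weak on the logit scale), N(log 1, 1) on the log field sd,
#' N(log 50, 1) on the log range in km.
#'
#' @param beta_mean,beta_sd Normal prior for each of the two intercepts, the
#'   socioeconomic slope and each free remoteness coordinate.
#' @param log_sigma_mean,log_sigma_sd Normal prior for `log_sigma_u`.
#' @param log_rho_mean,log_rho_sd Normal prior for `log_rho`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_mean = 0, beta_sd = 2,
                       log_sigma_mean = 0, log_sigma_sd = 1,
                       log_rho_mean = log(50), log_rho_sd = 1) {
  stopifnot(beta_sd > 0, log_sigma_sd > 0, log_rho_sd > 0)
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 log_sigma_mean = log_sigma_mean,
                 log_sigma_sd = log_sigma_sd,
                 log_rho_mean = log_rho_mean, log_rho_sd = log_rho_sd),
            class = "prior_spec")
}

# log prior density of the scalar block (internal)
log_prior_scalars <- function(params, priors) {
  sum(dnorm(c(params$beta0_young, params$beta0_old, params$beta_ses,
              params$gfree),
            priors$beta_mean, priors$beta_sd, log = TRUE)) +
    dnorm(params$log_sigma_u, priors$log_sigma_mean, priors$log_sigma_sd,
          log = TRUE) +
    dnorm(params$log_rho, priors$log_rho_mean, priors$log_rho_sd,
          log = TRUE) +
    dlogis(params$logit_w, log = TRUE)  # uniform prior on w
}

#' Exponential spatial covariance
#'
#' `Sigma[i, j] = sigma_u^2 * exp(-d[i, j] / rho)` with a relative jitter of
#' `1e-8 * sigma_u^2` on the diagonal so the Cholesky factorisation is
#' stable.
#'
#' @param distances Symmetric pairwise distance matrix (km), zero diagonal.
#' @param sigma_u Field standard deviation (> 0).
#' @param rho Range parameter in km (> 0).
#' @return Covariance matrix.
#' @export
gp_covariance <- function(distances, sigma_u, rho) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances) ||
      max(abs(distances - t(distances))) > 1e-8)
    stop("'distances' must be a symmetric matrix")
  stopifnot(sigma_u > 0, rho > 0)
  S <- sigma_u^2 * exp(-distances / rho)
  diag(S) <- diag(S) + 1e-8 * sigma_u^2
  S
}

# pairwise planar distances between fine-unit centroids (internal)
centroid_distances <- function(h) {
  as.matrix(dist(cbind(h$units$centroid_x_km, h$units$centroid_y_km)))
}

#' Linear predictor of the prevalence model
#'
#' `eta_i = beta0 + beta_ses * (decile_i - 5.5) + gamma[remoteness_i] + u_i`
#' with the intercept chosen by `age_model`.
#'
#' @param params A [model_params()] with field `u` of length `h$n` (zeros
#'   assumed when `NULL`).
#' @param h A `census_hierarchy`.
#' @param age_model `"young"` or `"old"`.
#' @return Numeric vector of logit prevalences per fine unit, in
#'   `h$fine_ids` order.
#' @export
linear_predictor <- function(params, h, age_model = c("young", "old")) {
  age_model <- match.arg(age_model)
  b0 <- if (age_model == "young") params$beta0_young else params$beta0_old
  u <- if (is.null(params$u)) rep(0, h$n) else params$u
  stopifnot(length(u) == h$n)
  g <- gamma_full(params)
  b0 + params$beta_ses * (h$units$ses_decile - 5.5) +
    g[match(h$units$remoteness, REMOTENESS_LEVELS)] + u
}

#' Logit-scale mixture for the middle age group
#'
#' @param eta_young,eta_old Conformable logit prevalence vectors.
#' @param w Mixing weight in (0, 1); `w = 1` recovers the youngest-group
#'   model.
#' @return `w * eta_young + (1 - w) * eta_old`.
#' @export
mixture_predictor <- function(eta_young, eta_old, w) {
  stopifnot(length(eta_young) == length(eta_old), w >= 0, w <= 1)
  w * eta_young + (1 - w) * eta_old
}

# n x 3 matrix of linear predictors for all age groups (internal)
compute_eta <- function(params, h) {
  ey <- linear_predictor(params, h, "young")
  eo <- linear_predictor(params, h, "old")
  w <- plogis(params$logit_w)
  cbind(age0_9 = ey, age10_14 = mixture_predictor(ey, eo, w),
        age15_19 = eo)
}

#' Joint log density of counts, field and scalar parameters
#'
#' Binomial log-likelihood of the latent counts given the model
#' probabilities, plus the Gaussian field prior under the exponential
#' covariance, plus the scalar priors.
#'
#' @param params A [model_params()] with field `u`.
#' @param y Integer matrix (fine units x 3 age groups) of latent case
#'   counts.
#' @param n_stated Integer matrix of stated-response denominators, same
#'   shape.
#' @param h A `census_hierarchy`.
#' @param priors A [prior_spec()].
#' @return Scalar log density.
#' @export
log_joint <- function(params, y, n_stated, h, priors = prior_spec()) {
  y <- as.matrix(y); n_stated <- as.matrix(n_stated)
  storage.mode(y) <- "integer"; storage.mode(n_stated) <- "integer"
  if (any(y < 0L) || any(y > n_stated))
    stop("latent counts must satisfy 0 <= y <= n_stated")
  u <- if (is.null(params$u)) rep(0, h$n) else params$u
  eta <- compute_eta(params, h)
  llb <- sum(dbinom(y, n_stated, plogis(eta), log = TRUE)[n_stated > 0L])
  S <- gp_covariance(centroid_distances(h), exp(params$log_sigma_u),
                     exp(params$log_rho))
  L <- chol(S)
  z <- backsolve(L, u, transpose = TRUE)
  llu <- -0.5 * sum(z^2) - sum(log(diag(L))) - 0.5 * h$n * log(2 * pi)
  llb + llu + log_prior_scalars(params, priors)
}
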