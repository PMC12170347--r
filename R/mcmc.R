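#' Sampler configuration
#'
#' @param n_iter Total iterations per chain.
#' @param n_burn Burn-in iterations (discarded; proposal adaptation happens
#'   only here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param count_proposal_sd Scale of the integer random-walk on latent
#'   counts: proposals are `y +/- k` with `k ~ 1 + Geometric(1 / (1 +
#'   scale))`.
#' @param adapt_interval Iterations between proposal-scale adaptations
#'   during burn-in.
#' @param target_accept Target acceptance rate for the scalar random-walk
#'   updates.
#' @param seed Integer seed; chain `c` of a multi-chain fit uses
#'   `seed + c - 1`.
#' @param n_chains Number of chains for [fit_reconstruction()].
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000L, n_burn = 2000L, thin = 4L,
                        count_proposal_sd = 1, adapt_interval = 50L,
                        target_accept = 0.35, seed = 20210810L,
                        n_chains = 2L) {
  stopifnot(n_burn < n_iter, thin >= 1L, count_proposal_sd > 0,
            adapt_interval >= 1L, target_accept > 0, target_accept < 1,
            n_chains >= 1L)
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin),
                 count_proposal_sd = count_proposal_sd,
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept, seed = as.integer(seed),
                 n_chains = as.integer(n_chains)),
            class = "mcmc_config")
}

# scalar parameter names in update order (internal)
SCALAR_COORDS <- c("beta0_young", "beta0_old", "beta_ses",
                   paste0("g", 1:4), "logit_w", "log_sigma_u", "log_rho")

# observation structure used by the sampler (internal): for every partition
# present in the published tables, the 1-based group index of each fine unit
# and the published positive counts as a (groups x ages) matrix
build_sampler_data <- function(observed, h) {
  parts <- intersect(c(names(SPATIAL_LEVELS), MARGIN_PARTITIONS),
                     unique(observed$level))
  if (!"L1" %in% parts)
    stop("published tables must include level L1 for all fine units")
  pos <- observed[observed$category == "positive", , drop = FALSE]
  gid <- list(); obs <- list()
  for (p in parts) {
    lab <- partition_labels(h, p)
    groups <- sort(unique(lab), method = "radix")
    rows <- pos[pos$level == p, , drop = FALSE]
    m <- matrix(NA_integer_, length(groups), 3L,
                dimnames = list(groups, AGE_GROUPS))
    m[cbind(match(rows$unit_id, groups),
            match(rows$age_group, AGE_GROUPS))] <- as.integer(rows$count)
    if (anyNA(m))
      stop("published tables are missing positive-count cells at level ", p)
    gid[[p]] <- match(lab, groups)
    obs[[p]] <- m
  }
  neg <- observed[observed$category == "negative" &
                    observed$level == "L1", , drop = FALSE]
  n_stated_pub <- NULL
  if (nrow(neg)) {
    mneg <- matrix(0L, h$n, 3L, dimnames = list(h$fine_ids, AGE_GROUPS))
    mneg[cbind(match(neg$unit_id, h$fine_ids),
               match(neg$age_group, AGE_GROUPS))] <- as.integer(neg$count)
    n_stated_pub <- pmax(obs$L1 + mneg, obs$L1)
  }
  list(parts = parts, gid = gid, obs = obs, n_stated_pub = n_stated_pub)
}

#' Initialise the sampler state
#'
#' Latent counts start at the published fine-level positive counts clipped
#' to `[0, n_stated]`; scalar parameters start at their prior means, the
#' mixing weight at 0.5, and the spatial field at zero.
#'
#' @param observed Published tables (from [publish_tables()] or read from
#'   CSV) covering at least level `L1`.
#' @param h A `census_hierarchy`.
#' @param seed Optional integer seed (`NULL` keeps the RNG stream).
#' @param n_stated Known stated-response denominators (fine units x 3
#'   integer matrix); when `NULL` they are derived from the published
#'   fine-level positive and negative counts.
#' @param priors A [prior_spec()].
#' @return An object of class `recon_state`.
#' @export
init_state <- function(observed, h, seed = NULL, n_stated = NULL,
                       priors = prior_spec()) {
  if (!is.null(seed)) set.seed(seed)
  sd_ <- build_sampler_data(observed, h)
  if (is.null(n_stated)) {
    n_stated <- sd_$n_stated_pub
    if (is.null(n_stated))
      stop("n_stated not supplied and no published negative counts at L1")
  }
  n_stated <- as.matrix(n_stated)
  storage.mode(n_stated) <- "integer"
  stopifnot(nrow(n_stated) == h$n, ncol(n_stated) == 3L)

  y <- pmin(pmax(sd_$obs$L1, 0L), n_stated)
  storage.mode(y) <- "integer"
  agg <- lapply(sd_$parts, function(p) {
    m <- rowsum(y, sd_$gid[[p]])
    storage.mode(m) <- "integer"
    m
  })
  names(agg) <- sd_$parts

  params <- model_params(beta0_young = priors$beta_mean,
                         beta0_old = priors$beta_mean,
                         beta_ses = priors$beta_mean,
                         gfree = rep(priors$beta_mean, 4L),
                         log_sigma_u = priors$log_sigma_mean,
                         log_rho = priors$log_rho_mean,
                         logit_w = 0, u = rep(0, h$n))

  D <- centroid_distances(h)
  cholR <- chol(exp(-D / exp(params$log_rho)) + diag(1e-8, h$n))
  state <- list(
    y = y, agg = agg, params = params,
    data = list(h = h, n_stated = n_stated, parts = sd_$parts,
                gid = sd_$gid, obs = sd_$obs, D = D,
                x_ses = h$units$ses_decile - 5.5,
                rem_idx = match(h$units$remoteness, REMOTENESS_LEVELS)),
    cache = list(cholR = cholR,
                 z = rep(0, h$n),  # whitened field: u = sigma_u * t(L) z
                 prop_sd = setNames(rep(0.2, length(SCALAR_COORDS)),
                                    SCALAR_COORDS),
                 acc = setNames(rep(0, length(SCALAR_COORDS)),
                                SCALAR_COORDS),
                 try = setNames(rep(0, length(SCALAR_COORDS)),
                                SCALAR_COORDS),
                 iter = 0L))
  state$cache$eta <- compute_eta(params, h)
  state$cache$off <- offset_part(state)
  state$cache$llb <- cpp_binom_loglik(y, n_stated, state$cache$off,
                                      params$u, params$beta0_young,
                                      params$beta0_old,
                                      plogis(params$logit_w))
  class(state) <- "recon_state"
  state
}

# covariate part of the linear predictor, excluding intercept and field
offset_part <- function(state) {
  p <- state$params
  g <- gamma_full(p)
  p$beta_ses * state$data$x_ses + g[state$data$rem_idx]
}

# The field is held in whitened form: z has a standard normal prior and
# u = centre(sigma_u * t(chol(R(rho))) %*% z), so the hyperparameters are
# informed by the data through the field amplitude and smoothness rather
# than coupling to u under its own prior.  The fitted field is constrained
# to sum to zero (the intercepts carry the level) -- the usual
# identifiability constraint for areal smoothing models, without which the
# field mean and the intercepts trade off along a direction the data cannot
# resolve.
field_from_z <- function(state) {
  u <- exp(state$params$log_sigma_u) *
    drop(crossprod(state$cache$cholR, state$cache$z))
  u - mean(u)
}

#' One block of the Gibbs cycle: Metropolis sweep over latent counts
#'
#' Each fine unit x age cell is proposed an integer step `y +/- k`; the
#' acceptance ratio combines the perturbation likelihood of every published
#' cell containing the unit (aggregates updated incrementally) with the
#' binomial model term.  Proposals outside `[0, n_stated]` are rejected.
#'
#' @param state A `recon_state`.
#' @param pcfg The [perturb_config()] that generated the tables.
#' @param mcfg An [mcmc_config()] (proposal scale).
#' @param n_sweeps Number of full sweeps to perform.
#' @param trace Record the full count state after every sweep (used by the
#'   stationarity tests; columns in unit-fastest, then age order).
#' @return The updated state; acceptance statistics in
#'   `state$last_counts`, and the trace matrix in `state$trace` when
#'   requested.
#' @export
update_counts <- function(state, pcfg = perturb_config(),
                          mcfg = mcmc_config(), n_sweeps = 1L,
                          trace = FALSE) {
  y <- state$y + 0L  # fresh copies: the C++ kernel updates in place
  agg <- lapply(state$agg, function(m) m + 0L)
  geom_p <- 1 / (1 + mcfg$count_proposal_sd)
  res <- cpp_sweep_counts(y, state$data$n_stated,
                          plogis(state$cache$eta),
                          unname(state$data$gid[state$data$parts]),
                          unname(agg[state$data$parts]),
                          unname(state$data$obs[state$data$parts]),
                          pcfg$noise_pmf, pcfg$d, pcfg$tau,
                          pcfg$zero_fixed, geom_p, as.integer(n_sweeps),
                          isTRUE(trace))
  state$y <- y
  state$agg <- agg
  state$cache$llb <- cpp_binom_loglik(y, state$data$n_stated,
                                      state$cache$off, state$params$u,
                                      state$params$beta0_young,
                                      state$params$beta0_old,
                                      plogis(state$params$logit_w))
  state$last_counts <- c(accept = res$accept, total = res$total)
  if (isTRUE(trace)) state$trace <- res$trace
  state
}

#' One block of the Gibbs cycle: elliptical slice sampling of the field
#'
#' Updates the spatial random field under its Gaussian-process prior and the
#' binomial likelihood; scalar parameters and latent counts are untouched.
#' The fitted field carries a sum-to-zero identifiability constraint (the
#' intercepts absorb the level), as is standard for areal smoothing models.
#'
#' @param state A `recon_state`.
#' @return The updated state.
#' @export
update_field <- function(state) {
  n <- state$data$h$n
  sig <- exp(state$params$log_sigma_u)
  nu_z <- rnorm(n)
  nu_u <- sig * drop(crossprod(state$cache$cholR, nu_z))
  nu_u <- nu_u - mean(nu_u)  # rotations then preserve the sum-to-zero field
  res <- cpp_ess_field(state$params$u, nu_u, state$cache$off,
                       state$params$beta0_young, state$params$beta0_old,
                       plogis(state$params$logit_w), state$y,
                       state$data$n_stated)
  th <- res$theta
  state$cache$z <- state$cache$z * cos(th) + nu_z * sin(th)
  state$params$u <- res$u
  state$cache$llb <- res$ll
  state$cache$eta <- compute_eta(state$params, state$data$h)
  state
}

#' One block of the Gibbs cycle: adaptive random walk on scalar parameters
#'
#' Coordinate-wise Metropolis updates of the intercepts, socioeconomic
#' slope, free remoteness coordinates and logit mixing weight (binomial
#' likelihood plus priors) and of the log field hyperparameters (Gaussian
#' field prior plus priors).  Proposal scales adapt towards the target
#' acceptance rate only while `adapt = TRUE` (burn-in).
#'
#' @param state A `recon_state`.
#' @param priors A [prior_spec()].
#' @param mcfg An [mcmc_config()].
#' @param adapt Adapt proposal scales this call.
#' @return The updated state.
#' @export
update_scalars <- function(state, priors = prior_spec(),
                           mcfg = mcmc_config(), adapt = FALSE) {
  p <- state$params
  ca <- state$cache
  y <- state$y; nst <- state$data$n_stated

  prior_one <- function(name, val) {
    switch(name,
           log_sigma_u = dnorm(val, priors$log_sigma_mean,
                               priors$log_sigma_sd, log = TRUE),
           log_rho = dnorm(val, priors$log_rho_mean, priors$log_rho_sd,
                           log = TRUE),
           logit_w = dlogis(val, log = TRUE),
           dnorm(val, priors$beta_mean, priors$beta_sd, log = TRUE))
  }
  get_coord <- function(name) {
    if (grepl("^g[1-4]$", name)) p$gfree[as.integer(substring(name, 2L))]
    else p[[name]]
  }
  set_coord <- function(pp, name, val) {
    if (grepl("^g[1-4]$", name))
      pp$gfree[as.integer(substring(name, 2L))] <- val
    else pp[[name]] <- val
    pp
  }

  for (name in SCALAR_COORDS) {
    cur <- get_coord(name)
    prop <- cur + rnorm(1L, 0, ca$prop_sd[[name]])
    ca$try[[name]] <- ca$try[[name]] + 1
    if (name %in% c("log_sigma_u", "log_rho")) {
      # field hyperparameters move the field through the whitened
      # representation (z fixed, u rescaled/resmoothed), so the binomial
      # likelihood informs them directly
      if (name == "log_rho") {
        cholR_new <- chol(exp(-state$data$D / exp(prop)) +
                            diag(1e-8, state$data$h$n))
        u_new <- exp(p$log_sigma_u) * drop(crossprod(cholR_new, ca$z))
        u_new <- u_new - mean(u_new)
      } else {
        cholR_new <- ca$cholR
        u_new <- p$u * exp(prop - cur)
      }
      llb_new <- cpp_binom_loglik(y, nst, ca$off, u_new, p$beta0_young,
                                  p$beta0_old, plogis(p$logit_w))
      lr <- llb_new - ca$llb + prior_one(name, prop) - prior_one(name, cur)
      if (is.finite(lr) && log(runif(1L)) < lr) {
        p[[name]] <- prop
        p$u <- u_new
        ca$cholR <- cholR_new
        ca$llb <- llb_new
        ca$acc[[name]] <- ca$acc[[name]] + 1
      }
    } else {
      pp <- set_coord(p, name, prop)
      off_new <- if (name %in% c("beta_ses", paste0("g", 1:4))) {
        g <- gamma_full(pp)
        pp$beta_ses * state$data$x_ses + g[state$data$rem_idx]
      } else ca$off
      llb_new <- cpp_binom_loglik(y, nst, off_new, p$u, pp$beta0_young,
                                  pp$beta0_old, plogis(pp$logit_w))
      lr <- llb_new - ca$llb + prior_one(name, prop) - prior_one(name, cur)
      if (is.finite(lr) && log(runif(1L)) < lr) {
        p <- pp
        ca$off <- off_new
        ca$llb <- llb_new
        ca$acc[[name]] <- ca$acc[[name]] + 1
      }
    }
  }

  ca$iter <- ca$iter + 1L
  if (adapt && ca$iter %% mcfg$adapt_interval == 0L) {
    rate <- ifelse(ca$try > 0, ca$acc / ca$try, mcfg$target_accept)
    ca$prop_sd <- pmin(pmax(ca$prop_sd * exp(0.8 * (rate -
                                                      mcfg$target_accept)),
                            1e-3), 10)
    ca$acc[] <- 0; ca$try[] <- 0
  }

  state$params <- p
  state$cache <- ca
  state$cache$eta <- compute_eta(p, state$data$h)
  state
}

#' Run one chain of the blocked Gibbs sampler
#'
#' Cycles latent-count Metropolis sweeps, elliptical slice sampling of the
#' spatial field, and adaptive random-walk updates of the scalar parameters;
#' stores thinned post-burn-in draws.  Aggregate caches are recomputed from
#' scratch every 1000 iterations and checked for exact agreement.
#'
#' @param observed Published tables covering at least level `L1`.
#' @param h A `census_hierarchy`.
#' @param pcfg A [perturb_config()].
#' @param priors A [prior_spec()].
#' @param mcfg An [mcmc_config()].
#' @param n_stated Known denominators (see [init_state()]).
#' @param chain_id Integer chain label stored with the draws.
#' @param verbose Print progress every 1000 iterations.
#' @return An object of class `recon_samples`: scalar draws (data frame with
#'   `chain` and `iter`), field draws (`u`, draws x units), latent count
#'   draws (`y`, draws x units x ages), plus metadata.
#' @export
run_chain <- function(observed, h, pcfg = perturb_config(),
                      priors = prior_spec(), mcfg = mcmc_config(),
                      n_stated = NULL, chain_id = 1L, verbose = FALSE) {
  set.seed(mcfg$seed)
  state <- init_state(observed, h, seed = NULL, n_stated = n_stated,
                      priors = priors)
  keep <- which(seq_len(mcfg$n_iter) > mcfg$n_burn &
                  (seq_len(mcfg$n_iter) - mcfg$n_burn) %% mcfg$thin == 0L)
  n_keep <- length(keep)
  sc_names <- c("beta0_young", "beta0_old", "beta_ses",
                paste0("gamma", 1:5), "log_sigma_u", "log_rho", "logit_w")
  scal <- matrix(NA_real_, n_keep, length(sc_names),
                 dimnames = list(NULL, sc_names))
  u_draws <- matrix(NA_real_, n_keep, h$n)
  y_draws <- array(NA_integer_, c(n_keep, h$n, 3L))
  cnt_acc <- c(0, 0)
  k <- 0L
  for (it in seq_len(mcfg$n_iter)) {
    state <- update_counts(state, pcfg, mcfg)
    if (it > mcfg$n_burn) cnt_acc <- cnt_acc + state$last_counts
    state <- update_field(state)
    state <- update_scalars(state, priors, mcfg, adapt = it <= mcfg$n_burn)
    if (it %% 1000L == 0L) {
      # periodic exact recomputation of the incremental aggregate caches
      for (p in state$data$parts) {
        fresh <- rowsum(state$y, state$data$gid[[p]])
        stopifnot(all(fresh == state$agg[[p]]))
      }
      if (verbose)
        message("iter ", it, " llb = ", signif(state$cache$llb, 6))
    }
    if (it > mcfg$n_burn &&
        (it - mcfg$n_burn) %% mcfg$thin == 0L) {
      k <- k + 1L
      pp <- state$params
      scal[k, ] <- c(pp$beta0_young, pp$beta0_old, pp$beta_ses,
                     gamma_full(pp), pp$log_sigma_u, pp$log_rho,
                     pp$logit_w)
      u_draws[k, ] <- pp$u
      y_draws[k, , ] <- state$y
    }
  }
  scalars <- data.frame(chain = chain_id, iter = keep, scal)
  scalars$sigma_u <- exp(scalars$log_sigma_u)
  scalars$rho <- exp(scalars$log_rho)
  scalars$w <- plogis(scalars$logit_w)
  structure(list(scalars = scalars, u = u_draws, y = y_draws,
                 chain = rep(chain_id, n_keep), fine_ids = h$fine_ids,
                 age_groups = AGE_GROUPS, n_stated = state$data$n_stated,
                 accept = list(
                   counts = unname(cnt_acc[1] / max(cnt_acc[2], 1)),
                   scalars = state$cache$acc /
                     pmax(state$cache$try, 1)),
                 mcfg = mcfg),
            class = "recon_samples")
}

# stack several chains' samples (internal)
combine_samples <- function(lst) {
  out <- lst[[1L]]
  if (length(lst) > 1L) {
    out$scalars <- do.call(rbind, lapply(lst, `[[`, "scalars"))
    out$u <- do.call(rbind, lapply(lst, `[[`, "u"))
    ys <- lapply(lst, `[[`, "y")
    nd <- sum(vapply(ys, function(a) dim(a)[1L], 0L))
    y <- array(NA_integer_, c(nd, dim(ys[[1L]])[2:3]))
    at <- 0L
    for (a in ys) {
      y[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out$y <- y
    out$chain <- unlist(lapply(lst, `[[`, "chain"))
  }
  out
}

#' Fit the reconstruction model
#'
#' The main user entry point: runs `n_chains` chains of [run_chain()] (chain
#' `c` seeded with `seed + c - 1`), combines the draws, and returns a fitted
#' model object with `print`, `summary`, `coef`, `predict` and `plot`
#' methods.
#'
#' @inheritParams run_chain
#' @return An object of class `recon_fit`.
#' @examples
#' \donttest{
#' sim <- simulate_truth(sim_config(n_fine = 40, n_per_l2 = 2, n_per_l3 = 2,
#'                                  n_per_l4 = 5, seed = 7))
#' tabs <- publish_tables(sim$hierarchy, sim$truth, seed = 7)
#' nst <- truth_matrices(sim$hierarchy, sim$truth)$n_stated
#' fit <- fit_reconstruction(tabs, sim$hierarchy, n_stated = nst,
#'                           mcfg = mcmc_config(n_iter = 400, n_burn = 200,
#'                                              thin = 2, n_chains = 1))
#' coef(fit)
#' }
#' @export
fit_reconstruction <- function(observed, h, pcfg = perturb_config(),
                               priors = prior_spec(), mcfg = mcmc_config(),
                               n_stated = NULL, verbose = FALSE) {
  chains <- vector("list", mcfg$n_chains)
  for (cc in seq_len(mcfg$n_chains)) {
    mc <- mcfg
    mc$seed <- mcfg$seed + cc - 1L
    chains[[cc]] <- run_chain(observed, h, pcfg, priors, mc,
                              n_stated = n_stated, chain_id = cc,
                              verbose = verbose)
  }
  samples <- combine_samples(chains)
  diag <- tryCatch(mcmc_diagnostics(samples), error = function(e) NULL)
  structure(list(samples = samples, hierarchy = h, pcfg = pcfg,
                 priors = priors, mcfg = mcfg,
                 n_stated = samples$n_stated, diagnostics = diag),
            class = "recon_fit")
}
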