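test_that("initial state clips published counts and is reproducible", {
  sc <- single_cell_state(o = 0L, n_stated = 40L)
  expect_identical(sc$state$y[1L, 1L], 0L)

  sc2 <- single_cell_state(o = 5L, n_stated = 3L)
  expect_identical(sc2$state$y[1L, 1L], 3L)

  sim <- simulate_truth(small_cfg(2))
  tabs <- publish_tables(sim$hierarchy, sim$truth, seed = 5)
  tm <- truth_matrices(sim$hierarchy, sim$truth)
  s1 <- init_state(tabs, sim$hierarchy, seed = 9L, n_stated = tm$n_stated)
  s2 <- init_state(tabs, sim$hierarchy, seed = 9L, n_stated = tm$n_stated)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$params, s2$params)
  expect_error(init_state(tabs[tabs$level != "L1", ], sim$hierarchy,
                          n_stated = tm$n_stated), "L1")
})

test_that("a noiseless mechanism pins the chain at the published truth", {
  sim <- simulate_truth(small_cfg(3))
  h <- sim$hierarchy
  tm <- truth_matrices(h, sim$truth)
  noop <- perturb_config(d = 0L, noise_pmf = 1, tau = 0L)
  tabs <- publish_tables(h, sim$truth, noop, seed = 1)
  state <- init_state(tabs, h, seed = 2L, n_stated = tm$n_stated)
  expect_equal(state$y, tm$y, ignore_attr = TRUE)
  set.seed(3)
  state2 <- update_counts(state, noop, mcmc_config(), n_sweeps = 50L)
  expect_identical(state2$y, state$y)
  expect_equal(unname(state2$last_counts["accept"]), 0)
})

test_that("single-cell stationary distribution matches exact enumeration", {
  pcfg <- perturb_config()
  set.seed(21)
  o <- perturb_count(2L, pcfg)  # published value under the mechanism
  sc <- single_cell_state(o = o, n_stated = 5L, p = 0.3, pcfg = pcfg)
  set.seed(22)
  st <- update_counts(sc$state, pcfg, mcmc_config(), n_sweeps = 30000L,
                      trace = TRUE)
  emp <- trace_freq(st$trace, 1L, 5L)
  exact <- single_cell_posterior(o, 5L, 0.3, pcfg)
  expect_lt(total_variation(emp, exact), 0.05)
})

test_that("three-unit joint distribution matches brute-force enumeration", {
  rec <- tiny_records()[1:3, ]
  rec$unit_id <- c("U1", "U2", "U3")
  h <- build_hierarchy(rec)
  pcfg <- perturb_config()
  oL1 <- c(0L, 3L, 4L)
  oS <- 5L
  observed <- rbind(
    data.frame(level = "L1", unit_id = rep(h$fine_ids, 3L),
               age_group = rep(c("age0_9", "age10_14", "age15_19"),
                               each = 3L),
               category = "positive",
               count = c(oL1, rep(0L, 6L)), suppressed_flag = FALSE),
    data.frame(level = "STATE", unit_id = "S",
               age_group = c("age0_9", "age10_14", "age15_19"),
               category = "positive", count = c(oS, 0L, 0L),
               suppressed_flag = FALSE))
  nst <- cbind(age0_9 = rep(3L, 3L), age10_14 = 0L, age15_19 = 0L)
  rownames(nst) <- h$fine_ids
  state <- init_state(observed, h, seed = 4L, n_stated = nst)
  p <- c(0.2, 0.4, 0.6)
  state$cache$eta <- matrix(qlogis(p), 3L, 3L)

  set.seed(23)
  st <- update_counts(state, pcfg, mcmc_config(), n_sweeps = 100000L,
                      trace = TRUE)
  key <- st$trace[, 1L] * 16L + st$trace[, 2L] * 4L + st$trace[, 3L]
  emp <- tabulate(key + 1L, nbins = 64L) / nrow(st$trace)

  grid <- expand.grid(y1 = 0:3, y2 = 0:3, y3 = 0:3)
  lp <- mapply(function(y1, y2, y3) {
    sum(perturbation_loglik(oL1, c(y1, y2, y3), pcfg)) +
      perturbation_loglik(oS, y1 + y2 + y3, pcfg) +
      sum(dbinom(c(y1, y2, y3), 3L, p, log = TRUE))
  }, grid$y1, grid$y2, grid$y3)
  w <- exp(lp - max(lp[is.finite(lp)])); w[!is.finite(lp)] <- 0
  exact <- w / sum(w)
  exact_keyed <- numeric(64L)
  exact_keyed[grid$y1 * 16L + grid$y2 * 4L + grid$y3 + 1L] <- exact
  expect_lt(total_variation(emp, exact_keyed), 0.05)
})

test_that("count proposals never leave [0, n_stated]", {
  sc <- single_cell_state(o = 3L, n_stated = 4L, p = 0.5)
  set.seed(24)
  st <- update_counts(sc$state, sc$pcfg, mcmc_config(count_proposal_sd = 5),
                      n_sweeps = 5000L, trace = TRUE)
  expect_gte(min(st$trace[, 1L]), 0L)
  expect_lte(max(st$trace[, 1L]), 4L)
})

test_that("field updates sample the constrained prior when data are absent", {
  cfg <- sim_config(n_fine = 20L, n_per_l2 = 5L, n_per_l3 = 2L,
                    n_per_l4 = 2L, seed = 6)
  sim <- simulate_truth(cfg)
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 7)
  nst0 <- matrix(0L, h$n, 3L, dimnames = list(h$fine_ids, NULL))
  state <- init_state(tabs, h, seed = 8L, n_stated = nst0)
  state$y <- matrix(0L, h$n, 3L)

  # oracle: sum-to-zero-projected exponential covariance at sigma = 1
  D <- as.matrix(dist(cbind(h$units$centroid_x_km, h$units$centroid_y_km)))
  S <- gp_covariance(D, 1, 50)
  C <- diag(h$n) - matrix(1 / h$n, h$n, h$n)
  S_proj <- C %*% S %*% C

  set.seed(25)
  n_draws <- 4000L
  us <- matrix(NA_real_, n_draws, h$n)
  for (i in seq_len(n_draws)) {
    state <- update_field(state)
    us[i, ] <- state$params$u
  }
  err <- function(m) {
    emp <- crossprod(m) / nrow(m)
    sqrt(sum((emp - S_proj)^2)) / sqrt(sum(S_proj^2))
  }
  expect_lt(err(us), err(us[1:400, , drop = FALSE]))  # error shrinks
  expect_lt(err(us), 0.25)
  expect_lt(abs(mean(diag(crossprod(us) / n_draws)) -
                  mean(diag(S_proj))), 0.15)
})

test_that("a vanishing field scale pins the field at zero", {
  sim <- simulate_truth(small_cfg(10))
  tabs <- publish_tables(sim$hierarchy, sim$truth, seed = 1)
  tm <- truth_matrices(sim$hierarchy, sim$truth)
  state <- init_state(tabs, sim$hierarchy, seed = 2L,
                      n_stated = tm$n_stated)
  state$params$log_sigma_u <- -30
  set.seed(26)
  for (i in 1:20) state <- update_field(state)
  expect_lt(max(abs(state$params$u)), 1e-8)
})

test_that("the field block leaves scalars untouched and gamma sum-to-zero", {
  sim <- simulate_truth(small_cfg(11))
  tabs <- publish_tables(sim$hierarchy, sim$truth, seed = 3)
  tm <- truth_matrices(sim$hierarchy, sim$truth)
  state <- init_state(tabs, sim$hierarchy, seed = 4L,
                      n_stated = tm$n_stated)
  state$params$gfree <- c(0.2, -0.3, 0.1, 0.4)
  before <- state$params
  set.seed(27)
  state <- update_field(state)
  for (nm in c("beta0_young", "beta0_old", "beta_ses", "gfree",
               "log_sigma_u", "log_rho", "logit_w"))
    expect_identical(state$params[[nm]], before[[nm]])
  expect_equal(sum(gamma_full(state$params)), 0)
  expect_false(identical(state$params$u, before$u))
})

test_that("scalar updates recover their priors under a flat likelihood", {
  cfg <- sim_config(n_fine = 20L, n_per_l2 = 5L, n_per_l3 = 2L,
                    n_per_l4 = 2L, seed = 12)
  sim <- simulate_truth(cfg)
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 13)
  nst0 <- matrix(0L, h$n, 3L)
  priors <- prior_spec()
  mcfg <- mcmc_config(n_iter = 100L, n_burn = 50L)
  state <- init_state(tabs, h, seed = 14L, n_stated = nst0)
  set.seed(28)
  n_it <- 8000L
  keep <- matrix(NA_real_, n_it, 3L)
  for (i in seq_len(n_it)) {
    state <- update_scalars(state, priors, mcfg, adapt = i <= 2000L)
    keep[i, ] <- c(state$params$beta0_young, state$params$log_rho,
                   plogis(state$params$logit_w))
  }
  post <- keep[seq(2001L, n_it, by = 24L), ]
  expect_gt(suppressWarnings(
    ks.test(post[, 1L], "pnorm", 0, 2)$p.value), 0.01)
  expect_gt(suppressWarnings(
    ks.test(post[, 2L], "pnorm", log(50), 1)$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(post[, 3L], "punif")$p.value), 0.01)
})

test_that("proposal adaptation runs in burn-in and freezes afterwards", {
  sim <- simulate_truth(small_cfg(13))
  tabs <- publish_tables(sim$hierarchy, sim$truth, seed = 15)
  tm <- truth_matrices(sim$hierarchy, sim$truth)
  mcfg <- mcmc_config(adapt_interval = 5L)
  state <- init_state(tabs, sim$hierarchy, seed = 16L,
                      n_stated = tm$n_stated)
  sd0 <- state$cache$prop_sd
  set.seed(29)
  for (i in 1:10) state <- update_scalars(state, prior_spec(), mcfg,
                                          adapt = TRUE)
  expect_false(identical(state$cache$prop_sd, sd0))
  sd1 <- state$cache$prop_sd
  for (i in 1:10) state <- update_scalars(state, prior_spec(), mcfg,
                                          adapt = FALSE)
  expect_identical(state$cache$prop_sd, sd1)
})

test_that("run_chain stores the requested draws reproducibly", {
  sim <- simulate_truth(small_cfg(14))
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 17)
  tm <- truth_matrices(h, sim$truth)
  mcfg1 <- mcmc_config(n_iter = 31L, n_burn = 30L, thin = 1L, seed = 30L)
  s1 <- run_chain(tabs, h, mcfg = mcfg1, n_stated = tm$n_stated)
  expect_equal(nrow(s1$scalars), 1L)

  mcfg2 <- mcmc_config(n_iter = 300L, n_burn = 100L, thin = 4L, seed = 31L)
  s2 <- run_chain(tabs, h, mcfg = mcfg2, n_stated = tm$n_stated)
  s3 <- run_chain(tabs, h, mcfg = mcfg2, n_stated = tm$n_stated)
  expect_equal(nrow(s2$scalars), 50L)
  expect_identical(s2$scalars, s3$scalars)
  expect_identical(s2$y, s3$y)
  expect_true(all(s2$y >= 0L))
  expect_true(all(sweep(s2$y, c(2, 3), tm$n_stated, "<=")))
})

test_that("denominators fall back to published positives plus negatives", {
  sim <- simulate_truth(small_cfg(15))
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 18)
  state <- init_state(tabs, h, seed = 19L)  # no n_stated supplied
  pos <- tabs[tabs$level == "L1" & tabs$category == "positive", ]
  neg <- tabs[tabs$level == "L1" & tabs$category == "negative", ]
  want <- pmax(matrix(pos$count + neg$count, h$n, 3L),
               matrix(pos$count, h$n, 3L))
  expect_equal(unname(state$data$n_stated), want)
})

test_that("chains mix across restarts on a mid-sized synthetic run", {
  cfg <- sim_config(n_fine = 100L, n_per_l2 = 5L, n_per_l3 = 2L,
                    n_per_l4 = 5L, seed = 16,
                    beta0_young = qlogis(0.01), beta0_old = qlogis(0.02))
  sim <- simulate_truth(cfg)
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 20)
  tm <- truth_matrices(h, sim$truth)
  fit <- fit_reconstruction(tabs, h, n_stated = tm$n_stated,
                            mcfg = mcmc_config(n_iter = 4500L,
                                               n_burn = 1500L, thin = 4L,
                                               n_chains = 2L, seed = 33L))
  dg <- mcmc_diagnostics(fit,
                         params = c("beta0_young", "beta_ses",
                                    "log_sigma_u"))
  expect_true(all(dg$rhat < 1.1))
  # scalar acceptance rates sit in the healthy random-walk window
  acc <- fit$samples$accept$scalars
  expect_true(all(acc > 0.1 & acc < 0.6))
})

test_that("stored draws aggregate coherently to every partition", {
  sim <- simulate_truth(small_cfg(17))
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 21)
  tm <- truth_matrices(h, sim$truth)
  s <- run_chain(tabs, h, mcfg = mcmc_config(n_iter = 200L, n_burn = 100L,
                                             thin = 5L, seed = 34L),
                 n_stated = tm$n_stated)
  for (p in c("L2", "L4", "STATE", "ses_decile", "remoteness")) {
    A <- aggregation_matrix(h, p)
    lab <- censrecon:::partition_labels(h, p)
    ok <- TRUE
    for (d in seq_len(dim(s$y)[1L])) {
      yd <- s$y[d, , ]
      ok <- ok && all(A %*% yd == rowsum(yd, lab)[rownames(A), ,
                                                  drop = FALSE])
    }
    expect_true(ok)
  }
})

test_that("diagnostics match white-noise, AR(1) and degenerate oracles", {
  set.seed(35)
  d <- data.frame(chain = rep(1:2, each = 1000L), x = rnorm(2000L))
  dg <- mcmc_diagnostics(d, "x")
  expect_gt(dg$rhat, 0.99); expect_lt(dg$rhat, 1.01)

  r <- 0.6; n <- 4000L
  x <- numeric(n); x[1L] <- rnorm(1L)
  for (i in 2:n) x[i] <- r * x[i - 1L] + sqrt(1 - r^2) * rnorm(1L)
  dg2 <- mcmc_diagnostics(data.frame(chain = 1L, x = x), "x")
  oracle <- n * (1 - r) / (1 + r)
  expect_lt(abs(dg2$ess - oracle) / oracle, 0.2)

  d3 <- data.frame(chain = rep(1:2, each = 300L), x = 1)
  dg3 <- mcmc_diagnostics(d3, "x")
  expect_identical(dg3$flag, "constant")
  expect_true(is.na(dg3$rhat))

  expect_error(mcmc_diagnostics(data.frame(chain = 1L, x = rnorm(50L))),
               "200 draws")
})
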