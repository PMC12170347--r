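# Fixtures are built in code: small hierarchies, single-cell sampler
# systems, and enumeration oracles shared across test files.

tiny_records <- function() {
  data.frame(
    unit_id = c("U1", "U2", "U3", "U4"),
    l2_id = c("A", "A", "B", "B"),
    l3_id = "C",
    l4_id = "D",
    state_id = "S",
    ses_decile = c(1L, 1L, 5L, 5L),
    remoteness = c("major_city", "major_city", "remote", "remote"),
    centroid_x_km = c(0, 1, 10, 11),
    centroid_y_km = c(0, 1, 10, 11),
    pop_age0_9 = 50L, pop_age10_14 = 40L, pop_age15_19 = 60L,
    stringsAsFactors = FALSE)
}

# a quick 40-unit synthetic world (divides 40 = 2 x 2 x 5 x 2)
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_fine = 40L, n_per_l2 = 2L, n_per_l3 = 2L, n_per_l4 = 5L,
         pop_range = c(20L, 60L), seed = seed),
    list(...))
  do.call(sim_config, args)
}

# single published cell: one fine unit, one active age group, observed at
# L1 only; model probability pinned to p by overriding the cached linear
# predictor
single_cell_state <- function(o, n_stated = 5L, p = 0.3,
                              pcfg = perturb_config()) {
  rec <- tiny_records()[1L, ]
  h <- build_hierarchy(rec)
  observed <- data.frame(level = "L1", unit_id = "U1",
                         age_group = c("age0_9", "age10_14", "age15_19"),
                         category = "positive",
                         count = c(o, 0L, 0L),
                         suppressed_flag = FALSE,
                         stringsAsFactors = FALSE)
  nst <- matrix(c(n_stated, 0L, 0L), 1L, 3L,
                dimnames = list("U1", c("age0_9", "age10_14", "age15_19")))
  state <- init_state(observed, h, seed = 1L, n_stated = nst)
  state$cache$eta <- matrix(qlogis(p), 1L, 3L)
  list(state = state, h = h, pcfg = pcfg, nst = nst, o = o, p = p)
}

# exact single-cell posterior over y = 0..n by enumeration
single_cell_posterior <- function(o, n, p, pcfg = perturb_config()) {
  lp <- perturbation_loglik(rep(o, n + 1L), 0:n, pcfg) +
    dbinom(0:n, n, p, log = TRUE)
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(lp)] <- 0
  w / sum(w)
}

# empirical distribution of a traced cell
trace_freq <- function(tr, col, n) {
  tabulate(tr[, col] + 1L, nbins = n + 1L) / nrow(tr)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
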