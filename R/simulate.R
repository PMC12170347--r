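#' Synthetic-census generator configuration
#'
#' Defines the generative conditions for the synthetic ground truth: a
#' square planar domain with `n_fine` fine units nested regularly into
#' coarser levels, a binomial response layer over stated respondents, and a
#' prevalence surface generated by the same logit model the sampler fits
#' (intercepts per age model, linear socioeconomic gradient, five
#' sum-to-zero remoteness effects, exponential-covariance Gaussian field,
#' logit-scale mixture for the middle age group).
#'
#' Defaults emulate the scale of the real analysis: 400 fine units with
#' 30-120 residents per age group (fine census units hold roughly 200-800
#' people across all ages), intercepts anchored at prevalences of 1.8 and
#' 5.2 per 1000 for the youngest and oldest age groups, a mild gradient
#' towards disadvantage (`beta_ses < 0`; decile 1 is most disadvantaged),
#' remoteness effects increasing towards very remote, and a mixing weight of
#' 0.9 favouring the youngest-group model.
#'
#' @param n_fine Number of fine units.
#' @param n_per_l2 Fine units per L2 unit.
#' @param n_per_l3 L2 units per L3 unit.
#' @param n_per_l4 L3 units per L4 unit.
#' @param domain_size_km Side of the square domain (km).
#' @param pop_range Integer range of per-age-group unit populations.
#' @param beta0_young,beta0_old Intercepts (logit scale).
#' @param beta_ses Socioeconomic slope per decile unit.
#' @param remoteness_effects Five effects, must sum to zero.
#' @param field_sd,field_range Field standard deviation and range (km);
#'   `field_sd = 0` switches the field off.
#' @param mix_w Mixing weight in (0, 1).
#' @param response_rate_range Per-unit stated-response rate interval.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fine = 400L, n_per_l2 = 5L, n_per_l3 = 4L,
                       n_per_l4 = 4L, domain_size_km = 500,
                       pop_range = c(30L, 120L),
                       beta0_young = qlogis(0.0018),
                       beta0_old = qlogis(0.0052),
                       beta_ses = -0.05,
                       remoteness_effects = c(-0.2, -0.1, 0, 0.1, 0.2),
                       field_sd = 0.3, field_range = 50, mix_w = 0.9,
                       response_rate_range = c(0.88, 0.95), seed = 1L) {
  stopifnot(n_fine >= 1L, domain_size_km > 0,
            length(pop_range) == 2L, pop_range[1L] >= 1L,
            pop_range[1L] <= pop_range[2L],
            length(remoteness_effects) == 5L,
            field_sd >= 0, field_range > 0,
            mix_w > 0, mix_w < 1,
            length(response_rate_range) == 2L,
            response_rate_range[1L] > 0, response_rate_range[2L] <= 1,
            response_rate_range[1L] <= response_rate_range[2L])
  if (abs(sum(remoteness_effects)) > 1e-10)
    stop("remoteness_effects must sum to zero")
  structure(list(n_fine = as.integer(n_fine),
                 n_per_l2 = as.integer(n_per_l2),
                 n_per_l3 = as.integer(n_per_l3),
                 n_per_l4 = as.integer(n_per_l4),
                 domain_size_km = domain_size_km,
                 pop_range = as.integer(pop_range),
                 beta0_young = beta0_young, beta0_old = beta0_old,
                 beta_ses = beta_ses,
                 remoteness_effects = remoteness_effects,
                 field_sd = field_sd, field_range = field_range,
                 mix_w = mix_w,
                 response_rate_range = response_rate_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# split ranked values into ng consecutive equal-size groups (internal)
rank_blocks <- function(v, ng) {
  ceiling(ng * rank(v, ties.method = "first") / length(v))
}

#' Simulate a synthetic census ground truth
#'
#' Scatters fine-unit centroids uniformly on the square, builds the nested
#' hierarchy by recursive spatial slicing (so coarse units are spatially
#' coherent), assigns socioeconomic deciles with L3-level autocorrelation
#' and remoteness categories as distance-from-centre quintiles of whole L3
#' blocks, draws the field from a zero-mean Gaussian process with
#' exponential covariance, and generates stated-response denominators and
#' case counts binomially.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `hierarchy` (a `census_hierarchy`) and `truth`
#'   (long data frame: `unit_id`, `age_group`, `N`, `n_stated`, `y`, `p`,
#'   `u`).
#' @export
simulate_truth <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_fine
  per_l2 <- cfg$n_per_l2
  n_l2 <- n / per_l2
  n_l3 <- n_l2 / cfg$n_per_l3
  n_l4 <- n_l3 / cfg$n_per_l4
  if (n_l2 != round(n_l2) || n_l3 != round(n_l3) || n_l4 != round(n_l4))
    stop("n_fine does not divide into the requested nesting")

  x <- runif(n, 0, cfg$domain_size_km)
  y_c <- runif(n, 0, cfg$domain_size_km)

  # recursive spatial slicing: x-slabs for L4, y within L4 for L3, x within
  # L3 for L2 -- gives contiguous blocks at every level
  l4 <- rank_blocks(x, n_l4)
  l3 <- integer(n); l2 <- integer(n)
  for (k in seq_len(n_l4)) {
    idx <- which(l4 == k)
    l3[idx] <- (k - 1L) * cfg$n_per_l4 + rank_blocks(y_c[idx], cfg$n_per_l4)
  }
  for (k in seq_len(n_l3)) {
    idx <- which(l3 == k)
    l2[idx] <- (k - 1L) * cfg$n_per_l3 + rank_blocks(x[idx], cfg$n_per_l3)
  }

  # SES deciles: L3 base value plus unit-level jitter, ranked into deciles
  ses_base <- rnorm(n_l3)
  ses_val <- ses_base[l3] + 0.5 * rnorm(n)
  decile <- rank_blocks(ses_val, 10L)

  # remoteness: whole-L3 blocks classified by distance from domain centre
  ctr <- cfg$domain_size_km / 2
  d_ctr <- sqrt((x - ctr)^2 + (y_c - ctr)^2)
  l3_d <- vapply(seq_len(n_l3), function(k) mean(d_ctr[l3 == k]), 0)
  rem <- REMOTENESS_LEVELS[rank_blocks(l3_d, 5L)[l3]]

  wd <- floor(log10(n)) + 1L
  records <- data.frame(
    unit_id = sprintf("U%0*d", wd, seq_len(n)),
    l2_id = sprintf("L2_%03d", l2),
    l3_id = sprintf("L3_%03d", l3),
    l4_id = sprintf("L4_%03d", l4),
    state_id = "S1",
    ses_decile = decile,
    remoteness = rem,
    centroid_x_km = x, centroid_y_km = y_c,
    stringsAsFactors = FALSE)
  for (a in AGE_GROUPS)
    records[[paste0("pop_", a)]] <-
      sample(cfg$pop_range[1L]:cfg$pop_range[2L], n, replace = TRUE)
  h <- build_hierarchy(records)  # sorts by unit_id (same order by padding)

  # spatial field under exponential covariance
  if (cfg$field_sd > 0) {
    S <- gp_covariance(centroid_distances(h), cfg$field_sd, cfg$field_range)
    u <- drop(crossprod(chol(S), rnorm(h$n)))
  } else u <- rep(0, h$n)

  pars <- model_params(beta0_young = cfg$beta0_young,
                       beta0_old = cfg$beta0_old,
                       beta_ses = cfg$beta_ses,
                       gfree = cfg$remoteness_effects[1:4],
                       logit_w = qlogis(cfg$mix_w), u = u)
  eta <- compute_eta(pars, h)
  p <- plogis(eta)

  rate <- runif(h$n, cfg$response_rate_range[1L], cfg$response_rate_range[2L])
  N <- h$pop
  n_stated <- matrix(rbinom(length(N), N, rep(rate, 3L)), h$n, 3L,
                     dimnames = dimnames(N))
  yy <- matrix(rbinom(length(N), n_stated, p), h$n, 3L,
               dimnames = dimnames(N))

  truth <- data.frame(
    unit_id = rep(h$fine_ids, 3L),
    age_group = rep(AGE_GROUPS, each = h$n),
    N = as.vector(N), n_stated = as.vector(n_stated), y = as.vector(yy),
    p = as.vector(p), u = rep(u, 3L), stringsAsFactors = FALSE)
  list(hierarchy = h, truth = truth)
}

#' Truth table in matrix form
#'
#' Reshapes the long truth data frame into fine-units-by-age-groups matrices
#' aligned with `h$fine_ids`, the form the sampler and the tests work with.
#'
#' @param h A `census_hierarchy`.
#' @param truth Truth data frame from [simulate_truth()].
#' @return List of matrices `N`, `n_stated`, `y` (integer) and `p`.
#' @export
truth_matrices <- function(h, truth) {
  out <- list()
  for (v in c("N", "n_stated", "y", "p")) {
    m <- matrix(NA_real_, h$n, 3L, dimnames = list(h$fine_ids, AGE_GROUPS))
    m[cbind(match(truth$unit_id, h$fine_ids),
            match(truth$age_group, AGE_GROUPS))] <- truth[[v]]
    if (v != "p") storage.mode(m) <- "integer"
    out[[v]] <- m
  }
  out
}

#' Publish synthetic tables through the privacy mechanism
#'
#' Aggregates the true counts of all three response categories (positive,
#' negative, not stated) to every spatial level and both covariate margins,
#' and passes each cell independently through [perturb_count()].
#'
#' @param h A `census_hierarchy`.
#' @param truth Truth data frame from [simulate_truth()].
#' @param pcfg A [perturb_config()].
#' @param seed Optional integer seed (`NULL` keeps the current RNG stream).
#' @return Long data frame: `level`, `unit_id`, `age_group`, `category`,
#'   `count`, `suppressed_flag` (always `FALSE`: suppression is
#'   indistinguishable from a published zero, matching the mechanism).
#' @export
publish_tables <- function(h, truth, pcfg = perturb_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- truth_matrices(h, truth)
  cat_counts <- list(positive = tm$y, negative = tm$n_stated - tm$y,
                     not_stated = tm$N - tm$n_stated)
  parts <- c(names(SPATIAL_LEVELS), MARGIN_PARTITIONS)
  out <- vector("list", length(parts) * 3L)
  k <- 0L
  for (p in parts) {
    A <- aggregation_matrix(h, p)
    for (cc in CATEGORIES) {
      agg <- A %*% cat_counts[[cc]]
      k <- k + 1L
      out[[k]] <- data.frame(
        level = p,
        unit_id = rep(rownames(A), 3L),
        age_group = rep(AGE_GROUPS, each = nrow(A)),
        category = cc,
        count = perturb_count(as.vector(agg), pcfg),
        suppressed_flag = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# default external (non-nested) partition: offset pairing of L2 units so
# external areas straddle L3 boundaries, like real administrative areas
#' Default external partition for register comparison
#'
#' Groups L2 units into external areas of `size` consecutive L2 units with
#' an offset of one, so the external partition is not nested in the L3/L4
#' levels (mimicking administrative areas that cut across the statistical
#' hierarchy).
#'
#' @param h A `census_hierarchy`.
#' @param size L2 units per external area.
#' @return Data frame with columns `fine_id`, `external_id`.
#' @export
default_external_map <- function(h, size = 2L) {
  l2 <- sort(unique(h$units$l2_id), method = "radix")
  grp <- 1L + ((seq_along(l2)) %/% size)  # offset: first area has size-1
  ext <- sprintf("EXT_%03d", grp)
  data.frame(fine_id = h$fine_ids,
             external_id = ext[match(h$units$l2_id, l2)],
             stringsAsFactors = FALSE)
}

#' Emulate disease-register publications
#'
#' Produces two register-style tables from the synthetic truth: a
#' hospital-register table (binomial thinning of true cases at a capture
#' probability, aggregated to L3, youngest and middle age groups), and a
#' public community-register table (thinned counts aggregated to an
#' external partition for the age groups 0-9 and 10-19, then censored below
#' 20 and rounded to the nearest ten via [ndss_censor_round()]).
#'
#' @param h A `census_hierarchy`.
#' @param truth Truth data frame from [simulate_truth()].
#' @param capture_hospital,capture_community Capture probabilities in
#'   (0, 1].
#' @param external_map Correspondence data frame (`fine_id`,
#'   `external_id`); defaults to [default_external_map()].
#' @param seed Optional integer seed.
#' @return List of data frames `hospital` (`unit_id`, `age_group`, `count`)
#'   and `community` (`unit_id`, `age_group`, `count`, `suppressed`), where
#'   suppressed community counts are reported as `NA` with
#'   `suppressed = TRUE`.
#' @export
emulate_registers <- function(h, truth, capture_hospital = 0.999,
                              capture_community = 0.85,
                              external_map = default_external_map(h),
                              seed = NULL) {
  if (any(c(capture_hospital, capture_community) <= 0) ||
      any(c(capture_hospital, capture_community) > 1))
    stop("capture probabilities must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  tm <- truth_matrices(h, truth)

  thin <- function(m, pr) {
    out <- matrix(rbinom(length(m), m, pr), nrow(m), ncol(m),
                  dimnames = dimnames(m))
    storage.mode(out) <- "integer"
    out
  }
  yh <- thin(tm$y, capture_hospital)
  A3 <- aggregation_matrix(h, "L3")
  hosp <- data.frame(
    unit_id = rep(rownames(A3), 2L),
    age_group = rep(AGE_GROUPS[1:2], each = nrow(A3)),
    count = as.vector(A3 %*% yh[, 1:2]),
    stringsAsFactors = FALSE)

  yc <- thin(tm$y, capture_community)
  Ae <- correspondence_map(h, external_map)
  raw <- cbind(age0_9 = as.vector(Ae %*% yc[, 1L]),
               age10_19 = as.vector(Ae %*% (yc[, 2L] + yc[, 3L])))
  rep_val <- ndss_censor_round(as.vector(raw))
  comm <- data.frame(
    unit_id = rep(rownames(Ae), 2L),
    age_group = rep(c("age0_9", "age10_19"), each = nrow(Ae)),
    count = rep_val,
    suppressed = is.na(rep_val),
    stringsAsFactors = FALSE)
  list(hospital = hosp, community = comm)
}
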