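# build a minimal recon_samples object from explicit count draws
fake_samples <- function(y, nst, fine_ids = NULL) {
  n <- dim(y)[2L]
  if (is.null(fine_ids)) fine_ids <- sprintf("U%03d", seq_len(n))
  dimnames(nst) <- list(fine_ids, c("age0_9", "age10_14", "age15_19"))
  structure(list(scalars = data.frame(chain = 1L,
                                      iter = seq_len(dim(y)[1L])),
                 u = matrix(0, dim(y)[1L], n), y = y,
                 chain = rep(1L, dim(y)[1L]), fine_ids = fine_ids,
                 age_groups = c("age0_9", "age10_14", "age15_19"),
                 n_stated = nst),
            class = "recon_samples")
}

test_that("constant draws give exact degenerate summaries", {
  y <- array(0L, c(50L, 1L, 3L)); y[, 1L, 1L] <- 2L
  nst <- matrix(c(1000L, 0L, 0L), 1L)
  ps <- prevalence_summary(fake_samples(y, nst))
  row <- ps[ps$age_product == "age0_14", ]
  expect_equal(row$median, 0.002)
  expect_equal(row$mean, 0.002)
  expect_equal(row$sd, 0)
  expect_identical(row$confidence_class, "higher")
})

test_that("the 25% dispersion rule separates confidence classes", {
  # sd/median = 0.30: draws split evenly between 70 and 130 cases
  y <- array(0L, c(1000L, 1L, 3L))
  y[, 1L, 1L] <- rep(c(70L, 130L), 500L)
  nst <- matrix(c(1000L, 0L, 0L), 1L)
  ps <- prevalence_summary(fake_samples(y, nst))
  row <- ps[ps$age_product == "age0_14", ]
  expect_gt(row$sd / row$median, 0.25)
  expect_identical(row$confidence_class, "lower")
})

test_that("summary quantiles match the order-statistics oracle", {
  set.seed(40)
  y <- array(rbinom(1000L, 50L, 0.3), c(1000L, 1L, 3L))
  nst <- matrix(c(50L, 50L, 50L), 1L)
  ps <- prevalence_summary(fake_samples(y, nst),
                           age_grouping = list(age15_19 = "age15_19"))
  prev <- sort(y[, 1L, 3L] / 50)
  oracle_q <- function(p) {
    hh <- (length(prev) - 1) * p + 1
    lo <- floor(hh)
    prev[lo] + (hh - lo) * (prev[min(lo + 1, length(prev))] - prev[lo])
  }
  expect_equal(ps$q2.5, oracle_q(0.025), tolerance = 1e-12)
  expect_equal(ps$q97.5, oracle_q(0.975), tolerance = 1e-12)
  expect_equal(ps$median, oracle_q(0.5), tolerance = 1e-12)
})

test_that("zero denominators are flagged and excluded from national summaries",
{
  y <- array(2L, c(10L, 2L, 3L))
  y[, 2L, ] <- 0L
  nst <- rbind(c(1000L, 1000L, 1000L), c(0L, 0L, 0L))
  ps <- prevalence_summary(fake_samples(y, nst))
  expect_identical(ps$flagged[ps$age_product == "age0_14"], c(FALSE, TRUE))
  nat <- national_summary(ps, "age0_14")
  expect_equal(unname(nat["median"]), 2)
})

test_that("national summary interpolates quartiles and ignores unit order", {
  y <- array(0L, c(10L, 3L, 3L))
  for (i in 1:3) y[, i, 1L] <- i  # per-unit prevalences 1,2,3 per 1000
  nst <- matrix(1000L, 3L, 3L); nst[, 2:3] <- c(0L, 0L, 0L)
  ps <- prevalence_summary(fake_samples(y, nst),
                           age_grouping = list(age0_14 = "age0_9"))
  nat <- national_summary(ps, "age0_14")
  expect_equal(unname(nat), c(2, 1.5, 2.5))
  perm <- ps[c(3, 1, 2), ]
  expect_equal(national_summary(perm, "age0_14"), nat)
})

test_that("confidence classification is scale invariant", {
  set.seed(41)
  y <- array(rbinom(300L, 40L, 0.2), c(100L, 1L, 3L))
  nst <- matrix(200L, 1L, 3L)
  cls1 <- prevalence_summary(fake_samples(y, nst))$confidence_class
  cls10 <- prevalence_summary(fake_samples(y * 10L, nst * 10L))$confidence_class
  expect_identical(cls1, cls10)
})

test_that("posterior aggregation matches per-draw brute force", {
  sim <- simulate_truth(small_cfg(18, beta0_young = qlogis(0.05)))
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 22)
  tm <- truth_matrices(h, sim$truth)
  s <- run_chain(tabs, h, mcfg = mcmc_config(n_iter = 200L, n_burn = 100L,
                                             thin = 4L, seed = 36L),
                 n_stated = tm$n_stated)
  A <- aggregation_matrix(h, "L3")
  agg <- aggregate_posterior(s, A)
  expect_identical(agg$unit_id, rownames(A))
  # brute-force oracle: per-draw dictionary grouping, then quantiles
  lab <- censrecon:::partition_labels(h, "L3")
  per_draw <- t(apply(s$y, 1L, function(m) {
    rowsum(rowSums(matrix(m, ncol = 3L)), lab)[rownames(A), 1L]
  }))
  expect_equal(agg$median,
               as.integer(round(apply(per_draw, 2L, median))))
  expect_equal(agg$cri_lo,
               as.integer(floor(apply(per_draw, 2L, quantile, 0.025))))
  expect_equal(agg$cri_hi,
               as.integer(ceiling(apply(per_draw, 2L, quantile, 0.975))))

  # identity aggregation reproduces fine-level summaries
  ident <- correspondence_map(h, data.frame(fine_id = h$fine_ids,
                                            external_id = h$fine_ids))
  af <- aggregate_posterior(s, ident, ages = "age0_9")
  qf <- apply(s$y[, , 1L], 2L, quantile, 0.5)
  expect_equal(af$median, as.integer(round(qf)))

  # single all-ones row gives the national count distribution
  one <- correspondence_map(h, data.frame(fine_id = h$fine_ids,
                                          external_id = "ALL"))
  a1 <- aggregate_posterior(s, one)
  tot <- apply(s$y, 1L, sum)
  expect_equal(a1$median, as.integer(round(median(tot))))
  expect_error(aggregate_posterior(s, A[, 1:3]), "match")
})

test_that("register comparison flags outliers and computes correlations", {
  agg <- data.frame(unit_id = c("A", "B", "C", "D"),
                    median = c(10L, 20L, 30L, 40L),
                    cri_lo = c(5L, 15L, 25L, 35L),
                    cri_hi = c(15L, 25L, 35L, 45L))
  reg_eq <- data.frame(unit_id = agg$unit_id, count = agg$median,
                       suppressed = FALSE)
  cmp <- compare_register(agg, reg_eq)
  expect_equal(cmp$correlation, 1)
  expect_equal(cmp$n_outliers, 0L)

  reg <- data.frame(unit_id = agg$unit_id, count = c(50L, 20L, 30L, NA),
                    suppressed = c(FALSE, FALSE, FALSE, TRUE))
  cmp2 <- compare_register(agg, reg)
  expect_identical(cmp2$table$outlier,
                   c(TRUE, FALSE, FALSE, FALSE))  # suppressed never flagged

  few <- compare_register(agg[1:3, ], data.frame(
    unit_id = c("A", "B", "C"), count = c(10L, NA, NA),
    suppressed = c(FALSE, TRUE, TRUE)))
  expect_true(is.na(few$correlation))
})

test_that("pearson correlation matches a hand-rolled oracle", {
  set.seed(42)
  x <- rpois(20L, 30); z <- x + rpois(20L, 5)
  agg <- data.frame(unit_id = sprintf("U%02d", 1:20), median = as.integer(x),
                    cri_lo = 0L, cri_hi = 1000L)
  cmp <- compare_register(agg, data.frame(unit_id = agg$unit_id,
                                          count = as.integer(z)))
  oracle <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  expect_equal(cmp$correlation, oracle, tolerance = 1e-12)
})

test_that("ratio statistics reproduce simple identities and invariances", {
  a <- c(x = 10, y = 20)
  expect_equal(ratio_statistics(a, a), 100)
  expect_equal(ratio_statistics(c(g = 384), c(g = 498), digits = 0), 77)
  set.seed(43)
  b <- c(x = 7, y = 31, z = 4)
  r1 <- ratio_statistics(a, b)
  r2 <- ratio_statistics(a * 3.7, b * 3.7)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(ratio_statistics(a, c(q = 5)), "shared labels")
  expect_error(ratio_statistics(a, c(x = 0, y = 0)), "zero")
  expect_equal(ratio_statistics(a, b, exclusions = "y"),
               100 * 10 / 7)
})

test_that("model-based prevalence tracks the generating surface", {
  sim <- simulate_truth(small_cfg(19))
  h <- sim$hierarchy
  tabs <- publish_tables(h, sim$truth, seed = 23)
  tm <- truth_matrices(h, sim$truth)
  fit <- fit_reconstruction(tabs, h, n_stated = tm$n_stated,
                            mcfg = mcmc_config(n_iter = 600L, n_burn = 300L,
                                               thin = 3L, n_chains = 1L,
                                               seed = 37L))
  ps <- prevalence_summary(fit, type = "model")
  expect_true(all(ps$mean > 0 & ps$mean < 1))
  expect_false(any(ps$flagged))
  # smoothed estimates live at the prevalence scale of the generator
  nat <- national_summary(ps, "age15_19")
  expect_gt(unname(nat["median"]), 1)
  expect_lt(unname(nat["median"]), 25)
})
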