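# per-draw model prevalence expit(eta) for every unit and age group
# (internal): returns a draws x units x 3 array
model_prevalence_draws <- function(samples, h) {
  sc <- samples$scalars
  nd <- nrow(sc)
  x_ses <- h$units$ses_decile - 5.5
  rem_idx <- match(h$units$remoteness, REMOTENESS_LEVELS)
  gmat <- as.matrix(sc[paste0("gamma", 1:5)])
  off <- outer(sc$beta_ses, x_ses) + gmat[, rem_idx, drop = FALSE] +
    samples$u
  eta_y <- sc$beta0_young + off
  eta_o <- sc$beta0_old + off
  eta_m <- sc$w * eta_y + (1 - sc$w) * eta_o
  out <- array(NA_real_, c(nd, h$n, 3L))
  out[, , 1L] <- plogis(eta_y)
  out[, , 2L] <- plogis(eta_m)
  out[, , 3L] <- plogis(eta_o)
  out
}

#' Per-unit posterior prevalence summaries with confidence classes
#'
#' For every stored draw, the per-unit prevalence of an age product is the
#' grouped case count divided by the grouped stated-response denominator;
#' summaries are empirical moments and quantiles (linear interpolation) over
#' draws.  A unit-product is classified `"higher"` confidence when the
#' posterior standard deviation is below 25% of the posterior median
#' prevalence, `"lower"` otherwise.  Units with a zero grouped denominator
#' are flagged and excluded from national summaries.
#'
#' Two prevalence definitions are available.  `type = "count"` (the
#' reconstruction summary) uses the latent count draws directly; its per-unit
#' medians are dominated by the discreteness of small counts.  `type =
#' "model"` evaluates the fitted smoothing model `expit(eta)` per draw (the
#' small-area estimate shown on maps), combining the two youngest age groups
#' by their stated-response weights.
#'
#' @param samples A `recon_samples` or `recon_fit` (required for
#'   `type = "model"` unless `hierarchy` is given).
#' @param denominators Stated-response denominators (fine units x 3); by
#'   default the ones stored with the samples.
#' @param age_grouping Named list mapping product names to age-group
#'   subsets; the default maps the two youngest groups to `age0_14` and
#'   keeps `age15_19`.
#' @param type Prevalence definition (see above).
#' @param hierarchy A `census_hierarchy`, needed for `type = "model"` when
#'   `samples` is not a `recon_fit`.
#' @return Data frame of class `prevalence_summary`: `unit_id`,
#'   `age_product`, `mean`, `median`, `sd`, `q2.5`, `q97.5` (per-1
#'   proportions), `confidence_class`, `flagged`.
#' @export
prevalence_summary <- function(samples, denominators = NULL,
                               age_grouping = list(
                                 age0_14 = c("age0_9", "age10_14"),
                                 age15_19 = "age15_19"),
                               type = c("count", "model"),
                               hierarchy = NULL) {
  type <- match.arg(type)
  if (inherits(samples, "recon_fit")) {
    hierarchy <- samples$hierarchy
    samples <- samples$samples
  }
  if (is.null(denominators)) denominators <- samples$n_stated
  stopifnot(dim(samples$y)[1L] >= 1L)
  p_model <- NULL
  if (type == "model") {
    if (is.null(hierarchy))
      stop("type = 'model' needs a recon_fit or an explicit hierarchy")
    p_model <- model_prevalence_draws(samples, hierarchy)
  }
  out <- list()
  for (prod in names(age_grouping)) {
    ages <- match(age_grouping[[prod]], samples$age_groups)
    if (anyNA(ages)) stop("unknown age group in age_grouping")
    den <- rowSums(denominators[, ages, drop = FALSE])
    flagged <- den == 0L
    if (type == "model") {
      wts <- denominators[, ages, drop = FALSE]
      bad <- rowSums(wts) == 0L
      wts[bad, ] <- 1L  # equal weights where no respondents
      wts <- wts / rowSums(wts)
      prev <- 0
      for (k in seq_along(ages))
        prev <- prev + sweep(p_model[, , ages[k]], 2L, wts[, k], "*")
      flagged <- rep(FALSE, length(den))  # model prevalence always defined
    } else {
      num <- apply(samples$y[, , ages, drop = FALSE], c(1L, 2L), sum)
      prev <- sweep(num, 2L, pmax(den, 1L), "/")  # draws x units
    }
    qs <- apply(prev, 2L, quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE)
    out[[prod]] <- data.frame(
      unit_id = samples$fine_ids,
      age_product = prod,
      mean = colMeans(prev),
      median = qs[2L, ],
      sd = apply(prev, 2L, sd),
      q2.5 = qs[1L, ],
      q97.5 = qs[3L, ],
      stringsAsFactors = FALSE)
    out[[prod]]$confidence_class <-
      ifelse(out[[prod]]$sd < 0.25 * out[[prod]]$median, "higher", "lower")
    out[[prod]]$flagged <- flagged
    out[[prod]][flagged, c("mean", "median", "sd", "q2.5", "q97.5")] <- NA
    out[[prod]]$confidence_class[flagged] <- NA
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("prevalence_summary", "data.frame")
  res
}

#' National median and interquartile range of small-area prevalence
#'
#' Median and IQR, across fine units, of the per-unit posterior median
#' prevalence of one age product, reported per 1000 population.
#'
#' @param ps A [prevalence_summary()].
#' @param age_product Which product to summarise.
#' @return Named vector `c(median, q25, q75)`, per 1000.
#' @export
national_summary <- function(ps, age_product = "age0_14") {
  x <- ps$median[ps$age_product == age_product & !ps$flagged]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no unflagged units for ", age_product)
  1000 * c(median = median(x),
           q25 = unname(quantile(x, 0.25)),
           q75 = unname(quantile(x, 0.75)))
}

#' Posterior coarse-level count summaries
#'
#' Aggregates every stored draw of the latent fine counts through an
#' aggregation matrix (exact integer sums per draw) and summarises: posterior
#' median rounded to integer, and the 95% credible interval as
#' `[floor(q2.5), ceiling(q97.5)]`.
#'
#' @param samples A `recon_samples` or `recon_fit`.
#' @param agg An [aggregation_matrix()] or [correspondence_map()] whose
#'   columns match the samples' fine-unit ordering.
#' @param ages Age groups (names or indices) to sum before aggregating;
#'   default all three.
#' @return Data frame: `unit_id`, `median`, `cri_lo`, `cri_hi`.
#' @export
aggregate_posterior <- function(samples, agg, ages = NULL) {
  if (inherits(samples, "recon_fit")) samples <- samples$samples
  if (ncol(agg) != dim(samples$y)[2L])
    stop("aggregation matrix columns do not match the fine-unit count")
  if (!is.null(colnames(agg)) &&
      !identical(colnames(agg), samples$fine_ids))
    stop("aggregation matrix column order does not match fine_ids")
  if (is.null(ages)) ages <- seq_len(dim(samples$y)[3L])
  if (is.character(ages)) ages <- match(ages, samples$age_groups)
  fine <- apply(samples$y[, , ages, drop = FALSE], c(1L, 2L), sum)
  coarse <- fine %*% t(unclass(agg))  # draws x coarse units
  qs <- apply(coarse, 2L, quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  data.frame(unit_id = rownames(agg),
             median = as.integer(round(qs[2L, ])),
             cri_lo = as.integer(floor(qs[1L, ])),
             cri_hi = as.integer(ceiling(qs[3L, ])),
             stringsAsFactors = FALSE)
}

#' Compare posterior count summaries against a register table
#'
#' Joins posterior coarse-unit summaries with register counts, flags
#' outliers (register value outside the 95% credible interval; never flagged
#' for suppressed register entries), and computes the Pearson correlation
#' between register counts and posterior medians over non-suppressed units
#' (and, when supplied, between register counts and raw published counts).
#'
#' @param agg_summary Output of [aggregate_posterior()].
#' @param register Data frame with `unit_id`, `count`, and optionally
#'   `suppressed` (missing counts are treated as suppressed).
#' @param raw_counts Optional named vector of raw published counts per unit
#'   for the secondary correlation.
#' @return List of class `register_comparison`: `table` (per-unit
#'   comparison), `correlation`, `correlation_raw`, `n_outliers`, `n_units`.
#' @export
compare_register <- function(agg_summary, register, raw_counts = NULL) {
  m <- merge(agg_summary, register[c("unit_id", "count",
                                     intersect("suppressed",
                                               names(register)))],
             by = "unit_id", all.x = TRUE)
  names(m)[names(m) == "count"] <- "register"
  if (!"suppressed" %in% names(m)) m$suppressed <- FALSE
  m$suppressed <- m$suppressed | is.na(m$register)
  m$outlier <- !m$suppressed &
    (m$register < m$cri_lo | m$register > m$cri_hi)
  ok <- !m$suppressed
  corr <- if (sum(ok) >= 3L) cor(m$register[ok], m$median[ok]) else NA_real_
  corr_raw <- NA_real_
  if (!is.null(raw_counts)) {
    rv <- raw_counts[m$unit_id]
    if (sum(ok & !is.na(rv)) >= 3L)
      corr_raw <- cor(m$register[ok & !is.na(rv)], rv[ok & !is.na(rv)])
  }
  structure(list(table = m, correlation = corr, correlation_raw = corr_raw,
                 n_outliers = sum(m$outlier), n_units = nrow(m)),
            class = "register_comparison")
}

#' @export
print.register_comparison <- function(x, ...) {
  cat("Register comparison over", x$n_units, "units:",
      x$n_outliers, "outlier(s) outside the 95% CrI",
      sprintf("(%.1f%%)", 100 * x$n_outliers / max(x$n_units, 1)), "\n")
  if (!is.na(x$correlation))
    cat("Pearson correlation (register vs posterior median):",
        round(x$correlation, 3), "\n")
  if (!is.na(x$correlation_raw))
    cat("Pearson correlation (register vs raw published):",
        round(x$correlation_raw, 3), "\n")
  invisible(x)
}

#' Ratio of two labelled count tables, as a percentage
#'
#' `100 * sum(a) / sum(b)` over the labels shared by both tables after
#' removing `exclusions` (the form of summary statements like "the overall
#' total from one source is X% of that from the other, excluding region Z").
#'
#' @param table_a,table_b Named numeric vectors of counts.
#' @param exclusions Labels to drop before summing.
#' @param digits Optional rounding of the reported percentage.
#' @return Percentage (scalar).
#' @export
ratio_statistics <- function(table_a, table_b, exclusions = character(),
                             digits = NULL) {
  labs <- setdiff(intersect(names(table_a), names(table_b)), exclusions)
  if (!length(labs)) stop("no shared labels after exclusions")
  sb <- sum(table_b[labs])
  if (sb == 0) stop("denominator table sums to zero")
  r <- 100 * sum(table_a[labs]) / sb
  if (!is.null(digits)) r <- round(r, digits)
  r
}
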