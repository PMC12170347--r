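# Convergence diagnostics: rank-normalised split R-hat and bulk effective
# sample size, computed as in modern MCMC practice (split each chain in
# half, rank-normalise the pooled draws, between/within variance ratio for
# R-hat, Geyer initial-monotone paired autocorrelation sums for ESS).

# draws (vector) + chain labels -> matrix of split half-chains (internal)
split_chain_matrix <- function(x, chain) {
  pieces <- split(x, chain)
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(v) v[seq_len(n)])
  half <- n %/% 2L
  cols <- list()
  for (v in pieces) {
    cols[[length(cols) + 1L]] <- v[seq_len(half)]
    cols[[length(cols) + 1L]] <- v[half + seq_len(half)]
  }
  do.call(cbind, cols)
}

rank_normalise <- function(m) {
  z <- qnorm((rank(as.vector(m), ties.method = "average") - 3 / 8) /
               (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

rhat_matrix <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2L, var))
  B <- n * var(colMeans(m))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_matrix <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  ac <- vapply(seq_len(nc), function(j)
    drop(acf(m[, j], lag.max = n - 1L, type = "covariance",
             plot = FALSE, demean = TRUE)$acf), numeric(n))
  mean_ac <- rowMeans(ac)
  W <- mean(ac[1L, ]) * n / (n - 1)
  B <- if (nc > 1L) n * var(colMeans(m)) else 0
  var_plus <- W * (n - 1) / n + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - mean_ac * n / (n - 1)) / var_plus
  # Geyer: sum paired rho_{2t} + rho_{2t+1} while positive and monotone
  tau <- 0
  prev <- Inf
  t <- 1L  # rho[1] is lag 0
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2L
  }
  tau <- max(2 * tau - 1, 1 / log10(n * nc))  # tau >= 1 effectively
  min(n * nc / tau, n * nc * log10(n * nc))
}

#' Convergence diagnostics for reconstruction samples
#'
#' Rank-normalised split R-hat and bulk effective sample size for every
#' scalar model parameter.  Chains are split in half, so a single long chain
#' can also be diagnosed.  Parameters with (numerically) constant draws are
#' flagged and get `NA` diagnostics.
#'
#' @param samples A `recon_samples`, `recon_fit`, or data frame of draws
#'   with a `chain` column.
#' @param params Character vector of columns to diagnose (default: all
#'   scalar parameters).
#' @return Data frame with columns `param`, `rhat`, `ess`, `flag`.
#' @export
mcmc_diagnostics <- function(samples, params = NULL) {
  if (inherits(samples, "recon_fit")) samples <- samples$samples
  df <- if (inherits(samples, "recon_samples")) samples$scalars else samples
  if (!"chain" %in% names(df)) stop("draws need a 'chain' column")
  if (is.null(params))
    params <- setdiff(names(df), c("chain", "iter"))
  n_chain <- length(unique(df$chain))
  n_draw <- min(table(df$chain))
  if (n_chain < 2L && n_draw < 200L)
    stop("need at least 2 chains or 200 draws per chain")
  out <- data.frame(param = params, rhat = NA_real_, ess = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_along(params)) {
    x <- df[[params[i]]]
    m <- split_chain_matrix(x, df$chain)
    if (max(x) - min(x) < 1e-12) {
      out$flag[i] <- "constant"
      next
    }
    z <- rank_normalise(m)
    out$rhat[i] <- rhat_matrix(z)
    out$ess[i] <- ess_matrix(z)
    if (is.na(out$rhat[i]) || is.na(out$ess[i])) out$flag[i] <- "undefined"
  }
  out
}
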