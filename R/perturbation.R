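#' Perturbation mechanism configuration
#'
#' Forward model of the table-publication privacy mechanism: integer noise
#' `eps` on `{-d..d}` drawn from a symmetric pmf is added to the true count,
#' the result floored at zero, and published counts at or below the
#' suppression threshold `tau` are released as zero.  True zeros are
#' published as exact zeros when `zero_fixed` (the default), reproducing the
#' behaviour that empty cells never acquire spurious cases.
#'
#' The defaults (`d = 2`, a peaked symmetric pmf, `tau = 2`) reproduce the
#' two qualitative phenomena the reconstruction must handle: published zeros
#' that hide small true counts, and large counts that are published almost
#' exactly.
#'
#' @param d Maximum noise magnitude (non-negative integer).
#' @param noise_pmf Probabilities over `-d:d`; must sum to one and be
#'   symmetric about zero.
#' @param tau Suppression threshold: noisy counts `<= tau` publish as zero.
#' @param zero_fixed Logical; publish true zeros as exact zeros.
#' @return An object of class `perturb_config`.
#' @examples
#' pcfg <- perturb_config()
#' perturb_count(100L, pcfg)
#' @export
perturb_config <- function(d = 2L,
                           noise_pmf = c(0.1, 0.2, 0.4, 0.2, 0.1),
                           tau = 2L, zero_fixed = TRUE) {
  d <- as.integer(d)
  tau <- as.integer(tau)
  if (d < 0L) stop("'d' must be a non-negative integer")
  if (tau < 0L) stop("'tau' must be a non-negative integer")
  if (length(noise_pmf) != 2L * d + 1L)
    stop("'noise_pmf' must have length 2*d + 1")
  if (any(noise_pmf < 0) || abs(sum(noise_pmf) - 1) > 1e-12)
    stop("'noise_pmf' must be non-negative and sum to 1")
  if (max(abs(noise_pmf - rev(noise_pmf))) > 1e-12)
    stop("'noise_pmf' must be symmetric about zero")
  structure(list(d = d, noise_pmf = as.numeric(noise_pmf), tau = tau,
                 zero_fixed = isTRUE(zero_fixed)),
            class = "perturb_config")
}

#' Apply the privacy mechanism to true counts
#'
#' @param y Vector of non-negative integer true counts.
#' @param pcfg A [perturb_config()].
#' @return Integer vector of published counts (zeros where suppressed).
#' @export
perturb_count <- function(y, pcfg = perturb_config()) {
  y <- as.integer(y)
  if (any(y < 0L)) stop("true counts must be non-negative")
  eps <- sample(seq(-pcfg$d, pcfg$d), length(y), replace = TRUE,
                prob = pcfg$noise_pmf)
  o <- pmax(0L, y + eps)
  o[o <= pcfg$tau] <- 0L
  if (pcfg$zero_fixed) o[y == 0L] <- 0L
  o
}

#' Exact log-likelihood of a published count given a candidate true count
#'
#' `exp(perturbation_loglik(o, y, pcfg))` is the exact probability that the
#' mechanism publishes `o` when the true count is `y`, including the
#' aggregated mass at `o = 0` (suppression plus flooring).  Impossible
#' pairs return `-Inf`.  Vectorised over `o` and `y` (recycled).
#'
#' @param o Published count(s).
#' @param y Candidate true count(s).
#' @param pcfg A [perturb_config()].
#' @return Numeric vector of log-probabilities.
#' @export
perturbation_loglik <- function(o, y, pcfg = perturb_config()) {
  n <- max(length(o), length(y))
  o <- rep_len(as.integer(o), n)
  y <- rep_len(as.integer(y), n)
  if (any(o < 0L) || any(y < 0L)) stop("counts must be non-negative")
  cpp_pert_loglik(o, y, pcfg$noise_pmf, pcfg$d, pcfg$tau, pcfg$zero_fixed)
}

#' Censor-and-round rule for public register map outputs
#'
#' Counts below 20 are suppressed; all others are rounded to the nearest
#' ten with ties rounded up (the publication rule of public diabetes
#' register maps).
#'
#' @param c Vector of non-negative integer counts.
#' @return Integer vector of reported values, `NA` where suppressed.
#' @examples
#' ndss_censor_round(c(19, 23, 25, 1410))
#' @export
ndss_censor_round <- function(c) {
  c <- as.integer(c)
  if (any(c < 0L, na.rm = TRUE)) stop("counts must be non-negative")
  out <- as.integer(10L * ((c + 5L) %/% 10L))  # half rounds up
  out[c < 20L] <- NA_integer_
  out
}
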