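#' @export
print.recon_fit <- function(x, ...) {
  nd <- nrow(x$samples$scalars)
  cat("Bayesian count reconstruction + geospatial prevalence model\n")
  cat("  fine units:", x$hierarchy$n,
      "| chains:", length(unique(x$samples$scalars$chain)),
      "| stored draws:", nd, "\n")
  cat("  posterior medians:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.recon_fit <- function(object, ...) {
  sc <- object$samples$scalars
  pars <- c("beta0_young", "beta0_old", "beta_ses", paste0("gamma", 1:5),
            "sigma_u", "rho", "w")
  vapply(pars, function(p) median(sc[[p]]), 0)
}

#' @export
summary.recon_fit <- function(object, ...) {
  sc <- object$samples$scalars
  pars <- c("beta0_young", "beta0_old", "beta_ses", paste0("gamma", 1:5),
            "sigma_u", "rho", "w")
  tab <- t(vapply(pars, function(p)
    c(median = median(sc[[p]]), mean = mean(sc[[p]]), sd = sd(sc[[p]]),
      q2.5 = unname(quantile(sc[[p]], 0.025)),
      q97.5 = unname(quantile(sc[[p]], 0.975))), numeric(5)))
  ps <- prevalence_summary(object, type = "model")
  nat <- list(age0_14 = national_summary(ps, "age0_14"),
              age15_19 = national_summary(ps, "age15_19"))
  structure(list(params = tab, national = nat, diagnostics =
                   object$diagnostics,
                 accept = object$samples$accept),
            class = "summary.recon_fit")
}

#' @export
print.summary.recon_fit <- function(x, ...) {
  cat("Scalar parameter posteriors:\n")
  print(round(x$params, 4))
  cat("\nNational small-area prevalence, median [IQR] per 1000:\n")
  for (p in names(x$national)) {
    v <- x$national[[p]]
    cat(sprintf("  %s: %.2f [%.2f-%.2f]\n", p, v["median"], v["q25"],
                v["q75"]))
  }
  if (!is.null(x$diagnostics)) {
    cat("\nWorst split R-hat:",
        round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}

#' Per-unit posterior prevalence from a fitted reconstruction
#'
#' @param object A `recon_fit`.
#' @param age_grouping See [prevalence_summary()].
#' @param ... Unused.
#' @return A [prevalence_summary()] data frame.
#' @export
predict.recon_fit <- function(object, age_grouping = list(
  age0_14 = c("age0_9", "age10_14"), age15_19 = "age15_19"), ...) {
  prevalence_summary(object, age_grouping = age_grouping)
}

#' Diagnostic and summary plots for a fitted reconstruction
#'
#' `type = "trace"` draws trace plots of key scalar parameters per chain;
#' `type = "prevalence"` plots per-unit posterior median prevalence against
#' the unit centroids (point size by prevalence); `type = "field"` shows the
#' posterior mean spatial field the same way.
#'
#' @param x A `recon_fit`.
#' @param type Plot type.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.recon_fit <- function(x, type = c("trace", "prevalence", "field"),
                           ...) {
  type <- match.arg(type)
  sc <- x$samples$scalars
  if (type == "trace") {
    pars <- c("beta0_young", "beta0_old", "beta_ses", "sigma_u", "w")
    old <- par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
    on.exit(par(old))
    for (p in pars) {
      m <- do.call(cbind, split(sc[[p]], sc$chain))
      matplot(m, type = "l", lty = 1, ylab = p, xlab = "", ...)
    }
  } else {
    h <- x$hierarchy
    if (type == "prevalence") {
      ps <- prevalence_summary(x)
      v <- ps$median[ps$age_product == "age0_14"]
      main <- "posterior median prevalence (ages 0-14)"
    } else {
      v <- colMeans(x$samples$u)
      main <- "posterior mean spatial field"
    }
    cexs <- 0.5 + 2 * (v - min(v, na.rm = TRUE)) /
      max(diff(range(v, na.rm = TRUE)), 1e-12)
    plot(h$units$centroid_x_km, h$units$centroid_y_km, cex = cexs,
         pch = 16, col = "#00000080", xlab = "x (km)", ylab = "y (km)",
         main = main, asp = 1, ...)
  }
  invisible(x)
}
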