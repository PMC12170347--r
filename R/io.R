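#' Read simulation, perturbation and prior settings from one YAML file
#'
#' The file may contain top-level blocks `sim`, `perturb`, `priors` and
#' `mcmc`; each block's entries are passed to the corresponding constructor
#' ([sim_config()], [perturb_config()], [prior_spec()], [mcmc_config()]),
#' with omitted entries taking the package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `sim`, `perturb`, `priors`, `mcmc`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, fn) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    do.call(fn, args)
  }
  list(sim = build("sim", sim_config),
       perturb = build("perturb", perturb_config),
       priors = build("priors", prior_spec),
       mcmc = build("mcmc", mcmc_config))
}

#' Persist and reload posterior samples
#'
#' Draws are written as a long CSV (`chain`, `iter`, `name`, `index`,
#' `value`) together with a JSON manifest recording the fine-unit ordering,
#' age groups, denominators and sampler configuration, so a `recon_samples`
#' object can be reconstructed exactly.
#'
#' @param samples A `recon_samples` or `recon_fit`.
#' @param dir Output directory (created if needed).
#' @return `write_samples` returns `dir` invisibly; `read_samples` returns a
#'   `recon_samples`.
#' @export
write_samples <- function(samples, dir) {
  if (inherits(samples, "recon_fit")) samples <- samples$samples
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- samples$scalars
  base <- sc[c("chain", "iter")]
  long <- list()
  for (nm in setdiff(names(sc), c("chain", "iter")))
    long[[nm]] <- data.frame(base, name = nm, index = 1L,
                             value = sc[[nm]])
  nd <- nrow(sc)
  for (j in seq_len(ncol(samples$u)))
    long[[paste0("u", j)]] <- data.frame(base, name = "u", index = j,
                                         value = samples$u[, j])
  for (a in seq_len(dim(samples$y)[3L]))
    for (j in seq_len(dim(samples$y)[2L]))
      long[[paste0("y", a, "_", j)]] <-
        data.frame(base, name = paste0("y_", samples$age_groups[a]),
                   index = j, value = samples$y[, j, a])
  write.csv(do.call(rbind, long), file.path(dir, "draws.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(fine_ids = samples$fine_ids,
                   age_groups = samples$age_groups,
                   n_stated = unname(as.data.frame(samples$n_stated)),
                   n_draws = nd,
                   mcfg = unclass(samples$mcfg),
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  long <- read.csv(file.path(dir, "draws.csv"), stringsAsFactors = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fine_ids <- man$fine_ids
  ages <- man$age_groups
  n <- length(fine_ids)
  key <- paste(long$chain, long$iter)
  draws <- unique(key)
  nd <- length(draws)
  di <- match(key, draws)
  scalars <- NULL
  u <- matrix(NA_real_, nd, n)
  y <- array(NA_integer_, c(nd, n, length(ages)))
  for (nm in unique(long$name)) {
    rows <- long$name == nm
    if (nm == "u") {
      u[cbind(di[rows], long$index[rows])] <- long$value[rows]
    } else if (startsWith(nm, "y_")) {
      a <- match(substring(nm, 3L), ages)
      y[cbind(di[rows], long$index[rows], a)] <-
        as.integer(long$value[rows])
    } else {
      v <- long$value[rows][order(di[rows])]
      scalars <- if (is.null(scalars))
        data.frame(chain = long$chain[rows][order(di[rows])],
                   iter = long$iter[rows][order(di[rows])],
                   setNames(data.frame(v), nm))
      else cbind(scalars, setNames(data.frame(v), nm))
    }
  }
  nst <- as.matrix(as.data.frame(man$n_stated))
  storage.mode(nst) <- "integer"
  dimnames(nst) <- list(fine_ids, ages)
  structure(list(scalars = scalars, u = u, y = y,
                 chain = scalars$chain, fine_ids = fine_ids,
                 age_groups = ages, n_stated = nst,
                 mcfg = do.call(mcmc_config, man$mcfg)),
            class = "recon_samples")
}

#' Export per-unit summaries as a GeoJSON FeatureCollection
#'
#' Writes one point feature per fine unit (the planar centroid, interpreted
#' as coordinates) with the summary columns as properties, suitable for
#' quick inspection in any GeoJSON viewer.
#'
#' @param h A `census_hierarchy`.
#' @param summary_df Data frame with a `unit_id` column (for example one age
#'   product of a [prevalence_summary()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geojson_summary <- function(h, summary_df, path) {
  idx <- match(h$fine_ids, summary_df$unit_id)
  feats <- lapply(seq_len(h$n), function(i) {
    props <- if (is.na(idx[i])) list(unit_id = h$fine_ids[i])
    else as.list(summary_df[idx[i], , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(h$units$centroid_x_km[i],
                                         h$units$centroid_y_km[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
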