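#' Build a nested areal hierarchy from fine-unit records
#'
#' The hierarchy is represented by one record per fine (level-1) unit
#' carrying its full parent chain, area-level covariates, planar centroid
#' (km) and population by age group.  Fine units are ordered
#' lexicographically by `unit_id` at construction; every aggregation matrix
#' and every count vector in the package uses that fixed ordering.
#'
#' @param area_records A data frame with columns `unit_id`, `l2_id`,
#'   `l3_id`, `l4_id`, `state_id`, `ses_decile` (integer 1-10), `remoteness`
#'   (one of `"major_city"`, `"inner_regional"`, `"outer_regional"`,
#'   `"remote"`, `"very_remote"`), `centroid_x_km`, `centroid_y_km`, and
#'   `pop_age0_9`, `pop_age10_14`, `pop_age15_19`.
#' @return An object of class `census_hierarchy`: a list with elements
#'   `units` (the validated, sorted records), `pop` (integer matrix, fine
#'   units by age groups), `fine_ids`, and `n`.
#' @export
build_hierarchy <- function(area_records) {
  req <- c("unit_id", "l2_id", "l3_id", "l4_id", "state_id", "ses_decile",
           "remoteness", "centroid_x_km", "centroid_y_km",
           paste0("pop_", AGE_GROUPS))
  missing_cols <- setdiff(req, names(area_records))
  if (length(missing_cols))
    stop("area_records is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(area_records) == 0L) stop("area_records must be non-empty")
  ar <- area_records[req]
  dup <- ar$unit_id[duplicated(ar$unit_id)]
  if (length(dup))
    stop("duplicate unit_id: ", paste(unique(dup), collapse = ", "))
  for (col in c("l2_id", "l3_id", "l4_id", "state_id"))
    if (any(is.na(ar[[col]]) | ar[[col]] == ""))
      stop("missing parent id in column '", col, "'")
  if (any(is.na(ar$ses_decile)) ||
      any(ar$ses_decile < 1L | ar$ses_decile > 10L) ||
      any(ar$ses_decile != round(ar$ses_decile)))
    stop("ses_decile must be an integer in 1..10")
  if (any(!ar$remoteness %in% REMOTENESS_LEVELS))
    stop("remoteness must be one of: ",
         paste(REMOTENESS_LEVELS, collapse = ", "))
  pop <- as.matrix(ar[paste0("pop_", AGE_GROUPS)])
  if (any(pop < 0) || any(pop != round(pop)))
    stop("populations must be non-negative integers")

  # each unit must have exactly one parent at the next coarser level
  chain <- list(c("l2_id", "l3_id"), c("l3_id", "l4_id"),
                c("l4_id", "state_id"))
  for (pr in chain) {
    tab <- unique(ar[pr])
    if (anyDuplicated(tab[[1L]]))
      stop("unit(s) at level '", pr[1L], "' mapped to more than one '",
           pr[2L], "' parent")
  }

  ord <- order(ar$unit_id, method = "radix")
  ar <- ar[ord, , drop = FALSE]
  rownames(ar) <- NULL
  pop <- pop[ord, , drop = FALSE]
  storage.mode(pop) <- "integer"
  dimnames(pop) <- list(ar$unit_id, AGE_GROUPS)
  ar$ses_decile <- as.integer(ar$ses_decile)
  structure(list(units = ar, pop = pop, fine_ids = ar$unit_id,
                 n = nrow(ar)),
            class = "census_hierarchy")
}

#' @export
print.census_hierarchy <- function(x, ...) {
  cat("Nested areal hierarchy:", x$n, "fine units |",
      length(unique(x$units$l2_id)), "L2 |",
      length(unique(x$units$l3_id)), "L3 |",
      length(unique(x$units$l4_id)), "L4 |",
      length(unique(x$units$state_id)), "state(s)\n")
  invisible(x)
}

# group labels of each fine unit under a named partition (internal)
partition_labels <- function(h, partition) {
  u <- h$units
  switch(partition,
         L1 = u$unit_id,
         L2 = u$l2_id,
         L3 = u$l3_id,
         L4 = u$l4_id,
         STATE = u$state_id,
         ses_decile = sprintf("ses_%02d", u$ses_decile),
         remoteness = u$remoteness,
         stop("unknown partition: '", partition, "'"))
}

#' Aggregation matrix from fine units to a coarser partition
#'
#' Returns a 0/1 matrix `A` (target units by fine units, columns in
#' `h$fine_ids` order) such that `A %*% v` gives partition totals of any
#' fine-unit count vector `v`.  Spatial levels (`"L2"`, `"L3"`, `"L4"`,
#' `"STATE"`, and the identity `"L1"`) and the two covariate
#' stratifications (`"ses_decile"`, `"remoteness"`) are all supported as
#' partitions.
#'
#' @param h A [build_hierarchy()] object.
#' @param partition Level or covariate name.
#' @return A base matrix with `dimnames`, a `"target_label"` attribute, and
#'   class `aggregation_matrix`.
#' @export
aggregation_matrix <- function(h, partition) {
  lab <- partition_labels(h, partition)
  groups <- sort(unique(lab), method = "radix")
  A <- matrix(0L, nrow = length(groups), ncol = h$n,
              dimnames = list(groups, h$fine_ids))
  A[cbind(match(lab, groups), seq_len(h$n))] <- 1L
  structure(A, target_label = partition,
            class = c("aggregation_matrix", "matrix", "array"))
}

#' Aggregation matrix to an external (non-nested) partition
#'
#' Builds the aggregation operator onto a partition, such as local
#' government areas, that is not an ancestor level of the hierarchy, from a
#' correspondence table of whole-unit assignments.  Fine units absent from
#' the map are collected in an explicit `"unassigned"` row when
#' `allow_unmapped = TRUE`, and are an error otherwise.
#'
#' @param h A [build_hierarchy()] object.
#' @param external_partition Data frame with columns `fine_id` and
#'   `external_id`; each `fine_id` at most once.
#' @param allow_unmapped Permit fine units missing from the map.
#' @return An `aggregation_matrix` onto the external partition.
#' @export
correspondence_map <- function(h, external_partition, allow_unmapped = FALSE) {
  ep <- external_partition
  if (!all(c("fine_id", "external_id") %in% names(ep)))
    stop("external_partition needs columns 'fine_id' and 'external_id'")
  if (anyDuplicated(ep$fine_id))
    stop("fine_id appears more than once in the correspondence table")
  unknown <- setdiff(ep$fine_id, h$fine_ids)
  if (length(unknown))
    stop("fine_id not in hierarchy: ", paste(unknown, collapse = ", "))
  lab <- ep$external_id[match(h$fine_ids, ep$fine_id)]
  if (anyNA(lab)) {
    if (!allow_unmapped)
      stop("unmapped fine units (set allow_unmapped = TRUE to collect ",
           "them in an 'unassigned' row)")
    lab[is.na(lab)] <- "unassigned"
  }
  groups <- sort(unique(as.character(lab)), method = "radix")
  A <- matrix(0L, nrow = length(groups), ncol = h$n,
              dimnames = list(groups, h$fine_ids))
  A[cbind(match(lab, groups), seq_len(h$n))] <- 1L
  structure(A, target_label = "external",
            class = c("aggregation_matrix", "matrix", "array"))
}

#' Write / read a hierarchy as CSV
#'
#' Round-trip serialisation of the fine-unit records, preserving the
#' lexicographic unit ordering.
#'
#' @param h A `census_hierarchy`.
#' @param path CSV file path.
#' @return `write_hierarchy` returns `path` invisibly; `read_hierarchy`
#'   returns a `census_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  write.csv(h$units, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  build_hierarchy(read.csv(path, stringsAsFactors = FALSE))
}
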