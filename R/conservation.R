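#' Within-group conservation of bile-salt profiles
#'
#' Summarizes, per taxonomic group (family or order), the set of profile
#' classes among member species, a heterogeneity flag (more than one class in
#' the group), and an overlap flag: whether every member shares at least one
#' broad compound type at >= 10% of its pool (heterogeneous groups can still
#' overlap, e.g. some members with C24 acids only and others with C24 plus
#' C27 acids).
#'
#' @param profiles List of [species_profile()] objects.
#' @param rank `"family"` or `"order_group"`.
#' @return Data frame with columns `group`, `n_species`, `classes`
#'   (comma-collapsed), `heterogeneous`, `overlap`.
#' @export
conservation_report <- function(profiles, rank = c("family", "order_group")) {
  rank <- match.arg(rank)
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, TRUE, "species_profile")))
  groups <- vapply(profiles, function(p) p[[rank]], "")
  if (all(is.na(groups))) {
    stop("no profile carries a '", rank, "' label")
  }
  keep <- !is.na(groups)
  profiles <- profiles[keep]
  groups <- groups[keep]

  rows <- lapply(sort(unique(groups)), function(g) {
    ps <- profiles[groups == g]
    classes <- sort(unique(vapply(ps, assign_class, "")))
    type_sets <- lapply(ps, function(p) {
      agg <- type_aggregates(p)[.COMPOUND_TYPES]
      names(agg)[agg >= 10]
    })
    shared <- Reduce(intersect, type_sets)
    data.frame(group = g, n_species = length(ps),
               classes = paste(classes, collapse = ","),
               heterogeneous = length(classes) > 1,
               overlap = length(shared) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
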