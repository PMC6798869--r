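#' Damage frequency of a leaf set
#'
#' Percent-as-proportion of leaves in a sample bearing any, specialized, or
#' generalized insect feeding damage. A leaf counts once per category no
#' matter how many qualifying DTs it bears; the denominator is the summed
#' tally of identifiable leaves, so field-tallied undamaged batches dilute
#' frequency exactly as the censused outcrop did.
#'
#' @param records Leaf records tibble (e.g. one unit of [pool_units()]).
#' @param dt_registry DT registry tibble (`dt_id`, `specialization`).
#' @param category `"total"`, `"specialized"` or `"generalized"`.
#' @return Proportion in \[0, 1\].
#' @export
damage_frequency <- function(records, dt_registry,
                             category = c("total", "specialized",
                                          "generalized")) {
  category <- match.arg(category)
  leaves <- identifiable(as_tibble(records))
  n <- sum(leaves$tally_count)
  if (n == 0) {
    abort("no identifiable leaves in the unit",
          class = "paleocensus_value_error")
  }
  qualifying <- category_dts(leaves, dt_registry, category)
  hit <- purrr::map_lgl(leaves$dts, ~ length(intersect(.x, qualifying)) > 0)
  sum(leaves$tally_count[hit]) / n
}

## DT ids belonging to a frequency category; errors on DTs absent from the
## registry so a typo in the census can't silently zero a category.
category_dts <- function(leaves, dt_registry, category) {
  seen <- unique(unlist(leaves$dts))
  missing <- setdiff(seen, dt_registry$dt_id)
  if (length(missing) > 0) {
    abort(paste0("damage types absent from registry: ",
                 paste(missing, collapse = ", ")),
          class = "paleocensus_mapping_error")
  }
  if (category == "total") return(dt_registry$dt_id)
  dt_registry$dt_id[!is.na(dt_registry$specialization) &
                      dt_registry$specialization ==
                      switch(category, specialized = "specialized",
                             generalized = "generalized")]
}

#' Specialized-to-generalized damage ratio
#'
#' Ratio of leaves bearing specialized damage to leaves bearing generalized
#' damage: 0 when specialized damage is absent but generalized damage
#' occurs, and `NA` (undefined, not an error) whenever no leaf bears
#' generalized damage.
#'
#' @inheritParams damage_frequency
#' @return Non-negative real, or `NA_real_` when undefined.
#' @export
spec_gen_ratio <- function(records, dt_registry) {
  leaves <- identifiable(as_tibble(records))
  if (sum(leaves$tally_count) == 0) {
    abort("no identifiable leaves in the unit",
          class = "paleocensus_value_error")
  }
  n_cat <- function(cat) {
    ids <- category_dts(leaves, dt_registry, cat)
    hit <- purrr::map_lgl(leaves$dts, ~ length(intersect(.x, ids)) > 0)
    sum(leaves$tally_count[hit])
  }
  n_spec <- n_cat("specialized")
  n_gen <- n_cat("generalized")
  if (n_gen == 0) NA_real_ else n_spec / n_gen
}

#' Per-unit herbivory summary
#'
#' Damage frequencies (total, specialized, generalized), the
#' specialized:generalized ratio, and observed DT richness for each unit.
#'
#' @param x A [census()] object.
#' @param by `"level"` or `"quarry"`.
#' @return Tibble with one row per unit: `unit_id`, `n_leaves`,
#'   `freq_total`, `freq_specialized`, `freq_generalized`,
#'   `spec_gen_ratio`, `dt_richness_total`, `dt_richness_specialized`.
#' @export
damage_summary <- function(x, by = c("level", "quarry")) {
  by <- match.arg(by)
  pooled <- pool_units(x, by = by)
  reg <- x$dts
  spec_ids <- reg$dt_id[!is.na(reg$specialization) &
                          reg$specialization == "specialized"]
  pooled |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_modify(function(g, key) {
      g_id <- identifiable(g)
      all_dts <- unlist(g_id$dts)
      tibble(
        n_leaves = sum(g_id$tally_count),
        freq_total = damage_frequency(g, reg, "total"),
        freq_specialized = damage_frequency(g, reg, "specialized"),
        freq_generalized = damage_frequency(g, reg, "generalized"),
        spec_gen_ratio = spec_gen_ratio(g, reg),
        dt_richness_total = length(unique(all_dts)),
        dt_richness_specialized = length(unique(intersect(all_dts, spec_ids)))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$unit_id)
}

#' Damage-type rarefaction on a leaf set
#'
#' Monte-Carlo rarefaction of DT richness in which the drawable universe is
#' every identifiable leaf — damaged or not — and a leaf contributes its
#' whole DT set, so leaves with no damage and leaves with multiple DTs are
#' both accounted for. Field-tally batches expand into individual undamaged
#' leaves before drawing.
#'
#' @inheritParams damage_frequency
#' @param dt_filter `"all"` or `"specialized"`; with `"specialized"` only
#'   DTs classed specialized in the registry count toward richness.
#' @inheritParams rarefy_species
#' @return A `rarefaction_curve` (see [rarefy_species()]).
#' @export
rarefy_dts <- function(records, dt_registry,
                       dt_filter = c("all", "specialized"), sizes = NULL,
                       n_resamples = 1000, seed = 1L) {
  dt_filter <- match.arg(dt_filter)
  leaves <- expand_tallies(identifiable(as_tibble(records)))
  if (nrow(leaves) == 0) {
    abort("no identifiable leaves to rarefy",
          class = "paleocensus_value_error")
  }
  keep <- category_dts(leaves, dt_registry,
                       if (dt_filter == "all") "total" else "specialized")
  curve <- rarefy_engine(leaves$dts, sizes, n_resamples, seed,
                         filter_ids = keep)
  attr(curve, "kind") <- paste0("dt_", dt_filter)
  curve
}

#' Damage-type rarefaction per host plant
#'
#' DT rarefaction restricted to the leaves of each sufficiently sampled
#' morphospecies (host) within one analysis unit. Hosts with fewer than
#' `min_leaves` identifiable leaves in the unit are excluded.
#'
#' @param x A [census()] object.
#' @param unit_id The unit to analyse.
#' @param by `"level"` or `"quarry"`.
#' @param min_leaves Minimum identifiable leaves for a host to be included
#'   (default 20).
#' @inheritParams rarefy_dts
#' @details Requested `sizes` larger than a host's leaf count are dropped
#'   for that host (each host's curve can only extend to its own sample).
#' @return Named list mapping `morphospecies_id` to `rarefaction_curve`;
#'   empty list when no host qualifies.
#' @export
per_host_curves <- function(x, unit_id, by = "level", min_leaves = 20,
                            dt_filter = "all", sizes = NULL,
                            n_resamples = 1000, seed = 1L) {
  pooled <- pool_units(x, by = by)
  leaves <- expand_tallies(identifiable(
    pooled[pooled$unit_id == unit_id, ]))
  counts <- table(leaves$morphospecies_id)
  hosts <- sort(names(counts)[counts >= min_leaves])
  out <- purrr::map(hosts, function(h) {
    n_h <- sum(leaves$morphospecies_id == h)
    sizes_h <- sizes[sizes <= n_h]
    if (length(sizes_h) == 0) sizes_h <- NULL
    rarefy_dts(leaves[leaves$morphospecies_id == h, ], x$dts,
               dt_filter = dt_filter, sizes = sizes_h,
               n_resamples = n_resamples, seed = seed)
  })
  setNames(out, hosts)
}
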