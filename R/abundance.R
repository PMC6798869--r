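#' Pool census records into analysis units
#'
#' Assigns each record to an analysis unit: its quarry, or the stratigraphic
#' level its quarry belongs to (pooling through the census unit map). Level
#' pooling is the disjoint union of the level's quarries; the total leaf
#' tally is conserved.
#'
#' @param x A [census()] object.
#' @param by `"level"` (default) or `"quarry"`.
#' @return The records tibble with a `unit_id` column prepended; original
#'   row order preserved.
#' @export
pool_units <- function(x, by = c("level", "quarry")) {
  stopifnot(inherits(x, "census"))
  by <- match.arg(by)
  rec <- x$records
  if (by == "quarry") {
    unit <- rec$quarry_id
  } else {
    map <- setNames(x$units$level_id, x$units$quarry_id)
    missing_q <- setdiff(unique(rec$quarry_id), names(map))
    if (length(missing_q) > 0) {
      abort(paste0("quarries missing from unit map: ",
                   paste(missing_q, collapse = ", ")),
            class = "paleocensus_mapping_error")
    }
    unit <- unname(map[rec$quarry_id])
  }
  dplyr::bind_cols(tibble(unit_id = unit), rec)
}

#' Unit-by-variable abundance matrix
#'
#' Builds the count matrix feeding rank abundance, rarefaction and
#' ordination. For `kind = "species"` a cell is the summed leaf tally of a
#' morphospecies in a unit (unidentified leaves excluded). For `kind = "dt"`
#' a cell is the number of identifiable leaves in the unit bearing that
#' damage type; a leaf carrying k distinct DTs contributes one leaf to each
#' of its k columns.
#'
#' @param x A [census()] object, or a pooled records tibble from
#'   [pool_units()].
#' @param kind `"species"` or `"dt"`.
#' @param by Passed to [pool_units()] when `x` is a census.
#' @return A tibble with `unit_id` (rows sorted lexicographically) followed
#'   by one integer column per variable (columns sorted lexicographically).
#' @export
#' @examples
#' cen <- census(tibble::tibble(
#'   specimen_id = c("a", "b", "c"), quarry_id = "Q", level_id = "A",
#'   morphospecies_id = c("sp1", "sp1", "sp2"),
#'   dts = list("DT1", character(), c("DT1", "DT2"))
#' ))
#' abundance_matrix(cen, "species")
#' abundance_matrix(cen, "dt")
abundance_matrix <- function(x, kind = c("species", "dt"), by = "level") {
  kind <- match.arg(kind)
  pooled <- if (inherits(x, "census")) pool_units(x, by = by) else as_tibble(x)
  if (nrow(pooled) == 0 || !"unit_id" %in% names(pooled)) {
    abort("abundance_matrix needs pooled records with at least one unit",
          class = "paleocensus_value_error")
  }
  units_all <- sort(unique(pooled$unit_id))

  if (kind == "species") {
    long <- pooled |>
      identifiable() |>
      dplyr::group_by(.data$unit_id, variable = .data$morphospecies_id) |>
      dplyr::summarise(n = sum(.data$tally_count), .groups = "drop")
  } else {
    long <- pooled |>
      identifiable() |>
      expand_tallies() |>
      dplyr::select("unit_id", "dts") |>
      tidyr::unchop("dts", keep_empty = FALSE) |>
      dplyr::group_by(.data$unit_id, variable = .data$dts) |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop")
  }

  wide <- long |>
    dplyr::mutate(n = as.integer(.data$n)) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "n",
                       values_fill = 0L)
  ## keep units that carried no countable variables (all-unidentified etc.)
  wide <- dplyr::left_join(tibble(unit_id = units_all), wide, by = "unit_id")
  wide[is.na(wide)] <- 0L
  vars <- sort(setdiff(names(wide), "unit_id"))
  wide[, c("unit_id", vars)]
}

## unit_id-keyed tibble -> plain numeric matrix with dimnames
abund_as_matrix <- function(ab) {
  m <- as.matrix(ab[, setdiff(names(ab), "unit_id"), drop = FALSE])
  rownames(m) <- ab$unit_id
  m
}
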