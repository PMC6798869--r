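#' Raunkiaer size-class scheme for leaf-area analysis
#'
#' The per-class representative log leaf areas feeding the leaf-area
#' paleoprecipitation proxy. The default `log_area` for each class is the
#' midpoint of the natural-log class boundaries of the Raunkiaer-Webb
#' series (areas in mm2, adjacent boundaries differing by a factor of 9:
#' leptophyll up to 25 mm2, nanophyll 25-225, microphyll 225-2025,
#' notophyll 2025-4500, mesophyll 4500-18225, macrophyll 18225-164025,
#' megaphyll above). These are the conventional values of the leaf-area
#' analysis literature; override the tibble (or read one with
#' [read_size_class_scheme()]) to use a different calibration.
#'
#' @return Tibble with `size_class` (ordered smallest to largest) and
#'   `log_area` (strictly increasing, ln mm2).
#' @export
#' @examples
#' size_class_scheme()
size_class_scheme <- function() {
  ## ln-midpoints of the factor-9 Raunkiaer-Webb area series (mm2);
  ## notophyll is the conventional split of Raunkiaer's mesophyll at
  ## 4500 mm2, hence its narrower band.
  bounds <- c(25 / 9, 25, 225, 2025, 4500, 18225, 164025, 164025 * 9)
  tibble(
    size_class = raunkiaer_classes(),
    log_area = (log(bounds[-length(bounds)]) + log(bounds[-1])) / 2
  )
}

#' Read a size-class scheme from delimited text
#'
#' @param path CSV/TSV with columns `size_class`, `log_area`.
#' @return Validated scheme tibble.
#' @export
read_size_class_scheme <- function(path) {
  sc <- read_delim_auto(path)
  stopifnot(all(c("size_class", "log_area") %in% names(sc)))
  if (anyDuplicated(sc$size_class) || any(diff(sc$log_area) <= 0)) {
    abort("scheme labels must be unique and log_area strictly increasing",
          class = "paleocensus_value_error")
  }
  as_tibble(sc[, c("size_class", "log_area")])
}

#' Leaf-margin estimate of mean annual temperature
#'
#' Leaf-margin analysis: MAT (deg C) is affine in the proportion P of
#' woody dicot morphospecies with untoothed (entire) margins,
#' \eqn{MAT = 30.6 P + 1.14}, with binomial sampling standard deviation
#' \eqn{\sigma = 30.6 \sqrt{P (1 - P) / r}} where r is the number of
#' margin-scored species in the sample.
#'
#' @param p_untoothed Proportion of untoothed species, in \[0, 1\].
#' @param r_species Number of margin-scored species (positive integer).
#' @return Tibble with `mat_C` and `mat_sigma_C`.
#' @export
#' @examples
#' lma_mat(0.5, 25)
lma_mat <- function(p_untoothed, r_species) {
  if (any(p_untoothed < 0 | p_untoothed > 1)) {
    abort("p_untoothed must lie in [0, 1]",
          class = "paleocensus_value_error")
  }
  if (any(r_species < 1)) {
    abort("r_species must be a positive integer",
          class = "paleocensus_value_error")
  }
  tibble(
    mat_C = 30.6 * p_untoothed + 1.14,
    mat_sigma_C = 30.6 * sqrt(p_untoothed * (1 - p_untoothed) / r_species)
  )
}

#' Untoothed-margin proportion of a unit's flora
#'
#' P and r for leaf-margin analysis: r counts the morphospecies present in
#' the unit whose margin state is scored (not `"unknown"`); P is the
#' untoothed share of those. Species present only as unidentified leaves
#' never enter.
#'
#' @param records Leaf records of one unit (e.g. filtered [pool_units()]).
#' @param species_registry Morphospecies registry with `margin_state`.
#' @return Tibble with `p_untoothed` and `r_species`.
#' @export
margin_proportion <- function(records, species_registry) {
  present <- setdiff(unique(as_tibble(records)$morphospecies_id),
                     UNIDENTIFIED)
  scored <- species_registry[
    species_registry$morphospecies_id %in% present &
      species_registry$margin_state %in% c("toothed", "untoothed"), ]
  if (nrow(scored) == 0) {
    abort("no margin-scored species present in the unit",
          class = "paleocensus_value_error")
  }
  tibble(
    p_untoothed = mean(scored$margin_state == "untoothed"),
    r_species = nrow(scored)
  )
}

#' Leaf-area estimate of mean annual precipitation
#'
#' Leaf-area analysis: \eqn{MAP = e^{0.548 \sum a_i p_i + 0.768}} (cm/yr),
#' where \eqn{p_i} is the proportion of leaves in Raunkiaer size class i
#' and \eqn{a_i} the class's representative natural-log leaf area. Leaves
#' of unknown size class are excluded before the proportions are formed.
#'
#' @param size_class_props Named numeric vector (or tibble with
#'   `size_class`, `prop`) of per-class leaf proportions or counts; an
#'   `"UNKNOWN"` entry is dropped and the rest renormalised.
#' @param scheme Size-class scheme tibble (default [size_class_scheme()]).
#' @return MAP point estimate in cm/yr (positive scalar).
#' @export
#' @examples
#' leaf_area_map(c(microphyll = 0.5, mesophyll = 0.5))
leaf_area_map <- function(size_class_props, scheme = size_class_scheme()) {
  if (is.data.frame(size_class_props)) {
    size_class_props <- setNames(size_class_props$prop,
                                 size_class_props$size_class)
  }
  p <- size_class_props[names(size_class_props) != SIZE_UNKNOWN]
  p <- p[p > 0]
  if (length(p) == 0 || sum(p) <= 0) {
    abort("no leaves with known size class",
          class = "paleocensus_value_error")
  }
  unknown_cls <- setdiff(names(p), scheme$size_class)
  if (length(unknown_cls) > 0) {
    abort(paste0("size classes absent from scheme: ",
                 paste(unknown_cls, collapse = ", ")),
          class = "paleocensus_mapping_error")
  }
  p <- p / sum(p)
  a <- setNames(scheme$log_area, scheme$size_class)[names(p)]
  unname(exp(0.548 * sum(a * p) + 0.768))
}

#' Asymmetric error bounds for a MAP estimate
#'
#' The leaf-area regression's standard error (0.359) lives on the
#' natural-log scale, so the plus and minus bounds on the cm/yr scale are
#' asymmetric: `plus = MAP (e^se - 1)`, `minus = MAP (1 - e^-se)`.
#'
#' @param map_cm MAP point estimate, cm/yr (positive).
#' @param se_ln Standard error on the log scale (default 0.359).
#' @return Tibble with `map_plus_cm` and `map_minus_cm`.
#' @export
#' @examples
#' map_error_bounds(145)
map_error_bounds <- function(map_cm, se_ln = 0.359) {
  if (any(map_cm <= 0)) {
    abort("MAP must be positive", class = "paleocensus_value_error")
  }
  tibble(
    map_plus_cm = map_cm * (exp(se_ln) - 1),
    map_minus_cm = map_cm * (1 - exp(-se_ln))
  )
}

#' Per-unit paleoclimate reconstruction
#'
#' Leaf-margin MAT (with binomial sigma) and leaf-area MAP (with
#' asymmetric log-scale bounds) for every analysis unit of a census.
#' Units with no margin-scored species, or no leaves of known size class,
#' get `NA` for the affected estimate rather than an error.
#'
#' @param x A [census()] object.
#' @param by `"level"` or `"quarry"`.
#' @param scheme Size-class scheme (default [size_class_scheme()]).
#' @return Tibble with one row per unit: `unit_id`, `p_untoothed`,
#'   `r_species`, `mat_C`, `mat_sigma_C`, `map_cm`, `map_plus_cm`,
#'   `map_minus_cm`.
#' @export
climate_summary <- function(x, by = c("level", "quarry"),
                            scheme = size_class_scheme()) {
  by <- match.arg(by)
  pooled <- pool_units(x, by = by)
  pooled |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_modify(function(g, key) {
      mat <- tryCatch({
        pr <- margin_proportion(g, x$species)
        dplyr::bind_cols(pr, lma_mat(pr$p_untoothed, pr$r_species))
      }, paleocensus_value_error = function(e) {
        tibble(p_untoothed = NA_real_, r_species = NA_integer_,
               mat_C = NA_real_, mat_sigma_C = NA_real_)
      })
      map <- tryCatch({
        leaves <- identifiable(g)
        props <- tapply(leaves$tally_count, leaves$size_class, sum)
        m <- leaf_area_map(c(props), scheme)
        dplyr::bind_cols(tibble(map_cm = m), map_error_bounds(m))
      }, paleocensus_value_error = function(e) {
        tibble(map_cm = NA_real_, map_plus_cm = NA_real_,
               map_minus_cm = NA_real_)
      })
      dplyr::bind_cols(mat, map)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$unit_id)
}
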