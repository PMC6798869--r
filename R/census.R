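#' Build a validated leaf census
#'
#' A census bundles the leaf-level records with three sidecar registries:
#' the morphospecies registry (margin states for leaf-margin analysis), the
#' damage-type (DT) registry (feeding group and generalized/specialized
#' class), and the quarry-to-stratigraphic-level map used for pooling.
#'
#' Each record is one censused leaf, or one field-tallied batch of undamaged
#' leaves of a known morphospecies (`tally_count > 1`, empty DT set). Batches
#' are first-class: they count in floral abundances and in damage-frequency
#' denominators, and they expand into individual undamaged leaves wherever
#' the leaf is the resampling unit.
#'
#' @param records Tibble with columns `specimen_id`, `quarry_id`,
#'   `morphospecies_id`, and optionally `level_id` (defaults to the quarry),
#'   `size_class` (defaults to `"UNKNOWN"`), `dts` (list-column of character
#'   DT ids, defaults to empty sets) and `tally_count` (defaults to 1).
#' @param species Morphospecies registry: tibble with `morphospecies_id` and
#'   `margin_state` (one of `"toothed"`, `"untoothed"`, `"unknown"`). Missing
#'   registry rows are synthesised with `margin_state = "unknown"`.
#' @param dts DT registry: tibble with `dt_id`, `feeding_group`,
#'   `specialization` (`"generalized"` or `"specialized"`).
#' @param units Quarry-to-level map: tibble with `quarry_id`, `level_id`.
#'   Defaults to the distinct pairs present in `records`.
#'
#' @return An object of class `census`: a list of the four validated tibbles.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   specimen_id = c("L1", "L2", "L3"),
#'   quarry_id = "Q1", level_id = "A",
#'   morphospecies_id = c("sp1", "sp1", "sp2"),
#'   size_class = "microphyll",
#'   dts = list(character(), "DT12", c("DT12", "DT2")),
#'   tally_count = 1L
#' )
#' census(recs, dts = tibble::tibble(
#'   dt_id = c("DT12", "DT2"),
#'   feeding_group = c("galling", "hole feeding"),
#'   specialization = c("specialized", "generalized")
#' ))
census <- function(records, species = NULL, dts = NULL, units = NULL) {
  records <- as_tibble(records)
  req <- c("specimen_id", "quarry_id", "morphospecies_id")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    abort(paste0("census records are missing mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "paleocensus_schema_error")
  }
  if (!"level_id" %in% names(records)) records$level_id <- records$quarry_id
  if (!"size_class" %in% names(records)) records$size_class <- SIZE_UNKNOWN
  if (!"tally_count" %in% names(records)) records$tally_count <- 1L
  if (!"dts" %in% names(records)) {
    records$dts <- rep(list(character()), nrow(records))
  }
  records <- dplyr::mutate(
    records,
    specimen_id = as.character(.data$specimen_id),
    quarry_id = as.character(.data$quarry_id),
    level_id = as.character(.data$level_id),
    morphospecies_id = as.character(.data$morphospecies_id),
    size_class = as.character(.data$size_class),
    tally_count = as.integer(.data$tally_count),
    dts = purrr::map(.data$dts, ~ sort(unique(as.character(.x))))
  )
  records <- records[, c("specimen_id", "quarry_id", "level_id",
                         "morphospecies_id", "size_class", "dts",
                         "tally_count")]

  bad_size <- !(records$size_class %in% c(raunkiaer_classes(), SIZE_UNKNOWN))
  if (any(bad_size)) {
    warn(paste0("unknown size-class label(s) mapped to UNKNOWN: ",
                paste(unique(records$size_class[bad_size]), collapse = ", ")))
    records$size_class[bad_size] <- SIZE_UNKNOWN
  }

  if (is.null(units)) {
    units <- dplyr::distinct(records, .data$quarry_id, .data$level_id)
  }
  units <- dplyr::mutate(as_tibble(units),
                         quarry_id = as.character(.data$quarry_id),
                         level_id = as.character(.data$level_id))

  ids_seen <- setdiff(unique(records$morphospecies_id), UNIDENTIFIED)
  if (is.null(species)) {
    species <- tibble(morphospecies_id = ids_seen, margin_state = "unknown")
  } else {
    species <- dplyr::mutate(as_tibble(species),
                             morphospecies_id = as.character(.data$morphospecies_id),
                             margin_state = as.character(.data$margin_state))
    extra <- setdiff(ids_seen, species$morphospecies_id)
    if (length(extra) > 0) {
      species <- dplyr::bind_rows(
        species, tibble(morphospecies_id = extra, margin_state = "unknown"))
    }
  }

  dts_seen <- sort(unique(as.character(unlist(records$dts))))
  if (is.null(dts)) {
    dts <- tibble(dt_id = dts_seen, feeding_group = NA_character_,
                  specialization = NA_character_)
  } else {
    dts <- as_tibble(dts)
    if (!"feeding_group" %in% names(dts)) dts$feeding_group <- NA_character_
    dts <- dplyr::mutate(dts,
                         dt_id = as.character(.data$dt_id),
                         specialization = as.character(.data$specialization))
  }

  out <- structure(
    list(records = records, species = species, dts = dts, units = units),
    class = "census")
  validate_census(out)
}

#' Validate a census object
#'
#' Checks the structural invariants: positive tallies, empty DT sets on
#' tally batches, registry coverage of every morphospecies and DT appearing
#' in the records, and unit-map coverage of every quarry.
#'
#' @param x A `census` object.
#' @return `x`, invisibly-validated (returned unchanged on success).
#' @export
validate_census <- function(x) {
  stopifnot(inherits(x, "census"))
  rec <- x$records
  if (any(rec$tally_count < 1L)) {
    abort("tally_count must be >= 1 for every record",
          class = "paleocensus_value_error")
  }
  batch_damaged <- rec$tally_count > 1L & lengths(rec$dts) > 0L
  if (any(batch_damaged)) {
    abort("field-tally batches (tally_count > 1) must have empty DT sets",
          class = "paleocensus_value_error")
  }
  if (anyDuplicated(x$species$morphospecies_id)) {
    abort("duplicate morphospecies_id in species registry",
          class = "paleocensus_value_error")
  }
  if (anyDuplicated(x$dts$dt_id)) {
    abort("duplicate dt_id in DT registry", class = "paleocensus_value_error")
  }
  ok_margin <- x$species$margin_state %in% c("toothed", "untoothed", "unknown")
  if (!all(ok_margin)) {
    abort("margin_state must be toothed, untoothed or unknown",
          class = "paleocensus_value_error")
  }
  ok_spec <- is.na(x$dts$specialization) |
    x$dts$specialization %in% c("generalized", "specialized")
  if (!all(ok_spec)) {
    abort("specialization must be generalized or specialized",
          class = "paleocensus_value_error")
  }
  sp_missing <- setdiff(setdiff(unique(rec$morphospecies_id), UNIDENTIFIED),
                        x$species$morphospecies_id)
  if (length(sp_missing) > 0) {
    abort(paste0("morphospecies missing from registry: ",
                 paste(sp_missing, collapse = ", ")),
          class = "paleocensus_value_error")
  }
  dt_missing <- setdiff(unique(unlist(rec$dts)), x$dts$dt_id)
  if (length(dt_missing) > 0) {
    abort(paste0("damage types missing from registry: ",
                 paste(dt_missing, collapse = ", ")),
          class = "paleocensus_value_error")
  }
  q_missing <- setdiff(unique(rec$quarry_id), x$units$quarry_id)
  if (length(q_missing) > 0) {
    abort(paste0("quarries missing from unit map: ",
                 paste(q_missing, collapse = ", ")),
          class = "paleocensus_mapping_error")
  }
  x
}

#' @export
print.census <- function(x, ...) {
  n_leaves <- sum(x$records$tally_count)
  cat("<census> ", nrow(x$records), " records (", n_leaves, " leaves), ",
      length(setdiff(unique(x$records$morphospecies_id), UNIDENTIFIED)),
      " morphospecies, ", length(unique(unlist(x$records$dts))), " DTs, ",
      length(unique(x$units$level_id)), " levels / ",
      length(unique(x$units$quarry_id)), " quarries\n", sep = "")
  invisible(x)
}

## Expand field-tally batches into one row per leaf (tally_count == 1).
## The leaf is the sampling unit for every herbivory computation.
expand_tallies <- function(records) {
  if (all(records$tally_count == 1L)) return(records)
  idx <- rep.int(seq_len(nrow(records)), records$tally_count)
  out <- records[idx, ]
  out$tally_count <- 1L
  out
}

identifiable <- function(records) {
  records[records$morphospecies_id != UNIDENTIFIED, ]
}
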