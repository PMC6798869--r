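#' Read a leaf census from delimited text
#'
#' Reads a census table (CSV or TSV, autodetected from the file extension)
#' with one row per leaf or per field-tallied batch of undamaged leaves.
#' Damage types may be encoded in either of two dialects, both accepted:
#' wide 0/1 columns named like `DT12`, or a single list column whose cells
#' hold `;`-separated DT ids. Column names in the file are mapped onto the
#' standard names through `schema`, so files deposited with headers such as
#' `"field number"`, `"site"`, `"size classification"` and `"species"` read
#' without renaming.
#'
#' @param path Census file (`.csv` or `.tsv`/`.txt`).
#' @param schema Named list or character vector mapping standard column
#'   names (`specimen_id`, `quarry_id`, `level_id`, `morphospecies_id`,
#'   `size_class`, `tally_count`, `dts`) to the column names used in the
#'   file, or the path to a JSON file holding that mapping. Unmapped
#'   standard names are looked up verbatim.
#' @param species,dts,units Optional sidecar registries: tibbles, or paths
#'   to delimited files with the registry columns (see [census()]).
#'
#' @return A validated [census()] object. Row order of the file is
#'   preserved. Unknown size-class labels are mapped to `"UNKNOWN"` with a
#'   warning.
#' @export
read_census <- function(path, schema = NULL, species = NULL, dts = NULL,
                        units = NULL) {
  if (!file.exists(path)) {
    abort(paste0("census file not found: ", path),
          class = "paleocensus_io_error")
  }
  schema <- load_schema(schema)
  raw <- read_delim_auto(path)

  std <- c("specimen_id", "quarry_id", "level_id", "morphospecies_id",
           "size_class", "tally_count", "dts")
  colmap <- purrr::map_chr(std, ~ schema[[.x]] %||% .x)
  names(colmap) <- std

  mandatory <- c("specimen_id", "quarry_id", "morphospecies_id")
  for (m in mandatory) {
    if (!colmap[[m]] %in% names(raw)) {
      abort(paste0("census file is missing mandatory column '", colmap[[m]],
                   "' (standard field ", m, ")"),
            class = "paleocensus_schema_error")
    }
  }

  rec <- tibble(
    specimen_id = as.character(raw[[colmap[["specimen_id"]]]]),
    quarry_id = as.character(raw[[colmap[["quarry_id"]]]]),
    morphospecies_id = as.character(raw[[colmap[["morphospecies_id"]]]])
  )
  rec$level_id <- if (colmap[["level_id"]] %in% names(raw)) {
    as.character(raw[[colmap[["level_id"]]]])
  } else rec$quarry_id
  rec$size_class <- if (colmap[["size_class"]] %in% names(raw)) {
    as.character(raw[[colmap[["size_class"]]]])
  } else SIZE_UNKNOWN
  rec$tally_count <- if (colmap[["tally_count"]] %in% names(raw)) {
    as.integer(raw[[colmap[["tally_count"]]]])
  } else 1L
  rec$dts <- parse_dt_columns(raw, colmap[["dts"]], exclude = unname(colmap))

  species <- load_registry(species)
  dts <- load_registry(dts)
  units <- load_registry(units)
  census(rec, species = species, dts = dts, units = units)
}

## Extract per-leaf DT sets from either dialect. Wide columns are any not
## claimed by the schema whose name looks like a DT id (e.g. "DT38"); they
## must be strictly 0/1 (NA treated as 0 is NOT allowed: the deposited
## presence/absence coding is complete).
parse_dt_columns <- function(raw, list_col, exclude) {
  if (list_col %in% names(raw)) {
    return(purrr::map(raw[[list_col]], function(cell) {
      if (is.na(cell) || !nzchar(trimws(cell))) return(character())
      trimws(strsplit(as.character(cell), ";", fixed = TRUE)[[1]])
    }))
  }
  dt_cols <- setdiff(grep("^DT[0-9]+$", names(raw), value = TRUE), exclude)
  if (length(dt_cols) == 0) {
    return(rep(list(character()), nrow(raw)))
  }
  mat <- as.matrix(raw[, dt_cols, drop = FALSE])
  bad <- which(!(mat %in% c(0, 1)) | is.na(mat))
  if (length(bad) > 0) {
    row_idx <- ((bad[1] - 1) %% nrow(mat)) + 1
    abort(paste0("non-binary value in DT column at row ", row_idx),
          class = "paleocensus_value_error")
  }
  apply(mat, 1, function(r) dt_cols[r == 1], simplify = FALSE)
}

load_schema <- function(schema) {
  if (is.null(schema)) return(list())
  if (is.character(schema) && length(schema) == 1 && file.exists(schema) &&
      grepl("\\.json$", schema, ignore.case = TRUE)) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  as.list(schema)
}

load_registry <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  read_delim_auto(x)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, comment = "#",
                    name_repair = "minimal")
}

#' Write a census and its registries to delimited text
#'
#' The records table is written with the DT sets serialised as a
#' `;`-separated `dts` column; the three registries go to sidecar files next
#' to `path` (suffixes `_species`, `_dts`, `_units`). [read_census()] on the
#' written files reproduces the census field-by-field.
#'
#' @param x A [census()] object.
#' @param path Output file for the records (`.csv` or `.tsv`).
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return Invisibly, a named character vector of the four paths written.
#' @export
write_census <- function(x, path, overwrite = FALSE) {
  stopifnot(inherits(x, "census"))
  ext <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) ".tsv" else ".csv"
  stem <- sub("\\.(csv|tsv)$", "", path, ignore.case = TRUE)
  paths <- c(records = path,
             species = paste0(stem, "_species", ext),
             dts = paste0(stem, "_dts", ext),
             units = paste0(stem, "_units", ext))
  if (!overwrite && any(file.exists(paths))) {
    abort("output files exist; pass overwrite = TRUE to replace them",
          class = "paleocensus_io_error")
  }
  flat <- dplyr::mutate(x$records,
                        dts = purrr::map_chr(.data$dts, paste, collapse = ";"))
  writer <- if (ext == ".tsv") readr::write_tsv else readr::write_csv
  writer(flat, paths[["records"]])
  writer(x$species, paths[["species"]])
  writer(x$dts, paths[["dts"]])
  writer(x$units, paths[["units"]])
  invisible(paths)
}

#' Read a census written by [write_census()]
#'
#' @param path Records file written by [write_census()]; sidecar registry
#'   files are located by their suffixes.
#' @inheritParams read_census
#' @return A validated [census()] object.
#' @export
read_census_bundle <- function(path, schema = NULL) {
  ext <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) ".tsv" else ".csv"
  stem <- sub("\\.(csv|tsv)$", "", path, ignore.case = TRUE)
  read_census(path, schema = schema,
              species = paste0(stem, "_species", ext),
              dts = paste0(stem, "_dts", ext),
              units = paste0(stem, "_units", ext))
}
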