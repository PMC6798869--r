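## Orchestration: census -> summary tables, rarefaction curves, ordination
## score files, each written as delimited text with a provenance header.

provenance_header <- function(meta) {
  meta <- c(list(artifact = paste0("paleocensus ",
                                   as.character(utils::packageVersion("paleocensus")))),
            meta)
  paste0("# ", paste(names(meta), unlist(meta), sep = "=", collapse = " | "))
}

write_with_header <- function(df, path, meta, overwrite = FALSE) {
  if (!overwrite && file.exists(path)) {
    abort(paste0("output exists (pass overwrite = TRUE): ", path),
          class = "paleocensus_io_error")
  }
  writeLines(provenance_header(meta), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

config_hash <- function(x) rlang::hash(x)

#' Summary tables for a census
#'
#' Writes one summary table per grouping (quarry and stratigraphic level):
#' leaf tally, species richness, Shannon diversity, Pielou's J, leaf-margin
#' MAT with sigma, leaf-area MAP with asymmetric bounds, damage
#' frequencies, and the specialized:generalized ratio. Full-precision
#' columns are kept; presentation columns (`*_print`) round H and J to 2
#' decimals and climate values to 1, mirroring how such tables are
#' published. Computation and rounding are strictly separated.
#'
#' @param x A [census()] object.
#' @param out_dir Output directory (created if needed).
#' @param scheme Size-class scheme for MAP.
#' @param overwrite Overwrite existing outputs? Default `FALSE`.
#' @return Invisibly, named vector of the files written. The merged
#'   per-level tibble is attached as attribute `"level"`.
#' @export
run_summarize <- function(x, out_dir, scheme = size_class_scheme(),
                          overwrite = FALSE) {
  stopifnot(inherits(x, "census"))
  if (nrow(x$records) == 0) {
    abort("census has no records; nothing to summarise",
          class = "paleocensus_value_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = config_hash(list(x$units, scheme)), seed = "none")

  build <- function(by) {
    diversity_summary(x, by = by) |>
      dplyr::left_join(climate_summary(x, by = by, scheme = scheme),
                       by = "unit_id") |>
      dplyr::left_join(damage_summary(x, by = by),
                       by = c("unit_id", "n_leaves")) |>
      dplyr::mutate(
        shannon_print = round(.data$shannon, 2),
        pielou_print = round(.data$pielou, 2),
        mat_C_print = round(.data$mat_C, 1),
        mat_sigma_C_print = round(.data$mat_sigma_C, 1),
        map_cm_print = round(.data$map_cm, 1),
        map_plus_cm_print = round(.data$map_plus_cm, 1),
        map_minus_cm_print = round(.data$map_minus_cm, 1)
      )
  }
  paths <- c(quarry = file.path(out_dir, "summary_quarry.csv"),
             level = file.path(out_dir, "summary_level.csv"))
  tabs <- list(quarry = build("quarry"), level = build("level"))
  for (nm in names(paths)) {
    write_with_header(tabs[[nm]], paths[[nm]], meta, overwrite)
  }
  out <- paths
  attr(out, "quarry") <- tabs$quarry
  attr(out, "level") <- tabs$level
  invisible(out)
}

#' Rarefaction curve files for a census
#'
#' Writes one curve file per unit (or per unit and host for
#' `target = "per_host"`): floral rarefaction, DT rarefaction on the bulk
#' flora, specialized-DT rarefaction, or per-host DT rarefaction. Each
#' file's provenance header records seed, number of resamples and filter,
#' so identical seeds give identical files.
#'
#' @param x A [census()] object.
#' @param target `"flora"`, `"dts"`, `"dts_specialized"` or `"per_host"`.
#' @param out_dir Output directory.
#' @param by `"level"` or `"quarry"`.
#' @param sizes,n_resamples,seed Sampling parameters (see
#'   [rarefy_species()]).
#' @param min_leaves Host inclusion threshold for `"per_host"`.
#' @param overwrite Overwrite existing outputs?
#' @return Invisibly, character vector of files written.
#' @export
run_rarefy <- function(x, target = c("flora", "dts", "dts_specialized",
                                     "per_host"),
                       out_dir, by = "level", sizes = NULL,
                       n_resamples = 1000, seed = 1L, min_leaves = 20,
                       overwrite = FALSE) {
  target <- match.arg(target)
  stopifnot(inherits(x, "census"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pooled <- pool_units(x, by = by)
  units <- sort(unique(pooled$unit_id))
  meta0 <- list(config = config_hash(list(target, by, sizes, n_resamples,
                                          min_leaves)),
                seed = seed, n_resamples = n_resamples, filter = target)
  written <- character()
  for (u in units) {
    g <- pooled[pooled$unit_id == u, ]
    if (target == "per_host") {
      curves <- per_host_curves(x, u, by = by, min_leaves = min_leaves,
                                sizes = sizes, n_resamples = n_resamples,
                                seed = seed)
      for (h in names(curves)) {
        p <- file.path(out_dir, paste0("rarefy_per_host_", u, "_", h, ".csv"))
        write_with_header(as_tibble(curves[[h]]), p,
                          c(meta0, list(unit = u, host = h)), overwrite)
        written <- c(written, p)
      }
    } else {
      curve <- switch(
        target,
        flora = {
          counts <- table(expand_tallies(identifiable(g))$morphospecies_id)
          rarefy_species(setNames(as.integer(counts), names(counts)),
                         sizes = sizes, n_resamples = n_resamples,
                         seed = seed)
        },
        dts = rarefy_dts(g, x$dts, "all", sizes = sizes,
                         n_resamples = n_resamples, seed = seed),
        dts_specialized = rarefy_dts(g, x$dts, "specialized", sizes = sizes,
                                     n_resamples = n_resamples, seed = seed)
      )
      p <- file.path(out_dir, paste0("rarefy_", target, "_", u, ".csv"))
      write_with_header(as_tibble(curve), p, c(meta0, list(unit = u)),
                        overwrite)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Ordination score files for a census
#'
#' Runs NMDS on the unit-by-species or unit-by-DT count matrix (Euclidean
#' distances on raw counts) and writes site scores, variable scores, and a
#' one-line stress report.
#'
#' @param x A [census()] object.
#' @param matrix_kind `"species"` or `"dt"`.
#' @param out_dir Output directory.
#' @param by `"level"` or `"quarry"`.
#' @param k,n_restarts,seed NMDS parameters (see [nmds()]).
#' @param overwrite Overwrite existing outputs?
#' @return Invisibly, named vector of files written; the fitted `nmds_ord`
#'   is attached as attribute `"fit"`.
#' @export
run_ordinate <- function(x, matrix_kind = c("species", "dt"), out_dir,
                         by = "level", k = 2, n_restarts = 20, seed = 1L,
                         overwrite = FALSE) {
  matrix_kind <- match.arg(matrix_kind)
  stopifnot(inherits(x, "census"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ab <- abundance_matrix(x, matrix_kind, by = by)
  fit <- nmds(distance_matrix(ab), k = k, n_restarts = n_restarts,
              seed = seed)
  meta <- list(config = config_hash(list(matrix_kind, by, k, n_restarts)),
               seed = seed, stress = format(fit$stress, digits = 6),
               converged = fit$converged)
  paths <- c(
    sites = file.path(out_dir, paste0("nmds_", matrix_kind, "_sites.csv")),
    variables = file.path(out_dir,
                          paste0("nmds_", matrix_kind, "_variables.csv")),
    stress = file.path(out_dir, paste0("nmds_", matrix_kind, "_stress.csv"))
  )
  write_with_header(fit$site_scores, paths[["sites"]], meta, overwrite)
  write_with_header(variable_scores(fit, ab), paths[["variables"]], meta,
                    overwrite)
  write_with_header(glance(fit), paths[["stress"]], meta, overwrite)
  out <- paths
  attr(out, "fit") <- fit
  invisible(out)
}

#' Run the whole pipeline from a configuration file
#'
#' Reads a YAML or JSON run configuration (input paths, unit map, sampling
#' parameters, output directory), applies any `overrides` (overrides win),
#' and runs summarise, rarefy (all four targets) and ordinate (both
#' matrices) into the output directory.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#'   Recognised fields: `census`, `species`, `dts`, `units`, `schema`,
#'   `scheme` (paths); `out_dir`; `by`; `sizes`; `n_resamples`; `seed`
#'   (mandatory for any resampling); `min_leaves`; `k`; `n_restarts`;
#'   `overwrite`.
#' @param overrides Named list overriding config fields.
#' @return Invisibly, list of the files written by each stage.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- modifyList(
    list(by = "level", sizes = NULL, n_resamples = 1000,
         min_leaves = 20, k = 2, n_restarts = 20, overwrite = FALSE),
    modifyList(as.list(config), as.list(overrides)))
  if (is.null(cfg$seed)) {
    abort("run configuration must set a seed",
          class = "paleocensus_config_error")
  }
  if (is.null(cfg$out_dir)) {
    abort("run configuration must set out_dir",
          class = "paleocensus_config_error")
  }
  x <- read_census(cfg$census, schema = cfg$schema, species = cfg$species,
                   dts = cfg$dts, units = cfg$units)
  scheme <- if (is.null(cfg$scheme)) size_class_scheme() else
    read_size_class_scheme(cfg$scheme)
  res <- list()
  res$summarize <- run_summarize(x, cfg$out_dir, scheme = scheme,
                                 overwrite = cfg$overwrite)
  for (tg in c("flora", "dts", "dts_specialized", "per_host")) {
    res[[paste0("rarefy_", tg)]] <- run_rarefy(
      x, tg, cfg$out_dir, by = cfg$by, sizes = cfg$sizes,
      n_resamples = cfg$n_resamples, seed = cfg$seed,
      min_leaves = cfg$min_leaves, overwrite = cfg$overwrite)
  }
  for (mk in c("species", "dt")) {
    res[[paste0("ordinate_", mk)]] <- run_ordinate(
      x, mk, cfg$out_dir, by = cfg$by, k = cfg$k,
      n_restarts = cfg$n_restarts, seed = cfg$seed,
      overwrite = cfg$overwrite)
  }
  invisible(res)
}
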