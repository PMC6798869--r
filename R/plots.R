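#' Plot a rarefaction curve
#'
#' Mean richness against subsample size with the 95% percentile band.
#'
#' @param object A `rarefaction_curve` (see [rarefy_species()],
#'   [rarefy_dts()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  kind <- attr(object, "kind") %||% "richness"
  ylab <- if (startsWith(kind, "dt")) "DT richness" else "Species richness"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$size, y = .data$mean_richness)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Leaves sampled", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot several rarefaction curves together
#'
#' @param curves Named list of `rarefaction_curve` objects (names become
#'   the legend, e.g. unit ids).
#' @return A ggplot.
#' @export
plot_rarefaction <- function(curves) {
  df <- purrr::imap(curves, ~ dplyr::mutate(as_tibble(.x), unit = .y)) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$mean_richness,
                                   colour = .data$unit, fill = .data$unit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Leaves sampled", y = "Richness",
                  colour = "Unit", fill = "Unit") +
    ggplot2::theme_minimal()
}

#' Rank abundance plot for each unit of a census
#'
#' @param x A [census()] object.
#' @param by `"level"` or `"quarry"`.
#' @param label_top Label species whose count is at least this (default 45).
#' @return A ggplot, faceted by unit.
#' @export
plot_rank_abundance <- function(x, by = "level", label_top = 45) {
  ab <- abundance_matrix(x, "species", by = by)
  m <- abund_as_matrix(ab)
  df <- purrr::map(rownames(m), function(u) {
    dplyr::mutate(rank_abundance(m[u, ]), unit = u)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$proportion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      data = dplyr::filter(df, .data$count >= label_top),
      ggplot2::aes(label = .data$species_id), vjust = -0.6, size = 2.8) +
    ggplot2::facet_wrap(~unit) +
    ggplot2::labs(x = "Species rank", y = "Relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot an NMDS ordination
#'
#' Units as labelled points; optionally the variables (morphospecies or
#' DTs) as crosses at their abundance-weighted positions.
#'
#' @param object An `nmds_ord` from [nmds()].
#' @param variables Optional variable-score tibble from
#'   [variable_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmds_ord <- function(object, variables = NULL, ...) {
  p <- ggplot2::ggplot(object$site_scores,
                       ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if (!is.null(variables)) {
    placed <- dplyr::filter(variables, .data$placed)
    p <- p + ggplot2::geom_point(data = placed, shape = 4,
                                 colour = "grey50")
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$unit_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      subtitle = paste0("stress = ", format(object$stress, digits = 3))) +
    ggplot2::theme_minimal()
}
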