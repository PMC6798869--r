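#' Euclidean distance matrix between analysis units
#'
#' Distances are taken on the raw counts of the unit-by-variable matrix
#' (no transformation or relative-abundance standardisation by default,
#' matching an ordination of count data).
#'
#' @param ab Abundance tibble from [abundance_matrix()] (or any tibble with
#'   a `unit_id` column and numeric columns).
#' @param metric Distance metric; only `"euclidean"` is offered.
#' @param transform Optional function applied to the count matrix before
#'   distances are taken (e.g. `sqrt`); default none.
#' @return A `dist` object labelled by `unit_id`.
#' @export
distance_matrix <- function(ab, metric = "euclidean", transform = NULL) {
  metric <- match.arg(metric, "euclidean")
  m <- abund_as_matrix(ab)
  if (nrow(m) < 2) {
    abort("distance matrix needs at least 2 units",
          class = "paleocensus_value_error")
  }
  if (!is.null(transform)) m <- transform(m)
  dist(m, method = metric)
}

#' Nonmetric multidimensional scaling with Kruskal stress-1
#'
#' Global nonmetric MDS minimising Kruskal's stress-1
#' \eqn{\sqrt{\sum (\hat d_{ij} - f(d_{ij}))^2 / \sum \hat d_{ij}^2}}, with
#' the monotone transform f fit by isotonic regression (via
#' \code{vegan::monoMDS}). The configuration is refined from several
#' starts: restart 0 is initialised from metric MDS (classical scaling) and
#' subsequent restarts from random Gaussian configurations; the lowest-
#' stress solution is kept. The returned scores are centred and rotated to
#' principal axes with deterministic axis signs, so runs are comparable;
#' NMDS axes are otherwise arbitrary up to rotation and reflection.
#'
#' @param d A `dist` from [distance_matrix()].
#' @param k Number of ordination dimensions (default 2; must be `< n` units).
#' @param n_restarts Number of starting configurations (default 20).
#' @param max_iter Iteration cap per start (default 300).
#' @param tol Stress convergence tolerance (default 1e-7).
#' @param seed Integer seed for the random restarts.
#' @return An `nmds_ord` object: list with `site_scores` (tibble `unit_id`,
#'   `NMDS1..k`), `stress`, `converged`, `n_restarts`, `seed`, `k`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-7,
                 seed = 1L) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (k >= n) {
    abort("k must be smaller than the number of units",
          class = "paleocensus_value_error")
  }
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  best <- with_seed(seed, {
    init0 <- cmdscale(d, k = k)
    if (ncol(init0) < k) { # degenerate distances: pad with zeros
      init0 <- cbind(init0, matrix(0, n, k - ncol(init0)))
    }
    fits <- lapply(seq_len(n_restarts), function(i) {
      y <- if (i == 1) init0 else matrix(stats::rnorm(n * k), n, k)
      vegan::monoMDS(d, y = y, k = k, model = "global",
                     maxit = max_iter, smin = tol, sfgrmin = tol,
                     sratmax = 1 - 1e-9)
    })
    fits[[which.min(vapply(fits, function(f) f$stress, numeric(1)))]]
  })

  pts <- principal_axes(best$points)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(
    list(
      site_scores = dplyr::bind_cols(tibble(unit_id = labels),
                                     as_tibble(pts)),
      stress = best$stress,
      ## monoMDS stops for maxit only when no other criterion fired
      converged = !identical(best$maxits, best$iters) || best$stress <= tol,
      n_restarts = n_restarts,
      seed = as.integer(seed),
      k = k
    ),
    class = "nmds_ord")
}

## centre, rotate to principal axes, and fix axis signs (largest-magnitude
## coordinate on each axis made positive) for run-to-run comparability
principal_axes <- function(pts) {
  pts <- scale(pts, scale = FALSE)
  s <- svd(pts)
  rot <- pts %*% s$v
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  rot
}

#' Variable scores for an ordination
#'
#' Places each variable (morphospecies or DT) at the abundance-weighted
#' average of the site scores of the units where it occurs — the
#' conventional way of showing which variables pull each unit's placement.
#' Variables occurring nowhere are returned with `placed = FALSE` and `NA`
#' coordinates.
#'
#' @param fit An `nmds_ord` from [nmds()] (or a site-score tibble).
#' @param ab The abundance tibble the ordination was built from.
#' @return Tibble with `variable`, the k score columns, and `placed`.
#' @export
variable_scores <- function(fit, ab) {
  scores <- if (inherits(fit, "nmds_ord")) fit$site_scores else as_tibble(fit)
  m <- abund_as_matrix(ab)
  if (!identical(sort(rownames(m)), sort(scores$unit_id))) {
    abort("unit labels of ordination and abundance matrix differ",
          class = "paleocensus_mapping_error")
  }
  m <- m[scores$unit_id, , drop = FALSE]
  coords <- as.matrix(scores[, -1, drop = FALSE])
  tot <- colSums(m)
  w <- t(m) %*% coords # variables x k, unnormalised
  out <- sweep(w, 1, ifelse(tot > 0, tot, NA_real_), "/")
  dplyr::bind_cols(
    tibble(variable = colnames(m)),
    as_tibble(out),
    tibble(placed = tot > 0)
  ) |>
    dplyr::arrange(.data$variable)
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat("<nmds ordination> k = ", x$k, ", stress = ",
      format(x$stress, digits = 4), ", ", x$n_restarts,
      " restarts (seed ", x$seed, "), ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  invisible(x)
}

#' @rdname nmds
#' @param x An `nmds_ord` object.
#' @param ... Unused.
#' @export
tidy.nmds_ord <- function(x, ...) {
  x$site_scores
}

#' @rdname nmds
#' @export
glance.nmds_ord <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, n_restarts = x$n_restarts,
         converged = x$converged, seed = x$seed)
}
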