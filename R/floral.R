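#' Species richness of an abundance vector
#'
#' @param counts Non-negative integer abundance vector.
#' @return Number of strictly positive entries.
#' @export
#' @examples
#' richness(c(0, 0, 3))
richness <- function(counts) {
  check_counts(counts, allow_empty = TRUE)
  sum(counts > 0)
}

#' Shannon-Wiener diversity
#'
#' \eqn{H = -\sum p_i \ln p_i} over the positive entries, with natural
#' logarithm (the convention under which Pielou's J reproduces as
#' \eqn{H / \ln S}).
#'
#' @inheritParams richness
#' @return Non-negative real.
#' @export
#' @examples
#' shannon(rep(1, 10)) # = log(10)
shannon <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Pielou's evenness J
#'
#' \eqn{J = H / \ln S}; 1 when all species are equally abundant. Undefined
#' for fewer than two species.
#'
#' @inheritParams richness
#' @return Real in \[0, 1\].
#' @export
pielou <- function(counts) {
  check_counts(counts)
  s <- richness(counts)
  if (s < 2) {
    abort("Pielou's J is undefined for fewer than 2 species",
          class = "paleocensus_value_error")
  }
  shannon(counts) / log(s)
}

check_counts <- function(counts, allow_empty = FALSE) {
  if (any(counts < 0)) {
    abort("abundance counts must be non-negative",
          class = "paleocensus_value_error")
  }
  if (!allow_empty && (length(counts) == 0 || sum(counts) == 0)) {
    abort("abundance vector has no positive counts",
          class = "paleocensus_value_error")
  }
  invisible(counts)
}

#' Rank abundance table
#'
#' Species sorted by decreasing relative abundance, ties broken
#' lexicographically by species id so output is deterministic.
#'
#' @param counts Named non-negative abundance vector (zero entries dropped).
#' @return Tibble with `rank`, `species_id`, `count`, `proportion`
#'   (proportions sum to 1).
#' @export
#' @examples
#' rank_abundance(c(sp2 = 30, sp1 = 50, sp3 = 20))
rank_abundance <- function(counts) {
  check_counts(counts)
  if (is.null(names(counts))) {
    names(counts) <- sprintf("sp%03d", seq_along(counts))
  }
  tot <- sum(counts)
  tibble(species_id = names(counts), count = as.numeric(counts)) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$species_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  proportion = .data$count / tot) |>
    dplyr::select("rank", "species_id", "count", "proportion")
}

#' Per-unit floral diversity summary
#'
#' Leaf tally, species richness, Shannon diversity and (where defined)
#' Pielou's J for each analysis unit of a census.
#'
#' @param x A [census()] object.
#' @param by `"level"` or `"quarry"` (see [pool_units()]).
#' @return Tibble with one row per unit: `unit_id`, `n_leaves`, `richness`,
#'   `shannon`, `pielou` (`NA` when fewer than two species).
#' @export
diversity_summary <- function(x, by = c("level", "quarry")) {
  by <- match.arg(by)
  ab <- abundance_matrix(x, "species", by = by)
  m <- abund_as_matrix(ab)
  tibble(
    unit_id = rownames(m),
    n_leaves = as.integer(rowSums(m)),
    richness = unname(apply(m, 1, richness)),
    shannon = unname(apply(m, 1, function(r)
      if (sum(r) > 0) shannon(r) else NA_real_)),
    pielou = unname(apply(m, 1, function(r) {
      if (richness(r) >= 2) shannon(r) / log(richness(r)) else NA_real_
    }))
  )
}

#' Individual-based rarefaction of plant species richness
#'
#' Monte-Carlo rarefaction: at each subsample size m, m individual leaves
#' are drawn without replacement from the unit's identified leaves,
#' `n_resamples` times; the mean and the 2.5/97.5 percentile band of the
#' distinct-species count are reported. The Monte-Carlo mean converges on
#' the exact hypergeometric expectation
#' \eqn{E[S_m] = \sum_i 1 - \binom{N - n_i}{m} / \binom{N}{m}}.
#'
#' @param counts Named non-negative integer abundance vector.
#' @param sizes Increasing subsample sizes; default an even grid up to the
#'   total count.
#' @param n_resamples Number of Monte-Carlo draws per size (default 1000).
#' @param seed Integer seed; the curve is reproducible given the seed.
#' @return A `rarefaction_curve`: tibble with `size`, `mean_richness`,
#'   `sd_richness` (across resamples), `lower95`, `upper95`, plus
#'   attributes `n_resamples`, `seed`, `kind`.
#' @export
#' @examples
#' rarefy_species(c(sp1 = 2, sp2 = 1), sizes = 1:3, n_resamples = 200, seed = 1)
rarefy_species <- function(counts, sizes = NULL, n_resamples = 1000,
                           seed = 1L) {
  check_counts(counts)
  counts <- counts[counts > 0]
  if (is.null(names(counts))) {
    names(counts) <- sprintf("sp%03d", seq_along(counts))
  }
  items <- rep(names(counts), times = counts)
  sets <- as.list(items) # one label per leaf
  curve <- rarefy_engine(sets, sizes, n_resamples, seed,
                         filter_ids = NULL)
  attr(curve, "kind") <- "species"
  curve
}

## Core leaf-resampling engine shared by floral and damage-type
## rarefaction. `sets` is a list with one element per drawable leaf holding
## the ids that leaf contributes (its species label, or its DT set, possibly
## empty). Richness of a draw = number of distinct ids over drawn leaves.
rarefy_engine <- function(sets, sizes, n_resamples, seed, filter_ids = NULL) {
  n <- length(sets)
  if (!is.null(filter_ids)) {
    sets <- purrr::map(sets, intersect, y = filter_ids)
  }
  if (is.null(sizes)) {
    sizes <- unique(round(seq(1, n, length.out = min(n, 25))))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0 || any(sizes < 1)) {
    abort("subsample sizes must be positive integers",
          class = "paleocensus_value_error")
  }
  if (any(sizes > n)) {
    abort(paste0("subsample size exceeds the number of drawable leaves (",
                 n, ")"),
          class = "paleocensus_value_error")
  }
  ## map ids to integers once; per-leaf integer sets keep the inner loop cheap
  ids <- unique(unlist(sets))
  isets <- purrr::map(sets, ~ match(.x, ids))
  m_max <- max(sizes)

  ## One random leaf permutation per resample; richness at size m is the
  ## number of distinct ids among the first m leaves of the permutation.
  ## The first m leaves of a random permutation are a uniform without-
  ## replacement subset, so each size's marginal matches independent draws,
  ## while each resample's accumulation curve is monotone by construction.
  draws <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      perm <- sample.int(n, m_max)
      pseq <- isets[perm]
      idvec <- unlist(pseq)
      if (length(idvec) == 0) return(integer(length(sizes)))
      pos <- rep.int(seq_len(m_max), lengths(pseq))
      first_pos <- pos[!duplicated(idvec)] # already ordered by pos
      vapply(sizes, function(m) sum(first_pos <= m), integer(1))
    }, integer(length(sizes)))
  })
  draws <- matrix(draws, nrow = length(sizes)) # sizes x resamples
  qs <- apply(draws, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- tibble(
    size = sizes,
    mean_richness = rowMeans(draws),
    sd_richness = apply(draws, 1, sd),
    lower95 = qs[1, ],
    upper95 = qs[2, ]
  )
  structure(out, class = c("rarefaction_curve", class(out)),
            n_resamples = n_resamples, seed = seed)
}

## Run code under a local RNG state: seeded, and the caller's stream is
## untouched afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("<rarefaction curve> ", nrow(x), " sizes, n_resamples = ",
      attr(x, "n_resamples"), ", seed = ", attr(x, "seed"), "\n", sep = "")
  NextMethod()
}
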