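#' Configuration for the synthetic census generator
#'
#' Describes a simulated leaf census with the statistical structure the
#' downstream analyses assume: a fixed morphospecies pool with a rank
#' abundance law and per-species margin states, per-leaf Raunkiaer size
#' classes, and per-leaf insect damage drawn from a weighted DT pool.
#'
#' @param units Tibble (or named integer vector) of analysis units:
#'   `unit_id`, `n_leaves`.
#' @param species_pool_size Number of morphospecies in the regional pool.
#' @param abundance_model `"geometric"` (rank abundance decaying as
#'   `k^(rank-1)`) or `"uniform"`.
#' @param k Geometric decay in (0, 1); ignored for the uniform model.
#' @param p_untoothed Probability a pool species is untoothed; margin state
#'   is a species-level property fixed at pool creation (leaf-margin
#'   analysis scores species, not leaves).
#' @param size_class_probs Named probability vector over Raunkiaer classes
#'   (must sum to 1 within 1e-9).
#' @param damage_prob Per-leaf probability of bearing any insect damage.
#' @param dt_pool Tibble with `dt_id`, `feeding_group`, `specialization`
#'   and per-DT attack `weight`.
#' @param max_dts_per_leaf Cap on DTs per damaged leaf (default 4); the
#'   count of DTs on a damaged leaf follows a truncated geometric law
#'   (halving probability per extra DT), so most damaged leaves carry one.
#' @param seed Integer seed; the generated census is a pure function of the
#'   configuration.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(units,
                              species_pool_size = 40,
                              abundance_model = c("geometric", "uniform"),
                              k = 0.8,
                              p_untoothed = 0.6,
                              size_class_probs = c(
                                leptophyll = 0.02, nanophyll = 0.08,
                                microphyll = 0.40, notophyll = 0.25,
                                mesophyll = 0.20, macrophyll = 0.04,
                                megaphyll = 0.01),
                              damage_prob = 0.2,
                              dt_pool = default_dt_pool(),
                              max_dts_per_leaf = 4,
                              seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  if (is.numeric(units) && !is.null(names(units))) {
    units <- tibble(unit_id = names(units), n_leaves = as.integer(units))
  }
  units <- as_tibble(units)
  stopifnot(all(c("unit_id", "n_leaves") %in% names(units)))
  if (nrow(units) > 0 && any(units$n_leaves < 1)) {
    abort("each unit needs a positive number of leaves",
          class = "paleocensus_config_error")
  }
  probs <- c(p_untoothed, damage_prob, size_class_probs)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "paleocensus_config_error")
  }
  if (abs(sum(size_class_probs) - 1) > 1e-9) {
    abort("size_class_probs must sum to 1 (tolerance 1e-9)",
          class = "paleocensus_config_error")
  }
  if (!all(names(size_class_probs) %in% raunkiaer_classes())) {
    abort("size_class_probs must be named by Raunkiaer classes",
          class = "paleocensus_config_error")
  }
  if (abundance_model == "geometric" && (k <= 0 || k >= 1)) {
    abort("geometric decay k must lie in (0, 1)",
          class = "paleocensus_config_error")
  }
  dt_pool <- as_tibble(dt_pool)
  if (damage_prob > 0 && nrow(dt_pool) == 0) {
    abort("dt_pool must be non-empty when damage_prob > 0",
          class = "paleocensus_config_error")
  }
  if (nrow(dt_pool) > 0 && !"weight" %in% names(dt_pool)) {
    dt_pool$weight <- 1
  }
  structure(
    list(units = units, species_pool_size = as.integer(species_pool_size),
         abundance_model = abundance_model, k = k,
         p_untoothed = p_untoothed, size_class_probs = size_class_probs,
         damage_prob = damage_prob, dt_pool = dt_pool,
         max_dts_per_leaf = as.integer(max_dts_per_leaf),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Default damage-type pool for simulations
#'
#' A small pool spanning the common feeding groups: generalized external
#' feeding (holes, margins, skeletonization, surface) and specialized
#' mining, galling and piercing, with heavier attack weights on the
#' generalized types, as observed in most fossil censuses.
#'
#' @return Tibble with `dt_id`, `feeding_group`, `specialization`, `weight`.
#' @export
default_dt_pool <- function() {
  tibble(
    dt_id = sprintf("DT%02d", c(1, 2, 3, 5, 12, 14, 16, 26, 29, 32, 34,
                                46, 57, 62)),
    feeding_group = c("hole feeding", "hole feeding", "hole feeding",
                      "hole feeding", "margin feeding", "margin feeding",
                      "skeletonization", "surface feeding", "surface feeding",
                      "galling", "galling", "piercing and sucking", "mining",
                      "hole feeding"),
    specialization = c("generalized", "generalized", "generalized",
                       "generalized", "generalized", "generalized",
                       "generalized", "generalized", "generalized",
                       "specialized", "specialized", "specialized",
                       "specialized", "generalized"),
    weight = c(10, 8, 6, 4, 6, 4, 3, 3, 2, 2, 1.5, 1, 1, 2)
  )
}

#' Generate a synthetic leaf census
#'
#' Draws a census from a [simulation_config()]: every leaf of every unit
#' draws its morphospecies from the pool's abundance law, its size class
#' from the class probabilities, and — with probability `damage_prob` — a
#' set of 1 to `max_dts_per_leaf` DTs sampled by weight without
#' replacement. Margin states are fixed per species at pool creation.
#' Byte-identical output for identical configurations (same seed).
#'
#' @param config A [simulation_config()].
#' @return A validated [census()] object whose registries carry the true
#'   margin states and DT classes.
#' @export
#' @examples
#' cfg <- simulation_config(c(A = 50, B = 50), seed = 7)
#' generate_census(cfg)
generate_census <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_sp <- config$species_pool_size
  sp_ids <- sprintf("sp%03d", seq_len(n_sp))

  with_seed(config$seed, {
    margins <- ifelse(rbinom(n_sp, 1, config$p_untoothed) == 1,
                      "untoothed", "toothed")
    species <- tibble(morphospecies_id = sp_ids, margin_state = margins)
    sp_prob <- switch(config$abundance_model,
                      geometric = config$k ^ (seq_len(n_sp) - 1),
                      uniform = rep(1, n_sp))
    sp_prob <- sp_prob / sum(sp_prob)

    recs <- purrr::pmap(config$units, function(unit_id, n_leaves) {
      n <- as.integer(n_leaves)
      sp <- sample(sp_ids, n, replace = TRUE, prob = sp_prob)
      sizes <- sample(names(config$size_class_probs), n, replace = TRUE,
                      prob = config$size_class_probs)
      damaged <- rbinom(n, 1, config$damage_prob) == 1
      dts <- vector("list", n)
      dts[] <- list(character())
      if (any(damaged)) {
        pool <- config$dt_pool
        kmax <- min(config$max_dts_per_leaf, nrow(pool))
        ## truncated geometric count of DTs per damaged leaf
        kprob <- 0.5 ^ (seq_len(kmax) - 1)
        for (i in which(damaged)) {
          n_dt <- sample.int(kmax, 1, prob = kprob)
          dts[[i]] <- sample(pool$dt_id, n_dt, prob = pool$weight)
        }
      }
      tibble(
        specimen_id = sprintf("%s-%04d", unit_id, seq_len(n)),
        quarry_id = unit_id, level_id = unit_id,
        morphospecies_id = sp, size_class = sizes, dts = dts,
        tally_count = 1L
      )
    })

    empty <- tibble(specimen_id = character(), quarry_id = character(),
                    level_id = character(), morphospecies_id = character(),
                    size_class = character(), dts = list(),
                    tally_count = integer())
    census(dplyr::bind_rows(c(list(empty), recs)), species = species,
           dts = config$dt_pool[, c("dt_id", "feeding_group",
                                    "specialization")])
  })
}

#' Check a synthetic census against its generating parameters
#'
#' Compares the empirical damage frequency, untoothed species share, and
#' size-class frequencies of a generated census with the configured
#' values, using exact binomial 95% intervals (Clopper-Pearson) on the
#' empirical counts.
#'
#' @param x The census produced by [generate_census()].
#' @param config The same [simulation_config()].
#' @return Tibble with `parameter`, `configured`, `estimated`, `lower95`,
#'   `upper95`, `inside_95`.
#' @export
recovery_report <- function(x, config) {
  stopifnot(inherits(x, "census"), inherits(config, "simulation_config"))
  leaves <- expand_tallies(x$records)
  n <- nrow(leaves)
  rows <- list()

  n_damaged <- sum(lengths(leaves$dts) > 0)
  rows$damage_prob <- binom_row("damage_prob", config$damage_prob,
                                n_damaged, n)

  n_untoothed <- sum(x$species$margin_state == "untoothed")
  rows$p_untoothed <- binom_row("p_untoothed", config$p_untoothed,
                                n_untoothed, nrow(x$species))

  cls <- names(config$size_class_probs)
  obs <- table(factor(leaves$size_class, levels = cls))
  for (cl in cls) {
    rows[[paste0("size_", cl)]] <- binom_row(
      paste0("size_class.", cl), config$size_class_probs[[cl]],
      as.integer(obs[[cl]]), n)
  }
  dplyr::bind_rows(rows)
}

binom_row <- function(name, p_true, successes, n) {
  ci <- if (n > 0) binom.test(successes, n)$conf.int else c(NA_real_, NA_real_)
  tibble(
    parameter = name, configured = p_true,
    estimated = if (n > 0) successes / n else NA_real_,
    lower95 = ci[1], upper95 = ci[2],
    inside_95 = !is.na(ci[1]) & p_true >= ci[1] & p_true <= ci[2]
  )
}
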