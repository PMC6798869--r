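# Fixtures and independent oracles used across the suite.

toy_dt_registry <- function() {
  tibble::tibble(
    dt_id = c("DT1", "DT2", "DT12", "DT33"),
    feeding_group = c("hole feeding", "margin feeding", "galling", "mining"),
    specialization = c("generalized", "generalized", "specialized",
                       "specialized")
  )
}

toy_species_registry <- function() {
  tibble::tibble(
    morphospecies_id = c("sp1", "sp2", "sp3", "sp4", "sp5", "sp6"),
    margin_state = c("untoothed", "untoothed", "untoothed", "toothed",
                     "unknown", "unknown")
  )
}

# Two quarries per level A, one quarry in level B.
toy_records <- function() {
  tibble::tibble(
    specimen_id = sprintf("L%02d", 1:8),
    quarry_id = c("A.1", "A.1", "A.1", "A.2", "A.2", "B.1", "B.1", "B.1"),
    level_id  = c("A", "A", "A", "A", "A", "B", "B", "B"),
    morphospecies_id = c("sp1", "sp1", "sp2", "sp3", "UNIDENTIFIED",
                         "sp4", "sp5", "sp6"),
    size_class = c("microphyll", "microphyll", "mesophyll", "notophyll",
                   "microphyll", "nanophyll", "mesophyll", "microphyll"),
    dts = list(c("DT1", "DT12"), character(), "DT2", character(),
               "DT1", "DT33", character(), character()),
    tally_count = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  )
}

toy_census <- function(records = toy_records()) {
  census(records, species = toy_species_registry(),
         dts = toy_dt_registry())
}

# Exact hypergeometric expectation of distinct-id richness when m leaves
# are drawn without replacement from N: sum_d 1 - C(N - n_d, m) / C(N, m),
# where n_d = number of leaves carrying id d. Independent of the package's
# Monte-Carlo engine.
hyper_expected_richness <- function(sets, m) {
  n <- length(sets)
  ids <- unique(unlist(sets))
  if (length(ids) == 0) return(0)
  n_d <- vapply(ids, function(d) {
    sum(vapply(sets, function(s) d %in% s, logical(1)))
  }, numeric(1))
  sum(1 - exp(lchoose(n - n_d, m) - lchoose(n, m)))
}

# Brute-force expectation by enumerating all C(N, m) subsets (tiny N only).
enumerate_expected_richness <- function(sets, m) {
  combs <- utils::combn(length(sets), m, simplify = FALSE)
  mean(vapply(combs, function(ix) length(unique(unlist(sets[ix]))),
              numeric(1)))
}

expect_curve_valid <- function(curve) {
  expect_s3_class(curve, "rarefaction_curve")
  expect_true(all(curve$lower95 <= curve$mean_richness + 1e-12))
  expect_true(all(curve$mean_richness <= curve$upper95 + 1e-12))
  expect_true(all(diff(curve$mean_richness) >= -1e-12))
}

# abundance tibble -> labelled matrix (test-local; mirrors nothing internal)
as_mat <- function(ab) {
  m <- as.matrix(ab[, setdiff(names(ab), "unit_id"), drop = FALSE])
  rownames(m) <- ab$unit_id
  m
}
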