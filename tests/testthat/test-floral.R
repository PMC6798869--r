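test_that("richness, Shannon and Pielou match closed forms", {
  expect_equal(richness(c(0, 0, 3)), 1)
  expect_equal(richness(integer()), 0)
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(rep(3, 10)), log(10))
  expect_equal(shannon(c(5, 3, 2)), 1.029653, tolerance = 1e-6)
  expect_equal(pielou(c(5, 3, 2)), 1.029653 / log(3), tolerance = 1e-6)
  expect_equal(pielou(c(4, 4, 4, 4)), 1)
  expect_error(richness(c(-1, 2)), class = "paleocensus_value_error")
  expect_error(shannon(c(0, 0)), class = "paleocensus_value_error")
  expect_error(pielou(c(9, 0)), class = "paleocensus_value_error")
})

test_that("shannon <= log(richness) with equality only for even counts", {
  set.seed(42)
  for (i in 1:25) {
    x <- rpois(sample(2:12, 1), lambda = sample(1:20, 1)) + 1L
    expect_lte(shannon(x), log(richness(x)) + 1e-12)
    if (length(unique(x)) > 1) {
      expect_lt(shannon(x), log(richness(x)))
    }
  }
})

test_that("rank abundance sorts by proportion with lexicographic ties", {
  ra <- rank_abundance(c(b = 20, a = 50, c = 30))
  expect_equal(ra$species_id, c("a", "c", "b"))
  expect_equal(ra$proportion, c(0.5, 0.3, 0.2))
  expect_equal(sum(ra$proportion), 1)
  # tie: equal counts ordered by id
  tie <- rank_abundance(c(zed = 5, ant = 5))
  expect_equal(tie$species_id, c("ant", "zed"))
  # single species
  expect_equal(rank_abundance(c(only = 7))$proportion, 1)
  # dominance fixture: 128 of 229 leaves
  dom <- rank_abundance(c(sp_dom = 128, sp_b = 60, sp_c = 41))
  expect_equal(dom$proportion[1], 128 / 229)
  expect_equal(round(dom$proportion[1], 3), 0.559)
  expect_error(rank_abundance(c(a = 0)), class = "paleocensus_value_error")
})

test_that("diversity_summary agrees with the scalar metrics per unit", {
  cen <- toy_census()
  ds <- diversity_summary(cen, by = "quarry")
  m <- as_mat(abundance_matrix(cen, "species", by = "quarry"))
  for (u in rownames(m)) {
    row <- ds[ds$unit_id == u, ]
    expect_equal(row$richness, richness(m[u, ]))
    expect_equal(row$shannon, shannon(m[u, ]))
  }
  # A.2 has a single identified species: J undefined -> NA
  expect_true(is.na(ds$pielou[ds$unit_id == "A.2"]))
})

test_that("species rarefaction reproduces enumeration and boundary cases", {
  # counts [2,1] at m = 2: three equally likely pairs -> E[S] = 5/3
  rc <- rarefy_species(c(sp1 = 2, sp2 = 1), sizes = 1:3,
                       n_resamples = 3000, seed = 7)
  expect_curve_valid(rc)
  expect_equal(rc$mean_richness[1], 1) # m = 1 always one species
  expect_equal(rc$mean_richness[2], 5 / 3,
               tolerance = 3 * rc$sd_richness[2] / sqrt(3000) / (5 / 3))
  sets <- list("sp1", "sp1", "sp2")
  expect_equal(enumerate_expected_richness(sets, 2), 5 / 3)
  # m = total: exactly observed richness, zero-width band
  expect_equal(rc$mean_richness[3], 2)
  expect_equal(rc$lower95[3], rc$upper95[3])
  expect_error(rarefy_species(c(a = 2), sizes = 5),
               class = "paleocensus_value_error")
})

test_that("Monte-Carlo means track the hypergeometric expectation", {
  counts <- c(a = 9, b = 5, c = 3, d = 1, e = 1)
  sets <- as.list(rep(names(counts), counts))
  rc <- rarefy_species(counts, sizes = c(2, 5, 10, 15),
                       n_resamples = 1500, seed = 3)
  for (i in seq_len(nrow(rc))) {
    expected <- hyper_expected_richness(sets, rc$size[i])
    se <- rc$sd_richness[i] / sqrt(1500)
    expect_lt(abs(rc$mean_richness[i] - expected), 3 * se + 1e-9)
  }
  # vegan's exact interpolator as a second, fully independent oracle
  expect_equal(hyper_expected_richness(sets, 10),
               unname(vegan::rarefy(counts, 10)[1]), tolerance = 1e-10)
})

test_that("rarefaction is seed-reproducible and permutation-invariant", {
  counts <- c(a = 4, b = 3, c = 2, d = 1)
  r1 <- rarefy_species(counts, sizes = c(2, 6), n_resamples = 400, seed = 11)
  r2 <- rarefy_species(counts, sizes = c(2, 6), n_resamples = 400, seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # permuting the counts vector does not change the curve distributionally;
  # with the same seed the draws are over leaf indices, so means must agree
  perm <- counts[c(3, 1, 4, 2)]
  r3 <- rarefy_species(perm, sizes = c(2, 6), n_resamples = 400, seed = 11)
  expect_equal(r3$mean_richness, r1$mean_richness, tolerance = 0.15)
  r4 <- rarefy_species(counts, sizes = c(2, 6), n_resamples = 400, seed = 12)
  expect_false(identical(r1$mean_richness, r4$mean_richness))
})
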