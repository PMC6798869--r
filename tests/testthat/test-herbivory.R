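reg <- toy_dt_registry()

leafset <- function(dts, tally = NULL, sp = NULL) {
  n <- length(dts)
  if (is.null(sp)) sp <- rep("sp1", n)
  if (is.null(tally)) tally <- rep(1L, n)
  tibble::tibble(
    specimen_id = sprintf("L%d", seq_len(n)),
    quarry_id = "Q", level_id = "A",
    morphospecies_id = sp,
    size_class = "UNKNOWN",
    dts = dts,
    tally_count = tally
  )
}

test_that("damage frequency counts leaves once per category", {
  # 2 damaged of 8 leaves
  lv <- leafset(c(list(c("DT1", "DT2"), "DT12"), rep(list(character()), 6)))
  expect_equal(damage_frequency(lv, reg, "total"), 0.25)
  expect_equal(damage_frequency(lv, reg, "generalized"), 1 / 8)
  expect_equal(damage_frequency(lv, reg, "specialized"), 1 / 8)
  # all undamaged
  lv0 <- leafset(rep(list(character()), 4))
  for (cat in c("total", "specialized", "generalized")) {
    expect_equal(damage_frequency(lv0, reg, cat), 0)
  }
  expect_error(damage_frequency(lv[0, ], reg),
               class = "paleocensus_value_error")
  bad <- leafset(list("DT99"))
  expect_error(damage_frequency(bad, reg),
               class = "paleocensus_mapping_error")
})

test_that("tally batches dilute the denominator and split-invariance holds", {
  batch <- leafset(list("DT1", character()), tally = c(1L, 9L))
  expect_equal(damage_frequency(batch, reg, "total"), 0.1)
  split <- leafset(c(list("DT1"), rep(list(character()), 9)))
  expect_equal(damage_frequency(split, reg, "total"),
               damage_frequency(batch, reg, "total"))
  # unidentified leaves are excluded from the denominator
  mixed <- leafset(list("DT1", character(), character()),
                   sp = c("sp1", "sp1", "UNIDENTIFIED"))
  expect_equal(damage_frequency(mixed, reg, "total"), 0.5)
})

test_that("specialized:generalized ratio handles degenerate denominators", {
  lv <- leafset(c(rep(list("DT12"), 3), rep(list("DT1"), 6),
                  rep(list(character()), 3)))
  expect_equal(spec_gen_ratio(lv, reg), 0.5)
  expect_equal(spec_gen_ratio(leafset(list("DT1", character())), reg), 0)
  expect_true(is.na(spec_gen_ratio(leafset(list("DT12")), reg)))
})

test_that("DT rarefaction matches exhaustive enumeration on 3 leaves", {
  sets <- list(c("DT1", "DT2"), "DT1", character())
  lv <- leafset(sets)
  rc <- rarefy_dts(lv, reg, "all", sizes = 1:3, n_resamples = 4000, seed = 2)
  expect_curve_valid(rc)
  expect_equal(enumerate_expected_richness(sets, 2), 5 / 3)
  expect_equal(rc$mean_richness[2], 5 / 3, tolerance = 0.05)
  # m = all leaves: observed richness, zero-width band
  expect_equal(rc$mean_richness[3], 2)
  expect_equal(rc$lower95[3], rc$upper95[3])
  # all-undamaged leaves give an identically zero curve
  rc0 <- rarefy_dts(leafset(rep(list(character()), 5)), reg, "all",
                    sizes = c(1, 3, 5), n_resamples = 100, seed = 1)
  expect_equal(rc0$mean_richness, c(0, 0, 0))
  expect_error(rarefy_dts(lv, reg, sizes = 10),
               class = "paleocensus_value_error")
})

test_that("DT Monte-Carlo means track the hypergeometric expectation", {
  set.seed(99)
  for (rep_i in 1:6) {
    n <- sample(6:12, 1)
    pool <- reg$dt_id
    sets <- purrr::map(seq_len(n), function(i) {
      if (runif(1) < 0.4) character() else
        sample(pool, sample(1:3, 1))
    })
    lv <- leafset(sets)
    sizes <- sort(sample(seq_len(n), 3))
    rc <- rarefy_dts(lv, reg, "all", sizes = sizes,
                     n_resamples = 1200, seed = rep_i)
    for (i in seq_along(sizes)) {
      expected <- hyper_expected_richness(sets, sizes[i])
      se <- rc$sd_richness[i] / sqrt(1200)
      expect_lt(abs(rc$mean_richness[i] - expected), 3 * se + 1e-9)
    }
  }
})

test_that("specialized filter never exceeds the unfiltered curve", {
  set.seed(7)
  sets <- purrr::map(1:30, function(i) {
    if (runif(1) < 0.5) character() else sample(reg$dt_id, sample(1:3, 1))
  })
  lv <- leafset(sets)
  sizes <- c(5, 15, 30)
  all_c <- rarefy_dts(lv, reg, "all", sizes, n_resamples = 500, seed = 4)
  spec_c <- rarefy_dts(lv, reg, "specialized", sizes, n_resamples = 500,
                       seed = 4)
  expect_true(all(spec_c$mean_richness <= all_c$mean_richness + 1e-12))
  expect_true(all(spec_c$upper95 <= all_c$upper95 + 1e-12))
})

test_that("per-host curves apply the 20-leaf threshold within a unit", {
  host_a <- leafset(rep(list("DT1"), 20), sp = rep("hostA", 20))
  host_b <- leafset(rep(list(character()), 19), sp = rep("hostB", 19))
  host_b$specimen_id <- sprintf("M%d", 1:19)
  cen <- census(dplyr::bind_rows(host_a, host_b), dts = reg)
  curves <- per_host_curves(cen, "A", sizes = c(5, 10), n_resamples = 50)
  expect_equal(names(curves), "hostA") # 19 leaves -> excluded, 20 -> included
  expect_s3_class(curves$hostA, "rarefaction_curve")

  # a shared host censused at two levels yields two comparable curves
  two <- dplyr::bind_rows(
    leafset(rep(list("DT1"), 25), sp = rep("shared", 25)),
    within_level_b <- {
      b <- leafset(rep(list("DT2"), 25), sp = rep("shared", 25))
      b$quarry_id <- "Q2"; b$level_id <- "B"
      b$specimen_id <- sprintf("N%d", 1:25); b
    })
  cen2 <- census(two, dts = reg)
  c_a <- per_host_curves(cen2, "A", sizes = c(5, 20), n_resamples = 50)
  c_b <- per_host_curves(cen2, "B", sizes = c(5, 20), n_resamples = 50)
  expect_equal(names(c_a), "shared")
  expect_equal(names(c_b), "shared")
})

test_that("damage_summary satisfies the category inequalities", {
  cfg <- simulation_config(c(U1 = 250, U2 = 250), damage_prob = 0.3,
                           seed = 21)
  cen <- generate_census(cfg)
  ds <- damage_summary(cen)
  expect_true(all(ds$freq_specialized <= ds$freq_total))
  expect_true(all(ds$freq_generalized <= ds$freq_total))
  expect_true(all(ds$freq_total <=
                    ds$freq_specialized + ds$freq_generalized + 1e-12))
})
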