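ab_from_matrix <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(unit_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("euclidean distances satisfy metric identities", {
  m <- rbind(u1 = c(0, 0), u2 = c(3, 4), u3 = c(0, 0))
  ab <- ab_from_matrix(m)
  d <- as.matrix(distance_matrix(ab))
  expect_equal(d["u1", "u2"], 5)
  expect_equal(d["u1", "u3"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # column permutation leaves distances unchanged
  ab_perm <- ab[, c("unit_id", "V2", "V1")]
  expect_equal(as.matrix(distance_matrix(ab_perm)), d)
  expect_error(distance_matrix(ab[1, ]), class = "paleocensus_value_error")
})

test_that("natively embeddable configurations reach near-zero stress", {
  m <- cbind(x = c(0, 1, 2, 5), pad = 0)
  rownames(m) <- paste0("u", 1:4)
  fit <- nmds(distance_matrix(ab_from_matrix(m)), k = 2, n_restarts = 5,
              seed = 2)
  expect_lt(fit$stress, 1e-6)
  # site scores centred
  expect_equal(colMeans(as.matrix(fit$site_scores[, -1])),
               c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
})

test_that("duplicated units receive coincident scores", {
  set.seed(5)
  m <- matrix(rpois(5 * 8, 6), nrow = 5,
              dimnames = list(paste0("u", 1:5), paste0("sp", 1:8)))
  m[5, ] <- m[4, ]
  fit <- nmds(distance_matrix(ab_from_matrix(m)), k = 2, n_restarts = 10,
              seed = 9)
  sc <- as.matrix(fit$site_scores[, -1])
  expect_lt(sqrt(sum((sc[4, ] - sc[5, ])^2)),
            1e-3 * max(1, max(abs(sc))))
})

test_that("stress is invariant under orthogonal transforms of the scores", {
  # stress depends only on interpoint distances; rotating/reflecting a
  # recovered configuration must reproduce the same stress when refit from
  # the transformed configuration's distances
  set.seed(31)
  pts <- matrix(rnorm(6 * 2), ncol = 2,
                dimnames = list(paste0("u", 1:6), NULL))
  d <- dist(pts)
  theta <- runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  refl <- diag(c(1, -1))
  for (tr in list(rot, rot %*% refl)) {
    d2 <- dist(pts %*% tr)
    expect_equal(as.vector(d2), as.vector(d), tolerance = 1e-12)
  }
  fit <- nmds(d, k = 2, n_restarts = 5, seed = 1)
  fit2 <- nmds(dist(pts %*% rot), k = 2, n_restarts = 5, seed = 1)
  expect_equal(fit$stress, fit2$stress, tolerance = 1e-6)
})

test_that("more restarts never increase the best stress", {
  set.seed(77)
  m <- matrix(rpois(6 * 20, 4), nrow = 6,
              dimnames = list(paste0("u", 1:6), paste0("v", 1:20)))
  d <- distance_matrix(ab_from_matrix(m))
  s1 <- nmds(d, n_restarts = 1, seed = 5)$stress
  s5 <- nmds(d, n_restarts = 5, seed = 5)$stress
  s20 <- nmds(d, n_restarts = 20, seed = 5)$stress
  expect_lte(s5, s1 + 1e-12)
  expect_lte(s20, s5 + 1e-12)
})

test_that("planar point clouds are recovered up to Procrustes alignment", {
  set.seed(12)
  for (i in 1:3) {
    pts <- matrix(rnorm(8 * 2), ncol = 2,
                  dimnames = list(paste0("u", 1:8), NULL))
    fit <- nmds(dist(pts), k = 2, n_restarts = 10, seed = i)
    proc <- vegan::procrustes(pts, as.matrix(fit$site_scores[, -1]),
                              symmetric = FALSE, scale = TRUE)
    per_point <- sqrt(rowSums((stats::fitted(proc) - pts)^2))
    expect_lt(mean(per_point), 1e-3)
  }
})

test_that("k >= number of units is rejected", {
  m <- rbind(u1 = c(1, 2), u2 = c(3, 4))
  expect_error(nmds(distance_matrix(ab_from_matrix(m)), k = 2),
               class = "paleocensus_value_error")
})

test_that("variable scores are abundance-weighted site averages", {
  m <- rbind(u1 = c(spA = 4, spB = 2, spC = 0, spD = 1),
             u2 = c(spA = 0, spB = 2, spC = 0, spD = 1),
             u3 = c(spA = 0, spB = 0, spC = 0, spD = 1))
  ab <- ab_from_matrix(m)
  sites <- tibble::tibble(unit_id = c("u1", "u2", "u3"),
                          NMDS1 = c(1, -1, 3), NMDS2 = c(2, 0, -2))
  vs <- variable_scores(sites, ab)
  # only in u1 -> u1's score
  expect_equal(unlist(vs[vs$variable == "spA", c("NMDS1", "NMDS2")]),
               c(NMDS1 = 1, NMDS2 = 2))
  # equal in u1 and u2 -> midpoint
  expect_equal(unlist(vs[vs$variable == "spB", c("NMDS1", "NMDS2")]),
               c(NMDS1 = 0, NMDS2 = 1))
  # uniform across all units -> centroid
  expect_equal(unlist(vs[vs$variable == "spD", c("NMDS1", "NMDS2")]),
               c(NMDS1 = 1, NMDS2 = 0))
  # absent everywhere -> flagged, NA coordinates
  expect_false(vs$placed[vs$variable == "spC"])
  expect_true(is.na(vs$NMDS1[vs$variable == "spC"]))
})

test_that("tidy and glance expose scores and fit statistics", {
  set.seed(2)
  m <- matrix(rpois(5 * 10, 5), nrow = 5,
              dimnames = list(paste0("u", 1:5), paste0("v", 1:10)))
  fit <- nmds(distance_matrix(ab_from_matrix(m)), seed = 8)
  td <- tidy(fit)
  expect_equal(names(td), c("unit_id", "NMDS1", "NMDS2"))
  gl <- glance(fit)
  expect_equal(gl$stress, fit$stress)
  expect_true(is.logical(gl$converged))
})
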