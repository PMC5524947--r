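test_that("clusterability alpha matches hand values and its invariances", {
  c1 <- symmetry_group("C1")
  same <- list(directions = rbind(c(0, 0, 1))[rep(1, 7), ], weights = rep(0.8, 7))
  expect_equal(clusterability_alpha(same, c1), 0)

  ortho <- list(directions = rbind(c(1, 0, 0), c(0, 1, 0)), weights = c(1, 1))
  expect_equal(clusterability_alpha(ortho, c1), pi / 2)

  set.seed(31)
  ms <- random_matchset(5)
  a <- clusterability_alpha(ms, c1)
  # permutation of entries
  perm <- sample(5)
  expect_equal(clusterability_alpha(list(directions = ms$directions[perm, ],
                                         weights = ms$weights[perm]), c1),
               a, tolerance = 1e-12)
  # common positive rescaling of weights
  expect_equal(clusterability_alpha(list(directions = ms$directions,
                                         weights = 17.3 * ms$weights), c1),
               a, tolerance = 1e-12)
  expect_error(clusterability_alpha(list(directions = ms$directions[1, , drop = FALSE],
                                         weights = 1), c1), "at least 2")
  expect_error(clusterability_alpha(list(directions = ms$directions,
                                         weights = rep(0, 5)), c1), "degenerate")
})

test_that("alpha and chi agree with brute-force double-loop oracles", {
  set.seed(32)
  for (sym in list(symmetry_group("C1"), symmetry_group("C3"))) {
    for (i in 1:25) {
      ms <- random_matchset(7)
      expect_equal(clusterability_alpha(ms, sym),
                   brute_alpha(ms$directions, ms$weights, sym),
                   tolerance = 1e-12)
      p_hat <- random_unit_vectors(1)[1, ]
      expect_equal(accuracy_chi(p_hat, ms, sym),
                   brute_chi(p_hat, ms$directions, ms$weights, sym),
                   tolerance = 1e-12)
    }
  }
})

test_that("duplicating the most central match never increases alpha", {
  # the duplicate adds mass at zero distance plus pairs at the duplicated
  # match's mean distance; for the match with minimal weighted mean distance
  # to the rest that mean is <= alpha, so alpha cannot grow
  set.seed(33)
  c1 <- symmetry_group("C1")
  for (i in 1:50) {
    ms <- random_matchset(6)
    D <- cryoval:::geodesic_cross(ms$directions, ms$directions, c1)
    mdist <- vapply(1:6, function(k)
      sum(ms$weights[-k] * D[k, -k]) / sum(ms$weights[-k]), numeric(1))
    j <- which.min(mdist)
    aug <- list(directions = rbind(ms$directions, ms$directions[j, ]),
                weights = c(ms$weights, ms$weights[j]))
    expect_lte(clusterability_alpha(aug, c1),
               clusterability_alpha(ms, c1) + 1e-12)
  }
})

test_that("accuracy chi handles the trivial geometries", {
  c1 <- symmetry_group("C1")
  p <- c(0, 0, 1)
  ms <- list(directions = rbind(p)[rep(1, 4), ], weights = c(1, 0.5, 0.3, 0.2))
  expect_equal(accuracy_chi(p, ms, c1), 0)
  d60 <- euler_to_direction(0, 60)
  expect_equal(accuracy_chi(p, list(directions = rbind(d60), weights = 0.42), c1),
               pi / 3, tolerance = 1e-12)
  expect_error(accuracy_chi(p, list(directions = rbind(d60), weights = 0), c1),
               "degenerate")
})

test_that("noise references are reproducible and symmetry-ordered", {
  a1 <- noise_alpha_reference(7, 100, seed = 41)
  a2 <- noise_alpha_reference(7, 100, seed = 41)
  expect_identical(as.numeric(a1), as.numeric(a2))

  p <- euler_to_direction(40, 70)
  x1 <- noise_chi_reference(p, 7, 100, seed = 42)
  expect_identical(as.numeric(x1),
                   as.numeric(noise_chi_reference(p, 7, 100, seed = 42)))
  expect_gt(as.numeric(x1), 0)
  expect_lt(as.numeric(x1), pi)

  # smaller asymmetric unit shrinks the reference distances
  c1 <- symmetry_group("C1"); c2 <- symmetry_group("C2")
  m1 <- vapply(1:20, function(s) as.numeric(noise_alpha_reference(7, 100, c1, s)),
               numeric(1))
  m2 <- vapply(1:20, function(s) as.numeric(noise_alpha_reference(7, 100, c2, s)),
               numeric(1))
  expect_lt(mean(m2), mean(m1))
})

test_that("quality scores are the exact two-point linear maps", {
  expect_equal(precision_score(1.5, 0.3, 1.5), 0)
  expect_equal(precision_score(0.3, 0.3, 1.5), 1)
  expect_equal(precision_score(0.9, 0.3, 1.5), 0.5)
  expect_equal(accuracy_score(1.5, 0.3, 1.5), 0)
  expect_equal(accuracy_score(0.3, 0.3, 1.5), 1)

  set.seed(43)
  for (i in 1:100) {
    refs <- sort(runif(2, 0, pi)); x <- runif(1, -1, 4)
    oracle <- (x - refs[2]) / (refs[1] - refs[2])   # line through the 2 points
    expect_equal(precision_score(x, refs[1], refs[2]), oracle, tolerance = 1e-12)
    expect_equal(accuracy_score(x, refs[1], refs[2]), oracle, tolerance = 1e-12)
  }
  # exact linearity: q(a) + q(b) = 2 q((a+b)/2)
  a <- runif(50); b <- runif(50)
  expect_equal(precision_score(a, 0.2, 1.4) + precision_score(b, 0.2, 1.4),
               2 * precision_score((a + b) / 2, 0.2, 1.4), tolerance = 1e-12)
  # degenerate references are flagged, not extrapolated
  expect_true(is.na(precision_score(0.5, 1.0, 1.0 + 1e-10)))
})

test_that("Q value and pruning are consistent and monotone", {
  sc <- data.frame(q_p = c(1, 0.6, 0.9, 0.2), q_a = c(1, 0.4, 0.8, 0.9))
  expect_equal(q_value(sc, 0.5), 50)
  expect_identical(prune(sc, 0.5), c(1L, 3L))
  expect_equal(q_value(data.frame(q_p = rep(1, 4), q_a = rep(1, 4))), 100)
  expect_equal(q_value(data.frame(q_p = rep(0, 4), q_a = rep(0, 4)), 0.5), 0)
  expect_equal(q_value(data.frame(q_p = c(1, 1, 1, 0), q_a = c(1, 1, 1, 0))), 75)
  expect_error(q_value(data.frame(q_p = numeric(), q_a = numeric())), "empty")

  set.seed(44)
  sc2 <- data.frame(q_p = rnorm(200, 0.5, 0.5), q_a = rnorm(200, 0.5, 0.5))
  taus <- seq(-0.5, 1.5, by = 0.1)
  qs <- vapply(taus, function(t) q_value(sc2, t), numeric(1))
  expect_true(all(diff(qs) <= 0))
  # selection size matches Q at the same tau
  for (t in c(0.2, 0.5, 0.8))
    expect_equal(100 * length(prune(sc2, t)) / nrow(sc2), q_value(sc2, t))
  expect_identical(prune(sc2, -Inf), seq_len(200))
  expect_identical(length(prune(sc2, max(sc2$q_p, sc2$q_a) + 1)), 0L)

  # NA scores (degenerate references) count as failing
  sc3 <- data.frame(q_p = c(1, NA), q_a = c(1, 1))
  expect_equal(q_value(sc3, 0.5), 50)
})
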