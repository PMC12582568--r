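test_that("inverse-distance features match a brute-force distance oracle", {
  # two atoms 2 apart: 1/d = 0.5, invariant under pair order
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, 1] <- 2
  expect_equal(as.numeric(inverse_distance_features(coords, cbind(1, 2))), 0.5)
  expect_equal(unname(inverse_distance_features(coords, cbind(2, 1))[1, 1]),
               unname(inverse_distance_features(coords, cbind(1, 2))[1, 1]))
  # random 5-atom frames, all 10 pairs, against direct recomputation
  set.seed(8)
  coords <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  pairs <- t(combn(5, 2))
  fm <- inverse_distance_features(coords, pairs)
  for (t in 1:4) for (p in seq_len(nrow(pairs))) {
    d <- sqrt(sum((coords[t, pairs[p, 1], ] - coords[t, pairs[p, 2], ])^2))
    expect_equal(unname(fm[t, p]), 1 / d)
  }
  coords[2, 3, ] <- coords[2, 1, ]
  expect_error(inverse_distance_features(coords, pairs), "frame 2")
})

test_that("coordination number switching function hits its exact values", {
  expect_equal(coordination_number(1e-12), 1, tolerance = 1e-9)
  expect_equal(coordination_number(4.5), 0.5, tolerance = 1e-12)
  expect_equal(coordination_number(9), 255 / 65535, tolerance = 1e-12)
  # additivity over pairs and frames
  m <- matrix(c(4.5, 9, 9, 4.5), 2)
  expect_equal(coordination_number(m), rep(0.5 + 255 / 65535, 2),
               tolerance = 1e-12)
})

test_that("tICA recovers autocorrelation structure and slow directions", {
  set.seed(4)
  # 1-D case: single component, eigenvalue equals the lag autocorrelation
  n <- 5000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  tm <- fit_tica(matrix(x, ncol = 1), lag = 2)
  xc <- x - mean(x)
  ac <- mean(head(xc, -2) * tail(xc, -2)) /
    (0.5 * (mean(head(xc, -2)^2) + mean(tail(xc, -2)^2)))
  expect_equal(tm$eigenvalues[1], ac, tolerance = 1e-6)
  # slow coordinate mixed with white noise: top tIC aligns with the slow one
  slow <- as.numeric(stats::arima.sim(list(ar = 0.98), n))
  feats <- cbind(slow + 0.1 * rnorm(n), rnorm(n), rnorm(n))
  tm2 <- fit_tica(feats, lag = 5)
  v <- tm2$components[, 1]
  cosine <- abs(v[1]) / sqrt(sum(v^2))
  expect_gt(cosine, 0.99)
  expect_true(all(tm2$eigenvalues <= 1 + 1e-8))
  # projection of the training mean is the zero vector
  expect_equal(as.numeric(predict(tm2, matrix(tm2$mean, 1))),
               rep(0, tm2$n_components), tolerance = 1e-10)
})

test_that("combined biased/unbiased tIC space concatenates both projections", {
  set.seed(12)
  f_u <- matrix(rnorm(600), ncol = 3)
  f_b <- matrix(rnorm(600), ncol = 3)
  m_u <- fit_tica(f_u, lag = 1)
  m_b <- fit_tica(f_b, lag = 1)
  comb <- combine_tics(m_u, m_b, f_u)
  expect_equal(ncol(comb), m_u$n_components + m_b$n_components)
  # identical models duplicate the block
  same <- combine_tics(m_u, m_u, f_u)
  expect_equal(same[, seq_len(m_u$n_components)],
               same[, m_u$n_components + seq_len(m_u$n_components)])
  expect_error(combine_tics(m_u, m_b, f_u[, 1:2]), "dimension mismatch")
})

test_that("k-means clustering is exact on separated data and idempotent", {
  set.seed(3)
  blob1 <- matrix(rnorm(100, 0, 0.2), ncol = 2)
  blob2 <- matrix(rnorm(100, 5, 0.2), ncol = 2)
  x <- rbind(blob1, blob2)
  cm <- cluster_kmeans(x, k = 2, seed = 7)
  lab <- assign_states(cm, x)
  expect_length(unique(lab[1:50]), 1)
  expect_length(unique(lab[51:100]), 1)
  expect_false(lab[1] == lab[51])
  # k = number of distinct points: inertia 0
  pts <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  cm0 <- cluster_kmeans(pts, k = 3, seed = 1)
  expect_equal(cm0$inertia, 0)
  expect_identical(sort(assign_states(cm0, pts)), 0:2)
  # idempotent assignment
  expect_identical(assign_states(cm, x), lab)
  expect_error(cluster_kmeans(x, k = 0, seed = 1), "at least 1")
})

test_that("k-means inertia is non-increasing in the number of restarts", {
  set.seed(9)
  x <- matrix(rnorm(400), ncol = 2)
  inertias <- vapply(c(1, 3, 6), function(r)
    cluster_kmeans(x, k = 5, seed = 5, n_restarts = r)$inertia, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
})

test_that("bias matrix assembly follows the harmonic umbrella formula", {
  wins <- make_umbrella_set(c(-0.5, 0.5), 10)
  states <- list(c(0L, 1L), c(1L, 0L), c(0L, 0L))
  cvs <- list(c(-0.5, 0.2), c(0.5, -0.1), c(0, 1))
  md <- assemble_multi_ensemble(states, c(0L, 1L, 2L), wins, cvs)
  # at a window center the bias vanishes
  expect_equal(md$bias[3, 3], 10 * (0.5 - 0.5)^2 / 2)
  expect_equal(md$bias[1, 2], 10 * (-0.5 - (-0.5))^2 / 2)
  # unbiased column is identically zero
  expect_true(all(md$bias[, 1] == 0))
  # frame alignment contract
  expect_length(md$state, 6)
  expect_length(md$ensemble, 6)
  expect_equal(nrow(md$bias), 6)
  # kcal/mol force constant at 300 K: c = 10 kcal/mol, x - y = 1 A
  w1 <- make_umbrella_set(0, 10)
  md2 <- assemble_multi_ensemble(list(0L), 1L, w1, list(1), kT = kt_in_kcal())
  expect_equal(md2$bias[1, 2], 10 / (2 * 0.59616), tolerance = 1e-4)
  expect_error(
    assemble_multi_ensemble(states, c(0L, 1L, 3L), wins, cvs),
    "lacking a window")
})
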