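test_that("macrostate frame sampling follows the stationary weights", {
  # single positive-weight frame: all draws identical
  we <- sample_macrostate_frames(c(0, 1, 0), c(10L, 20L, 30L), n = 50,
                                 seed = 4)
  expect_true(all(we$frames == 20L))
  expect_equal(sum(we$weights), 1)
  # two frames with weights (0.9, 0.1): empirical ratio within 3 sigma
  big <- sample_macrostate_frames(c(0.9, 0.1), c(1L, 2L), n = 1e5, seed = 8)
  p_hat <- mean(big$frames == 1L)
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / 1e5))
  # deterministic per seed
  expect_identical(
    sample_macrostate_frames(c(0.3, 0.7), 1:2, n = 100, seed = 12)$frames,
    sample_macrostate_frames(c(0.3, 0.7), 1:2, n = 100, seed = 12)$frames)
  expect_error(sample_macrostate_frames(c(0, 0), 1:2, seed = 1), "zero")
})

test_that("symmetric K-L divergence: identity, swap symmetry, Gaussian closed form", {
  set.seed(31)
  a <- matrix(rnorm(4e4), ncol = 2)
  # identical ensembles: divergence vanishes up to pseudocount epsilon
  d0 <- kl_per_residue(a, a)
  expect_true(all(d0$per_feature < 1e-6))
  expect_true(all(d0$per_feature >= 0))
  # swapping the ensembles leaves the profile unchanged
  b <- matrix(rnorm(4e4, 0.5), ncol = 2)
  expect_equal(kl_per_residue(a, b)$per_feature,
               kl_per_residue(b, a)$per_feature, tolerance = 1e-12)
  # N(0,1) vs N(1,1): D_sym = (mu difference)^2 / (2 sigma^2) = 0.5
  x <- matrix(rnorm(2e5), ncol = 1)
  y <- matrix(rnorm(2e5, 1), ncol = 1)
  dsym <- kl_per_residue(x, y, n_bins = 50)$per_feature
  expect_lt(abs(dsym - 0.5) / 0.5, 0.1)
  # per-residue aggregation sums the features mapped to each residue
  d2 <- kl_per_residue(a, b, residue_map = list(r1 = 1:2, r2 = 2))
  expect_equal(unname(d2$per_residue["r1"]), sum(d2$per_feature))
  expect_equal(unname(d2$per_residue["r2"]), d2$per_feature[2],
               ignore_attr = TRUE)
})

test_that("weighted event probabilities and the triad indicator behave exactly", {
  expect_equal(weighted_event_probability(c(TRUE, TRUE), c(2, 3)), 1)
  expect_equal(
    weighted_event_probability(c(TRUE, FALSE, FALSE), c(0.5, 0.25, 0.25)),
    0.5)
  # rescaling invariance
  expect_equal(
    weighted_event_probability(c(TRUE, FALSE), c(1, 3)),
    weighted_event_probability(c(TRUE, FALSE), c(10, 30)))
  expect_error(weighted_event_probability(TRUE, c(1, 2)), "same length")
  # strict < on all three distances at the 5 A threshold
  expect_false(triad_indicator(4.9, 4.9, 5.1))
  expect_false(triad_indicator(5, 4, 4))
  expect_true(triad_indicator(4.9, 4.9, 4.999))
})

test_that("trajectory bootstrap reports per-replicate estimates faithfully", {
  trajs <- lapply(1:20, function(i) rep(i, 5))
  # fraction 1: identical replicates, sd 0
  b1 <- bootstrap_errors(function(tr) mean(unlist(tr)), trajs,
                         n_boot = 3, fraction = 1, seed = 2)
  expect_equal(unname(b1$sd), 0)
  # constant estimator: sd 0 regardless of resampling
  b2 <- bootstrap_errors(function(tr) 7, trajs, n_boot = 4,
                         fraction = 0.8, seed = 3)
  expect_equal(unname(b2$sd), 0)
  expect_equal(unname(b2$mean), 7)
  # linear estimator: replicates match direct recomputation on each subset
  b3 <- bootstrap_errors(function(tr) sum(unlist(tr)), trajs,
                         n_boot = 3, fraction = 0.9, seed = 5)
  expect_equal(nrow(b3$replicates), 3)
  expect_true(all(b3$replicates <= sum(unlist(trajs))))
  # failures are excluded and counted
  flaky <- function(tr) if (length(tr) && tr[[1]][1] == 1) stop("bad") else 1
  b4 <- bootstrap_errors(flaky, trajs, n_boot = 6, fraction = 0.5, seed = 9)
  expect_equal(nrow(b4$replicates) + b4$failed, 6)
})

test_that("contact probabilities count weighted sub-cutoff frames", {
  d <- matrix(c(3, 6, 4, 5, 2, 7), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("p1", "p2")))
  expect_equal(unname(contact_probability(d, cutoff = 1)), c(0, 0))
  expect_equal(unname(contact_probability(d, cutoff = 100)), c(1, 1))
  # manual enumeration at cutoff 4.5 with uniform weights
  expect_equal(unname(contact_probability(d, cutoff = 4.5)),
               c(mean(d[, 1] < 4.5), mean(d[, 2] < 4.5)))
  # weighted version
  w <- c(0.5, 0.25, 0.25)
  expect_equal(unname(contact_probability(d, 4.5, w))[1],
               sum(w[d[, 1] < 4.5]))
})

test_that("dihedral mutual information: self, null, Gaussian closed form, symmetry", {
  set.seed(71)
  n <- 1e5
  x <- rnorm(n) * pi / 6 # 6-sigma range stays inside (-pi, pi]
  # self-information equals the (corrected) marginal entropy estimate
  expect_equal(mutual_information_dihedrals(x, x),
               local({
                 breaks <- seq(-pi, pi, length.out = 31)
                 p <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                               30) / n
                 p <- p[p > 0]
                 -sum(p * log(p)) + (length(p) - 1) / (2 * n)
               }),
               tolerance = 1e-10)
  # independent series: below the bias-corrected null threshold
  y_ind <- rnorm(n) * pi / 6
  expect_lt(mutual_information_dihedrals(x, y_ind), 0.02)
  # correlated Gaussians: MI = -0.5 ln(1 - rho^2) = 0.830 nats at rho = 0.9
  rho <- 0.9
  y <- rho * (x / (pi / 6)) + sqrt(1 - rho^2) * rnorm(n)
  y <- y * pi / 6
  mi <- mutual_information_dihedrals(x, y)
  expect_lt(abs(mi - 0.8304) / 0.8304, 0.1)
  # symmetry and the shuffled null
  expect_equal(mutual_information_dihedrals(x, y),
               mutual_information_dihedrals(y, x), tolerance = 1e-12)
  expect_lt(mutual_information_dihedrals(x, sample(y)), 0.02)
  expect_warning(mutual_information_dihedrals(rep(0, 100), rnorm(100)),
                 "constant")
})
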