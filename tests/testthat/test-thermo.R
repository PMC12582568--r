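test_that("weighted PMF: flat case, rescaling invariance, harmonic recovery", {
  set.seed(6)
  # uniform weights on uniform occupancy: flat W = 0
  x <- rep(seq(-0.95, 0.95, by = 0.1), times = 10)
  g <- weighted_pmf(x, rep(1, length(x)), seq(-1, 1, by = 0.1))
  expect_equal(as.numeric(g$W), rep(0, 20), tolerance = 1e-12)
  # doubling all weights changes nothing
  g2 <- weighted_pmf(x, rep(2, length(x)), seq(-1, 1, by = 0.1))
  expect_equal(g$W, g2$W)
  # Boltzmann weights on a harmonic potential recover the parabola
  kappa <- 4
  xs <- seq(-1.5, 1.5, length.out = 4001)
  w <- exp(-0.5 * kappa * xs^2)
  edges <- seq(-1.5, 1.5, length.out = 61)
  gh <- weighted_pmf(xs, w, edges)
  mid <- (head(edges, -1) + tail(edges, -1)) / 2
  ref <- 0.5 * kappa * mid^2
  ref <- ref - min(ref)
  expect_lt(mean(abs(gh$W - ref)), 0.05)
  # frames outside the grid are dropped and counted
  gd <- weighted_pmf(c(x, 5), rep(1, length(x) + 1), seq(-1, 1, by = 0.1))
  expect_equal(gd$n_dropped, 1)
})

test_that("bulk depth policies average the intended bins", {
  x <- seq(-0.95, 0.95, by = 0.1)
  g <- weighted_pmf(x, rep(1, 20), seq(-1, 1, by = 0.1))
  # perfectly flat bulk: every policy returns the plateau value
  expect_equal(bulk_depth(g, rep(TRUE, 20), n_bins = 5), 0)
  expect_equal(bulk_depth(g, rep(TRUE, 20), n_bins = 5, policy = "highest"), 0)
  # noisy bulk with the all-bins policy: plain average
  gn <- weighted_pmf(x, exp(seq(0, 1, length.out = 20)),
                     seq(-1, 1, by = 0.1))
  mask <- rep(TRUE, 20)
  expect_equal(bulk_depth(gn, mask, policy = "all"),
               mean(gn$W[is.finite(gn$W)]))
  # single-bin mask returns that bin's value
  m1 <- c(TRUE, rep(FALSE, 19))
  expect_equal(bulk_depth(gn, m1, n_bins = 1), gn$W[1])
  expect_error(bulk_depth(g, rep(FALSE, 20)), "no finite bulk")
})

test_that("standard binding dG: identity, unit-volume cases, Gaussian-trap oracle", {
  # single bound bin of volume V_o with W = 0 and dW = 0 collapses to 0
  side <- 1661^(1 / 3)
  g1 <- weighted_pmf(matrix(0, 2, 3), c(1, 1),
                     lapply(1:3, function(d) c(-side / 2, side / 2)))
  b1 <- standard_binding_dG(g1, delta_W = 0, V_o = 1661)
  expect_equal(b1$dG_kt, 0, tolerance = 1e-12)
  expect_equal(b1$dG_V, 0) # V_u defaults to V_o
  # decomposition identity holds exactly with an explicit V_u
  b2 <- standard_binding_dG(g1, delta_W = 0.7, V_o = 1661, V_u = 5e4)
  expect_identical(b2$dG_kt, b2$dG_pmf + b2$dG_V)
  expect_equal(b2$dG_V, -log(5e4 / 1661))
  # 3-D harmonic trap against the restricted Gaussian integral (quadrature)
  kap <- 2
  thr <- kcal_to_kt(1)
  edges3 <- lapply(1:3, function(d) seq(-4, 4, length.out = 41))
  mids <- lapply(edges3, function(e) (head(e, -1) + tail(e, -1)) / 2)
  pts <- as.matrix(expand.grid(mids[[1]], mids[[2]], mids[[3]]))
  w <- exp(-0.5 * kap * rowSums(pts^2))
  pmf <- weighted_pmf(pts, w, edges3)
  bfe <- standard_binding_dG(pmf, delta_W = 0, V_o = 1661,
                             bound_threshold = thr)
  # closed form: Gaussian configurational integral restricted to U < thr
  G_restricted <- (2 * pi / kap)^1.5 * stats::pgamma(thr, 3 / 2)
  expect_lt(abs(bfe$dG_kt - (-log(G_restricted / 1661))), 0.15)
  expect_error(standard_binding_dG(pmf, 0, bound_threshold = -5), "no bound")
})

test_that("metadynamics bias evaluation is exact, additive and order-free", {
  h <- hills_log(time = 1, center = 0.3, width = 0.2, height = 0.7)
  expect_equal(metad_bias(h, 0.3), 0.7)
  expect_lt(metad_bias(h, 0.3 + 10 * 0.2), 1e-20 * 0.7)
  # two hills at distance sigma: 0.4 e^{-1/2} + 0.2 e^{-1/2}
  h2 <- hills_log(time = c(1, 2), center = c(0, 0), width = 0.5,
                  height = c(0.4, 0.2))
  expect_equal(metad_bias(h2, 0.5), 0.6 * exp(-0.5), tolerance = 1e-12)
  # additive in hills, independent of deposition order
  h2r <- hills_log(time = c(2, 1), center = c(0, 0), width = 0.5,
                   height = c(0.2, 0.4))
  expect_identical(metad_bias(h2, 0.5), metad_bias(h2r, 0.5))
  expect_equal(metad_bias(h2, 0.5, up_to_time = 1), 0.4 * exp(-0.5))
})

test_that("hills logs round-trip through their text serialization", {
  h <- hills_log(time = c(10, 20, 30), center = cbind(c(0, 0.5, -0.2)),
                 width = 0.15, height = c(0.4, 0.35, 0.3),
                 bias_factor = 10)
  f <- tempfile(fileext = ".tsv")
  write_hills(h, f)
  h2 <- read_hills(f)
  expect_equal(h2$time, h$time)
  expect_equal(h2$center, h$center, ignore_attr = TRUE)
  expect_equal(h2$height, h$height)
  expect_equal(h2$bias_factor, 10)
  unlink(f)
})

test_that("free-energy reconstruction applies the well-tempered prefactor", {
  # zero hills: flat zero profile
  h0 <- hills_log(time = numeric(0), center = matrix(numeric(0), ncol = 1),
                  width = matrix(numeric(0), ncol = 1), height = numeric(0),
                  bias_factor = 10)
  expect_equal(metad_free_energy(h0, seq(-1, 1, 0.5)), rep(0, 5))
  # T = 300, dT = 4200: prefactor (T + dT)/dT = 1.0714 on -V_meta
  gamma <- (300 + 4200) / 300
  h1 <- hills_log(time = 1, center = 0, width = 0.5, height = 1,
                  bias_factor = gamma)
  fe <- metad_free_energy(h1, c(0, 100))
  # profile anchored at 0 far away; depth at the hill = prefactor * height
  expect_equal(fe[1] - fe[2], -(4500 / 4200) * 1, tolerance = 1e-6)
  expect_equal(4500 / 4200, 1.0714, tolerance = 1e-4)
  expect_error(metad_free_energy(h1, 0, bias_factor = 0.5), "bias factor")
})

test_that("final-bias reweighting recovers the Boltzmann density of a toy run", {
  pot <- potential_spec("double_well", h = 4)
  md <- metadynamics_params(hill_height = 0.5, hill_width = 0.15,
                            deposition_stride = 1000, bias_factor = 10)
  run <- simulate_wt_metadynamics(pot, md,
           langevin_params(timestep = 0.002, n_steps = 1.5e6, stride = 100,
                           seed = 23, x0 = -1), grid_range = c(-2.5, 2.5))
  # zero bias: uniform weights
  w0 <- metad_reweight(c(0.1, 0.2, 0.3),
                       hills_log(numeric(0), matrix(numeric(0), ncol = 1),
                                 matrix(numeric(0), ncol = 1), numeric(0)))
  expect_equal(w0, rep(1 / 3, 3))
  w <- metad_reweight(run$trajectory, run$hills)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # total-variation distance to the analytic Boltzmann histogram
  edges <- seq(-1.5, 1.5, length.out = 31)
  keep <- run$trajectory >= -1.5 & run$trajectory < 1.5
  acc <- tapply(w[keep], discretize_cv(run$trajectory[keep], edges), sum)
  p_est <- rep(0, 30)
  p_est[as.integer(names(acc)) + 1L] <- acc
  p_est <- p_est / sum(p_est)
  p_ref <- exp(-analytic_reference(pot, edges))
  p_ref <- p_ref / sum(p_ref)
  expect_lt(0.5 * sum(abs(p_est - p_ref)), 0.1)
})
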