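test_that("free diffusion obeys the Einstein relation for the MSD", {
  pot <- potential_spec("harmonic", kappa = 1e-12) # effectively flat
  n_steps <- 200L
  reps <- simulate_langevin(pot,
    langevin_params(timestep = 0.01, n_steps = n_steps, stride = 10,
                    seed = 11, x0 = rep(0, 5000)))
  # regression of MSD(t) on t through the origin: slope should be 2*D
  t_phys <- seq_len(nrow(reps)) * 0.01 * 10
  msd <- rowMeans(reps^2)
  slope <- sum(msd * t_phys) / sum(t_phys^2)
  expect_equal(slope, 2 * 1, tolerance = 0.05)
})

test_that("harmonic stationary variance matches 1/(beta*kappa) within 3 SE", {
  kappa <- 4
  dt <- 0.002
  x <- simulate_langevin(potential_spec("harmonic", kappa = kappa),
                         langevin_params(timestep = dt, n_steps = 1e6,
                                         stride = 1, seed = 21))
  x <- x[-seq_len(1000)] # discard equilibration
  # correlation time ~ 1/(kappa*D*dt) steps; conservative ESS estimate
  ess <- length(x) * kappa * dt / 2
  se <- 0.25 * sqrt(2 / ess)
  expect_lt(abs(var(x) - 1 / kappa), 3 * se + kappa * dt / 2 * 0.25)
})

test_that("the integrator is deterministic per seed and guards divergence", {
  pot <- potential_spec("double_well", h = 5)
  p <- langevin_params(timestep = 0.002, n_steps = 5000, stride = 5, seed = 3)
  expect_identical(simulate_langevin(pot, p), simulate_langevin(pot, p))
  # a huge timestep on a stiff potential must abort, not return garbage
  expect_error(
    simulate_langevin(pot, langevin_params(timestep = 50, n_steps = 1000,
                                           seed = 1, x0 = 1.4,
                                           domain_guard = 10)),
    "diverged")
})

test_that("generic (R-level) and compiled integrator paths agree in law", {
  # tabulated version of the same harmonic potential goes down the R path
  xs <- seq(-4, 4, length.out = 400)
  pot_tab <- potential_spec("tabulated", x = xs, u = 0.5 * 4 * xs^2)
  x <- simulate_langevin(pot_tab,
         langevin_params(timestep = 0.002, n_steps = 2e5, stride = 10,
                         seed = 5))
  expect_lt(abs(var(x[-(1:100)]) - 0.25), 0.03)
})

test_that("markov chain sampling: degenerate, analytic and biased cases", {
  # identity matrix: the chain never moves
  expect_identical(simulate_markov_chain(diag(3), 50, seed = 1,
                                         start_state = 1),
                   rep(0L, 50))
  # two-state chain with pi = (2/3, 1/3)
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  s <- simulate_markov_chain(T2, 1e6, seed = 42)
  p1 <- mean(s == 1L)
  se <- sqrt((1 / 3) * (2 / 3) / (1e6 / 10)) # ~10-step correlation time
  expect_lt(abs(p1 - 1 / 3), 3 * se)
  # zero bias reproduces the unbiased sequence exactly
  expect_identical(simulate_markov_chain(T2, 1000, seed = 9),
                   simulate_markov_chain(T2, 1000, seed = 9,
                                         state_bias = c(0, 0)))
  expect_error(simulate_markov_chain(matrix(c(1, 1, 0, 1), 2), 10, seed = 1),
               "row-stochastic")
})

test_that("square-root state-bias reweighting preserves detailed balance exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    en <- runif(4, 0, 3)
    T_mat <- metastable_bd_chain(en, base_rate = 0.25)
    b <- runif(4, -2, 2)
    Tb <- biased_chain(T_mat, b)
    pib <- bd_stationary(en + b)
    flux <- pib * Tb
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    expect_equal(rowSums(Tb), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("umbrella window ladders are validated and evenly spaced", {
  ws <- make_umbrella_set(c(-1, 0, 1), 20)
  expect_length(ws, 3)
  expect_identical(vapply(ws, `[[`, numeric(1), "ensemble_id"), c(1, 2, 3))
  expect_identical(make_umbrella_set(numeric(0), 20), list())
  centers <- seq(-1.5, 1.5, length.out = 21)
  expect_equal(unique(round(diff(centers), 10)), 0.15)
  expect_error(make_umbrella_set(c(0, 0, 1), 20), "strictly increasing")
})

test_that("zero-height hills reduce metadynamics to plain Langevin", {
  pot <- potential_spec("double_well", h = 3)
  lp <- langevin_params(timestep = 0.002, n_steps = 4000, stride = 4,
                        seed = 17, x0 = -1)
  md <- metadynamics_params(hill_height = 0, hill_width = 0.2,
                            deposition_stride = 500, bias_factor = 10)
  run <- simulate_wt_metadynamics(pot, md, lp)
  plain <- simulate_langevin(pot, lp)
  expect_identical(run$trajectory, plain)
  expect_true(all(run$hills$height == 0))
  expect_error(metadynamics_params(bias_factor = 1), "bias_factor")
})

test_that("well-tempered hill heights decay monotonically at a fixed CV value", {
  pot <- potential_spec("double_well", h = 3)
  md <- metadynamics_params(hill_height = 0.4, hill_width = 0.2,
                            deposition_stride = 250, bias_factor = 8)
  run <- simulate_wt_metadynamics(pot, md,
           langevin_params(timestep = 0.002, n_steps = 1e5, stride = 50,
                           seed = 31, x0 = -1))
  # the height that would be deposited at x = -1 decays as the bias fills in
  w_t <- md$hill_height *
    exp(-metad_bias(run$hills, matrix(-1), up_to_time = run$hills$time) /
          (md$bias_factor - 1))
  expect_true(all(diff(w_t) <= 1e-12))
  expect_gt(length(run$hills$time), 100)
})

test_that("analytic reference free energies match quadrature expectations", {
  edges <- seq(-1, 1, length.out = 11)
  flat <- potential_spec("tabulated", x = c(-2, 2), u = c(0, 0))
  expect_equal(analytic_reference(flat, edges), rep(0, 10), tolerance = 1e-10)
  # harmonic: narrow bins recover the parabola up to a constant
  kappa <- 4
  pot <- potential_spec("harmonic", kappa = kappa)
  fine <- seq(-1, 1, length.out = 201)
  f <- analytic_reference(pot, fine)
  mid <- (head(fine, -1) + tail(fine, -1)) / 2
  expect_lt(max(abs((f - min(f)) -
                      (0.5 * kappa * mid^2 - min(0.5 * kappa * mid^2)))),
            0.01)
  # symmetric double well is symmetric bin-by-bin
  dw <- potential_spec("double_well", h = 5)
  fdw <- analytic_reference(dw, seq(-1.5, 1.5, length.out = 31))
  expect_equal(fdw, rev(fdw), tolerance = 1e-8)
})
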