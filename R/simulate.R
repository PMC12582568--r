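#' Parameters for the Brownian-dynamics integrator
#'
#' Overdamped Langevin (Brownian) dynamics in reduced units: the estimators
#' downstream only require the correct stationary distribution and kinetic
#' structure, so inertial terms are deliberately omitted.
#'
#' @param timestep integration timestep (reduced time), > 0.
#' @param diffusion_coefficient diffusion constant D (reduced units), > 0.
#' @param n_steps number of integration steps.
#' @param stride save every `stride`-th step (>= 1).
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @param x0 starting coordinate(s); a vector starts one independent replica
#'   per element.
#' @param domain_guard abort if |x| exceeds this bound (divergence guard).
#' @return an object of class `langevin_params`.
#' @export
langevin_params <- function(timestep = 0.01, diffusion_coefficient = 1,
                            n_steps = 1000L, stride = 1L, seed = 1L,
                            x0 = 0, domain_guard = 1e3) {
  stopifnot(timestep > 0, diffusion_coefficient > 0, n_steps >= 1,
            stride >= 1, is.numeric(x0), domain_guard > 0)
  structure(list(timestep = timestep,
                 diffusion_coefficient = diffusion_coefficient,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = as.integer(seed), x0 = x0,
                 domain_guard = domain_guard),
            class = "langevin_params")
}

# map a potential_spec to the integrator's built-in force codes; returns NULL
# when no closed-form C-side gradient exists (tabulated, 2-D forms)
builtin_pot_code <- function(potential) {
  switch(potential$form,
    double_well = list(code = 1L,
                       par = c(potential$parameters$h,
                               potential$parameters$tilt %||% 0)),
    harmonic = list(code = 2L,
                    par = c(potential$parameters$kappa,
                            potential$parameters$x0 %||% 0)),
    NULL)
}

#' Simulate an overdamped Langevin trajectory on a model potential
#'
#' Euler-Maruyama update `x <- x - beta * D * grad(U + bias) * dt +
#' sqrt(2 D dt) * eta` with standard-normal noise.  The stationary density of
#' the discretized dynamics approaches `exp(-beta (U + bias))` as the
#' timestep shrinks.
#'
#' @param potential a [potential_spec()] (1-D forms for the fast path).
#' @param params a [langevin_params()].
#' @param bias optional bias: an `umbrella_window` (harmonic restraint) or a
#'   list with a `$gradient(x)` function (energies in kT).
#' @return numeric vector of saved frames, or a frames-by-replicas matrix
#'   when `params$x0` has length > 1.
#' @examples
#' pot <- potential_spec("harmonic", kappa = 4)
#' x <- simulate_langevin(pot, langevin_params(n_steps = 2000, seed = 7))
#' var(x)  # approaches 1/(beta*kappa) = 0.25 for long runs
#' @export
simulate_langevin <- function(potential, params, bias = NULL) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "langevin_params"))
  g0 <- potential$gradient(params$x0[1])
  if (any(!is.finite(g0)))
    stop("potential gradient not finite at the starting point")
  builtin <- builtin_pot_code(potential)
  bias_code <- 0L
  bias_par <- c(0, 0)
  bias_fun <- NULL
  if (!is.null(bias)) {
    if (inherits(bias, "umbrella_window")) {
      bias_code <- 1L
      bias_par <- c(bias$force_constant, bias$center)
    } else if (is.list(bias) && is.function(bias$gradient)) {
      bias_fun <- bias$gradient
    } else {
      stop("`bias` must be an umbrella_window or a list with a $gradient function")
    }
  }
  if (!is.null(builtin) && is.null(bias_fun)) {
    out <- with_seed(params$seed,
      langevin_cpp(as.numeric(params$x0), params$n_steps, params$timestep,
                   params$diffusion_coefficient, potential$beta,
                   params$stride, builtin$code, builtin$par,
                   bias_code, bias_par, params$domain_guard))
    return(if (ncol(out) == 1L) drop(out) else out)
  }
  # generic (R-level) path for tabulated potentials or functional biases
  simulate_langevin_r(potential, params, bias, bias_code, bias_par, bias_fun)
}

simulate_langevin_r <- function(potential, params, bias, bias_code, bias_par,
                                bias_fun) {
  if (potential$ndim != 1L)
    stop("the generic integrator path supports 1-D potentials only")
  grad <- function(x) {
    g <- potential$gradient(x)
    if (bias_code == 1L) g <- g + bias_par[1] * (x - bias_par[2])
    if (!is.null(bias_fun)) g <- g + bias_fun(x)
    g
  }
  n_rep <- length(params$x0)
  pref <- potential$beta * params$diffusion_coefficient * params$timestep
  noise <- sqrt(2 * params$diffusion_coefficient * params$timestep)
  n_frames <- params$n_steps %/% params$stride
  out <- matrix(NA_real_, n_frames, n_rep)
  with_seed(params$seed, {
    x <- as.numeric(params$x0)
    fi <- 0L
    for (s in seq_len(params$n_steps)) {
      x <- x - pref * grad(x) + noise * rnorm(n_rep)
      if (any(abs(x) > params$domain_guard) || any(!is.finite(x)))
        stop(sprintf("trajectory diverged at step %d", s))
      if (s %% params$stride == 0L) {
        fi <- fi + 1L
        out[fi, ] <- x
      }
    }
  })
  if (n_rep == 1L) drop(out) else out
}

#' Simulate a discrete Markov chain, optionally under a state bias
#'
#' Draws a state sequence from a row-stochastic transition matrix.  When
#' per-state bias energies `state_bias` (in kT) are supplied, the chain is
#' rebuilt with square-root reweighting of the off-diagonal elements,
#' `T^b_ij = T_ij exp(-(b_j - b_i)/2)` (diagonal absorbing the remainder),
#' which preserves detailed balance with respect to the biased Boltzmann
#' weights `pi_i exp(-b_i)`.  This gives biased ensembles with analytically
#' known stationary laws, the discrete oracle used in estimator tests.
#'
#' @param transition_matrix row-stochastic square matrix.
#' @param n_frames number of frames to draw.
#' @param seed integer seed.
#' @param start_state 1-based starting state (default 1).
#' @param state_bias optional per-state bias energies in kT.
#' @return integer vector of 0-based state indices of length `n_frames`.
#' @export
simulate_markov_chain <- function(transition_matrix, n_frames, seed,
                                  start_state = 1L, state_bias = NULL) {
  trans <- as.matrix(transition_matrix)
  n <- nrow(trans)
  if (ncol(trans) != n || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-8))
    stop("`transition_matrix` must be row-stochastic")
  if (!is.null(state_bias)) {
    stopifnot(length(state_bias) == n)
    trans <- biased_chain(trans, state_bias)
  }
  stopifnot(start_state >= 1, start_state <= n, n_frames >= 1)
  with_seed(seed,
            markov_chain_cpp(trans, as.integer(n_frames),
                             as.integer(start_state) - 1L))
}

#' @rdname simulate_markov_chain
#' @param trans row-stochastic matrix to reweight.
#' @export
biased_chain <- function(trans, state_bias) {
  n <- nrow(trans)
  b <- as.numeric(state_bias)
  out <- trans * exp(-(matrix(b, n, n, byrow = TRUE) - b) / 2)
  diag(out) <- 0
  rs <- rowSums(out)
  # strong bias can overflow a row; a single global rescaling of all
  # off-diagonal elements preserves detailed balance exactly
  if (max(rs) > 1) out <- out / max(rs)
  diag(out) <- 1 - rowSums(out)
  out
}

#' Build a ladder of umbrella-sampling windows
#'
#' One harmonic restraint window per center along a collective variable,
#' with ensemble ids 1..K (ensemble 0 is reserved for unbiased data).  The
#' restraint energy of window k at CV value x is
#' `force_constant/2 * (x - center_k)^2` in kT.
#'
#' @param centers strictly increasing window centers (CV units).
#' @param force_constant harmonic force constant in kT per CV unit squared
#'   (a single value or one per window).
#' @return list of `umbrella_window` objects.
#' @examples
#' make_umbrella_set(seq(-1.5, 1.5, length.out = 21), force_constant = 20)
#' @export
make_umbrella_set <- function(centers, force_constant) {
  if (length(centers) == 0) return(list())
  if (anyDuplicated(centers) || is.unsorted(centers, strictly = TRUE))
    stop("`centers` must be strictly increasing without duplicates")
  stopifnot(all(force_constant >= 0))
  fc <- rep_len(force_constant, length(centers))
  mapply(function(y, k, id) {
    structure(list(center = y, force_constant = k, ensemble_id = id),
              class = "umbrella_window")
  }, centers, fc, seq_along(centers), SIMPLIFY = FALSE)
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window %d: center %g, force constant %g kT\n",
              x$ensemble_id, x$center, x$force_constant))
  invisible(x)
}

#' Parameters for well-tempered metadynamics
#'
#' @param hill_height initial Gaussian height (omega * tau) in kT.
#' @param hill_width Gaussian width sigma in CV units.
#' @param deposition_stride deposit a hill every this many integration steps.
#' @param bias_factor well-tempered bias factor gamma = (T + dT)/T (> 1);
#'   hill heights decay as exp(-V_meta/(kB dT)).
#' @param temperature system temperature in Kelvin (only used to translate
#'   `bias_factor` into a boost temperature for reporting).
#' @return object of class `metadynamics_params`.
#' @export
metadynamics_params <- function(hill_height = 0.5, hill_width = 0.2,
                                deposition_stride = 500L, bias_factor = 10,
                                temperature = 300) {
  stopifnot(hill_height >= 0, hill_width > 0, deposition_stride >= 1)
  if (bias_factor <= 1)
    stop("`bias_factor` must exceed 1 (boost temperature dT must be positive)")
  structure(list(hill_height = hill_height, hill_width = hill_width,
                 deposition_stride = as.integer(deposition_stride),
                 bias_factor = bias_factor, temperature = temperature,
                 delta_T = (bias_factor - 1) * temperature),
            class = "metadynamics_params")
}

#' Simulate a well-tempered metadynamics run on a 1-D model potential
#'
#' Brownian dynamics with a history-dependent repulsive bias: every
#' `deposition_stride` steps a Gaussian hill is added at the current CV
#' position, with height `hill_height * exp(-V_meta(x, t)/(kB dT))` so that
#' heights decay as the bias fills the landscape.  The running bias enters
#' the force on the particle.
#'
#' @param potential a 1-D [potential_spec()] with a built-in form
#'   (`double_well` or `harmonic`).
#' @param metad a [metadynamics_params()].
#' @param params a [langevin_params()]; `deposition_stride` must divide
#'   `n_steps`.
#' @param grid_range range on which the accumulated bias is tracked.
#' @return list with `trajectory` (saved frames) and `hills` (a
#'   [hills_log()] of deposited Gaussians).
#' @export
simulate_wt_metadynamics <- function(potential, metad, params,
                                     grid_range = c(-3, 3)) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(metad, "metadynamics_params"),
            inherits(params, "langevin_params"))
  if (params$n_steps %% metad$deposition_stride != 0)
    stop("deposition stride must divide n_steps")
  builtin <- builtin_pot_code(potential)
  if (is.null(builtin))
    stop("well-tempered metadynamics requires a built-in 1-D potential form")
  dT_over_T <- metad$bias_factor - 1 # kB*dT in kT units
  res <- with_seed(params$seed,
    wtmetad_cpp(params$x0[1], params$n_steps, params$timestep,
                params$diffusion_coefficient, potential$beta, params$stride,
                builtin$code, builtin$par, metad$hill_height,
                metad$hill_width, dT_over_T, metad$deposition_stride,
                grid_range[1], grid_range[2], 601L, params$domain_guard))
  hills <- hills_log(time = res$hill_time,
                     center = matrix(res$hill_center, ncol = 1),
                     width = metad$hill_width,
                     height = res$hill_height,
                     bias_factor = metad$bias_factor,
                     temperature = metad$temperature)
  list(trajectory = res$trajectory, hills = hills)
}

#' Bundle trajectories from several ensembles into a synthetic dataset
#'
#' @param trajectories list of per-frame coordinate/CV vectors.
#' @param ensemble_ids integer vector, one id per trajectory (0 = unbiased,
#'   1..K = umbrella windows).
#' @param ground_truth the generating [potential_spec()].
#' @param windows list of umbrella windows defining the biased ensembles.
#' @param hills optional [hills_log()].
#' @return object of class `synthetic_dataset`.
#' @export
synthetic_dataset <- function(trajectories, ensemble_ids, ground_truth,
                              windows = list(), hills = NULL) {
  stopifnot(length(trajectories) == length(ensemble_ids),
            all(lengths(trajectories) > 0))
  ids <- sort(unique(as.integer(ensemble_ids)))
  win_ids <- vapply(windows, `[[`, integer(1) + 0, "ensemble_id")
  missing <- setdiff(ids[ids != 0L], win_ids)
  if (length(missing))
    stop("ensemble id(s) without a defined bias: ",
         paste(missing, collapse = ", "))
  structure(list(trajectories = trajectories,
                 ensemble_ids = as.integer(ensemble_ids),
                 ground_truth = ground_truth, windows = windows,
                 hills = hills),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic multi-ensemble dataset: %d trajectories (%d unbiased, %d biased), %d frames total\n",
    length(x$trajectories), sum(x$ensemble_ids == 0L),
    sum(x$ensemble_ids != 0L), sum(lengths(x$trajectories))))
  invisible(x)
}
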