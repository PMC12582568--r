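# Independent oracles used across the suite.  These deliberately avoid the
# package's own estimation code paths: brute-force likelihood maximization,
# closed forms, and direct stochastic simulation.

# birth-death transition matrix with Metropolis rates between neighbours,
# detailed-balanced w.r.t. exp(-energies)
metastable_bd_chain <- function(energies, base_rate = 0.2) {
  n <- length(energies)
  T_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    T_mat[i, i + 1] <- base_rate * min(1, exp(-(energies[i + 1] - energies[i])))
    T_mat[i + 1, i] <- base_rate * min(1, exp(-(energies[i] - energies[i + 1])))
  }
  diag(T_mat) <- 1 - rowSums(T_mat)
  T_mat
}

bd_stationary <- function(energies) {
  p <- exp(-(energies - min(energies)))
  p / sum(p)
}

# closed-form committor of a birth-death chain between single states a < b
# (product formula over the ratio of backward to forward rates)
bd_committor_closed <- function(T_mat, a, b) {
  n <- nrow(T_mat)
  rho <- cumprod(c(1, vapply((a + 1):(b - 1), function(i)
    T_mat[i, i - 1] / T_mat[i, i + 1], numeric(1))))
  q <- c(0, cumsum(rho) / sum(rho))
  out <- numeric(n)
  out[b:n] <- 1
  out[a:b] <- q
  out
}

# exact mean first-passage time from `start` to the absorbing set, via the
# fundamental matrix of the chain restricted to transient states
exact_mfpt <- function(T_mat, start, absorb) {
  trans <- setdiff(seq_len(nrow(T_mat)), absorb)
  Q <- T_mat[trans, trans, drop = FALSE]
  tau <- solve(diag(length(trans)) - Q, rep(1, length(trans)))
  tau[match(start, trans)]
}

# direct first-passage Monte Carlo via the renewal construction: the sink
# is rewired to teleport back to the source, so a single long chain yields
# independent first-passage samples as the gaps between sink arrivals
mc_first_passage <- function(T_mat, start, absorb, n_runs, seed,
                             chunk = 2e7L) {
  stopifnot(length(absorb) == 1L, length(start) == 1L)
  Tr <- T_mat
  Tr[absorb, ] <- 0
  Tr[absorb, start] <- 1
  times <- numeric(0)
  offset <- 0            # absolute frame index of the end of previous chunks
  last_hit <- 0          # absolute frame of the last sink arrival (0 = start)
  state0 <- start
  it <- 0L
  while (length(times) < n_runs && it < 200L) {
    it <- it + 1L
    s <- simulate_markov_chain(Tr, chunk, seed = seed + it,
                               start_state = state0)
    state0 <- s[length(s)] + 1L
    if (it > 1L) s <- s[-1L] # continuation chunks re-emit the carried state
    hits <- which(s == (absorb - 1L)) + offset
    if (length(hits)) {
      # steps from each (re)start at last_hit + 1 until the next arrival
      times <- c(times, diff(c(last_hit, hits)) - 1)
      last_hit <- hits[length(hits)]
    }
    offset <- offset + length(s)
  }
  head(times, n_runs)
}

# brute-force reversible MLE: maximize prod T_ij^c_ij over the reversible
# family by unconstrained optimization on the log of the symmetric flux
# variables (independent of the package's fixed-point iteration)
bruteforce_reversible_mle <- function(C) {
  n <- nrow(C)
  up <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  negll <- function(theta) {
    X <- matrix(0, n, n)
    X[upper.tri(X, diag = TRUE)] <- exp(theta)
    X <- X + t(X) - diag(diag(X))
    T_mat <- X / rowSums(X)
    -sum(C[C > 0] * log(T_mat[C > 0]))
  }
  init <- log((C + t(C))[upper.tri(C, diag = TRUE)] + 0.1)
  opt <- optim(init, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  X <- matrix(0, n, n)
  X[upper.tri(X, diag = TRUE)] <- exp(opt$par)
  X <- X + t(X) - diag(diag(X))
  X / rowSums(X)
}

# small canonical double-well multi-ensemble dataset shared by TRAM tests
# (cached per session; scaled down from the full study conditions)
small_double_well_data <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pot <- potential_spec("double_well", h = 4)
    wins <- make_umbrella_set(seq(-1.4, 1.4, length.out = 9), 15)
    ds <- generate_double_well_dataset(pot, wins, n_unbiased = 4,
            unbiased_steps = 20000, umbrella_steps = 6000,
            timestep = 0.002, stride = 20, seed = 2024)
    edges <- seq(-1.6, 1.6, length.out = 21)
    states <- discretize_cv(ds$trajectories, edges)
    cache <<- list(
      potential = pot, windows = wins, dataset = ds, bin_edges = edges,
      data = assemble_multi_ensemble(states, ds$ensemble_ids, ds$windows,
                                     ds$trajectories, n_states = 20))
    cache
  }
})
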