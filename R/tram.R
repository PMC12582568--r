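#' Per-ensemble transition and occupation counts
#'
#' Counts interstate transitions at the given lag separately within every
#' thermodynamic ensemble, using only contiguous same-ensemble trajectory
#' segments (pairs never cross trajectory or ensemble boundaries), together
#' with the per-state frame counts `N_i^k` that enter the local-equilibrium
#' part of the likelihood.
#'
#' @param data a [assemble_multi_ensemble()] object.
#' @param lag lag time in frames (>= 1).
#' @param mode `"sliding"` (default) or `"strided"` counting.
#' @param count_biased if `FALSE`, transition counts from biased ensembles
#'   are zeroed and those ensembles contribute only local-equilibrium
#'   (occupation) information.
#' @return object of class `tram_counts`: `counts` (list of n x n matrices,
#'   element k+1 is ensemble k), `state_counts` (n x K matrix `N_i^k`),
#'   `lag`, `empty_ensembles`.
#' @export
count_per_ensemble <- function(data, lag, mode = c("sliding", "strided"),
                               count_biased = TRUE) {
  stopifnot(inherits(data, "multi_ensemble_data"), lag >= 1)
  mode <- match.arg(mode)
  n <- data$n_states
  K <- data$n_ensembles
  counts <- vector("list", K)
  N <- matrix(0, n, K)
  empty <- integer()
  # contiguous same-(trajectory, ensemble) segments
  seg <- cumsum(c(TRUE, diff(data$traj) != 0 | diff(data$ensemble) != 0))
  seg_states <- split(data$state, seg)
  seg_ens <- vapply(split(data$ensemble, seg), `[[`, integer(1), 1L)
  for (k in seq_len(K) - 1L) {
    segs_k <- seg_states[seg_ens == k]
    if (length(segs_k) == 0) {
      counts[[k + 1L]] <- matrix(0, n, n)
      empty <- c(empty, k)
      next
    }
    N[, k + 1L] <- tabulate(unlist(segs_k, use.names = FALSE) + 1L, nbins = n)
    usable <- any(lengths(segs_k) > lag)
    if (usable && (count_biased || k == 0L)) {
      counts[[k + 1L]] <- count_transitions(segs_k, lag, mode, n)$counts
    } else {
      counts[[k + 1L]] <- matrix(0, n, n)
    }
  }
  structure(list(counts = counts, state_counts = N, lag = as.integer(lag),
                 empty_ensembles = empty),
            class = "tram_counts")
}

#' Solve the multi-ensemble reweighting self-consistency equations
#'
#' Iterates the coupled updates of the Lagrangian multipliers `v_i^k`, the
#' local reduced free energies `f_i^k` and the `R_i^k` aggregates until the
#' largest change in `f` falls below `tol`, then recovers the per-ensemble
#' transition matrices `p_ij^k` and the per-frame unbiased stationary
#' weights `mu(x)`.  All accumulation is in log space, so umbrella bias
#' energies of tens of kT are handled safely.  The model is restricted to
#' the largest connected component of the count graph pooled over
#' ensembles; dropped states (and their frames) are reported.
#'
#' @param data a `multi_ensemble_data`.
#' @param counts a [count_per_ensemble()] result.
#' @param tol convergence tolerance on `max |delta f|` (default 1e-8 kT).
#' @param max_iter iteration budget (default 1e5).
#' @return object of class `tram_model`: `f` (states x ensembles local free
#'   energies, kT), `log_v`, `log_R`, `transition_matrices` (list over
#'   ensembles), `log_mu` and `mu` (per retained frame, normalized),
#'   `frame_kept` (logical over input frames), `active_set` (original
#'   0-based state ids), `dropped`, `converged`, `iterations`,
#'   `increment_history`, `lag`, plus the retained per-frame `state` and
#'   `ensemble` vectors.
#' @export
solve_tram <- function(data, counts, tol = 1e-8, max_iter = 1e5) {
  stopifnot(inherits(data, "multi_ensemble_data"),
            inherits(counts, "tram_counts"))
  if (all(vapply(counts$counts, sum, numeric(1)) == 0))
    stop("no ensemble has nonzero transition counts")
  n <- data$n_states
  K <- data$n_ensembles
  # connectivity of the reversible multi-ensemble model lives on the
  # symmetrized count graph pooled over ensembles
  pooled <- Reduce(`+`, counts$counts)
  act <- largest_connected_set(pooled + t(pooled))
  # states never observed, or outside the pooled connected set, are dropped
  act <- intersect(act, which(rowSums(counts$state_counts) > 0) - 1L)
  dropped <- setdiff(which(rowSums(counts$state_counts) > 0) - 1L, act)
  if (length(act) < 2) stop("connected set has fewer than 2 states")
  keep <- data$state %in% act
  remap <- match(data$state[keep], act) - 1L # 0-based within active set
  ct <- lapply(counts$counts, function(cm) {
    m <- cm[act + 1L, act + 1L, drop = FALSE]
    m + t(m)
  })
  colsum <- lapply(counts$counts, function(cm)
    colSums(cm[act + 1L, act + 1L, drop = FALSE]))
  N <- counts$state_counts[act + 1L, , drop = FALSE]
  res <- tram_solve_cpp(ct, colsum, N, data$bias[keep, , drop = FALSE],
                        remap, tol, as.integer(max_iter), 1L)
  if (!res$converged)
    warning(sprintf(
      "TRAM did not converge in %d iterations (last increment %.3g)",
      res$iterations, tail(res$increments, 1)))
  inc <- res$increments
  if (length(inc) > 20) {
    tail_inc <- inc[-seq_len(ceiling(length(inc) * 0.1))]
    if (mean(diff(tail_inc) <= 0) < 0.5)
      warning("self-consistency increments are not decreasing; inspect increment_history")
  }
  structure(list(f = res$f, log_v = res$log_v, log_R = res$log_R,
                 log_mu = as.numeric(res$log_mu),
                 mu = exp(as.numeric(res$log_mu)),
                 transition_matrices = res$transition_matrices,
                 frame_kept = keep, active_set = act, dropped = dropped,
                 converged = res$converged, iterations = res$iterations,
                 increment_history = inc, lag = counts$lag,
                 state = remap, ensemble = data$ensemble[keep],
                 n_ensembles = K, counts = counts),
            class = "tram_model")
}

#' @export
print.tram_model <- function(x, ...) {
  cat(sprintf(
    "TRAM model: %d states, %d ensembles, lag %d frames; %s after %d iterations\n",
    length(x$active_set), x$n_ensembles, x$lag,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  if (length(x$dropped))
    cat(sprintf("  %d state(s) dropped as disconnected\n", length(x$dropped)))
  invisible(x)
}

#' @export
summary.tram_model <- function(object, ...) {
  print(object)
  st <- stationary_from_tram(object)
  cat("unbiased stationary free energies (kT, first states):",
      paste(signif(head(st$free_energy, 8), 4), collapse = ", "), "\n")
  invisible(object)
}

#' One-call TRAM fit from a multi-ensemble dataset
#'
#' @inheritParams count_per_ensemble
#' @inheritParams solve_tram
#' @return a `tram_model`.
#' @export
tram <- function(data, lag, tol = 1e-8, max_iter = 1e5,
                 mode = c("sliding", "strided"), count_biased = TRUE) {
  cm <- count_per_ensemble(data, lag, match.arg(mode), count_biased)
  solve_tram(data, cm, tol = tol, max_iter = max_iter)
}

#' Unbiased stationary distribution and free energies from a TRAM model
#'
#' Aggregates the per-frame unbiased stationary weights by state,
#' `pi_i = sum of mu(x) over frames x assigned to state i`, and reports the
#' corresponding free energies `-ln pi_i` anchored so the lowest is 0.
#'
#' @param model a `tram_model`.
#' @return list with `pi` (simplex vector over active states),
#'   `free_energy` (kT), and `states` (original 0-based state ids).
#' @export
stationary_from_tram <- function(model) {
  stopifnot(inherits(model, "tram_model"))
  n <- length(model$active_set)
  pi_vec <- vapply(seq_len(n) - 1L, function(i) sum(model$mu[model$state == i]),
                   numeric(1))
  pi_vec <- pi_vec / sum(pi_vec)
  fe <- -log(pi_vec)
  list(pi = pi_vec, free_energy = fe - min(fe[is.finite(fe)]),
       states = model$active_set)
}

#' Reversible transition model of one ensemble from a TRAM fit
#'
#' Extracts the transition matrix of ensemble `k` (default the unbiased
#' ensemble, the physically meaningful one for kinetics), restricted to the
#' connected states of that ensemble, together with the local stationary
#' distribution `pi_i^k` proportional to `exp(-f_i^k)`.
#'
#' @param model a `tram_model`.
#' @param ensemble 0-based ensemble index (default 0, unbiased).
#' @return an `msm_model`.
#' @export
tram_msm <- function(model, ensemble = 0L) {
  stopifnot(inherits(model, "tram_model"),
            ensemble >= 0, ensemble < model$n_ensembles)
  p <- model$transition_matrices[[ensemble + 1L]]
  # restrict to the largest connected component of this ensemble's
  # *symmetrized* count graph: the reversible transition matrix has an
  # edge (i, j) exactly where c_ij + c_ji > 0, so its connectivity is
  # undirected by construction
  if (!is.null(model$counts)) {
    cm <- model$counts$counts[[ensemble + 1L]][model$active_set + 1L,
                                               model$active_set + 1L,
                                               drop = FALSE]
    active <- largest_connected_set(cm + t(cm)) + 1L
  } else {
    active <- which(is.finite(model$log_v[, ensemble + 1L]))
  }
  if (length(active) < 2) stop("ensemble has fewer than 2 connected states")
  T_sub <- p[active, active, drop = FALSE]
  T_sub <- T_sub / rowSums(T_sub)
  pi_sub <- exp(-(model$f[active, ensemble + 1L] -
                    min(model$f[active, ensemble + 1L])))
  pi_sub <- pi_sub / sum(pi_sub)
  new_msm_model(T_sub, pi_sub, model$lag, model$active_set[active])
}

#' Robustness of kinetics to the amount of unbiased data
#'
#' Rebuilds both estimators on subsampled datasets: for each fraction and
#' seed a random subset of the unbiased trajectories is retained (biased
#' data kept in full), TRAM is re-solved on the reduced multi-ensemble
#' dataset, a plain MSM is re-estimated on the reduced unbiased data alone,
#' and the slowest implied timescale (plus an optional free-energy
#' difference between two state groups) is recorded for each.
#'
#' @param data a `multi_ensemble_data`.
#' @param fractions numeric fractions in (0, 1] of unbiased trajectories to
#'   keep.
#' @param seeds integer seeds, one subsample per seed.
#' @param lag lag in frames for both estimators.
#' @param groups optional list of two vectors of 0-based state indices; when
#'   given, `delta_g = -ln(pi_A/pi_B)` is reported as a free-energy-difference
#'   analog.
#' @param tol,max_iter passed to [solve_tram()].
#' @return data.frame with columns `fraction`, `seed`, `estimator`,
#'   `slowest_timescale`, `delta_g`, `flagged` (TRUE when the subsample
#'   left no usable unbiased transitions).
#' @export
data_fraction_experiment <- function(data, fractions, seeds, lag,
                                     groups = NULL, tol = 1e-8,
                                     max_iter = 1e5) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  unb_traj <- unique(data$traj[data$ensemble == 0L])
  rows <- list()
  for (fr in fractions) {
    n_keep <- max(1L, ceiling(fr * length(unb_traj)))
    for (sd in seeds) {
      keep_unb <- if (n_keep >= length(unb_traj)) unb_traj else
        with_seed(sd, sort(sample(unb_traj, n_keep)))
      keep_traj <- data$traj %in% keep_unb | data$ensemble != 0L
      sub <- subset_frames(data, keep_traj)
      for (est in c("TRAM", "MSM")) {
        row <- list(fraction = fr, seed = sd, estimator = est,
                    slowest_timescale = NA_real_, delta_g = NA_real_,
                    flagged = FALSE)
        fit <- tryCatch({
          if (est == "TRAM") {
            tm <- suppressWarnings(
              tram(sub, lag, tol = tol, max_iter = max_iter))
            m0 <- tram_msm(tm, 0L)
            st <- stationary_from_tram(tm)
            list(ts = implied_timescales(m0, 1),
                 pi = st$pi, states = st$states)
          } else {
            segs <- split(sub$state[sub$ensemble == 0L],
                          sub$traj[sub$ensemble == 0L])
            mm <- msm(segs, lag, n_states = sub$n_states)
            list(ts = implied_timescales(mm, 1),
                 pi = mm$stationary, states = mm$active_set)
          }
        }, error = function(e) NULL)
        if (is.null(fit)) {
          row$flagged <- TRUE
        } else {
          row$slowest_timescale <- fit$ts
          if (!is.null(groups)) {
            pa <- sum(fit$pi[fit$states %in% groups[[1]]])
            pb <- sum(fit$pi[fit$states %in% groups[[2]]])
            row$delta_g <- if (pa > 0 && pb > 0) -log(pa / pb) else NA_real_
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# restrict a multi_ensemble_data to a logical frame mask (whole trajectories
# expected; segment structure is preserved through the traj vector)
subset_frames <- function(data, keep) {
  structure(list(state = data$state[keep], ensemble = data$ensemble[keep],
                 traj = data$traj[keep],
                 bias = data$bias[keep, , drop = FALSE],
                 cv = data$cv[keep],
                 n_states = data$n_states, n_ensembles = data$n_ensembles),
            class = "multi_ensemble_data")
}
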