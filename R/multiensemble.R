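#' Assemble the three-array multi-ensemble representation
#'
#' The multi-ensemble estimator consumes three frame-aligned arrays: the
#' discrete state index of every frame, the ensemble index of every frame,
#' and the bias-energy matrix giving the reduced bias `b^k(x)` every frame
#' would feel in every ensemble.  For a harmonic umbrella window k with
#' center `y_k` and force constant `c_k`, the bias on a frame with CV value
#' x is `c_k (x - y_k)^2 / (2 kT)`; the unbiased ensemble's column is zero.
#'
#' @param state_seqs list of per-trajectory 0-based state index vectors.
#' @param ensemble_ids integer vector, one per trajectory: 0 for unbiased,
#'   window `ensemble_id` for umbrella trajectories.
#' @param windows list of `umbrella_window`s covering all nonzero ids.
#' @param cv_values list of per-trajectory CV value vectors (frame-aligned
#'   with `state_seqs`).
#' @param kT thermal energy in the units of the window force constants
#'   (1 if force constants are already in kT; `kt_in_kcal()` if they are in
#'   kcal/mol).
#' @param n_states total number of states (default: max observed + 1).
#' @return object of class `multi_ensemble_data` with per-frame vectors
#'   `state`, `ensemble`, `traj`, the frames x ensembles `bias` matrix
#'   (column e is ensemble e-1), `n_states` and `n_ensembles`.
#' @export
assemble_multi_ensemble <- function(state_seqs, ensemble_ids, windows,
                                    cv_values, kT = 1,
                                    n_states = NULL) {
  stopifnot(length(state_seqs) == length(ensemble_ids),
            length(cv_values) == length(state_seqs))
  if (!all(lengths(state_seqs) == lengths(cv_values)))
    stop("state and CV arrays must be frame-aligned")
  ensemble_ids <- as.integer(ensemble_ids)
  win_ids <- vapply(windows, `[[`, numeric(1), "ensemble_id")
  if (length(win_ids) && (anyDuplicated(win_ids) ||
      !identical(sort(as.integer(win_ids)), seq_along(win_ids))))
    stop("window ensemble ids must be unique and contiguous from 1")
  missing <- setdiff(unique(ensemble_ids[ensemble_ids != 0L]), win_ids)
  if (length(missing))
    stop("trajectory ensemble id(s) lacking a window: ",
         paste(missing, collapse = ", "))
  state <- unlist(state_seqs, use.names = FALSE)
  cv <- unlist(cv_values, use.names = FALSE)
  traj <- rep(seq_along(state_seqs), lengths(state_seqs))
  ensemble <- rep(ensemble_ids, lengths(state_seqs))
  n_ens <- length(windows) + 1L
  bias <- matrix(0, length(state), n_ens)
  for (w in windows) {
    bias[, w$ensemble_id + 1L] <-
      w$force_constant * (cv - w$center)^2 / (2 * kT)
  }
  if (any(!is.finite(bias))) stop("non-finite bias energies")
  if (is.null(n_states)) n_states <- max(state) + 1L
  stopifnot(all(state >= 0), all(state < n_states))
  structure(list(state = as.integer(state), ensemble = ensemble,
                 traj = as.integer(traj), bias = bias, cv = cv,
                 n_states = as.integer(n_states),
                 n_ensembles = as.integer(n_ens)),
            class = "multi_ensemble_data")
}

#' @export
print.multi_ensemble_data <- function(x, ...) {
  cat(sprintf(
    "Multi-ensemble data: %d frames, %d states, %d ensembles (%d unbiased frames)\n",
    length(x$state), x$n_states, x$n_ensembles, sum(x$ensemble == 0L)))
  invisible(x)
}

# split a per-frame vector into contiguous same-trajectory segments
split_by_traj <- function(data, what = "state") {
  split(data[[what]], data$traj)
}
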