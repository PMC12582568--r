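#' Count interstate transitions at a lag
#'
#' Sliding-window counting uses every `(t, t + lag)` frame pair within each
#' trajectory (maximal data use); strided counting advances by `lag` between
#' pairs.  Pairs never span trajectory boundaries.
#'
#' @param state_seqs a 0-based integer state sequence or a list of them
#'   (one per trajectory).
#' @param lag lag time in frames (>= 1).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @param n_states total state count (default: max observed + 1).
#' @return object of class `count_model`: `counts` (n x n matrix), `lag`,
#'   `mode`, `n_states`, `active_set` (0-based indices of the largest
#'   strongly connected component of the count graph).
#' @examples
#' count_transitions(c(0, 1, 0, 1, 1), lag = 1)$counts
#' @export
count_transitions <- function(state_seqs, lag, mode = c("sliding", "strided"),
                              n_states = NULL) {
  mode <- match.arg(mode)
  if (!is.list(state_seqs)) state_seqs <- list(state_seqs)
  stopifnot(lag >= 1)
  if (all(lengths(state_seqs) <= lag))
    stop("all trajectories are shorter than the lag")
  if (is.null(n_states))
    n_states <- max(unlist(lapply(state_seqs, max))) + 1L
  n <- as.integer(n_states)
  counts <- matrix(0, n, n)
  for (s in state_seqs) {
    s <- as.integer(s)
    if (length(s) <= lag) next
    from_idx <- seq_len(length(s) - lag)
    if (mode == "strided") from_idx <- from_idx[seq(1, length(from_idx), by = lag)]
    i <- s[from_idx]
    j <- s[from_idx + lag]
    tab <- tabulate(i * n + j + 1L, nbins = n * n)
    counts <- counts + matrix(tab, n, n, byrow = TRUE)
  }
  structure(list(counts = counts, lag = as.integer(lag), mode = mode,
                 n_states = n, active_set = largest_connected_set(counts)),
            class = "count_model")
}

# largest strongly connected component of the directed count graph,
# returned as 0-based state indices; ties broken by total counts
largest_connected_set <- function(counts) {
  n <- nrow(counts)
  g <- igraph::graph_from_adjacency_matrix(counts > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership, comp$no)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    tot <- vapply(cand, function(cc) {
      idx <- which(comp$membership == cc)
      sum(counts[idx, idx, drop = FALSE])
    }, numeric(1))
    cand <- cand[which.max(tot)]
  }
  sort(which(comp$membership == cand[1])) - 1L
}

#' Reversible maximum-likelihood Markov state model
#'
#' Maximizes the transition-matrix likelihood `prod (T_ij)^(c_ij)` subject
#' to detailed balance `pi_i T_ij = pi_j T_ji`, using the standard
#' self-consistent fixed-point iteration on the unnormalized reversible
#' flux variables.  Estimation is restricted to the largest strongly
#' connected component of the count graph; dropped states are reported in
#' the returned object.
#'
#' @param counts a `count_model` (or a bare count matrix, taken at `lag`).
#' @param tol convergence tolerance on the stationary vector (default 1e-10).
#' @param max_iter iteration budget (default 1e6).
#' @param lag lag in frames when `counts` is a bare matrix.
#' @return object of class `msm_model`: `transition_matrix` (row-stochastic,
#'   reversible), `stationary` (simplex vector), `eigenvalues` (descending,
#'   first is 1), `lag`, `active_set` (0-based original state indices),
#'   `dropped` states, `counts`.
#' @export
estimate_reversible_mle <- function(counts, tol = 1e-10, max_iter = 1e6,
                                    lag = 1L) {
  if (!inherits(counts, "count_model")) {
    counts <- structure(list(counts = as.matrix(counts),
                             lag = as.integer(lag), mode = "sliding",
                             n_states = nrow(as.matrix(counts)),
                             active_set = largest_connected_set(as.matrix(counts))),
                        class = "count_model")
  }
  act <- counts$active_set
  if (length(act) == 0) stop("empty connected set; no transitions observed")
  dropped <- setdiff(seq_len(counts$n_states) - 1L, act)
  C <- counts$counts[act + 1L, act + 1L, drop = FALSE]
  n <- nrow(C)
  csym <- C + t(C)
  if (sum(csym) == 0) stop("no transitions within the connected set")
  ci <- rowSums(C)
  # fixed point on the reversible flux variables x_ij
  X <- csym / sum(csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    q <- ci / xi
    denom <- outer(q, q, "+")
    Xn <- csym / denom
    Xn <- Xn / sum(Xn)
    pin <- rowSums(Xn)
    if (max(abs(pin - xi / sum(xi))) < tol) { X <- Xn; break }
    X <- Xn
  }
  pi_vec <- rowSums(X)
  T_mat <- X / pi_vec
  T_mat <- T_mat / rowSums(T_mat)
  new_msm_model(T_mat, pi_vec / sum(pi_vec), counts$lag, act, dropped, counts)
}

new_msm_model <- function(T_mat, pi_vec, lag, active_set, dropped = integer(),
                          counts = NULL) {
  # spectrum through the symmetrized similarity transform (real for a
  # reversible matrix)
  s <- sqrt(pi_vec)
  sym <- (T_mat * outer(s, 1 / s)) # D^{1/2} T D^{-1/2}
  ev <- eigen((sym + t(sym)) / 2, symmetric = TRUE, only.values = TRUE)$values
  structure(list(transition_matrix = T_mat, stationary = pi_vec,
                 eigenvalues = sort(ev, decreasing = TRUE),
                 lag = as.integer(lag), active_set = active_set,
                 dropped = dropped, counts = counts),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("Reversible MSM: %d states, lag %d frames\n",
              nrow(x$transition_matrix), x$lag))
  if (length(x$dropped))
    cat(sprintf("  %d disconnected state(s) dropped: %s\n", length(x$dropped),
                paste(head(x$dropped, 10), collapse = ", ")))
  its <- implied_timescales(x)
  cat("  slowest implied timescales (frames):",
      paste(signif(head(its, 3), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.msm_model <- function(object, ...) {
  cat(sprintf("Reversible MSM at lag %d with %d active states\n",
              object$lag, nrow(object$transition_matrix)))
  cat("eigenvalues:",
      paste(signif(head(object$eigenvalues, 6), 5), collapse = ", "), "\n")
  cat("implied timescales (frames):",
      paste(signif(head(implied_timescales(object), 5), 5), collapse = ", "),
      "\n")
  cat("stationary distribution (first states):",
      paste(signif(head(object$stationary, 6), 4), collapse = ", "), "\n")
  invisible(object)
}

#' Convenience Markov state model fit from discrete trajectories
#'
#' Counts transitions and estimates the reversible maximum-likelihood
#' transition matrix in one call.
#'
#' @inheritParams count_transitions
#' @inheritParams estimate_reversible_mle
#' @return an `msm_model`.
#' @export
msm <- function(state_seqs, lag, mode = c("sliding", "strided"),
                n_states = NULL, tol = 1e-10, max_iter = 1e6) {
  cm <- count_transitions(state_seqs, lag, match.arg(mode), n_states)
  estimate_reversible_mle(cm, tol = tol, max_iter = max_iter)
}

#' Implied relaxation timescales
#'
#' `t_i = -lag / ln(lambda_(i+1))` for each non-unit eigenvalue.
#' Eigenvalues at 1 give `Inf`; negative eigenvalues have no well-defined
#' timescale and are reported as `NaN`.
#'
#' @param model an `msm_model` (or any object with `eigenvalues` and `lag`).
#' @param k number of timescales to return (default: all available).
#' @return numeric vector of timescales in frame units of the lag.
#' @export
implied_timescales <- function(model, k = NULL) {
  lam <- model$eigenvalues[-1]
  ts <- rep(NaN, length(lam)) # negative eigenvalues: undefined timescale
  ts[lam >= 1] <- Inf
  pos <- lam > 0 & lam < 1
  ts[pos] <- -model$lag / log(lam[pos])
  if (!is.null(k)) ts <- ts[seq_len(min(k, length(ts)))]
  ts
}

#' VAMP-2 score of a reversible model
#'
#' Sum of the squares of the `k` slowest (largest) eigenvalues, the
#' variational score used to select the number of states and projection
#' dimensions: a larger score means more slow-process variance captured.
#'
#' @param model an `msm_model`.
#' @param k number of eigenvalues to include (including the stationary one).
#' @return numeric score in `[0, k]`.
#' @export
vamp2_score <- function(model, k) {
  stopifnot(k >= 1, k <= length(model$eigenvalues))
  sum(model$eigenvalues[seq_len(k)]^2)
}

#' Chapman-Kolmogorov test
#'
#' Markovianity check: the model propagated to `factor * lag` (matrix power)
#' is compared with a model re-estimated directly at that longer lag.  Both
#' matrices and their maximum absolute deviation are returned per factor;
#' factors the data cannot support are skipped with a warning.
#'
#' @param model an `msm_model` estimated from `state_seqs` at its lag.
#' @param state_seqs the discrete trajectories (0-based).
#' @param factors integer lag multiples to test.
#' @return list of per-factor results: `factor`, `predicted`, `estimated`,
#'   `max_abs_dev` (computed on the shared state set).
#' @export
ck_test <- function(model, state_seqs, factors = c(1L, 2L, 4L)) {
  if (!is.list(state_seqs)) state_seqs <- list(state_seqs)
  out <- list()
  for (f in as.integer(factors)) {
    long_lag <- model$lag * f
    if (all(lengths(state_seqs) <= long_lag)) {
      warning(sprintf("factor %d skipped: trajectories shorter than %d frames",
                      f, long_lag))
      next
    }
    pred <- matrix_power(model$transition_matrix, f)
    est_model <- msm(state_seqs, lag = long_lag)
    shared <- intersect(model$active_set, est_model$active_set)
    ia <- match(shared, model$active_set)
    ib <- match(shared, est_model$active_set)
    dev <- max(abs(pred[ia, ia, drop = FALSE] -
                     est_model$transition_matrix[ib, ib, drop = FALSE]))
    out[[length(out) + 1L]] <- list(factor = f, predicted = pred,
                                    estimated = est_model$transition_matrix,
                                    shared_states = shared,
                                    max_abs_dev = dev)
  }
  out
}

matrix_power <- function(m, p) {
  out <- diag(nrow(m))
  base <- m
  while (p > 0) {
    if (p %% 2 == 1) out <- out %*% base
    base <- base %*% base
    p <- p %/% 2
  }
  out
}
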