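#' Forward committor probabilities
#'
#' Solves the committor linear system for a row-stochastic transition
#' matrix: `q_i = 0` on the source set A, `q_i = 1` on the sink set B, and
#' for intermediate states `q_i = sum_k p_ik q_k`.  The system is solved by
#' a dense direct solve (state counts here are at most thousands); no
#' iteration tolerance is involved.
#'
#' @param transition_matrix row-stochastic n x n matrix.
#' @param A,B disjoint nonempty 1-based index vectors of source and sink
#'   microstates.
#' @return object of class `committor_result`: `q_plus` (length n,
#'   in `[0, 1]`), `A`, `B`.
#' @examples
#' # symmetric nearest-neighbour walk on 5 states: q = (0, .25, .5, .75, 1)
#' T5 <- diag(0.5, 5)
#' for (i in 1:4) { T5[i, i + 1] <- 0.25; T5[i + 1, i] <- 0.25 }
#' T5[1, 1] <- 0.75; T5[5, 5] <- 0.75
#' committor(T5, A = 1, B = 5)$q_plus
#' @export
committor <- function(transition_matrix, A, B) {
  T_mat <- as.matrix(transition_matrix)
  n <- nrow(T_mat)
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0 || length(B) == 0 || length(intersect(A, B)))
    stop("A and B must be nonempty and disjoint")
  if (any(abs(rowSums(T_mat) - 1) > 1e-8))
    stop("`transition_matrix` must be row-stochastic")
  q <- numeric(n)
  q[B] <- 1
  inter <- setdiff(seq_len(n), c(A, B))
  if (length(inter)) {
    M <- diag(length(inter)) - T_mat[inter, inter, drop = FALSE]
    rhs <- rowSums(T_mat[inter, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("singular committor system: ", conditionMessage(e)))
    q[inter] <- sol
  }
  # states with no path to B can pick up tiny negative roundoff
  q <- pmin(pmax(q, 0), 1)
  if (length(inter) && any(q[inter] == 0))
    warning("some intermediate states have no path to B (committor 0)")
  structure(list(q_plus = q, A = A, B = B), class = "committor_result")
}

#' Transition-path-theory rate and mean first-passage time
#'
#' Rate of A -> B transitions,
#' `k_AB = [sum_{i in A} sum_{k notin A} pi_i p_ik q_k] /
#'         [tau sum_i pi_i (1 - q_i)]`,
#' with the mean first-passage time reported as `1/k_AB` in the physical
#' units of the lag time.
#'
#' @param transition_matrix row-stochastic matrix.
#' @param pi stationary distribution (simplex vector).
#' @param q a `committor_result` for the same A, B (or a bare committor
#'   vector, in which case `A` must be supplied).
#' @param lag_time physical duration of one lag step (default 1).
#' @param A source set (taken from `q` when it is a `committor_result`).
#' @return list with `rate` (per unit `lag_time`) and `mfpt`.
#' @export
tpt_rate <- function(transition_matrix, pi, q, lag_time = 1, A = NULL) {
  T_mat <- as.matrix(transition_matrix)
  if (inherits(q, "committor_result")) {
    A <- q$A
    qv <- q$q_plus
  } else {
    qv <- as.numeric(q)
    if (is.null(A)) stop("`A` must be supplied with a bare committor vector")
  }
  stopifnot(length(pi) == nrow(T_mat), length(qv) == nrow(T_mat))
  notA <- setdiff(seq_len(nrow(T_mat)), A)
  num <- sum(pi[A] * (T_mat[A, notA, drop = FALSE] %*% qv[notA]))
  den <- lag_time * sum(pi * (1 - qv))
  if (den <= 0)
    stop("undefined rate: all stationary probability lies in the sink set")
  rate <- num / den
  list(rate = rate, mfpt = if (rate > 0) 1 / rate else Inf)
}

#' Define non-overlapping macrostates
#'
#' @param ... named vectors of 0-based microstate indices.
#' @return a named list of class `macrostate_set`.
#' @export
macrostate_set <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every macrostate must be named")
  if (any(lengths(sets) == 0)) stop("macrostates must be nonempty")
  all_states <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_states)) stop("macrostates must not overlap")
  structure(lapply(sets, as.integer), class = "macrostate_set")
}

#' Pairwise mean first-passage times between macrostates
#'
#' Applies the committor/rate machinery to every ordered macrostate pair.
#' Diagonal entries are not applicable (`NA`); unreachable pairs give `Inf`
#' with a report attribute.
#'
#' @param model an `msm_model` (or a list with `transition_matrix`,
#'   `stationary`, and optionally `active_set` of 0-based state ids).
#' @param macrostates a [macrostate_set()] of 0-based microstate indices
#'   (matching the model's `active_set` labels when present).
#' @param lag_time physical duration of one lag step.
#' @return square matrix of MFPTs in `lag_time` units, dimnames the
#'   macrostate names.
#' @export
macrostate_mfpt_table <- function(model, macrostates, lag_time = 1) {
  stopifnot(inherits(macrostates, "macrostate_set"))
  T_mat <- model$transition_matrix
  pi_vec <- model$stationary
  labels <- if (!is.null(model$active_set)) model$active_set
            else seq_len(nrow(T_mat)) - 1L
  sets <- lapply(macrostates, function(s) {
    idx <- match(s, labels)
    idx[!is.na(idx)]
  })
  if (any(lengths(sets) == 0))
    stop("a macrostate has no microstates present in the model")
  nm <- names(macrostates)
  out <- matrix(NA_real_, length(sets), length(sets),
                dimnames = list(from = nm, to = nm))
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a == b) next
      res <- tryCatch({
        qc <- committor(T_mat, sets[[a]], sets[[b]])
        tpt_rate(T_mat, pi_vec, qc, lag_time)$mfpt
      }, error = function(e) Inf)
      out[a, b] <- res
    }
  }
  out
}
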