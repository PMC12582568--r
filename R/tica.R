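#' Time-lagged independent component analysis (tICA)
#'
#' Linear projection onto the slowest collective degrees of freedom: solves
#' the generalized eigenproblem of the symmetrized time-lagged covariance
#' against the instantaneous covariance.  The symmetrized estimator forces
#' real eigenvalues bounded by 1 (up to regularization tolerance); the
#' instantaneous covariance is ridge-regularized by `epsilon` on the
#' diagonal.  No kinetic-map scaling is applied.
#'
#' @param features a numeric frames x features matrix or a list of such
#'   matrices (one per trajectory, shared feature definition).
#' @param lag lag time in frames; every trajectory must be longer than this.
#' @param n_components number of components to keep (default all).
#' @param epsilon diagonal ridge on the instantaneous covariance.
#' @return an object of class `tica_model` with elements `lag`, `mean`,
#'   `eigenvalues` (descending), `components` (features x n_components),
#'   `n_components`.
#' @export
fit_tica <- function(features, lag, n_components = NULL, epsilon = 1e-10) {
  trajs <- if (is.list(features)) features else list(features)
  trajs <- lapply(trajs, function(m) as.matrix(m))
  stopifnot(lag >= 1)
  if (any(vapply(trajs, nrow, 1L) <= lag))
    stop("every trajectory must be longer than the lag")
  d <- ncol(trajs[[1]])
  heads <- do.call(rbind, lapply(trajs, function(m) m[seq_len(nrow(m) - lag), , drop = FALSE]))
  tails <- do.call(rbind, lapply(trajs, function(m) m[(lag + 1):nrow(m), , drop = FALSE]))
  n <- nrow(heads)
  m <- colMeans(rbind(heads, tails))
  h <- sweep(heads, 2, m)
  t2 <- sweep(tails, 2, m)
  c0 <- (crossprod(h) + crossprod(t2)) / (2 * n)
  ct <- (crossprod(h, t2) + crossprod(t2, h)) / (2 * n)
  c0r <- c0 + diag(epsilon, d)
  ch <- tryCatch(chol(c0r), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular instantaneous covariance; increasing ridge regularization")
    c0r <- c0 + diag(1e-6 * max(diag(c0), 1), d)
    ch <- chol(c0r)
  }
  cinv <- backsolve(ch, diag(d))          # R^{-1}, C0 = R'R
  b <- t(cinv) %*% ct %*% cinv            # symmetric whitened lagged cov
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  comp <- cinv %*% e$vectors[, ord, drop = FALSE]
  if (is.null(n_components)) n_components <- d
  n_components <- min(n_components, d)
  structure(list(lag = lag, mean = m,
                 eigenvalues = vals[seq_len(n_components)],
                 components = comp[, seq_len(n_components), drop = FALSE],
                 n_components = n_components),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: lag %d frames, %d components\n",
              x$lag, x$n_components))
  cat("eigenvalues:", paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "),
      if (x$n_components > 5) "..." else "", "\n")
  invisible(x)
}

#' Project features onto fitted tICs
#'
#' @param object a `tica_model`.
#' @param newdata frames x features matrix (same feature definition as the
#'   training data), or a list of such matrices.
#' @param ... unused.
#' @return frames x components projection matrix (or list thereof).
#' @export
predict.tica_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata))
    return(lapply(newdata, function(m) predict(object, m)))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean))
    stop("feature dimension mismatch")
  sweep(newdata, 2, object$mean) %*% object$components
}

#' Combined biased/unbiased tIC representation
#'
#' Represents every frame (biased or unbiased alike) by its projection onto
#' the tICs fitted on unbiased data concatenated with its projection onto
#' the tICs fitted on biased data; the output width is the sum of the two
#' component counts.  This shared coordinate system lets frames from all
#' ensembles be clustered into one set of Markovian states.
#'
#' @param unbiased_model,biased_model `tica_model`s fitted on the same
#'   feature definition.
#' @param features frames x features matrix or list of matrices.
#' @return frames x (n_u + n_b) matrix (or list, matching the input).
#' @export
combine_tics <- function(unbiased_model, biased_model, features) {
  stopifnot(inherits(unbiased_model, "tica_model"),
            inherits(biased_model, "tica_model"))
  if (length(unbiased_model$mean) != length(biased_model$mean))
    stop("feature dimension mismatch between the two tICA models")
  if (is.list(features) && !is.matrix(features))
    return(lapply(features, function(m)
      combine_tics(unbiased_model, biased_model, m)))
  cbind(predict(unbiased_model, features), predict(biased_model, features))
}
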