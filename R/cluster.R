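#' k-means clustering of projected features into Markovian states
#'
#' k-means with k-means++ initialization and multiple restarts; the restart
#' with the lowest inertia (total within-cluster sum of squares) is kept.
#' Assignment of new frames is to the nearest center, with ties broken
#' deterministically toward the lowest center index.
#'
#' @param features frames x dims numeric matrix (or list of matrices, which
#'   are pooled for fitting).
#' @param k number of clusters (>= 1, <= number of distinct frames).
#' @param seed integer seed controlling initialization.
#' @param n_restarts independent k-means++ starts (default 5).
#' @param iter_max Lloyd iterations per start.
#' @return object of class `cluster_model` with `k`, `centers`, `inertia`,
#'   `seed`.
#' @export
cluster_kmeans <- function(features, k, seed = 1L, n_restarts = 5L,
                           iter_max = 100L) {
  x <- if (is.list(features) && !is.matrix(features))
    do.call(rbind, lapply(features, as.matrix)) else as.matrix(features)
  if (k < 1) stop("`k` must be at least 1")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct)
    stop("`k` exceeds the number of distinct frames")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers0 <- with_seed(seeds[r], kmeanspp_init(x, k))
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers0, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(k = as.integer(k), centers = unname(best$centers),
                 inertia = best$tot.withinss, seed = as.integer(seed)),
            class = "cluster_model")
}

# k-means++ seeding: iteratively pick centers with probability proportional
# to the squared distance to the nearest already-chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = p)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means state model: k = %d, inertia = %.4g\n", x$k, x$inertia))
  invisible(x)
}

#' Assign frames to their nearest cluster center
#'
#' @param model a `cluster_model`.
#' @param features frames x dims matrix or list of matrices.
#' @return integer vector (or list of vectors) of 0-based state indices.
#' @export
assign_states <- function(model, features) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.list(features) && !is.matrix(features))
    return(lapply(features, function(m) assign_states(model, m)))
  x <- as.matrix(features)
  if (ncol(x) != ncol(model$centers)) stop("feature dimension mismatch")
  # squared distances via the expansion |x - c|^2 = |x|^2 - 2 x.c + |c|^2
  cc <- rowSums(model$centers^2)
  d2 <- outer(rowSums(x^2), cc, "+") - 2 * x %*% t(model$centers)
  max.col(-d2, ties.method = "first") - 1L
}

#' Discretize 1-D collective-variable values into uniform bins
#'
#' Half-open bins `[lo, hi)`; values below the first edge map to the first
#' bin, values at or above the last edge to the last bin.  Convenience for
#' 1-D model systems where k-means is unnecessary.
#'
#' @param x numeric vector (or list of vectors) of CV values.
#' @param bin_edges increasing numeric vector of bin edges.
#' @return integer vector (or list) of 0-based bin indices.
#' @export
discretize_cv <- function(x, bin_edges) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE), length(bin_edges) >= 2)
  if (is.list(x)) return(lapply(x, discretize_cv, bin_edges = bin_edges))
  n_bins <- length(bin_edges) - 1L
  idx <- findInterval(x, bin_edges, rightmost.closed = FALSE)
  pmin(pmax(idx, 1L), n_bins) - 1L
}
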