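#' Sample representative frames of a macrostate by stationary weight
#'
#' Draws `n` frames with replacement, with probability proportional to the
#' (e.g. TRAM-derived) stationary weight of each frame, to build a weighted
#' conformational ensemble representing one macrostate.
#'
#' @param weights non-negative per-frame weights over `macrostate_frames`.
#' @param macrostate_frames indices of the frames belonging to the
#'   macrostate.
#' @param n number of representative frames (default 1000).
#' @param seed integer seed (sampling is deterministic per seed).
#' @return object of class `weighted_ensemble`: `frames` (sampled indices),
#'   `weights` (uniform over the sample), `provenance`.
#' @export
sample_macrostate_frames <- function(weights, macrostate_frames, n = 1000L,
                                     seed = 1L) {
  stopifnot(length(weights) == length(macrostate_frames), all(weights >= 0))
  if (sum(weights) == 0) stop("all frame weights are zero")
  picked <- with_seed(seed,
    sample(macrostate_frames, n, replace = TRUE, prob = weights))
  structure(list(frames = picked, weights = rep(1 / n, n),
                 provenance = "stationary-weight resampling"),
            class = "weighted_ensemble")
}

# symmetric KL divergence of two histograms on shared bins, with a
# pseudocount to regularize empty bins
symmetric_kl_hist <- function(a, b, breaks, pseudocount) {
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), length(breaks) - 1L)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), length(breaks) - 1L)
  p <- (pa + pseudocount) / sum(pa + pseudocount)
  q <- (pb + pseudocount) / sum(pb + pseudocount)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

#' Per-feature and per-residue symmetric Kullback-Leibler divergence
#'
#' Compares the distributions of every (inverse-distance) feature between
#' two conformational ensembles: each feature is histogrammed on shared
#' bins spanning the pooled range, regularized with a pseudocount, and the
#' symmetrized divergence `D_sym = (KL(P||Q) + KL(Q||P))/2` is computed.
#' Per-residue aggregates sum the divergences of every feature involving
#' that residue.
#'
#' @param features_A,features_B frames x features matrices with a shared
#'   feature definition (e.g. [inverse_distance_features()] evaluated on
#'   frames sampled from two macrostates).
#' @param residue_map optional list mapping residue names to feature column
#'   indices (a feature may appear under several residues).
#' @param n_bins histogram bins (default 50); coarsened with a warning when
#'   either ensemble has fewer frames than bins.
#' @return object of class `divergence_profile`: `per_feature` (named
#'   vector of divergences, all >= 0), `per_residue` (or `NULL`), `n_bins`.
#' @export
kl_per_residue <- function(features_A, features_B, residue_map = NULL,
                           n_bins = 50L) {
  A <- as.matrix(features_A)
  B <- as.matrix(features_B)
  if (ncol(A) != ncol(B)) stop("shared feature definition required")
  if (nrow(A) == 0 || nrow(B) == 0) stop("both ensembles must be nonempty")
  if (min(nrow(A), nrow(B)) < n_bins) {
    n_bins <- max(5L, min(nrow(A), nrow(B)) %/% 2L)
    warning(sprintf("fewer frames than bins; coarsened to %d bins", n_bins))
  }
  pseudo <- 1 / ((nrow(A) + nrow(B)) * n_bins)
  per_feature <- vapply(seq_len(ncol(A)), function(j) {
    rng <- range(c(A[, j], B[, j]))
    if (rng[1] == rng[2]) return(0)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    symmetric_kl_hist(A[, j], B[, j], breaks, pseudo)
  }, numeric(1))
  names(per_feature) <- colnames(A)
  per_residue <- NULL
  if (!is.null(residue_map)) {
    per_residue <- vapply(residue_map, function(cols) sum(per_feature[cols]),
                          numeric(1))
  }
  structure(list(per_feature = per_feature, per_residue = per_residue,
                 n_bins = n_bins),
            class = "divergence_profile")
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("Symmetric K-L divergence profile: %d features (%d bins)\n",
              length(x$per_feature), x$n_bins))
  top <- sort(x$per_feature, decreasing = TRUE)
  cat("  largest divergences:",
      paste(sprintf("%s=%.3g", names(head(top, 3)), head(top, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Weighted probability of a per-frame event
#'
#' `p = sum_t w_t * 1[event_t]` with normalized weights; invariant under
#' global weight rescaling and bounded in `[0, 1]`.
#'
#' @param indicator logical (or 0/1) vector, one entry per frame.
#' @param weights non-negative per-frame weights (renormalized internally).
#' @return scalar probability.
#' @export
weighted_event_probability <- function(indicator, weights) {
  if (length(indicator) != length(weights))
    stop("indicator and weights must have the same length")
  stopifnot(all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  sum(w[as.logical(indicator)])
}

#' Three-way contact (triad) indicator
#'
#' A triad interaction is formed in a frame when all three pairwise
#' distances are strictly below the threshold (default 5 Angstrom, the
#' criterion used for side-chain oxygen triads).
#'
#' @param d12,d13,d23 per-frame pairwise distances.
#' @param threshold strict upper bound (default 5).
#' @return logical vector per frame.
#' @export
triad_indicator <- function(d12, d13, d23, threshold = 5) {
  d12 < threshold & d13 < threshold & d23 < threshold
}

#' Bootstrap errors by trajectory resampling
#'
#' Re-runs a deterministic estimator on replicates in which a random
#' fraction of the (unbiased) trajectories is dropped without replacement,
#' mirroring the trajectory-bootstrap error estimates used for
#' multi-ensemble kinetic models (the default drops 5% per replicate, 3
#' replicates).  A standard deviation over so few replicates is a coarse
#' spread measure and is reported as-is.
#'
#' @param estimator_fn function taking a list of trajectories and returning
#'   a numeric scalar or vector.
#' @param trajectories list of trajectory objects to resample.
#' @param n_boot number of replicates (default 3).
#' @param fraction fraction of trajectories retained per replicate
#'   (default 0.95).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `replicates` (matrix, one row per
#'   successful replicate) and `failed` (count of failed replicates).
#' @export
bootstrap_errors <- function(estimator_fn, trajectories, n_boot = 3L,
                             fraction = 0.95, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, n_boot >= 1)
  n <- length(trajectories)
  n_keep <- max(1L, round(fraction * n))
  seeds <- derive_seeds(seed, n_boot)
  reps <- list()
  failed <- 0L
  for (b in seq_len(n_boot)) {
    keep <- if (n_keep >= n) seq_len(n) else
      with_seed(seeds[b], sort(sample.int(n, n_keep)))
    val <- tryCatch(estimator_fn(trajectories[keep]),
                    error = function(e) NULL)
    if (is.null(val)) failed <- failed + 1L else reps[[length(reps) + 1L]] <- val
  }
  if (length(reps) == 0) stop("estimator failed in every replicate")
  mat <- do.call(rbind, reps)
  list(mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
       replicates = mat, failed = failed)
}

#' Weighted contact probabilities
#'
#' Weighted fraction of frames in which each pairwise distance is below the
#' cutoff; one probability per distance column, for use as rows of a
#' contact-probability heatmap over macrostates.
#'
#' @param distance_features frames x pairs matrix of distances (consistent
#'   units with `cutoff`).
#' @param cutoff contact cutoff (default 4.5, heavy-atom convention).
#' @param weights optional per-frame weights (default uniform).
#' @return named numeric vector of contact probabilities in `[0, 1]`.
#' @export
contact_probability <- function(distance_features, cutoff = 4.5,
                                weights = NULL) {
  d <- as.matrix(distance_features)
  if (is.null(weights)) weights <- rep(1, nrow(d))
  stopifnot(length(weights) == nrow(d), all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  p <- colSums((d < cutoff) * w)
  names(p) <- colnames(d)
  p
}

#' Histogram mutual information between two dihedral-angle series
#'
#' Plug-in mutual information on a periodic 2-D histogram with
#' Miller-Madow bias correction (each entropy corrected by
#' `(occupied bins - 1)/(2 n)`), clipped at 0.  Angles are binned on
#' uniform bins over `(-pi, pi]`.
#'
#' @param angles_i,angles_j angle series in radians, in `(-pi, pi]`.
#' @param n_bins bins per angle (default 30).
#' @return mutual information in nats (>= 0).
#' @export
mutual_information_dihedrals <- function(angles_i, angles_j, n_bins = 30L) {
  stopifnot(length(angles_i) == length(angles_j))
  n <- length(angles_i)
  if (length(unique(angles_i)) == 1L || length(unique(angles_j)) == 1L) {
    warning("constant input; mutual information is 0")
    return(0)
  }
  if (any(abs(c(angles_i, angles_j)) > pi + 1e-9))
    stop("angles must lie in (-pi, pi]")
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  bi <- pmin(pmax(findInterval(angles_i, breaks, all.inside = TRUE), 1L), n_bins)
  bj <- pmin(pmax(findInterval(angles_j, breaks, all.inside = TRUE), 1L), n_bins)
  joint <- tabulate((bi - 1L) * n_bins + bj, n_bins * n_bins) / n
  pi_m <- tabulate(bi, n_bins) / n
  pj_m <- tabulate(bj, n_bins) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mm <- function(p) (sum(p > 0) - 1) / (2 * n) # Miller-Madow entropy bias
  hi <- h(pi_m) + mm(pi_m)
  hj <- h(pj_m) + mm(pj_m)
  hij <- h(joint) + mm(joint)
  max(hi + hj - hij, 0)
}
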