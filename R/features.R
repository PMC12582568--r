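#' Pairwise inverse-distance features
#'
#' Converts per-frame Cartesian coordinates into the inverse-distance feature
#' set commonly used to capture ligand-pocket geometry: one column per atom
#' pair, entries `1/d_ij` in inverse length units.
#'
#' @param coordinates a frames x atoms x 3 array, or a list of
#'   atoms x 3 matrices (one per frame).
#' @param atom_pairs two-column integer matrix of 1-based atom indices.
#' @return a `feature_matrix`: numeric frames x pairs matrix with labels
#'   `"inv_d_<i>_<j>"`.
#' @export
inverse_distance_features <- function(coordinates, atom_pairs) {
  if (is.list(coordinates)) {
    n_atoms <- nrow(coordinates[[1]])
    coords <- array(NA_real_, c(length(coordinates), n_atoms, 3))
    for (t in seq_along(coordinates)) coords[t, , ] <- coordinates[[t]]
  } else {
    coords <- coordinates
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  atom_pairs <- as.matrix(atom_pairs)
  stopifnot(ncol(atom_pairs) == 2,
            all(atom_pairs >= 1), all(atom_pairs <= dim(coords)[2]))
  n_frames <- dim(coords)[1]
  out <- matrix(NA_real_, n_frames, nrow(atom_pairs))
  for (p in seq_len(nrow(atom_pairs))) {
    i <- atom_pairs[p, 1]; j <- atom_pairs[p, 2]
    d <- sqrt(rowSums((coords[, i, , drop = FALSE] -
                         coords[, j, , drop = FALSE])^2, dims = 1))
    if (any(d == 0)) {
      frame <- which(d == 0)[1]
      stop(sprintf("coincident atoms (d = 0) at frame %d, pair (%d, %d)",
                   frame, i, j))
    }
    out[, p] <- 1 / d
  }
  colnames(out) <- sprintf("inv_d_%d_%d", atom_pairs[, 1], atom_pairs[, 2])
  structure(out, class = c("feature_matrix", "matrix", "array"))
}

#' Coordination-number collective variable
#'
#' Smooth switching-function count of contacts between two atom groups,
#' `CN = sum_ij [1 - (d_ij/d0)^8] / [1 - (d_ij/d0)^16]` with reference
#' distance `d0 = 4.5` Angstrom.  Each term decays smoothly from 1 (close
#' contact) to 0; the removable singularity at `d_ij = d0` is evaluated as
#' the limit `1/(1 + r^8) = 0.5`.
#'
#' @param distances numeric vector or frames x pairs matrix of distances
#'   between ligand atoms and residue anchor atoms (Angstrom).
#' @param d0 switching reference distance (default 4.5 Angstrom).
#' @return scalar per frame (vector), the summed switching terms.
#' @examples
#' coordination_number(4.5)   # exactly 0.5
#' coordination_number(9)     # 255/65535
#' @export
coordination_number <- function(distances, d0 = 4.5) {
  d <- as.matrix(distances)
  stopifnot(all(is.finite(d)), all(d >= 0), d0 > 0)
  r8 <- (d / d0)^8
  term <- ifelse(abs(r8 - 1) < 1e-12,
                 0.5,                      # limit at d = d0
                 (1 - r8) / (1 - r8^2))    # = 1/(1 + r8) off the singularity
  rowSums(term)
}
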