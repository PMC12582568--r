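#' Record of deposited metadynamics hills
#'
#' Stores the Gaussians deposited during a (well-tempered) metadynamics
#' run: deposition time, center(s) in CV space, width(s) and height.  The
#' delimited-text serialization is dialect-compatible with common
#' metadynamics hills logs (columns `time`, one center and one width per
#' CV, `height`, optional `bias_factor`).
#'
#' @param time numeric deposition times.
#' @param center hills x CVs matrix of Gaussian centers (vector for 1 CV).
#' @param width Gaussian widths per CV (single value, vector per CV, or
#'   hills x CVs matrix).
#' @param height non-negative Gaussian heights (energy units, kT here).
#' @param bias_factor optional well-tempered bias factor gamma.
#' @param temperature optional system temperature (K).
#' @return object of class `hills_log`.
#' @export
hills_log <- function(time, center, width, height, bias_factor = NULL,
                      temperature = 300) {
  center <- as.matrix(center)
  n <- nrow(center)
  stopifnot(length(time) == n, length(height) == n, all(height >= 0))
  if (!is.matrix(width))
    width <- matrix(width, n, ncol(center), byrow = length(width) == ncol(center))
  stopifnot(all(width > 0), nrow(width) == n, ncol(width) == ncol(center))
  structure(list(time = as.numeric(time), center = center, width = width,
                 height = as.numeric(height), n_cv = ncol(center),
                 bias_factor = bias_factor, temperature = temperature),
            class = "hills_log")
}

#' @export
print.hills_log <- function(x, ...) {
  cat(sprintf("Hills log: %d hills over %d CV(s), heights in [%.3g, %.3g]\n",
              length(x$time), x$n_cv, min(x$height), max(x$height)))
  invisible(x)
}

#' @rdname hills_log
#' @param file path of a delimited hills file.
#' @param hills a `hills_log` to write.
#' @export
write_hills <- function(hills, file) {
  stopifnot(inherits(hills, "hills_log"))
  df <- data.frame(time = hills$time)
  for (d in seq_len(hills$n_cv)) df[[paste0("center", d)]] <- hills$center[, d]
  for (d in seq_len(hills$n_cv)) df[[paste0("width", d)]] <- hills$width[, d]
  df$height <- hills$height
  if (!is.null(hills$bias_factor)) df$bias_factor <- hills$bias_factor
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname hills_log
#' @export
read_hills <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  n_cv <- sum(grepl("^center", names(df)))
  hills_log(time = df$time,
            center = as.matrix(df[grepl("^center", names(df))]),
            width = as.matrix(df[grepl("^width", names(df))]),
            height = df$height,
            bias_factor = if ("bias_factor" %in% names(df))
              df$bias_factor[1] else NULL)
}

#' Accumulated metadynamics bias at a point
#'
#' Sum over the deposited hills (optionally only those up to `up_to_time`)
#' of `height * prod_i exp(-(S_i - center_i)^2 / (2 width_i^2))`; the bias
#' is repulsive (positive) by convention.  Additive in hills and
#' independent of hill order.
#'
#' @param hills a [hills_log()].
#' @param point numeric CV point (length `n_cv`) or points x CVs matrix.
#' @param up_to_time include only hills with `time <= up_to_time`.
#' @return bias energy value(s) at the point(s), same units as the heights.
#' @export
metad_bias <- function(hills, point, up_to_time = Inf) {
  stopifnot(inherits(hills, "hills_log"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = hills$n_cv)
  if (ncol(pts) != hills$n_cv) stop("point dimension does not match the hills")
  keep <- hills$time <= up_to_time
  if (!any(keep)) return(numeric(nrow(pts)))
  ctr <- hills$center[keep, , drop = FALSE]
  wid <- hills$width[keep, , drop = FALSE]
  h <- hills$height[keep]
  vapply(seq_len(nrow(pts)), function(r) {
    logg <- rowSums(-sweep(ctr, 2, pts[r, ])^2 / (2 * wid^2))
    sum(h * exp(logg))
  }, numeric(1))
}

#' Free-energy profile from the final well-tempered bias
#'
#' In well-tempered metadynamics the converged bias underestimates the free
#' energy by the factor `dT/(T + dT)`; the profile is recovered as
#' `dG(S) = -(T + dT)/dT * V_meta(S, t_final)`, anchored so the minimum is
#' 0.
#'
#' @param hills a [hills_log()] carrying a `bias_factor` gamma, or supply
#'   `bias_factor` explicitly; `gamma = (T + dT)/T` so the prefactor is
#'   `gamma/(gamma - 1)`.
#' @param grid_points numeric vector (1 CV) or points x CVs matrix.
#' @param bias_factor overrides the value stored in `hills`.
#' @return free energies at the grid points (kT), min anchored to 0.
#' @export
metad_free_energy <- function(hills, grid_points, bias_factor = NULL) {
  gamma <- bias_factor %||% hills$bias_factor
  if (is.null(gamma) || gamma <= 1)
    stop("a bias factor > 1 (positive boost temperature) is required")
  v <- metad_bias(hills, if (is.matrix(grid_points)) grid_points
                  else matrix(grid_points, ncol = hills$n_cv))
  dg <- -(gamma / (gamma - 1)) * v
  dg - min(dg)
}

#' Reweight metadynamics frames to the unbiased ensemble
#'
#' Final-bias reweighting: each frame gets weight proportional to
#' `exp(+V_meta(s_t, t_final)/kT)`, normalized to sum to 1.  (A
#' time-dependent reweighting would additionally track the moving bias
#' offset; the final-bias estimator is the simplest consistent choice for
#' converged runs.)
#'
#' @param cv_series per-frame CV values (vector or frames x CVs matrix).
#' @param hills a [hills_log()] with heights in kT.
#' @return normalized per-frame weights.
#' @export
metad_reweight <- function(cv_series, hills) {
  pts <- if (is.matrix(cv_series)) cv_series
         else matrix(cv_series, ncol = hills$n_cv)
  v <- metad_bias(hills, pts)
  w <- exp(v - max(v))
  w / sum(w)
}
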