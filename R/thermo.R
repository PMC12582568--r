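#' Weighted multidimensional potential of mean force
#'
#' Bins collective-variable values on a regular grid (half-open bins
#' `[lo, hi)` in each dimension) and converts the accumulated normalized
#' frame weights into free energies `W = -ln(sum of weights in bin)`,
#' anchored so the lowest finite bin is 0.  Empty bins are `+Inf`.  The
#' result is invariant under global rescaling of the weights.
#'
#' @param cv_values frames x dims matrix (or vector for 1-D) of CV values.
#' @param frame_weights per-frame weights (e.g. TRAM stationary weights);
#'   renormalized internally.
#' @param bin_edges list of increasing edge vectors, one per dimension (or
#'   a single vector for 1-D).
#' @param kT thermal energy used only to tag the grid's units (energies are
#'   returned in kT).
#' @param weights_source provenance tag stored on the grid (e.g. `"tram"`,
#'   `"uniform"`).
#' @return object of class `pmf_grid`: `W` (array of free energies in kT),
#'   `bin_edges`, `bin_volume`, `n_dropped` frames outside the grid,
#'   `weights_source`.
#' @export
weighted_pmf <- function(cv_values, frame_weights, bin_edges, kT = 1,
                         weights_source = "user") {
  x <- as.matrix(cv_values)
  if (!is.list(bin_edges)) bin_edges <- list(bin_edges)
  stopifnot(ncol(x) == length(bin_edges))
  for (e in bin_edges)
    stopifnot(length(e) >= 2, !is.unsorted(e, strictly = TRUE))
  w <- as.numeric(frame_weights)
  stopifnot(length(w) == nrow(x), all(w >= 0))
  w <- w / sum(w)
  dims <- vapply(bin_edges, function(e) length(e) - 1L, integer(1))
  idx <- matrix(NA_integer_, nrow(x), ncol(x))
  inside <- rep(TRUE, nrow(x))
  for (d in seq_along(bin_edges)) {
    id <- findInterval(x[, d], bin_edges[[d]], rightmost.closed = FALSE)
    inside <- inside & id >= 1L & id <= dims[d]
    idx[, d] <- id
  }
  n_dropped <- sum(!inside)
  idx <- idx[inside, , drop = FALSE]
  w_in <- w[inside]
  # linear bin index (first dimension fastest, as in array storage)
  lin <- idx[, 1]
  if (ncol(idx) > 1) {
    mult <- cumprod(dims)
    for (d in 2:ncol(idx)) lin <- lin + (idx[, d] - 1L) * mult[d - 1L]
  }
  mass <- numeric(prod(dims))
  agg <- rowsum(w_in, lin)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  W <- -log(mass)
  W[!is.finite(W)] <- Inf
  finite <- is.finite(W)
  if (!any(finite)) stop("all bins are empty")
  W <- W - min(W[finite])
  dim(W) <- dims
  structure(list(W = W, bin_edges = bin_edges,
                 bin_volume = prod(vapply(bin_edges,
                                          function(e) mean(diff(e)),
                                          numeric(1))),
                 bin_widths = lapply(bin_edges, diff),
                 n_dropped = n_dropped, kT = kT,
                 weights_source = weights_source),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("PMF grid: %s bins, %d empty, depth range [0, %.3g] kT\n",
              paste(dim(as.array(x$W)), collapse = " x "),
              sum(!is.finite(x$W)), max(x$W[is.finite(x$W)])))
  if (x$n_dropped > 0)
    cat(sprintf("  %d frames fell outside the grid and were dropped\n",
                x$n_dropped))
  invisible(x)
}

#' Bulk plateau depth of a PMF
#'
#' Averages the free energy over bins of the bulk (unbound) region to give
#' the plateau value `delta W` that references the PMF depth.  The default
#' policy averages the `n_bins` best-sampled (lowest-W) finite bulk bins;
#' `policy = "highest"` instead averages the `n_bins` highest-W finite bulk
#' bins, and `policy = "all"` averages every finite bulk bin.  If fewer
#' than `n_bins` finite bulk bins exist, all of them are used with a
#' warning.
#'
#' @param grid a `pmf_grid`.
#' @param bulk_mask logical array (same shape as `grid$W`) or vector of
#'   linear bin indices marking the bulk region.
#' @param n_bins number of bulk bins to average (default 100).
#' @param policy `"lowest"` (default), `"highest"`, or `"all"`.
#' @return scalar `delta W` in kT.
#' @export
bulk_depth <- function(grid, bulk_mask, n_bins = 100L,
                       policy = c("lowest", "highest", "all")) {
  policy <- match.arg(policy)
  stopifnot(inherits(grid, "pmf_grid"))
  w <- if (is.logical(bulk_mask)) grid$W[bulk_mask] else grid$W[as.integer(bulk_mask)]
  w <- w[is.finite(w)]
  if (length(w) == 0) stop("no finite bulk bins")
  if (policy != "all" && length(w) < n_bins) {
    warning(sprintf("only %d finite bulk bins available (requested %d); using all",
                    length(w), n_bins))
    n_bins <- length(w)
  }
  sel <- switch(policy,
                lowest = sort(w)[seq_len(n_bins)],
                highest = sort(w, decreasing = TRUE)[seq_len(n_bins)],
                all = w)
  mean(sel)
}

#' Standard binding free energy with volumetric correction
#'
#' Computes the PMF contribution from the Boltzmann-weighted volume of the
#' bound region, `dG = -kT ln[ sum_bound exp(-W) dV / V_o ] - delta_W`
#' (energies in kT), where the bound region collects bins with free energy
#' below `bound_threshold` above the anchored minimum, `delta_W` is the
#' bulk plateau depth, and `V_o` is the standard-state volume (1661
#' Angstrom^3 per molecule at 1 M).  When the unbound-region volume `V_u`
#' is supplied, the volumetric correction `dG_V = -ln(V_u / V_o)` and the
#' PMF term are reported separately; the decomposition
#' `dG = dG_pmf + dG_V` holds exactly by construction.
#'
#' @param grid a `pmf_grid` whose coordinates are in the same length units
#'   as `V_o` (conventionally Angstrom).
#' @param delta_W bulk plateau depth in kT (see [bulk_depth()]).
#' @param V_o standard-state volume (default 1661, in Angstrom^3).
#' @param V_u volume of the unbound region of the simulation box; default
#'   `V_o` (no correction).
#' @param bound_threshold bound-region cutoff above the PMF minimum, in kT
#'   (default 1 kcal/mol at 300 K).
#' @param temperature temperature for the kcal/mol conversion of the output.
#' @return object of class `binding_free_energy` with `dG_kt`, `dG_kcal`,
#'   `dG_pmf`, `dG_V`, `delta_W`, `V_o`, `V_u`, `n_bound_bins`.
#' @export
standard_binding_dG <- function(grid, delta_W, V_o = 1661, V_u = V_o,
                                bound_threshold = kcal_to_kt(1),
                                temperature = 300) {
  stopifnot(inherits(grid, "pmf_grid"), V_o > 0, V_u > 0)
  W <- grid$W
  bound <- is.finite(W) & W < bound_threshold
  if (!any(bound))
    stop(sprintf("no bound bins under the %.3g kT threshold", bound_threshold))
  vol <- bin_volume_array(grid)
  bound_integral <- sum(exp(-W[bound]) * vol[bound])
  dG_V <- -log(V_u / V_o)
  dG_pmf <- -log(bound_integral / V_u) - delta_W
  dG <- dG_pmf + dG_V
  structure(list(dG_kt = dG, dG_kcal = kt_to_kcal(dG, temperature),
                 dG_pmf = dG_pmf, dG_V = dG_V, delta_W = delta_W,
                 V_o = V_o, V_u = V_u, bound_threshold = bound_threshold,
                 n_bound_bins = sum(bound)),
            class = "binding_free_energy")
}

# per-bin volume array for a (possibly non-uniform) grid
bin_volume_array <- function(grid) {
  widths <- grid$bin_widths
  vol <- widths[[1]]
  if (length(widths) > 1)
    for (d in 2:length(widths)) vol <- outer(vol, widths[[d]])
  array(vol, dim = dim(as.array(grid$W)))
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("Standard binding free energy: %.3f kT (%.3f kcal/mol)\n",
              x$dG_kt, x$dG_kcal))
  cat(sprintf("  dG_pmf = %.3f kT, dG_V = %.3f kT, bulk depth dW = %.3f kT\n",
              x$dG_pmf, x$dG_V, x$delta_W))
  cat(sprintf("  %d bound bins under %.3g kT; V_o = %g, V_u = %g\n",
              x$n_bound_bins, x$bound_threshold, x$V_o, x$V_u))
  invisible(x)
}
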