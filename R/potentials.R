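#' Model potentials with analytic energies and gradients
#'
#' Defines the ground-truth potentials the synthetic-data generators sample
#' from.  Energies are in kT (with `beta` the inverse temperature in the same
#' reduced units, default 1), lengths in reduced units.  Available forms:
#'
#' * `"double_well"`: U(x) = h (x^2 - 1)^2, a symmetric double well with
#'   minima at x = -1, 1 and barrier height `h` kT at x = 0.  An optional
#'   `tilt` parameter adds a linear term `tilt * x`, offsetting the two wells
#'   (used for asymmetric-well studies).
#' * `"harmonic"`: U(x) = kappa/2 * (x - x0)^2.
#' * `"funnel2d"`: U(x, y) = h (x^2 - 1)^2 + kappa_y/2 * y^2, a double well
#'   with a harmonic orthogonal coordinate.
#' * `"tabulated"`: linear interpolation of user-supplied `(x, u)` nodes;
#'   gradient by finite slope of the interpolant.
#'
#' @param form one of `"double_well"`, `"harmonic"`, `"funnel2d"`,
#'   `"tabulated"`.
#' @param ... named numeric parameters of the chosen form (see Details).
#' @param beta inverse temperature; energies are in kT so the default is 1.
#' @return An object of class `potential_spec` with `$energy(x)` and
#'   `$gradient(x)` functions.
#' @examples
#' pot <- potential_spec("double_well", h = 5)
#' pot$energy(0)     # barrier top: 5 kT
#' pot$gradient(1)   # minimum: zero force
#' @export
potential_spec <- function(form = c("double_well", "harmonic", "funnel2d",
                                    "tabulated"),
                           ..., beta = 1) {
  form <- match.arg(form)
  pars <- list(...)
  stopifnot(beta > 0)
  spec <- switch(form,
    double_well = {
      h <- pars$h %||% 5
      tilt <- pars$tilt %||% 0
      stopifnot(h > 0)
      list(
        parameters = list(h = h, tilt = tilt),
        energy = function(x) h * (x^2 - 1)^2 + tilt * x,
        gradient = function(x) 4 * h * x * (x^2 - 1) + tilt
      )
    },
    harmonic = {
      kappa <- pars$kappa %||% 1
      x0 <- pars$x0 %||% 0
      stopifnot(kappa > 0)
      list(
        parameters = list(kappa = kappa, x0 = x0),
        energy = function(x) 0.5 * kappa * (x - x0)^2,
        gradient = function(x) kappa * (x - x0)
      )
    },
    funnel2d = {
      h <- pars$h %||% 5
      kappa_y <- pars$kappa_y %||% 2
      stopifnot(h > 0, kappa_y > 0)
      list(
        parameters = list(h = h, kappa_y = kappa_y),
        energy = function(x) {
          x <- matrix(x, ncol = 2)
          h * (x[, 1]^2 - 1)^2 + 0.5 * kappa_y * x[, 2]^2
        },
        gradient = function(x) {
          x <- matrix(x, ncol = 2)
          cbind(4 * h * x[, 1] * (x[, 1]^2 - 1), kappa_y * x[, 2])
        }
      )
    },
    tabulated = {
      x <- pars$x
      u <- pars$u
      stopifnot(is.numeric(x), is.numeric(u), length(x) == length(u),
                length(x) >= 2, !is.unsorted(x, strictly = TRUE))
      efun <- stats::approxfun(x, u, rule = 2)
      slopes <- diff(u) / diff(x)
      gfun <- function(p) {
        idx <- pmin(pmax(findInterval(p, x), 1L), length(slopes))
        slopes[idx]
      }
      list(parameters = list(x = x, u = u), energy = efun, gradient = gfun)
    }
  )
  structure(
    list(form = form, parameters = spec$parameters, beta = beta,
         energy = spec$energy, gradient = spec$gradient,
         ndim = if (form == "funnel2d") 2L else 1L),
    class = "potential_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.potential_spec <- function(x, ...) {
  pars <- paste(names(x$parameters),
                vapply(x$parameters, function(p) paste(signif(p, 4), collapse = ","),
                       character(1)),
                sep = " = ", collapse = ", ")
  cat(sprintf("Model potential '%s' (%s; beta = %g, energies in kT)\n",
              x$form, pars, x$beta))
  invisible(x)
}

#' Analytic binned free-energy reference for a model potential
#'
#' Integrates the Boltzmann density of a 1-D potential over each bin by
#' adaptive quadrature and returns per-bin free energies
#' F_bin = -ln integral(exp(-beta U)) anchored so the lowest bin is 0.
#' This is the ground truth that estimated -ln(pi) profiles are compared
#' against in recovery tests.
#'
#' @param potential a 1-D [potential_spec()].
#' @param bin_edges increasing numeric vector of bin edges (half-open bins
#'   `[lo, hi)`).
#' @return numeric vector of length `length(bin_edges) - 1` of free energies
#'   in kT, min anchored to 0.
#' @examples
#' pot <- potential_spec("harmonic", kappa = 4)
#' analytic_reference(pot, seq(-1, 1, length.out = 11))
#' @export
analytic_reference <- function(potential, bin_edges) {
  stopifnot(inherits(potential, "potential_spec"), potential$ndim == 1L)
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2,
            !is.unsorted(bin_edges, strictly = TRUE))
  beta <- potential$beta
  dens <- function(x) exp(-beta * potential$energy(x))
  z <- vapply(seq_len(length(bin_edges) - 1L), function(i) {
    stats::integrate(dens, bin_edges[i], bin_edges[i + 1L],
                     rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1))
  if (all(z <= 0)) stop("integration domain has zero Boltzmann weight")
  f <- -log(z)
  f - min(f)
}
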