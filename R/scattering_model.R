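#' Convert between momentum transfer Q and Bragg spacing d
#'
#' Uses the convention `Q = 2*pi/d`, so the two functions are mutually
#' inverse involutions up to naming.
#'
#' @param q,d Positive numerics (1/Angstrom and Angstrom respectively).
#' @return `q_to_d` returns `d = 2*pi/Q` in Angstrom; `d_to_q` the inverse.
#' @examples
#' q_to_d(1.312)  # ~4.79 A, the cross-beta hydrogen-bonding repeat
#' q_to_d(0.63)   # ~10 A, the intersheet spacing
#' @export
q_to_d <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q_to_d: domain error: Q must be > 0")
  2 * pi / q
}

#' @rdname q_to_d
#' @export
d_to_q <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("d_to_q: domain error: d must be > 0")
  2 * pi / d
}

#' Solid cylinder cross-section unit
#'
#' The elementary diffracting unit: an infinitely long solid cylinder of
#' uniform density contrast, with optional Gaussian polydispersity in the
#' cross-section radius.
#'
#' @param r Mean cross-section radius (Angstrom), `> 0`.
#' @param sigma_r Gaussian polydispersity standard deviation (Angstrom),
#'   `>= 0` and `< r/3` for truncation safety.
#' @param density Uniform scattering-length/electron density contrast
#'   (arbitrary units).
#' @return An object of class `cylinder_unit`.
#' @export
cylinder_unit <- function(r, sigma_r = 0, density = 1) {
  if (!is.numeric(r) || r <= 0) stop("cylinder_unit: r must be > 0")
  if (!is.numeric(sigma_r) || sigma_r < 0)
    stop("cylinder_unit: sigma_r must be >= 0")
  if (sigma_r >= r / 3)
    stop("cylinder_unit: sigma_r must be < r/3 (truncation safety)")
  structure(list(r = r, sigma_r = sigma_r, density = density),
            class = "cylinder_unit")
}

#' Circular lattice of n equally spaced points
#'
#' @param n Number of elements on the circle (integer `>= 1`).
#' @param radius Circle radius (Angstrom, `>= 0`); must be 0 when `n = 1`.
#' @return An object of class `circular_lattice`.
#' @export
circular_lattice <- function(n, radius = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("circular_lattice: n must be an integer >= 1")
  if (!is.numeric(radius) || radius < 0)
    stop("circular_lattice: radius must be >= 0")
  if (n == 1L && radius != 0)
    stop("circular_lattice: radius must be 0 when n = 1")
  structure(list(n = n, radius = radius), class = "circular_lattice")
}

#' Two-level hierarchical arrangement of solid cylinders
#'
#' `n0` cylinder units on an inner circle of radius `r0`, the whole inner
#' assembly repeated `n1` times on an outer circle of radius `r1`. Emits a
#' warning (model still evaluable) if the inner units geometrically overlap.
#'
#' @param unit A [cylinder_unit].
#' @param inner Inner [circular_lattice] (`n0`, `r0`).
#' @param outer Outer [circular_lattice] (`n1`, `r1`); defaults to a single
#'   site (no superstructure).
#' @param scale Multiplicative intensity scale, `> 0`.
#' @return An object of class `hierarchical_model`.
#' @examples
#' # Four 106-A-diameter units on a 160-A circle (single level)
#' m <- hierarchical_model(cylinder_unit(53), circular_lattice(4, 80))
#' inner_assembly_diameter(m)
#' @export
hierarchical_model <- function(unit, inner, outer = circular_lattice(1L, 0),
                               scale = 1) {
  stopifnot(inherits(unit, "cylinder_unit"),
            inherits(inner, "circular_lattice"),
            inherits(outer, "circular_lattice"))
  if (!is.numeric(scale) || scale <= 0)
    stop("hierarchical_model: scale must be > 0")
  if (inner$n >= 2L &&
      2 * inner$radius * sin(pi / inner$n) < 2 * unit$r)
    warning("hierarchical_model: inner lattice spacing smaller than unit diameter (overlapping cylinders)")
  structure(list(unit = unit, inner = inner, outer = outer, scale = scale),
            class = "hierarchical_model")
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat(sprintf(paste0("<hierarchical_model> unit r = %g A (sigma %g), ",
                     "inner n0 = %d on r0 = %g A, outer n1 = %d on r1 = %g A, scale %g\n"),
              x$unit$r, x$unit$sigma_r, x$inner$n, x$inner$radius,
              x$outer$n, x$outer$radius, x$scale))
  cat(sprintf("  inner assembly diameter: %g A\n", inner_assembly_diameter(x)))
  invisible(x)
}

#' @rdname hierarchical_model
#' @param model A `hierarchical_model`.
#' @return `inner_assembly_diameter` returns the total cross-section
#'   diameter of the inner assembly, `2*r0 + 2*r`.
#' @export
inner_assembly_diameter <- function(model) {
  stopifnot(inherits(model, "hierarchical_model"))
  2 * model$inner$radius + 2 * model$unit$r
}

# 2 J1(x)/x with its series limit near x = 0.
.ff_amp_ratio <- function(x, fast = FALSE) {
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- 1 - x[small]^2 / 8
  if (any(!small)) {
    xb <- x[!small]
    out[!small] <- 2 * bessel_j(xb, 1, fast) / xb
  }
  out
}

#' Squared form factor of the cylinder cross-section
#'
#' For a monodisperse solid cylinder the equatorial amplitude is
#' `density * pi * r^2 * 2 J1(Q r) / (Q r)` (the argument `Q r` equals
#' `2 pi R r` in the reduced coordinate `R = Q / 2 pi`), with limit
#' `density * pi * r^2` at `Q = 0`. With polydispersity, the squared
#' amplitude is averaged over a Gaussian radius distribution truncated at
#' four standard deviations around the mean (truncated at positive radius) using 41-point Gauss-Legendre
#' quadrature with renormalized weights.
#'
#' @param unit A [cylinder_unit].
#' @param q Momentum transfer values, all `>= 0`.
#' @param fast Use the interpolation-table Bessel evaluation (internal
#'   optimizer use; reported values should keep the default).
#' @return Non-negative numeric vector, same length as `q`.
#' @export
form_factor_sq <- function(unit, q, fast = FALSE) {
  stopifnot(inherits(unit, "cylinder_unit"))
  if (any(q < 0)) stop("form_factor_sq: Q must be >= 0")
  if (unit$sigma_r <= 0) {
    amp <- unit$density * pi * unit$r^2 * .ff_amp_ratio(q * unit$r, fast)
    return(amp^2)
  }
  gl <- gauss_legendre(41L)
  lo <- max(1e-6, unit$r - 4 * unit$sigma_r)
  hi <- unit$r + 4 * unit$sigma_r
  rn <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
  w <- gl$weights * exp(-0.5 * ((rn - unit$r) / unit$sigma_r)^2)
  w <- w / sum(w)
  x <- outer(q, rn)                      # |q| x 41 arguments
  ratio <- matrix(.ff_amp_ratio(as.vector(x), fast), nrow = length(q))
  amp2 <- (unit$density * pi)^2 *
    sweep(ratio, 2L, rn^2, `*`)^2
  drop(amp2 %*% w)
}

#' Cylindrically averaged interference function of a circular lattice
#'
#' For `n` equally spaced points on a circle of given radius the
#' cylindrical average of the squared lattice sum is
#' `Phi^2(Q) = n * (1 + sum_{m=1}^{n-1} J0(2 Q radius sin(pi m / n)))`,
#' with `Phi^2(0) = n^2` and `Phi^2 == 1` for `n = 1`.
#'
#' @param lattice A [circular_lattice].
#' @param q Momentum transfer values, all `>= 0`.
#' @param fast See [form_factor_sq].
#' @return Numeric vector, same length as `q`.
#' @export
lattice_interference <- function(lattice, q, fast = FALSE) {
  stopifnot(inherits(lattice, "circular_lattice"))
  if (any(q < 0)) stop("lattice_interference: Q must be >= 0")
  n <- lattice$n
  if (n == 1L) return(rep(1, length(q)))
  m <- seq_len(n - 1L)
  chords <- 2 * lattice$radius * sin(pi * m / n)
  x <- outer(q, chords)
  j0 <- matrix(bessel_j(as.vector(x), 0, fast), nrow = length(q))
  n * (1 + rowSums(j0))
}

# Scale-free intensity values on arbitrary q >= 0 (internal work-horse).
.model_values <- function(model, q, fast = FALSE) {
  model$scale *
    form_factor_sq(model$unit, q, fast) *
    lattice_interference(model$inner, q, fast) *
    lattice_interference(model$outer, q, fast)
}

#' Equatorial intensity of the hierarchical cylinder model
#'
#' The cylindrically averaged equatorial intensity is the product of the
#' unit form factor and the two lattice interference functions,
#' `I(Q) = scale * f^2(Q) * Phi^2(n0, r0, Q) * Phi~^2(n1, r1, Q)`. The
#' factorization is exact for a single level (`n1 = 1`) and an approximation
#' of the true cylindrical average otherwise; [oracle_intensity] quantifies
#' the deviation.
#'
#' `model_intensity_at` evaluates at arbitrary `Q >= 0` (including the
#' `Q = 0` limit `scale * (density pi r^2)^2 * n0^2 * n1^2`);
#' `model_intensity` wraps a strictly positive grid into a [profile1d].
#'
#' @param model A [hierarchical_model].
#' @param q_grid Strictly increasing grid of positive Q values.
#' @param q Arbitrary Q values `>= 0`.
#' @param fast See [form_factor_sq].
#' @return `model_intensity` returns a [profile1d]; `model_intensity_at` a
#'   numeric vector.
#' @export
model_intensity <- function(model, q_grid, fast = FALSE) {
  stopifnot(inherits(model, "hierarchical_model"))
  if (length(q_grid) == 0L) stop("model_intensity: input error: empty grid")
  profile1d(q_grid, model_intensity_at(model, q_grid, fast),
            label = "model")
}

#' @rdname model_intensity
#' @export
model_intensity_at <- function(model, q, fast = FALSE) {
  stopifnot(inherits(model, "hierarchical_model"))
  if (any(q < 0)) stop("model_intensity_at: Q must be >= 0")
  .model_values(model, q, fast)
}

# Explicit cylinder-center coordinates of the two-level arrangement: the
# inner ring is rotated onto each outer-circle site.
.model_centers <- function(model) {
  n0 <- model$inner$n; r0 <- model$inner$radius
  n1 <- model$outer$n; r1 <- model$outer$radius
  th1 <- 2 * pi * (seq_len(n1) - 1L) / n1
  th0 <- 2 * pi * (seq_len(n0) - 1L) / n0
  ang <- outer(th0, th1, `+`)            # inner ring rotated with its site
  cx <- as.vector(r0 * cos(ang) + rep(r1 * cos(th1), each = n0))
  cy <- as.vector(r0 * sin(ang) + rep(r1 * sin(th1), each = n0))
  cbind(cx, cy)
}

#' Brute-force cylindrical average of the literal structure
#'
#' Places all `n0 * n1` cylinder centers explicitly in the plane and
#' computes `|sum_j F(Q) exp(i Q . c_j)|^2` averaged over `n_azimuth`
#' equally spaced directions of the scattering vector. This is the exact
#' (to quadrature error) cylindrical average of the literal structure and
#' serves as the independent oracle for [model_intensity]; the two agree to
#' machine precision whenever `n1 = 1`.
#'
#' @param model A [hierarchical_model] (the unit is taken monodisperse at
#'   its mean radius unless `sigma_r = 0`; the incoherent polydispersity
#'   average multiplies through the common form factor).
#' @param q Momentum transfer values, all `>= 0`.
#' @param n_azimuth Number of azimuthal quadrature points (`>= 360`).
#' @return Numeric vector of intensities, same length as `q`.
#' @export
oracle_intensity <- function(model, q, n_azimuth = 720L) {
  stopifnot(inherits(model, "hierarchical_model"))
  n_azimuth <- as.integer(n_azimuth)
  if (n_azimuth < 360L) stop("oracle_intensity: n_azimuth must be >= 360")
  if (any(q < 0)) stop("oracle_intensity: Q must be >= 0")
  cen <- .model_centers(model)
  phi <- 2 * pi * (seq_len(n_azimuth) - 1L) / n_azimuth
  ux <- cos(phi); uy <- sin(phi)
  ff <- form_factor_sq(model$unit, q)
  lat <- vapply(seq_along(q), function(k) {
    dots <- q[k] * (outer(ux, cen[, 1L]) + outer(uy, cen[, 2L]))
    amps <- rowSums(exp(1i * dots))
    mean(Mod(amps)^2)
  }, numeric(1L))
  model$scale * ff * lat
}
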