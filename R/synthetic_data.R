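# Seed-deterministic synthetic data with machine-readable ground truth:
# equatorial profiles, oriented 2D patterns, powder profiles, decay curves,
# and the four named sample scenarios.

.apply_noise <- function(values, noise_fraction, seed) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  if (noise_fraction == 0) return(values)
  with_seed(seed,
            pmax(values * (1 + noise_fraction * stats::rnorm(length(values))), 0))
}

#' Synthetic equatorial profile with known ground truth
#'
#' Model intensity plus a polynomial background, then multiplicative
#' Gaussian noise (`sigma` proportional to intensity, a stand-in for
#' counting statistics at high flux), floored at zero. The full generator
#' parameter set, including the seed, is attached as `attr(, "truth")`.
#'
#' @param model A [hierarchical_model].
#' @param q_grid Strictly increasing positive Q grid.
#' @param background_coeffs Ascending polynomial background coefficients.
#' @param noise_fraction Relative noise level (0 = noiseless).
#' @param seed Integer seed (local to the call; caller RNG untouched).
#' @return A [profile1d] with a `truth` attribute.
#' @export
gen_profile <- function(model, q_grid, background_coeffs = 0,
                        noise_fraction = 0, seed = NULL) {
  clean <- model_intensity_at(model, q_grid) +
    polyval(background_coeffs, q_grid)
  noisy <- .apply_noise(clean, noise_fraction, seed)
  out <- profile1d(q_grid, noisy, label = "synthetic equatorial profile")
  attr(out, "truth") <- list(model = model,
                             background_coeffs = background_coeffs,
                             noise_fraction = noise_fraction, seed = seed)
  out
}

# Azimuthal Gaussian kernel with 180-degree (Friedel) periodicity.
.az_kernel <- function(phi, center, sigma) {
  y <- 0
  for (k in -1:1) {
    d <- ((phi - center) %% 180) + 180 * k
    y <- y + exp(-0.5 * (d / sigma)^2)
  }
  y
}

#' Synthetic 2D fiber pattern with oriented populations
#'
#' Each pixel receives `sum_pop weight * I_model(Q) * G(phi - phi_pop;
#' sigma_pop)` (angles folded to a half-turn), on top of an isotropic
#' background level, with optional multiplicative noise; a beam-stop disc
#' is zeroed. `model` may be a single [hierarchical_model] or a list of
#' them with `model_weights` (an intensity-weighted superposition, as for
#' a mixed sample); `model = NULL` produces a weak featureless central
#' blob (the near-featureless scenario). A warning is emitted when the
#' detector's Q range misses the model's main features.
#'
#' @param model A [hierarchical_model], a list of them, or `NULL`.
#' @param populations `data.frame(center, sigma, weight)` of fiber-axis
#'   populations in degrees (weights positive, summing to 1), or `NULL`
#'   for an isotropic pattern.
#' @param geometry A [detector_geometry].
#' @param shape `(rows, cols)` of the detector grid.
#' @param amplitude Peak radial amplitude above background.
#' @param background Isotropic background level.
#' @param noise_fraction,seed See [gen_profile].
#' @param beamstop_mm Beam-stop disc radius (mm) zeroed around the center.
#' @param axis_direction Fiber-axis azimuth on the image (degrees).
#' @param model_weights Weights when `model` is a list.
#' @return A [pattern2d] with a `truth` attribute.
#' @export
gen_pattern <- function(model, populations, geometry,
                        shape = c(129L, 129L), amplitude = 100,
                        background = 1, noise_fraction = 0, seed = NULL,
                        beamstop_mm = 6, axis_direction = 0,
                        model_weights = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (!is.null(populations)) {
    populations <- as.data.frame(populations)
    if (any(populations$weight <= 0) ||
        abs(sum(populations$weight) - 1) > 1e-8)
      stop("gen_pattern: population weights must be positive and sum to 1")
  }
  skel <- pattern2d(matrix(0, shape[1L], shape[2L]), geometry,
                    axis_direction = axis_direction)
  pm <- .pixel_map(skel)
  models <- if (is.null(model)) list()
            else if (inherits(model, "hierarchical_model")) list(model)
            else model
  w <- model_weights %||% rep(1 / max(length(models), 1L), length(models))
  if (length(models)) {
    radial <- 0
    for (j in seq_along(models))
      radial <- radial + w[j] * model_intensity_at(models[[j]], as.vector(pm$q))
    qpk <- as.vector(pm$q)[which.max(radial * as.vector(pm$q > 0))]
    if (max(pm$q) < 2 * qpk)
      warning("gen_pattern: detector Q range barely covers the model features")
    radial <- radial / max(radial)
  } else {
    q0 <- max(pm$q) / 10                  # weak featureless central blob
    radial <- 0.05 * exp(-(as.vector(pm$q) / q0)^2)
  }
  ang <- if (is.null(populations)) 1 else {
    a <- 0
    for (j in seq_len(nrow(populations)))
      a <- a + populations$weight[j] *
        .az_kernel(as.vector(pm$phi), populations$center[j],
                   populations$sigma[j])
    a
  }
  vals <- background + amplitude * radial * ang
  vals <- .apply_noise(vals, noise_fraction, seed)
  vals[as.vector(pm$rho) <= beamstop_mm] <- 0
  out <- pattern2d(matrix(vals, shape[1L], shape[2L]), geometry,
                   axis_direction = axis_direction)
  attr(out, "truth") <- list(models = models, model_weights = w,
                             populations = populations,
                             amplitude = amplitude, background = background,
                             noise_fraction = noise_fraction, seed = seed,
                             beamstop_mm = beamstop_mm,
                             axis_direction = axis_direction)
  out
}

#' Synthetic powder profile with rings at given d-spacings
#'
#' Gaussian peaks at `Q = 2 pi / d` on a smooth polynomial background.
#'
#' @param d_spacings Bragg spacings in Angstrom (may be empty for pure
#'   background).
#' @param widths Gaussian sigmas (1/Angstrom), recycled.
#' @param heights Peak heights, recycled.
#' @param q_grid Strictly increasing positive Q grid.
#' @param background_coeffs Ascending polynomial background coefficients.
#' @param noise_fraction,seed See [gen_profile].
#' @return A [profile1d] with a `truth` attribute.
#' @export
gen_powder <- function(d_spacings, widths = 0.02, heights = 1, q_grid,
                       background_coeffs = c(1, 0),
                       noise_fraction = 0, seed = NULL) {
  if (length(d_spacings) && any(d_spacings <= 0))
    stop("gen_powder: d_spacings must be > 0")
  widths <- rep_len(widths, length(d_spacings))
  heights <- rep_len(heights, length(d_spacings))
  y <- polyval(background_coeffs, q_grid)
  centers <- if (length(d_spacings)) 2 * pi / d_spacings else numeric()
  for (j in seq_along(centers))
    y <- y + heights[j] * exp(-0.5 * ((q_grid - centers[j]) / widths[j])^2)
  y <- .apply_noise(y, noise_fraction, seed)
  out <- profile1d(q_grid, y, label = "synthetic powder profile")
  attr(out, "truth") <- list(d_spacings = d_spacings, widths = widths,
                             heights = heights,
                             background_coeffs = background_coeffs,
                             noise_fraction = noise_fraction, seed = seed)
  out
}

#' Synthetic D-to-H exchange decay curve
#'
#' Exact exponential `i_inf + (i0 - i_inf) exp(-t/tau)` plus multiplicative
#' Gaussian noise, floored at zero.
#'
#' @param tau Exchange time (hours), `> 0`.
#' @param i0,i_inf Initial intensity and asymptote.
#' @param t_grid Times (hours).
#' @param noise_fraction,seed See [gen_profile].
#' @return A [decay_curve] with a `truth` attribute.
#' @export
gen_decay <- function(tau, i0 = 1, i_inf = 0, t_grid,
                      noise_fraction = 0, seed = NULL) {
  if (tau <= 0) stop("gen_decay: tau must be > 0")
  y <- i_inf + (i0 - i_inf) * exp(-t_grid / tau)
  y <- .apply_noise(y, noise_fraction, seed)
  out <- decay_curve(t_grid, y)
  attr(out, "truth") <- list(tau = tau, i0 = i0, i_inf = i_inf,
                             noise_fraction = noise_fraction, seed = seed)
  out
}

#' The four named sample scenarios
#'
#' Versioned ground-truth scenarios emulating the study's four samples:
#'
#' * `WT`: four 106-Angstrom-diameter units on a 160-Angstrom circle
#'   (single level), a symmetric double orientation tilted 31 degrees,
#'   high crystallinity, exchange time 2.58 h.
#' * `A2V`: three 36-Angstrom units in a 132-Angstrom bundle, three
#'   bundles on a 196-Angstrom-diameter circle, a single tight
#'   orientation, low crystallinity, exchange time 1.90 h.
#' * `WT_A2V`: intensity-weighted superposition of the two arrangements,
#'   tilt pair 27 degrees, exchange time 2.45 h.
#' * `WT_1to6A2V`: no resolvable model; a weak, near-featureless pattern
#'   with no preferred direction.
#'
#' @return A named list of `sample_scenario` objects with fields `name`,
#'   `model` (or `NULL`), `models`/`model_weights` for superpositions,
#'   `populations`, `background_coeffs`, `crystallinity_regime` and
#'   `decay_tau` (hours).
#' @export
sample_scenarios <- function() {
  wt_model <- hierarchical_model(cylinder_unit(53), circular_lattice(4L, 80))
  a2v_model <- hierarchical_model(cylinder_unit(18), circular_lattice(3L, 48),
                                  circular_lattice(3L, 98))
  pops <- function(centers, sigma) {
    data.frame(center = centers, sigma = sigma,
               weight = rep(1 / length(centers), length(centers)))
  }
  sc <- function(name, model, models, model_weights, populations, regime, tau) {
    structure(list(name = name, model = model, models = models,
                   model_weights = model_weights, populations = populations,
                   background_coeffs = c(2, -4),
                   crystallinity_regime = regime, decay_tau = tau,
                   version = "1.0"),
              class = "sample_scenario")
  }
  list(
    WT = sc("WT", wt_model, NULL, NULL,
            pops(c(90 - 15.5, 90 + 15.5), 6), "high", 2.58),
    A2V = sc("A2V", a2v_model, NULL, NULL, pops(90, 4), "low", 1.90),
    WT_A2V = sc("WT_A2V", NULL, list(wt_model, a2v_model), c(0.5, 0.5),
                pops(c(90 - 13.5, 90 + 13.5), 6), "high", 2.45),
    WT_1to6A2V = sc("WT_1to6A2V", NULL, NULL, NULL, NULL, "low", NA_real_)
  )
}

#' @export
print.sample_scenario <- function(x, ...) {
  cat(sprintf("<sample_scenario '%s'> crystallinity %s, tau %s h, %s\n",
              x$name, x$crystallinity_regime,
              if (is.na(x$decay_tau)) "-" else format(x$decay_tau),
              if (is.null(x$model) && is.null(x$models)) "no model"
              else "with ground-truth model"))
  invisible(x)
}
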