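# Shared fixtures, built in code at test time.

wt_model <- function() {
  hierarchical_model(cylinder_unit(53), circular_lattice(4L, 80))
}

a2v_model <- function() {
  hierarchical_model(cylinder_unit(18), circular_lattice(3L, 48),
                     circular_lattice(3L, 98))
}

default_geometry <- function() {
  detector_geometry(wavelength = 4.5, distance = 4000, pixel_size = 3,
                    beam_center = c(64, 64))
}

q_grid_sa <- function(n = 500L) seq(0.005, 0.25, length.out = n)

# integral width -> Gaussian sigma for a target coherence length L = 2pi/iw
sigma_for_L <- function(L) (2 * pi / L) / sqrt(2 * pi)

powder_fixture <- function(noise = 0, seed = NULL) {
  gen_powder(c(10, 4.7),
             widths = c(sigma_for_L(35), sigma_for_L(33)),
             heights = c(4, 3),
             q_grid = seq(0.2, 2, length.out = 600L),
             background_coeffs = c(3, -1),
             noise_fraction = noise, seed = seed)
}

trapz_test <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}
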