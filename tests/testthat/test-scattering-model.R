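test_that("Q <-> d conversion is an involution and rejects non-positive input", {
  x <- c(0.045, 0.63, 1.312, 2 * pi)
  expect_equal(d_to_q(q_to_d(x)), x)
  expect_equal(q_to_d(2 * pi), 1)
  expect_error(q_to_d(0), "domain")
  expect_error(d_to_q(-1), "domain")
})

test_that("form factor limit, first zero, and polydispersity fill-in", {
  u <- cylinder_unit(53)
  expect_equal(form_factor_sq(u, 0), (pi * 53^2)^2)

  # numerically bracket the first zero of J1 and compare with Q = x1/r
  f <- function(q) form_factor_sq(u, q)
  root <- uniroot(function(q) besselJ(q * 53, 1), c(0.05, 0.09), tol = 1e-12)$root
  expect_equal(root, 3.8317 / 53, tolerance = 1e-4)
  expect_lt(f(root) / f(0), 1e-8)

  # Gaussian polydispersity fills the zero; cross-check the 41-point
  # Gauss-Legendre average against direct fine-grained quadrature
  up <- cylinder_unit(53, 5)
  got <- form_factor_sq(up, root)
  rg <- seq(53 - 4 * 5, 53 + 4 * 5, length.out = 4001)
  w <- exp(-0.5 * ((rg - 53) / 5)^2); w <- w / sum(w)
  mono <- vapply(rg, function(r) form_factor_sq(cylinder_unit(r), root),
                 numeric(1))
  expect_gt(got, 0)
  # Riemann reference vs 41-point Gauss-Legendre: agree to ~1e-5 relative
  expect_equal(got, sum(w * mono), tolerance = 1e-5)
})

test_that("interference function: n^2 at Q = 0, unity for n = 1, closed form", {
  for (n in 1:8) {
    lat <- circular_lattice(n, if (n == 1) 0 else 80)
    expect_equal(lattice_interference(lat, 0), n^2)
  }
  expect_equal(lattice_interference(circular_lattice(1, 0), seq(0, 0.3, 0.05)),
               rep(1, 7))
  # n = 2: explicit two-point azimuthal average equals 2 (1 + J0(2 Q rho))
  q <- 0.05
  expect_equal(lattice_interference(circular_lattice(2, 80), q),
               2 * (1 + besselJ(2 * q * 80, 0)))
  phi <- 2 * pi * (0:99999) / 1e5
  two_pt <- mean(Mod(exp(1i * q * 80 * cos(phi)) +
                       exp(1i * q * 80 * cos(phi + pi)))^2)
  expect_equal(lattice_interference(circular_lattice(2, 80), q), two_pt,
               tolerance = 1e-9)
})

test_that("single-level closed form matches the brute-force oracle to 1e-6", {
  q <- seq(0, 0.3, length.out = 121)
  for (n0 in c(2L, 4L, 5L)) {
    # n0 = 5 trips the (intended) overlap advisory; the sum stays evaluable
    m <- suppressWarnings(
      hierarchical_model(cylinder_unit(53), circular_lattice(n0, 80)))
    a <- model_intensity_at(m, q)
    b <- oracle_intensity(m, q, n_azimuth = 720L)
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-12)), 1e-6)
  }
})

test_that("two-level factorization agrees with the oracle at low Q (A2V)", {
  m <- a2v_model()
  q <- seq(0.001, 0.02, length.out = 25)
  a <- model_intensity_at(m, q)
  b <- oracle_intensity(m, q)
  expect_lt(max(abs(a - b) / b), 0.01)
  expect_equal(model_intensity_at(m, 0),
               3^2 * 3^2 * (pi * 18^2)^2)
  expect_equal(inner_assembly_diameter(m), 132)
})

test_that("intensities are finite and non-negative for random models", {
  set.seed(11)
  q <- seq(0, 0.3, length.out = 200)
  for (i in 1:20) {
    m <- suppressWarnings(hierarchical_model(
      cylinder_unit(runif(1, 10, 80), runif(1, 0, 3)),
      circular_lattice(sample(1:6, 1), 0) |>
        (\(l) if (l$n > 1) circular_lattice(l$n, runif(1, 20, 150)) else l)(),
      circular_lattice(1L, 0)))
    y <- model_intensity_at(m, q)
    expect_true(all(is.finite(y)) && all(y >= 0))
  }
})

test_that("polydispersity never deepens the form-factor minima", {
  r <- 53
  q0 <- 3.8317 / r                          # first J1 zero
  vals <- vapply(c(0, 1, 2, 3, 5, 8), function(s)
    form_factor_sq(cylinder_unit(r, s), q0), numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("model invariants: overlap warning, n1=1 reduces to form factor", {
  expect_warning(
    hierarchical_model(cylinder_unit(60), circular_lattice(4L, 50)),
    "overlap")
  m <- hierarchical_model(cylinder_unit(30), circular_lattice(1L, 0))
  q <- seq(0.01, 0.2, length.out = 50)
  expect_equal(model_intensity_at(m, q),
               form_factor_sq(cylinder_unit(30), q))
  expect_error(model_intensity(m, numeric(0)), "empty grid")
  expect_error(cylinder_unit(30, 11), "r/3")
  expect_error(circular_lattice(1, 10), "radius must be 0")
})
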