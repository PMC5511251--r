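test_that("background through minima: constant, ramp, and anchor interpolation", {
  q <- seq(0.1, 1, length.out = 200)
  # constant profile -> constant background, zero residual
  pc <- profile1d(q, rep(5, 200))
  bg <- estimate_background(pc, degree = 4)
  expect_equal(predict(bg, q), rep(5, 200), tolerance = 1e-9)

  # single Gaussian peak on a linear ramp -> ramp recovered within 2%
  ramp <- 10 - 4 * q
  pr <- profile1d(q, ramp + 3 * exp(-0.5 * ((q - 0.55) / 0.03)^2))
  bg <- estimate_background(pr, degree = 1)
  expect_equal(bg$coefficients[1], 10, tolerance = 0.02)
  expect_equal(bg$coefficients[2], -4, tolerance = 0.02)

  # clipped evaluation never exceeds the observed intensity
  b <- predict(bg, q)
  resid <- subtract_background(pr, bg)
  expect_true(all(resid$intensity >= 0))
})

test_that("degree reduction is recorded when anchors are scarce", {
  q <- seq(0.1, 1, length.out = 50)
  p <- profile1d(q, 10 - 4 * q)          # monotone: only endpoint anchors
  bg <- estimate_background(p, degree = 4)
  expect_lt(bg$degree, 4)
  expect_equal(bg$degree_requested, 4L)
  expect_equal(predict(bg, q), 10 - 4 * q, tolerance = 1e-6)
})

test_that("multi-Gaussian peak fit recovers centers and derived fields", {
  q <- seq(0.3, 1, length.out = 400)
  truth <- data.frame(center = c(0.5, 0.63), height = c(2, 5),
                      sigma = c(0.02, 0.02))
  y <- rep(0.5, length(q))
  for (i in 1:2) y <- y + truth$height[i] *
      exp(-0.5 * ((q - truth$center[i]) / truth$sigma[i])^2)
  p <- profile1d(q, y)
  pk <- fit_gaussian_peaks(p, 2, background_model(0.5))
  expect_equal(pk$center, truth$center, tolerance = 0.005)
  expect_equal(pk$width_sigma, truth$sigma, tolerance = 0.02)
  # derived-field identities hold exactly
  expect_equal(pk$integral_width, pk$integral_intensity / pk$height,
               tolerance = 1e-9)
  expect_equal(pk$d_spacing, 2 * pi / pk$center, tolerance = 1e-12)
  expect_error(fit_gaussian_peaks(p, 0), "1..6")
})

test_that("single Gaussian on pure noise is flagged weak", {
  set.seed(3)
  q <- seq(0.3, 1, length.out = 300)
  p <- profile1d(q, abs(rnorm(300, 0, 0.01)) + 1e-6)
  pk <- fit_gaussian_peaks(p, 1)
  expect_true(pk$weak[1])
})

test_that("coherence length inverts the integral width", {
  pk <- data.frame(integral_width = 2 * pi / 35)
  expect_equal(coherence_length(pk), 35)
  expect_equal(coherence_length(data.frame(integral_width = c(2 * pi / 30, 2 * pi / 40))),
               c(30, 40))
  expect_warning(coherence_length(data.frame(integral_width = 0)),
                 "resolution-limited")
})

test_that("merging rescales and reproduces the mother curve", {
  m <- wt_model()
  q <- seq(0.005, 0.25, length.out = 600)
  mother <- model_intensity(m, q)
  # two copies, one premultiplied by 3 -> merged equals original
  p1 <- mother
  p2 <- profile1d(q, 3 * mother$intensity)
  mg <- merge_profiles(list(p1, p2))
  expect_equal(mg$intensity, mother$intensity, tolerance = 1e-6)

  # three overlapping ranges with distinct scales -> mother within 0.5% RMS
  cut1 <- profile1d(q[q <= 0.06], 2.5 * mother$intensity[q <= 0.06])
  cut2 <- profile1d(q[q >= 0.05 & q <= 0.15],
                    0.7 * mother$intensity[q >= 0.05 & q <= 0.15])
  cut3 <- profile1d(q[q >= 0.13], 5 * mother$intensity[q >= 0.13])
  mg <- merge_profiles(list(cut2, cut3, cut1))
  ref <- approx(mother$q, mother$intensity, mg$q)$y
  sc <- median(mg$intensity / ref)
  rel <- (mg$intensity / sc - ref) / max(ref)
  expect_lt(sqrt(mean(rel^2)), 0.005)

  # disjoint ranges are an input error
  d1 <- profile1d(c(0.01, 0.02, 0.03), c(1, 2, 3))
  d2 <- profile1d(c(0.2, 0.3, 0.4), c(1, 2, 3))
  expect_error(merge_profiles(list(d1, d2)), "overlap")
})
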