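test_that("pinhole pixel maps to the geometric Q", {
  g <- detector_geometry(4.5, 4000, 3, c(10, 10))
  v <- matrix(0, 21, 21)
  v[11, 18] <- 100                        # row 10, col 17 (0-based): dx 7 px
  pat <- pattern2d(v, g)
  prof <- sector_integrate(pat, 90, 10)
  rho <- 7 * 3
  q_expect <- (4 * pi / 4.5) * sin(0.5 * atan(rho / 4000))
  hit <- prof$q[prof$intensity > 0]
  expect_equal(hit, q_expect, tolerance = 0.02)
})

test_that("isotropic pattern: sectors agree and azimuthal profile is flat", {
  pat <- gen_pattern(wt_model(), NULL, default_geometry())
  eq <- sector_integrate(pat, 90, 10)
  me <- sector_integrate(pat, 0, 10)
  ie <- approx(eq$q, eq$intensity, me$q)$y
  ok <- is.finite(ie) & me$intensity > 0
  rel <- (ie[ok] - me$intensity[ok]) / me$intensity[ok]
  expect_lt(sqrt(mean(rel^2)), 0.01)
  # flux conservation between the two 10-degree sectors
  expect_equal(trapz_test(eq$q, eq$intensity), trapz_test(me$q, me$intensity),
               tolerance = 0.02)
  az <- azimuthal_profile(pat, c(0.035, 0.055))
  expect_lt(sd(az$intensity) / mean(az$intensity), 0.02)
})

test_that("equatorial-only pattern leaves the meridian at background", {
  sc <- sample_scenarios()
  pat <- gen_pattern(sc$A2V$model, sc$A2V$populations, default_geometry(),
                     amplitude = 100, background = 1)
  eq <- sector_integrate(pat, 90, 10)
  me <- sector_integrate(pat, 0, 10)
  sel <- me$q > 0.03 & me$q < 0.06
  expect_lt(max(me$intensity[sel]), 2)    # ~ background level
  expect_gt(max(eq$intensity[eq$q > 0.03 & eq$q < 0.06]),
            3 * max(me$intensity[sel]))
})

test_that("azimuthal profile finds single and double populations", {
  g <- default_geometry()
  single <- gen_pattern(wt_model(),
                        data.frame(center = 90, sigma = 10, weight = 1), g)
  az <- azimuthal_profile(single, c(0.035, 0.055))
  ph_max <- az$phi[which.max(az$intensity)]
  expect_lt(min(abs(ph_max - 90), abs(ph_max - 270)), 2.1)  # Friedel mate
  o <- mutual_orientation(az)
  expect_identical(o$model, "single")
  expect_null(o$separation)

  sc <- sample_scenarios()
  double <- gen_pattern(sc$WT$model, sc$WT$populations, g)
  azd <- azimuthal_profile(double, c(0.035, 0.055))
  od <- mutual_orientation(azd)
  expect_identical(od$model, "double")
  expect_equal(od$separation, 31, tolerance = 0.04)
})

test_that("mutual orientation is invariant under consistent axis rotation", {
  sc <- sample_scenarios()
  g <- default_geometry()
  for (rot in c(0, 20)) {
    pat <- gen_pattern(sc$WT$model, sc$WT$populations, g,
                       axis_direction = rot)
    o <- mutual_orientation(azimuthal_profile(pat, c(0.035, 0.055)))
    expect_equal(o$separation, 31, tolerance = 0.05)
  }
})

test_that("sector and band validation errors", {
  pat <- gen_pattern(wt_model(), NULL, default_geometry())
  expect_error(sector_integrate(pat, 90, 0), "opening")
  expect_error(azimuthal_profile(pat, c(0.05, 0.04)), "Qlo < Qhi")
  expect_error(azimuthal_profile(pat, c(5, 6)), "empty Q band")
})
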