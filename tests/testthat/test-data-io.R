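test_that("profile round-trips through TSV to 1e-9 relative", {
  q <- sort(runif(50, 0.01, 1))
  p <- profile1d(q, exp(-q) * 100, sigma = sqrt(q), label = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$q, p$q, tolerance = 1e-9)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-9)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-9)
})

test_that("read_profile sorts rows, collapses duplicate Q, reports bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "0.02\t4.0", "0.01\t5.0", "0.02\t6.0"), f)
  p <- read_profile(f)
  expect_equal(p$q, c(0.01, 0.02))
  expect_equal(p$intensity, c(5.0, 5.0))  # duplicates averaged

  writeLines(c("0.01\t5.0", "0.02\tnot_a_number"), f)
  expect_error(read_profile(f), "line 2")
  writeLines(c("# only", "0.01\t5.0"), f)
  expect_error(read_profile(f), "fewer than 2")
})

test_that("profile1d enforces its invariants", {
  expect_error(profile1d(c(0.02, 0.01), c(1, 2)), "increasing")
  expect_error(profile1d(c(0, 0.01), c(1, 2)), "> 0")
  expect_error(profile1d(c(0.01, 0.02), c(1, -2)), ">= 0")
  expect_error(profile1d(c(0.01, 0.02), c(1, Inf)), "finite")
  expect_error(profile1d(c(0.01, 0.02), c(1, 2), sigma = c(-1, 0)), "sigma")
})

test_that("pattern round-trips exactly and missing geometry keys are named", {
  g <- default_geometry()
  set.seed(7)
  pat <- pattern2d(matrix(rexp(12), 3, 4), g, axis_direction = 15)
  mf <- withr::local_tempfile(fileext = ".mat.txt")
  hf <- withr::local_tempfile(fileext = ".geom.txt")
  write_pattern(pat, mf, hf)
  pat2 <- read_pattern(mf, hf)
  expect_identical(pat2$values, pat$values)
  expect_equal(pat2$axis_direction, 15)
  expect_equal(pat2$geometry$wavelength, g$wavelength)

  hl <- readLines(hf)
  writeLines(hl[!grepl("wavelength", hl)], hf)
  expect_error(read_pattern(mf, hf), "wavelength")

  writeLines(hl, hf)                      # restore valid header
  writeLines(c("1 2 3", "4 5"), mf)
  expect_error(read_pattern(mf, hf), "ragged")
})

test_that("3x3 matrix of ones and a valid header parse into 9 values", {
  mf <- withr::local_tempfile()
  hf <- withr::local_tempfile()
  writeLines(rep("1 1 1", 3), mf)
  writeLines(c("wavelength_A: 4.5", "distance_mm: 4000", "pixel_mm: 3",
               "beam_row: 1", "beam_col: 1"), hf)
  pat <- read_pattern(mf, hf)
  expect_equal(dim(pat$values), c(3L, 3L))
  expect_true(all(pat$values == 1))
  expect_equal(pat$axis_direction, 0)
})

test_that("analysis_config validates and reads JSON with unknown-key check", {
  expect_error(analysis_config(q_range = c(0.3, 0.1)), "Q1 < Q2")
  expect_error(analysis_config(sector_opening = 95), "sector_opening")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"q_range": [0.02, 0.2], "seed": 7}', f)
  cfg <- read_config(f)
  expect_equal(cfg$q_range, c(0.02, 0.2))
  expect_equal(cfg$seed, 7L)
  writeLines('{"q_rage": [0.02, 0.2]}', f)
  expect_error(read_config(f), "q_rage")
})

test_that("decay_curve rejects decreasing time and negative intensity", {
  expect_error(decay_curve(c(1, 0.5), c(1, 1)), "non-decreasing")
  expect_error(decay_curve(c(0, 1), c(1, -1)), ">= 0")
})
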