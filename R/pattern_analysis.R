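# 2D pattern reduction: pixel -> (Q, azimuth) mapping, sector and azimuthal
# integration, mutual-orientation extraction.

# Per-pixel reciprocal-space coordinates. Azimuth is measured in degrees
# from the fiber/field axis ("up" = decreasing row index, rotated by
# axis_direction), so the equator lies at +/- 90 degrees.
.pixel_map <- function(pattern) {
  g <- pattern$geometry
  nr <- nrow(pattern$values); nc <- ncol(pattern$values)
  row <- matrix(rep(0:(nr - 1L), nc), nr, nc)
  col <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  dx <- (col - g$beam_center[2L]) * g$pixel_size
  dy <- (g$beam_center[1L] - row) * g$pixel_size
  rho <- sqrt(dx^2 + dy^2)
  q <- (4 * pi / g$wavelength) * sin(0.5 * atan(rho / g$distance))
  phi <- (atan2(dx, dy) * 180 / pi - pattern$axis_direction) %% 360
  list(q = q, phi = phi, rho = rho)
}

# Median per-pixel Q step along a detector row through the beam center.
.pixel_dq <- function(pattern) {
  g <- pattern$geometry
  nmax <- max(dim(pattern$values))
  rho <- g$pixel_size * seq_len(nmax)
  qs <- (4 * pi / g$wavelength) * sin(0.5 * atan(rho / g$distance))
  stats::median(diff(qs))
}

#' Sector integration of a 2D pattern
#'
#' Averages pixel intensities whose azimuth lies within `opening/2` of
#' `center_azimuth` or its antipode (both half-sectors of the standard
#' "10 degree opening" are included), binned onto a regular Q grid whose
#' bin width is the median per-pixel Q step. Empty bins are dropped.
#'
#' @param pattern A [pattern2d].
#' @param center_azimuth Sector center in degrees from the fiber axis
#'   (0 = meridian, 90 = equator).
#' @param opening Full sector opening in degrees, in (0, 90].
#' @return A [profile1d].
#' @export
sector_integrate <- function(pattern, center_azimuth, opening = 10) {
  stopifnot(inherits(pattern, "pattern2d"))
  if (opening <= 0 || opening > 90)
    stop("sector_integrate: opening must be in (0, 90]")
  pm <- .pixel_map(pattern)
  sel <- fold_angle_dist(pm$phi, center_azimuth) <= opening / 2 & pm$rho > 0
  if (!any(sel)) stop("sector_integrate: analysis error: no pixels in sector")
  qs <- pm$q[sel]; is <- pattern$values[sel]
  bw <- .pixel_dq(pattern)
  breaks <- seq(0, max(qs) + bw, by = bw)
  bin <- findInterval(qs, breaks)
  qbin <- as.numeric(tapply(qs, bin, mean))
  ibin <- as.numeric(tapply(is, bin, mean))
  ok <- is.finite(qbin) & qbin > 0
  profile1d(qbin[ok], pmax(ibin[ok], 0),
            label = sprintf("sector %g deg (opening %g)", center_azimuth, opening))
}

#' Azimuthal intensity distribution over a radial band
#'
#' Mean intensity in 2-degree azimuth bins over pixels whose Q falls in
#' `q_band`; azimuth is relative to the fiber axis.
#'
#' @param pattern A [pattern2d].
#' @param q_band `(Qlo, Qhi)` radial band in 1/Angstrom, `Qlo < Qhi`.
#' @return An object of class `azimuthal_profile` with fields `phi`
#'   (bin centers, degrees in `[0, 360)`), `intensity` and `q_band`.
#' @export
azimuthal_profile <- function(pattern, q_band) {
  stopifnot(inherits(pattern, "pattern2d"))
  q_band <- as.numeric(q_band)
  if (length(q_band) != 2L || q_band[1L] >= q_band[2L])
    stop("azimuthal_profile: q_band must satisfy Qlo < Qhi")
  pm <- .pixel_map(pattern)
  sel <- pm$q >= q_band[1L] & pm$q <= q_band[2L] & pm$rho > 0
  if (!any(sel)) stop("azimuthal_profile: analysis error: empty Q band")
  ph <- pm$phi[sel]; is <- pattern$values[sel]
  bin <- floor(ph / 2)                    # 2-degree bins
  phi <- as.numeric(tapply(ph, bin, function(v) 2 * floor(v[1L] / 2) + 1))
  inten <- as.numeric(tapply(is, bin, mean))
  o <- order(phi)
  structure(list(phi = phi[o], intensity = inten[o], q_band = q_band),
            class = "azimuthal_profile")
}

#' @export
print.azimuthal_profile <- function(x, ...) {
  cat(sprintf("<azimuthal_profile> %d bins, Q band [%g, %g] 1/A\n",
              length(x$phi), x$q_band[1L], x$q_band[2L]))
  invisible(x)
}

#' @export
plot.azimuthal_profile <- function(x, ...) {
  graphics::plot(x$phi, x$intensity, type = "l",
                 xlab = "Azimuth (deg)", ylab = "Intensity", ...)
  invisible(x)
}

.gauss_const <- function(par, x, npk) {
  y <- rep(par[1L], length(x))
  for (k in seq_len(npk)) {
    a <- par[3 * k - 1L]; c0 <- par[3 * k]; s <- par[3 * k + 1L]
    y <- y + a * exp(-0.5 * ((x - c0) / s)^2)
  }
  y
}

.fit_az_gauss <- function(x, y, npk, starts) {
  span <- diff(range(x))
  lower <- c(0, rep(c(0, min(x), 0.5), npk))
  upper <- c(max(y), rep(c(2 * max(y), max(x), span / 2), npk))
  obj <- function(p) sum((y - .gauss_const(p, x, npk))^2)
  best <- NULL
  for (st in starts) {
    fit <- stats::nlminb(st, obj, lower = lower, upper = upper,
                         control = list(iter.max = 500L, eval.max = 1000L))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

#' Mutual orientation of fiber populations from the azimuthal profile
#'
#' Folds the azimuthal distribution to a half-turn (Friedel symmetry),
#' fits one and two Gaussians (plus a constant floor) and selects between
#' them by an F-test at `alpha`; ties and degenerate fits break toward the
#' single-population model. For a double orientation the separation is the
#' angular distance between the two centers, folded into (0, 90].
#'
#' @param az An [azimuthal_profile].
#' @param alpha Significance level of the model-selection F-test.
#' @return An object of class `orientation_result` with `peak_centers`
#'   (degrees on the folded half-turn), `widths` (Gaussian sigmas),
#'   `separation` (degrees, `NULL` for a single population), `model`
#'   (`"single"` or `"double"`) and the F-test `p_value`.
#' @export
mutual_orientation <- function(az, alpha = 0.05) {
  stopifnot(inherits(az, "azimuthal_profile"))
  ph <- az$phi %% 180
  grp <- match(round(ph, 6), unique(round(ph, 6)))
  x <- as.numeric(tapply(ph, grp, `[`, 1L))
  y <- as.numeric(tapply(az$intensity, grp, mean))
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  if (n < 10L) stop("mutual_orientation: analysis error: too few azimuth bins")
  b0 <- min(y)
  imax <- which.max(y)
  s1 <- list(c(b0, max(y) - b0, x[imax], 10))
  fit1 <- .fit_az_gauss(x, y, 1L, s1)
  # double-Gaussian starts: two largest separated maxima, else split c +/- s
  sm <- .moving_average(y, 3L)
  mx <- which(sm[2:(n - 1L)] > sm[1:(n - 2L)] & sm[2:(n - 1L)] >= sm[3:n]) + 1L
  mx <- mx[order(sm[mx], decreasing = TRUE)]
  c1 <- x[imax]
  c2 <- if (length(mx) >= 2L) x[mx[which(abs(x[mx] - c1) > 4)[1L]]] else NA
  if (is.na(c2)) c2 <- c1 + 15
  amp <- max(y) - b0
  s2 <- list(c(b0, amp, min(c1, c2), 6, amp, max(c1, c2), 6),
             c(b0, amp, c1 - 10, 8, amp, c1 + 10, 8))
  fit2 <- .fit_az_gauss(x, y, 2L, s2)
  tss <- sum((y - mean(y))^2)
  p1 <- 4L; p2 <- 7L
  use_double <- FALSE
  p_value <- NA_real_
  if (n > p2 && fit1$objective / max(tss, .Machine$double.eps) > 1e-9) {
    Fstat <- ((fit1$objective - fit2$objective) / (p2 - p1)) /
      (fit2$objective / (n - p2))
    if (is.finite(Fstat) && Fstat > 0) {
      p_value <- stats::pf(Fstat, p2 - p1, n - p2, lower.tail = FALSE)
      sep_raw <- abs(fit2$par[6L] - fit2$par[3L])
      sep <- min(sep_raw, 180 - sep_raw)
      use_double <- !is.na(p_value) && p_value < alpha && sep > 1
    }
  }
  if (use_double) {
    centers <- sort(c(fit2$par[3L], fit2$par[6L]))
    widths <- c(fit2$par[4L], fit2$par[7L])[order(c(fit2$par[3L], fit2$par[6L]))]
    sep_raw <- abs(diff(centers))
    structure(list(peak_centers = centers, widths = widths,
                   separation = min(sep_raw, 180 - sep_raw),
                   model = "double", p_value = p_value,
                   rss = fit2$objective),
              class = "orientation_result")
  } else {
    structure(list(peak_centers = fit1$par[3L], widths = fit1$par[4L],
                   separation = NULL, model = "single", p_value = p_value,
                   rss = fit1$objective),
              class = "orientation_result")
  }
}

#' @export
print.orientation_result <- function(x, ...) {
  if (x$model == "double")
    cat(sprintf("<orientation_result> double population: centers %.2f / %.2f deg, separation %.2f deg\n",
                x$peak_centers[1L], x$peak_centers[2L], x$separation))
  else
    cat(sprintf("<orientation_result> single population at %.2f deg (sigma %.2f)\n",
                x$peak_centers, x$widths))
  invisible(x)
}
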