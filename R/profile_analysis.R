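# 1D reduction: background through intensity minima, multi-Gaussian peak
# fitting, coherence lengths, multi-distance merging.

# Centered moving average with shrinking window at the edges.
.moving_average <- function(y, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(y)
  half <- window %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Least-squares polynomial fit in centered/scaled coordinates, returned as
# raw ascending coefficients over Q (degree <= a handful, so the expansion
# back to the monomial basis is well conditioned).
.polyfit_raw <- function(x, y, degree) {
  mu <- mean(x); sc <- max(stats::sd(x), .Machine$double.eps)
  t <- (x - mu) / sc
  X <- outer(t, 0:degree, `^`)
  ct <- qr.solve(qr(X, LAPACK = TRUE), y)
  # expand sum ct_k ((q - mu)/sc)^k into ascending powers of q
  coefs <- numeric(degree + 1L)
  base <- 1                               # polynomial "1" in q
  for (k in 0:degree) {
    coefs[seq_along(base)] <- coefs[seq_along(base)] + ct[k + 1L] * base
    if (k < degree) {
      # multiply base by (q - mu)/sc
      base <- (c(0, base) - mu * c(base, 0)) / sc
    }
  }
  coefs
}

#' Polynomial background through intensity minima
#'
#' Smooths the profile by a centered moving average, locates strict local
#' minima of the smoothed curve (both endpoints are always included as
#' anchors), and least-squares fits a polynomial of the requested degree
#' through the anchor `(Q, I)` points. If there are fewer anchors than
#' `degree + 1` coefficients, the degree is reduced and recorded.
#'
#' Evaluation against a profile is clipped to `[0, I(Q)]` so that the
#' background never exceeds the observed intensity (see
#' [subtract_background] and [crystallinity]).
#'
#' @param profile A [profile1d].
#' @param degree Requested polynomial degree, `>= 0`.
#' @param smooth_window Moving-average window in points (forced odd).
#' @return An object of class `background_model` with fields
#'   `coefficients` (ascending over Q), `anchor_points`, `degree`
#'   (used) and `degree_requested`.
#' @export
estimate_background <- function(profile, degree = 4L, smooth_window = 5L) {
  stopifnot(inherits(profile, "profile1d"))
  degree <- as.integer(degree)
  if (degree < 0) stop("estimate_background: degree must be >= 0")
  n <- length(profile$q)
  if (n < degree + 1L)
    stop("estimate_background: profile needs at least degree + 1 points")
  s <- .moving_average(profile$intensity, smooth_window)
  interior <- which(s[2:(n - 1L)] < s[1:(n - 2L)] &
                      s[2:(n - 1L)] < s[3:n]) + 1L
  anchors <- sort(unique(c(1L, interior, n)))
  d <- min(degree, length(anchors) - 1L)
  if (d < 0L) stop("estimate_background: analysis error: no usable anchors")
  coefs <- .polyfit_raw(profile$q[anchors], profile$intensity[anchors], d)
  structure(list(coefficients = coefs,
                 anchor_points = data.frame(q = profile$q[anchors],
                                            intensity = profile$intensity[anchors]),
                 degree = d, degree_requested = degree,
                 smooth_window = smooth_window),
            class = "background_model")
}

#' @rdname estimate_background
#' @param coefficients Ascending polynomial coefficients over Q, for
#'   constructing a background directly (e.g. a known constant level).
#' @export
background_model <- function(coefficients) {
  structure(list(coefficients = as.numeric(coefficients),
                 anchor_points = NULL,
                 degree = length(coefficients) - 1L,
                 degree_requested = length(coefficients) - 1L,
                 smooth_window = NA_integer_),
            class = "background_model")
}

#' @export
predict.background_model <- function(object, q, ...) {
  polyval(object$coefficients, q)
}

# Background evaluated on a profile's grid, clipped to [0, I(Q)].
background_values <- function(background, profile, clip = TRUE) {
  stopifnot(inherits(background, "background_model"),
            inherits(profile, "profile1d"))
  b <- polyval(background$coefficients, profile$q)
  if (clip) b <- pmin(pmax(b, 0), profile$intensity)
  b
}

#' Subtract a (clipped) background from a profile
#'
#' @param profile A [profile1d].
#' @param background A [background_model].
#' @return A [profile1d] of non-negative residual intensities.
#' @export
subtract_background <- function(profile, background) {
  b <- background_values(background, profile)
  profile1d(profile$q, profile$intensity - b,
            label = paste(profile$label, "(bg-subtracted)"))
}

.gauss_sum <- function(par, q, n_peaks) {
  y <- rep(0, length(q))
  for (k in seq_len(n_peaks)) {
    a <- par[3 * k - 2]; c0 <- par[3 * k - 1]; s <- par[3 * k]
    y <- y + a * exp(-0.5 * ((q - c0) / s)^2)
  }
  y
}

#' Multi-Gaussian peak fitting of a background-subtracted profile
#'
#' Fits a sum of `n_peaks` Gaussians to `I - B` by bounded nonlinear least
#' squares. Initial centers are placed at the largest residual maxima;
#' deterministic jittered restarts are attempted on poor convergence.
#'
#' @param profile A [profile1d].
#' @param n_peaks Number of Gaussians, 1..6.
#' @param background Optional [background_model] (zero background if NULL).
#' @param max_restarts Restarts with jittered starting values.
#' @return A data.frame of class `peak_fit`, sorted by center, with columns
#'   `center` (1/Angstrom), `height`, `width_sigma`, `integral_intensity`
#'   (`height * sigma * sqrt(2 pi)`), `integral_width`
#'   (`integral_intensity / height`), `d_spacing` (`2 pi / center`) and a
#'   logical `weak` flag for peaks indistinguishable from the noise floor.
#' @export
fit_gaussian_peaks <- function(profile, n_peaks, background = NULL,
                               max_restarts = 3L) {
  stopifnot(inherits(profile, "profile1d"))
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 1L || n_peaks > 6L)
    stop("fit_gaussian_peaks: n_peaks must be in 1..6")
  q <- profile$q
  resid <- if (is.null(background)) profile$intensity
           else profile$intensity - background_values(background, profile)
  sm <- .moving_average(resid, 5L)
  n <- length(q)
  maxima <- which(sm[2:(n - 1L)] > sm[1:(n - 2L)] &
                    sm[2:(n - 1L)] >= sm[3:n]) + 1L
  maxima <- maxima[order(sm[maxima], decreasing = TRUE)]
  centers <- q[maxima]
  if (length(centers) < n_peaks)
    centers <- c(centers,
                 stats::quantile(q, seq(0.2, 0.8, length.out = n_peaks)))
  centers <- centers[seq_len(n_peaks)]
  span <- diff(range(q))
  dq <- stats::median(diff(q))
  start <- as.vector(rbind(pmax(stats::approx(q, resid, centers)$y, 1e-8),
                           centers,
                           rep(span / (8 * n_peaks), n_peaks)))
  lower <- rep(c(0, min(q), dq / 2), n_peaks)
  upper <- rep(c(2 * max(abs(resid)) + 1e-9, max(q), span), n_peaks)
  obj <- function(p) sum((resid - .gauss_sum(p, q, n_peaks))^2)
  best <- NULL
  jitter_scales <- c(1, 0.5, 2, 0.25)
  for (a in seq_len(min(max_restarts + 1L, length(jitter_scales)))) {
    st <- start
    st[seq(3, length(st), by = 3)] <- st[seq(3, length(st), by = 3)] *
      jitter_scales[a]
    fit <- stats::nlminb(st, obj, lower = lower, upper = upper,
                         control = list(iter.max = 500L, eval.max = 1000L))
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (best$convergence == 0L) break
  }
  tss <- sum((resid - mean(resid))^2)
  if (is.null(best) || !is.finite(best$objective) ||
      (best$convergence != 0L && best$objective > 0.5 * tss))
    stop("fit_gaussian_peaks: analysis error: peak fit did not converge (best RSS ",
         format(best$objective), ")")
  p <- best$par
  out <- data.frame(center = p[seq(2, length(p), 3)],
                    height = p[seq(1, length(p), 3)],
                    width_sigma = p[seq(3, length(p), 3)])
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  out$integral_intensity <- out$height * out$width_sigma * sqrt(2 * pi)
  out$integral_width <- out$integral_intensity / out$height
  out$d_spacing <- 2 * pi / out$center
  noise_floor <- stats::mad(resid - .gauss_sum(p, q, n_peaks))
  out$weak <- out$height < 3 * noise_floor
  attr(out, "rss") <- best$objective
  class(out) <- c("peak_fit", "data.frame")
  out
}

#' Coherence length from a peak's integral width
#'
#' The Scherrer-type reciprocal of the integral breadth in Q units,
#' `L = 2 pi / integral_width`. A vanishing width gives an infinite,
#' resolution-limited length (flagged with a warning).
#'
#' @param peaks A `peak_fit` data.frame (or anything with an
#'   `integral_width` column).
#' @return Numeric vector of coherence lengths in Angstrom.
#' @export
coherence_length <- function(peaks) {
  iw <- peaks$integral_width
  if (is.null(iw)) stop("coherence_length: no integral_width column")
  L <- 2 * pi / iw
  if (any(!is.finite(L)))
    warning("coherence_length: resolution-limited peak (zero width)")
  L
}

#' Merge overlapping multi-distance scattering curves
#'
#' Orders the profiles by Q coverage and merges them sequentially: each
#' subsequent curve is scaled to the running merge by the median intensity
#' ratio over the overlap region, then concatenated; coincident Q points
#' are averaged after scaling.
#'
#' @param profiles A list of at least two [profile1d]s whose Q ranges
#'   overlap pairwise when ordered.
#' @return A single merged [profile1d].
#' @export
merge_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("merge_profiles: need at least 2 profiles")
  stopifnot(all(vapply(profiles, inherits, logical(1L), "profile1d")))
  ord <- order(vapply(profiles, function(p) min(p$q), numeric(1L)))
  acc <- profiles[[ord[1L]]]
  accq <- acc$q; acci <- acc$intensity
  for (k in ord[-1L]) {
    p <- profiles[[k]]
    lo <- max(min(accq), min(p$q)); hi <- min(max(accq), max(p$q))
    if (lo >= hi)
      stop("merge_profiles: input error: no overlap between consecutive profiles")
    qo <- p$q[p$q >= lo & p$q <= hi]
    if (length(qo) == 0L) qo <- (lo + hi) / 2
    ref <- stats::approx(accq, acci, xout = qo)$y
    cur <- stats::approx(p$q, p$intensity, xout = qo)$y
    ok <- is.finite(ref) & is.finite(cur) & cur > 0
    if (!any(ok))
      stop("merge_profiles: input error: empty or zero overlap")
    ratio <- stats::median(ref[ok] / cur[ok])
    accq <- c(accq, p$q)
    acci <- c(acci, p$intensity * ratio)
    o <- order(accq)
    accq <- accq[o]; acci <- acci[o]
    if (anyDuplicated(accq)) {
      grp <- match(accq, unique(accq))
      acci <- as.numeric(tapply(acci, grp, mean))
      accq <- unique(accq)
    }
  }
  profile1d(accq, pmax(acci, 0), label = "merged")
}
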