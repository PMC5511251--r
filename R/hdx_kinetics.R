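# Hydrogen-deuterium exchange kinetics from the time evolution of the
# predominant diffraction peak.

#' Band-integrated intensity time series
#'
#' Integrates each profile (trapezoid) over the Q band of the predominant
#' diffraction peak, yielding one intensity per time point.
#'
#' @param profiles Time-ordered list of [profile1d]s.
#' @param times Times in hours, same length as `profiles`.
#' @param q_band `(Qlo, Qhi)` with `Qlo < Qhi`, inside every profile's
#'   range.
#' @return A [decay_curve].
#' @export
peak_band_timeseries <- function(profiles, times, q_band) {
  if (!is.list(profiles) || length(profiles) < 4L)
    stop("peak_band_timeseries: need at least 4 time points")
  stopifnot(all(vapply(profiles, inherits, logical(1L), "profile1d")),
            length(times) == length(profiles))
  q_band <- as.numeric(q_band)
  if (length(q_band) != 2L || q_band[1L] >= q_band[2L])
    stop("peak_band_timeseries: input error: band must satisfy Qlo < Qhi")
  vals <- vapply(profiles, function(p) {
    if (min(p$q) > q_band[1L] || max(p$q) < q_band[2L])
      stop("peak_band_timeseries: input error: band outside profile range")
    qi <- c(q_band[1L],
            p$q[p$q > q_band[1L] & p$q < q_band[2L]],
            q_band[2L])
    yi <- stats::approx(p$q, p$intensity, xout = qi)$y
    trapz(qi, yi)
  }, numeric(1L))
  decay_curve(times, pmax(vals, 0))
}

#' Exponential fit of a D-to-H exchange decay curve
#'
#' Least-squares fit of `I(t) = i_inf + (i0 - i_inf) exp(-t / tau)`. The
#' three-parameter form (with floating asymptote) is the default because
#' the residual intensity of the plateau is a quantity of interest in its
#' own right; `model = "simple"` pins `i_inf = 0`. An increasing curve
#' (background build-up) is fit with negative amplitude and flagged with a
#' warning.
#'
#' @param curve A [decay_curve] with at least 4 points and non-constant
#'   intensity.
#' @param model `"asymptote"` (3 parameters) or `"simple"` (`i_inf = 0`).
#' @param window_h Optional upper time limit (hours) for the fitted range,
#'   e.g. the conventional 8-hour window.
#' @return An object of class `exchange_fit` with fields `tau` (hours),
#'   `i0`, `i_inf`, `residual_fraction` (`i_inf / i0`, soft-clipped to
#'   `[0, 1]` with a warning if the fit exits bounds) and `rms_residual`.
#' @export
fit_decay <- function(curve, model = c("asymptote", "simple"),
                      window_h = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  model <- match.arg(model)
  t <- curve$t; y <- curve$intensity
  if (!is.null(window_h)) {
    keep <- t <= window_h
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 4L) stop("fit_decay: need at least 4 points")
  if (stats::sd(y) == 0)
    stop("fit_decay: degenerate-input error: intensities are constant")
  span <- max(t) - min(t)
  start <- list(i0 = y[1L], i_inf = y[length(y)], tau = span / 3)
  d <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (model == "asymptote")
      stats::nls(y ~ i_inf + (i0 - i_inf) * exp(-t / tau), data = d,
                 start = start, algorithm = "port",
                 lower = c(i0 = -Inf, i_inf = -Inf, tau = 1e-9),
                 control = stats::nls.control(maxiter = 200L))
    else
      stats::nls(y ~ i0 * exp(-t / tau), data = d,
                 start = start[c("i0", "tau")], algorithm = "port",
                 lower = c(i0 = -Inf, tau = 1e-9),
                 control = stats::nls.control(maxiter = 200L))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct minimization on log(tau)
    obj <- function(p) {
      mu <- if (model == "asymptote")
        p[2L] + (p[1L] - p[2L]) * exp(-t / exp(p[3L]))
      else p[1L] * exp(-t / exp(p[2L]))
      sum((y - mu)^2)
    }
    st <- if (model == "asymptote") c(y[1L], y[length(y)], log(span / 3))
          else c(y[1L], log(span / 3))
    op <- stats::optim(st, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000L, reltol = 1e-14))
    if (op$convergence != 0L)
      stop("fit_decay: analysis error: exponential fit did not converge")
    cf <- if (model == "asymptote")
      c(i0 = op$par[1L], i_inf = op$par[2L], tau = exp(op$par[3L]))
    else c(i0 = op$par[1L], i_inf = 0, tau = exp(op$par[2L]))
    rss <- op$value
  } else {
    cf <- stats::coef(fit)
    if (model == "simple") cf <- c(cf["i0"], i_inf = 0, cf["tau"])
    rss <- sum(stats::resid(fit)^2)
  }
  i0 <- unname(cf["i0"]); i_inf <- unname(cf["i_inf"])
  tau <- unname(cf["tau"])
  if (i0 < i_inf)
    warning("fit_decay: increasing curve (negative decay amplitude)")
  rf <- if (i0 != 0) i_inf / i0 else NA_real_
  if (!is.na(rf) && (rf < 0 || rf > 1)) {
    warning("fit_decay: residual fraction outside [0, 1]; clipped")
    rf <- min(max(rf, 0), 1)
  }
  structure(list(tau = tau, i0 = i0, i_inf = i_inf,
                 residual_fraction = rf,
                 rms_residual = sqrt(rss / length(t)),
                 model = model, n = length(t)),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> tau = %.4g h, i0 = %.4g, i_inf = %.4g (residual fraction %.3g), rms %.3g\n",
              x$tau, x$i0, x$i_inf, x$residual_fraction, x$rms_residual))
  invisible(x)
}
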