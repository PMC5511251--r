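# Internal numerical helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of y over x (x increasing).
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Evaluate a polynomial with ascending coefficients at x.
polyval <- function(coefficients, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefficients))) y <- y * x + coefficients[k]
  y
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached per n.
.fd_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.fd_cache[[key]])) return(.fd_cache[[key]])
  if (n == 1L) {
    out <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord], weights = (2 * e$vectors[1L, ]^2)[ord])
  }
  .fd_cache[[key]] <- out
  out
}

# Linear-interpolation tables for J0/J1 used inside optimizer hot loops.
# Step 5e-4 keeps |error| < ~2e-8; anything out of range falls back to
# besselJ. Reported quantities are always re-evaluated with exact besselJ.
.bessel_table <- function(nu) {
  key <- paste0("bes", nu)
  if (is.null(.fd_cache[[key]])) {
    h <- 5e-4
    xmax <- 220
    x <- seq(0, xmax, by = h)
    .fd_cache[[key]] <- list(y = besselJ(x, nu), h = h, xmax = xmax,
                             n = length(x))
  }
  .fd_cache[[key]]
}

besselJ_fast <- function(x, nu) {
  tab <- .bessel_table(nu)
  u <- x / tab$h
  i <- floor(u)
  ok <- x >= 0 & x <= tab$xmax - tab$h
  if (all(ok)) {
    frac <- u - i
    tab$y[i + 1L] * (1 - frac) + tab$y[i + 2L] * frac
  } else {
    y <- numeric(length(x))
    io <- i[ok]
    frac <- u[ok] - io
    y[ok] <- tab$y[io + 1L] * (1 - frac) + tab$y[io + 2L] * frac
    y[!ok] <- besselJ(x[!ok], nu)
    y
  }
}

bessel_j <- function(x, nu, fast = FALSE) {
  if (fast) besselJ_fast(x, nu) else besselJ(x, nu)
}

# Smallest angular distance between azimuths a and b after folding to 180
# degrees (Friedel symmetry).
fold_angle_dist <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
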