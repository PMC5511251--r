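#' 1D scattering profile
#'
#' The common currency of the pipeline: an intensity curve `I(Q)` on a
#' strictly increasing momentum-transfer grid `Q` (in reciprocal Angstroms),
#' with optional per-point uncertainties.
#'
#' @param q Numeric vector of momentum-transfer values (1/Angstrom),
#'   strictly increasing and positive.
#' @param intensity Numeric vector of non-negative intensities (arbitrary
#'   units), same length as `q`.
#' @param sigma Optional per-point uncertainty, same length, all `>= 0`.
#' @param label Free-text label carried through the pipeline.
#' @return An object of class `profile1d`.
#' @examples
#' p <- profile1d(c(0.01, 0.02, 0.03), c(5, 4, 3))
#' p
#' @export
profile1d <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity) || length(q) < 2L)
    stop("profile1d: q and intensity must have equal length >= 2")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("profile1d: q must be finite and > 0")
  if (any(diff(q) <= 0))
    stop("profile1d: q must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop("profile1d: intensities must be finite")
  if (any(intensity < 0))
    stop("profile1d: intensities must be >= 0")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q) || any(!is.finite(sigma)) || any(sigma < 0))
      stop("profile1d: sigma must match q in length with all values >= 0")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label)[1L]),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d%s> %d points, Q in [%.4g, %.4g] 1/A%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' @export
as.data.frame.profile1d <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' @export
plot.profile1d <- function(x, ..., log = "") {
  graphics::plot(x$q, x$intensity, type = "l", log = log,
                 xlab = expression(Q ~ (ring(A)^-1)), ylab = "Intensity",
                 main = x$label, ...)
  invisible(x)
}

#' Read a 1D profile from whitespace/TSV text
#'
#' Expects 2 or 3 numeric columns (Q, intensity, optional sigma); lines
#' beginning with `#` are comments. Rows are sorted by Q and exact duplicate
#' Q rows are collapsed by averaging intensities (sigmas are RMS-combined).
#'
#' @param path Path to the text file.
#' @return A [profile1d].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("read_profile: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*(#|$)", lines)
  idx <- which(is_data)
  if (length(idx) < 2L)
    stop("read_profile: input error: fewer than 2 data rows in ", path)
  fields <- strsplit(trimws(lines[idx]), "[\t ,]+")
  ncols <- lengths(fields)
  if (any(ncols < 2L | ncols > 3L))
    stop(sprintf("read_profile: parse error at line %d: expected 2 or 3 columns, found %d",
                 idx[which(ncols < 2L | ncols > 3L)[1L]],
                 ncols[which(ncols < 2L | ncols > 3L)[1L]]))
  has_sigma <- all(ncols == 3L)
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- vapply(vals, function(v) any(is.na(v)), logical(1L))
  if (any(bad))
    stop(sprintf("read_profile: parse error at line %d: malformed numeric field '%s'",
                 idx[which(bad)[1L]], lines[idx[which(bad)[1L]]]))
  q <- vapply(vals, `[`, 0, 1L)
  i <- vapply(vals, `[`, 0, 2L)
  s <- if (has_sigma) vapply(vals, `[`, 0, 3L) else NULL
  ord <- order(q)
  q <- q[ord]; i <- i[ord]; if (!is.null(s)) s <- s[ord]
  if (anyDuplicated(q)) {
    grp <- match(q, unique(q))
    qa <- unique(q)
    ia <- as.numeric(tapply(i, grp, mean))
    sa <- if (!is.null(s)) as.numeric(tapply(s, grp, function(v) sqrt(mean(v^2))))
    q <- qa; i <- ia; s <- sa
  }
  profile1d(q, i, sigma = s, label = basename(path))
}

#' Write a 1D profile as full-precision TSV
#'
#' @param profile A [profile1d].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  header <- if (is.null(profile$sigma)) "# Q[1/A]\tI" else "# Q[1/A]\tI\tsigma"
  cols <- list(profile$q, profile$intensity)
  if (!is.null(profile$sigma)) cols <- c(cols, list(profile$sigma))
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = "\t"))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_profile: I/O error: cannot write ", path)
  invisible(path)
}

#' Detector geometry for mapping pixels to reciprocal space
#'
#' @param wavelength Beam wavelength (Angstrom), `> 0`.
#' @param distance Sample-to-detector distance (mm), `> 0`.
#' @param pixel_size Pixel edge (mm), `> 0`.
#' @param beam_center `(row, col)` of the direct beam, 0-based at pixel
#'   centers.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(wavelength, distance, pixel_size, beam_center) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("detector_geometry: wavelength must be > 0")
  if (!is.numeric(distance) || distance <= 0)
    stop("detector_geometry: distance must be > 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("detector_geometry: pixel_size must be > 0")
  beam_center <- as.numeric(beam_center)
  if (length(beam_center) != 2L || any(!is.finite(beam_center)))
    stop("detector_geometry: beam_center must be (row, col)")
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_size = pixel_size, beam_center = beam_center),
            class = "detector_geometry")
}

#' 2D detector pattern
#'
#' @param values Non-negative intensity matrix (rows = detector rows).
#' @param geometry A [detector_geometry].
#' @param axis_direction Azimuth (degrees) of the fiber/field axis on the
#'   image; 0 means "up" (towards decreasing row index).
#' @return An object of class `pattern2d`.
#' @export
pattern2d <- function(values, geometry, axis_direction = 0) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("pattern2d: empty grid")
  if (any(!is.finite(values))) stop("pattern2d: values must be finite")
  if (any(values < 0)) stop("pattern2d: values must be >= 0")
  stopifnot(inherits(geometry, "detector_geometry"))
  structure(list(values = values, geometry = geometry,
                 axis_direction = as.numeric(axis_direction)[1L]),
            class = "pattern2d")
}

#' @export
print.pattern2d <- function(x, ...) {
  cat(sprintf("<pattern2d> %d x %d pixels, lambda = %g A, L = %g mm, axis %g deg\n",
              nrow(x$values), ncol(x$values), x$geometry$wavelength,
              x$geometry$distance, x$axis_direction))
  invisible(x)
}

.geom_keys <- c("wavelength_A", "distance_mm", "pixel_mm", "beam_row", "beam_col")

#' Read a 2D pattern from a text matrix plus a geometry header
#'
#' The matrix file holds whitespace-separated rows of equal length; the
#' header file holds `key: value` lines with keys `wavelength_A`,
#' `distance_mm`, `pixel_mm`, `beam_row`, `beam_col` and optional
#' `axis_deg` (default 0).
#'
#' @param matrix_path Path to the intensity matrix text file.
#' @param header_path Path to the geometry header file.
#' @return A [pattern2d].
#' @export
read_pattern <- function(matrix_path, header_path) {
  if (!file.exists(matrix_path)) stop("read_pattern: file not found: ", matrix_path)
  if (!file.exists(header_path)) stop("read_pattern: file not found: ", header_path)
  hl <- readLines(header_path, warn = FALSE)
  hl <- hl[!grepl("^\\s*(#|$)", hl)]
  kv <- strsplit(hl, "\\s*[:=]\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  for (k in .geom_keys)
    if (!k %in% keys || is.na(vals[match(k, keys)]))
      stop("read_pattern: config error: missing geometry key '", k, "'")
  g <- stats::setNames(vals[match(.geom_keys, keys)], .geom_keys)
  axis <- if ("axis_deg" %in% keys) vals[match("axis_deg", keys)] else 0
  ml <- readLines(matrix_path, warn = FALSE)
  ml <- ml[!grepl("^\\s*(#|$)", ml)]
  rows <- lapply(strsplit(trimws(ml), "[\t ]+"),
                 function(f) suppressWarnings(as.numeric(f)))
  if (length(unique(lengths(rows))) != 1L)
    stop("read_pattern: format error: ragged rows in ", matrix_path)
  if (any(vapply(rows, anyNA, logical(1L))))
    stop("read_pattern: parse error: malformed numeric field in ", matrix_path)
  values <- do.call(rbind, rows)
  pattern2d(values,
            detector_geometry(g[["wavelength_A"]], g[["distance_mm"]],
                              g[["pixel_mm"]],
                              c(g[["beam_row"]], g[["beam_col"]])),
            axis_direction = axis)
}

#' Write a 2D pattern as text matrix plus geometry header
#'
#' @param pattern A [pattern2d].
#' @param matrix_path,header_path Output paths (conventionally `.mat.txt`
#'   and `.geom.txt`).
#' @return Invisibly, `matrix_path`.
#' @export
write_pattern <- function(pattern, matrix_path, header_path) {
  stopifnot(inherits(pattern, "pattern2d"))
  g <- pattern$geometry
  writeLines(c(sprintf("wavelength_A: %.17g", g$wavelength),
               sprintf("distance_mm: %.17g", g$distance),
               sprintf("pixel_mm: %.17g", g$pixel_size),
               sprintf("beam_row: %.17g", g$beam_center[1L]),
               sprintf("beam_col: %.17g", g$beam_center[2L]),
               sprintf("axis_deg: %.17g", pattern$axis_direction)),
             header_path)
  body <- apply(pattern$values, 1L,
                function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, matrix_path)
  invisible(matrix_path)
}

#' Time series of peak intensity for exchange kinetics
#'
#' @param t Times in hours, non-decreasing, all `>= 0`.
#' @param intensity Non-negative peak intensities.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(t, intensity) {
  t <- as.numeric(t); intensity <- as.numeric(intensity)
  if (length(t) != length(intensity))
    stop("decay_curve: t and intensity must have equal length")
  if (any(!is.finite(t)) || any(t < 0) || any(diff(t) < 0))
    stop("decay_curve: t must be non-decreasing and >= 0")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("decay_curve: intensities must be finite and >= 0")
  structure(list(t = t, intensity = intensity), class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d points over %.3g h\n", length(x$t),
              max(x$t) - min(x$t)))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the tunable knobs shared by the reduction and fitting steps.
#' `read_config()` loads the same structure from a JSON file; unknown keys
#' are rejected so typos fail loudly.
#'
#' @param q_range Analysis window `(Q1, Q2)` in 1/Angstrom.
#' @param background_degree Polynomial degree for background estimation.
#' @param smooth_window Moving-average window (points, odd) used before
#'   locating background anchor minima.
#' @param sector_opening Full sector opening (degrees) for 2D integration.
#' @param search_space A [search_space] for model fitting.
#' @param seed Integer seed for all stochastic steps.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(q_range = c(0.01, 0.25), background_degree = 4L,
                            smooth_window = 5L, sector_opening = 10,
                            search_space = NULL, seed = 1L) {
  q_range <- as.numeric(q_range)
  if (length(q_range) != 2L || q_range[1L] >= q_range[2L])
    stop("analysis_config: q_range must satisfy Q1 < Q2")
  if (background_degree < 0) stop("analysis_config: background_degree must be >= 0")
  if (sector_opening <= 0 || sector_opening > 90)
    stop("analysis_config: sector_opening must be in (0, 90]")
  structure(list(q_range = q_range,
                 background_degree = as.integer(background_degree),
                 smooth_window = as.integer(smooth_window),
                 sector_opening = sector_opening,
                 search_space = search_space,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path Path to a JSON configuration file.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  known <- c("q_range", "background_degree", "smooth_window",
             "sector_opening", "search_space", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("read_config: unknown configuration key(s): ",
         paste(extra, collapse = ", "))
  ss <- if (!is.null(raw$search_space)) do.call(search_space, raw$search_space)
  defaults <- analysis_config()
  args <- utils::modifyList(unclass(defaults), raw[setdiff(names(raw), "search_space")])
  args$search_space <- ss
  do.call(analysis_config, args)
}
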