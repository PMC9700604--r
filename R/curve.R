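#' Sampled tensile force process
#'
#' A `fbc_curve` holds a force-versus-strain process sampled on a strictly
#' increasing grid.  The strain axis may be normalized (`z = u / AE`, force
#' `FH` in (0, 1]) or physical (strain or elongation, force in N); the
#' `normalized` flag and unit labels are metadata only and are never
#' converted implicitly.
#'
#' @param x strain grid, strictly increasing, `x[1] >= 0`.
#' @param y force values, finite, same length as `x`.
#' @param normalized logical flag (NA when unknown).
#' @param units optional `c(strain, force)` unit labels.
#' @param Z0 upper limit of the intended grid (defaults to `max(x)`).
#' @return object of class `fbc_curve` (a list with elements `x`, `y`, and
#'   metadata `meta`).
#' @export
fbc_curve <- function(x, y, normalized = NA, units = NULL, Z0 = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("curve samples must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) stop("strain grid must be strictly increasing", call. = FALSE)
  if (x[1] < 0) stop("strain grid must start at x >= 0", call. = FALSE)
  structure(list(x = x, y = y,
                 meta = list(normalized = normalized, units = units,
                             Z0 = if (is.null(Z0)) max(x) else Z0,
                             N = length(x))),
            class = "fbc_curve")
}

#' @export
print.fbc_curve <- function(x, ...) {
  cat(sprintf("<fbc_curve> %d samples on [%g, %g], peak %g at %g%s\n",
              length(x$x), min(x$x), max(x$x),
              max(x$y), x$x[which.max(x$y)],
              if (isTRUE(x$meta$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Default evaluation grid
#'
#' The normalized strain domain is `[0, Z0]` with an adjustable partition;
#' the default treats z between 0 and 2 with 201 points.
#'
#' @param Z0 upper limit of the normalized strain domain.
#' @param N number of grid points.
#' @export
default_grid <- function(Z0 = 2, N = 201L) {
  seq(0, Z0, length.out = N)
}

#' Resample a curve onto a uniform partition by linear interpolation
#'
#' @param curve an [fbc_curve()].
#' @param grid target grid (defaults to the uniform partition of the curve's
#'   own range with `N` points).
#' @param N partition size when `grid` is not given.
#' @export
resample_curve <- function(curve, grid = NULL, N = 201L) {
  stopifnot(inherits(curve, "fbc_curve"))
  if (is.null(grid)) grid <- seq(min(curve$x), max(curve$x), length.out = N)
  y <- stats::approx(curve$x, curve$y, xout = grid, rule = 2)$y
  fbc_curve(grid, y, normalized = curve$meta$normalized,
            units = curve$meta$units, Z0 = max(grid))
}

#' Read / write a curve as two-column CSV
#'
#' The canonical interchange format is a comma-separated file with a header
#' (`strain,force`, `elongation_mm,force_N`, or any two column names), decimal
#' points, and optional `#` comment lines.  Values are written at full
#' precision so that a write-read cycle is lossless.  Duplicated or
#' non-increasing strain values are rejected with the offending line number.
#'
#' @param path file path.
#' @return [read_curve()] returns an [fbc_curve()]; `write_curve` returns
#'   `path` invisibly.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (length(lineno) < 3) stop("curve file needs a header and >= 2 rows", call. = FALSE)
  header <- strsplit(raw[lineno[1]], ",")[[1]]
  rows <- lineno[-1]
  parts <- strsplit(raw[rows], ",")
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s", rows[bad[1]], path), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  nf <- which(!is.finite(x) | !is.finite(y))
  if (length(nf)) {
    stop(sprintf("non-numeric value at line %d of %s", rows[nf[1]], path), call. = FALSE)
  }
  nd <- which(diff(x) <= 0)
  if (length(nd)) {
    stop(sprintf("strain values not strictly increasing at line %d of %s",
                 rows[nd[1] + 1L], path), call. = FALSE)
  }
  norm <- if (identical(trimws(header[1]), "z")) TRUE else NA
  fbc_curve(x, y, normalized = norm, units = trimws(header[1:2]))
}

#' @rdname read_curve
#' @param curve an [fbc_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fbc_curve"))
  units <- curve$meta$units
  if (is.null(units)) {
    units <- if (isTRUE(curve$meta$normalized)) c("z", "FH") else c("strain", "force")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(units[1], units[2], sep = ","), con)
  writeLines(sprintf("%.17g,%.17g", curve$x, curve$y), con)
  invisible(path)
}

#' Normalize / denormalize a curve
#'
#' Normalization divides strain by `u_N` and force by `F_N` so that the force
#' lands in `[0, 1)`; denormalization is the exact inverse.  Optionally the
#' normalized curve is resampled onto the `[0, Z0]` partition by linear
#' interpolation.
#'
#' @param curve an [fbc_curve()].
#' @param u_N strain scale (> 0), typically the mean fiber breaking strain.
#' @param F_N force scale (> 0), typically `n * mean_breaking_force`.
#' @param grid optional target grid for resampling after normalization.
#' @export
normalize_curve <- function(curve, u_N, F_N, grid = NULL) {
  stopifnot(inherits(curve, "fbc_curve"))
  if (u_N <= 0 || F_N <= 0) stop("normalization scales must be positive", call. = FALSE)
  out <- fbc_curve(curve$x / u_N, curve$y / F_N, normalized = TRUE,
                   units = c("z", "FH"))
  if (!is.null(grid)) out <- resample_curve(out, grid = grid)
  out
}

#' @rdname normalize_curve
#' @export
denormalize_curve <- function(curve, u_N, F_N) {
  stopifnot(inherits(curve, "fbc_curve"))
  if (u_N <= 0 || F_N <= 0) stop("normalization scales must be positive", call. = FALSE)
  fbc_curve(curve$x * u_N, curve$y * F_N, normalized = FALSE)
}
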