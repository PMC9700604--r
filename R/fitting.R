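#' Goodness of approximation between a modeled and a measured curve
#'
#' RMSE is the root mean squared residual related to the maximum measured
#' force at the given scaling, expressed in percent; R^2 is the squared
#' linear (Pearson) correlation between modeled and measured values — by
#' this definition it is correlation-based even for biased fits.
#'
#' @param model_y modeled forces (numeric vector or [fbc_curve()]).
#' @param measured_y measured forces on the same grid.
#' @return list with `rmse` (percent) and `r2` (NA with a warning when the
#'   measured curve is constant).
#' @export
goodness <- function(model_y, measured_y) {
  if (inherits(model_y, "fbc_curve")) model_y <- model_y$y
  if (inherits(measured_y, "fbc_curve")) measured_y <- measured_y$y
  if (length(model_y) != length(measured_y)) {
    stop("curves must share one grid", call. = FALSE)
  }
  rmse <- sqrt(mean((model_y - measured_y)^2)) / max(abs(measured_y)) * 100
  r2 <- if (stats::sd(measured_y) == 0 || stats::sd(model_y) == 0) {
    warning("constant curve: R^2 undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(model_y, measured_y)^2
  }
  list(rmse = rmse, r2 = r2)
}

#' Estimate normalizing parameters from a measured curve
#'
#' When the mean fiber breaking force and strain are unknown, the normalizing
#' scales are estimated from the curve itself.  Method `"e_bundle_fit"`
#' approximates the curve by a (possibly shifted) E-bundle relationship
#' `F(u) = k(u - u0) (1 - Q_epsN(u - u0))` with a linear characteristic, so
#' the virtual breaking-strain mean `epsN` gives `u_N = epsN` and
#' `F_N = k(u_N)`.  Method `"inflection_tangent"` takes the tangent of the
#' rising part at its inflection point as the tensile characteristic `k(u)`
#' and requires `u_N` to be supplied (or falls back to `u1`).  In both cases
#' the bounds chain `F* < k(u*) < F_N <= k(u1)` and `u* < u_N <= u1` is
#' checked, where `(u*, F*)` is the first global force peak and `u1` the
#' first crossing of `k(u)/2` with `F(u)` after the peak.
#'
#' @param curve an [fbc_curve()] whose global maximum is not at the first
#'   sample.
#' @param method estimation method, see Details.
#' @param u_N optional strain scale for the tangent method.
#' @return list with `u_N`, `F_N`, `eps_N`, `u_star`, `F_star`, `u1`,
#'   `k` (the fitted characteristic as a function), and `bounds_ok`.
#' @export
estimate_normalization <- function(curve,
                                   method = c("e_bundle_fit",
                                              "inflection_tangent"),
                                   u_N = NULL) {
  stopifnot(inherits(curve, "fbc_curve"))
  method <- match.arg(method)
  u <- curve$x; y <- curve$y
  ipk <- which.max(y)
  if (ipk <= 1 || ipk == length(u)) {
    stop("curve has no interior force peak; cannot estimate normalization",
         call. = FALSE)
  }
  u_star <- u[ipk]; F_star <- y[ipk]
  if (method == "e_bundle_fit") {
    # linear shifted E-bundle: F = c0*(u-u0)+ * survival(u-u0; epsN, sN)
    resid_fn <- function(p) {
      v <- pmax(u - p[4], 0)
      p[1] * v * stats::pnorm(v, p[2], p[3], lower.tail = FALSE) - y
    }
    start <- c(c0 = F_star / u_star, epsN = u_star * 1.2,
               sN = u_star * 0.25, u0 = 0)
    o <- suppressWarnings(
      minpack.lm::nls.lm(start, fn = resid_fn,
                         lower = c(1e-12, 1e-12, 1e-9, 0),
                         upper = c(Inf, max(u) * 2, max(u), u_star * 0.9)))
    p <- stats::coef(o)
    eps_N <- unname(p[2])
    k_fun <- function(x) unname(p[1]) * pmax(x - p[4], 0)
    u_N <- eps_N + unname(p[4])
    F_N <- k_fun(u_N)
  } else {
    # tangent at the inflection of the rising part
    rise <- seq_len(ipk)
    if (length(rise) < 5) stop("rising part too short for tangent method",
                               call. = FALSE)
    d1 <- diff(y[rise]) / diff(u[rise])
    infl <- which.max(d1)
    slope <- d1[infl]
    ui <- (u[rise][infl] + u[rise][infl + 1]) / 2
    yi <- stats::approx(u, y, ui)$y
    k_fun <- function(x) yi + slope * (x - ui)
    eps_N <- NA_real_
    F_N <- NULL
  }
  # u1: first crossing of k(u)/2 with F(u) after the peak
  after <- seq(ipk, length(u))
  gap <- k_fun(u[after]) / 2 - y[after]
  cross <- which(gap >= 0)
  u1 <- if (length(cross)) u[after][cross[1]] else max(u)
  if (method == "inflection_tangent") {
    if (is.null(u_N)) u_N <- u1
    F_N <- k_fun(u_N)
  }
  bounds_ok <- (F_star < k_fun(u_star)) && (k_fun(u_star) < F_N) &&
    (F_N <= k_fun(u1)) && (u_star < u_N) && (u_N <= u1)
  list(u_N = u_N, F_N = F_N, eps_N = eps_N,
       u_star = u_star, F_star = F_star, u1 = u1,
       k = k_fun, bounds_ok = bounds_ok, method = method)
}

# ---- Fourier descriptors and the learning database ---------------------

#' Fourier descriptor of a normalized curve
#'
#' Trigonometric least-squares regression of the curve on `[0, Z0]` treated
#' as one full period, with a constant and `n_harmonics` cosine/sine pairs.
#' The coefficient vector is the curve's shape descriptor used for
#' nearest-neighbour lookup in the learning database.
#'
#' @param curve an [fbc_curve()] sampled on (or resampled to) a uniform
#'   partition of `[0, Z0]`.
#' @param n_harmonics number of harmonics (default 8, giving 17
#'   coefficients).
#' @return object of class `fbc_fourier`: list with `a0`, `a`, `b`, `Z0`,
#'   `residual_rms`.
#' @export
fourier_descriptor <- function(curve, n_harmonics = 8L) {
  stopifnot(inherits(curve, "fbc_curve"))
  z <- curve$x; y <- curve$y
  if (length(z) < 2 * n_harmonics + 2) {
    stop("fewer samples than Fourier coefficients", call. = FALSE)
  }
  Z0 <- max(z)
  X <- matrix(1, length(z), 1 + 2 * n_harmonics)
  for (h in seq_len(n_harmonics)) {
    X[, 2 * h] <- cos(2 * pi * h * z / Z0)
    X[, 2 * h + 1] <- sin(2 * pi * h * z / Z0)
  }
  co <- unname(stats::lsfit(X, y, intercept = FALSE)$coefficients)
  fit <- as.vector(X %*% co)
  structure(list(a0 = co[1],
                 a = co[seq(2, 2 * n_harmonics, by = 2)],
                 b = co[seq(3, 2 * n_harmonics + 1, by = 2)],
                 Z0 = Z0, n_harmonics = n_harmonics,
                 residual_rms = sqrt(mean((fit - y)^2))),
            class = "fbc_fourier")
}

#' @rdname fourier_descriptor
#' @param fd an `fbc_fourier` descriptor.
#' @param z evaluation grid.
#' @export
fourier_reconstruct <- function(fd, z) {
  stopifnot(inherits(fd, "fbc_fourier"))
  out <- rep(fd$a0, length(z))
  for (h in seq_len(fd$n_harmonics)) {
    out <- out + fd$a[h] * cos(2 * pi * h * z / fd$Z0) +
      fd$b[h] * sin(2 * pi * h * z / fd$Z0)
  }
  out
}

#' @noRd
fourier_vector <- function(fd) c(fd$a0, fd$a, fd$b)

#' Model database for nearest-neighbour fit initialization
#'
#' An append-only collection of records pairing a Fourier descriptor `f`
#' with a fitted parameter vector `p`.  [nn_initialize()] returns the `p` of
#' the record whose descriptor is nearest (Euclidean distance) to the query,
#' breaking ties by the lowest record index; [db_learn()] appends a record
#' after a sufficiently good fit.  The database persists as line-delimited
#' JSON.
#'
#' @param path optional file to load (line-delimited JSON records).
#' @return object of class `fbc_db`.
#' @export
model_db <- function(path = NULL) {
  records <- list()
  if (!is.null(path) && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    records <- lapply(lines[nzchar(lines)], function(l) {
      r <- jsonlite::fromJSON(l)
      list(f = as.numeric(r$f), p = r$p)
    })
  }
  structure(list(records = records, path = path), class = "fbc_db")
}

#' @rdname model_db
#' @param db an `fbc_db`.
#' @param fd query descriptor ([fourier_descriptor()]).
#' @export
nn_initialize <- function(db, fd) {
  stopifnot(inherits(db, "fbc_db"))
  if (!length(db$records)) return(NULL)
  q <- fourier_vector(fd)
  d <- vapply(db$records, function(r) sqrt(sum((r$f - q)^2)), 0)
  db$records[[which.min(d)]]$p
}

#' @rdname model_db
#' @param p parameter vector (any JSON-serializable list/vector).
#' @param rmse goodness of the completed fit, percent.
#' @param accept_threshold store only when `rmse <= accept_threshold` and the
#'   threshold is positive (default 5 percent).
#' @export
db_learn <- function(db, fd, p, rmse, accept_threshold = 5) {
  stopifnot(inherits(db, "fbc_db"))
  if (!(accept_threshold > 0) || rmse > accept_threshold) return(db)
  rec <- list(f = fourier_vector(fd), p = p)
  db$records[[length(db$records) + 1L]] <- rec
  if (!is.null(db$path)) {
    line <- jsonlite::toJSON(rec, digits = NA, auto_unbox = FALSE)
    ok <- try(cat(line, "\n", sep = "", file = db$path, append = TRUE),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("could not append to model database at ", db$path, call. = FALSE)
    }
  }
  db
}
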