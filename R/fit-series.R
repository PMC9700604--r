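#' Fit the damage spectrum s(m)
#'
#' The relation between a component's mean breaking strain `m` and its SD `s`
#' is modeled by
#' \deqn{s(m) = \sqrt{s_0^2 + \omega^2 (m - M)^2},}
#' whose minimum `s0` sits at the overall mean breaking strain `M`.  Because
#' `s^2(m)` is a quadratic polynomial in `m`, the default method
#' (`"squared"`) fits `s^2` by ordinary least squares on `(1, m, m^2)` and
#' reads off `(M, s0, omega^2)` from the polynomial coefficients; a negative
#' vertex value is clamped to `s0 = 0` with a warning.  Method `"direct"`
#' minimizes the untransformed residuals `s(m_i) - s_i` by
#' Levenberg-Marquardt.  Goodness is reported as RMSE of the `s`-scale
#' residuals normalized by `max(s)` (percent) and as the squared Pearson
#' correlation between fitted and observed `s`.
#'
#' @param m component mean breaking strains (>= 3 distinct values).
#' @param s component breaking-strain SDs.
#' @param method `"squared"` (default) or `"direct"`, see Details.
#' @return list with `M`, `s0`, `omega2`, `fitted`, `rmse` (percent of
#'   `max(s)`), `r2` and `method`.
#' @examples
#' fit_damage_spectrum(m = c(6, 9.8, 12.3, 15.5, 19.5),
#'                     s = c(2, 1, 0.9, 0.4, 1.8))
#' @export
fit_damage_spectrum <- function(m, s, method = c("squared", "direct")) {
  method <- match.arg(method)
  if (length(m) < 3 || length(unique(m)) < 3) {
    stop("need at least 3 distinct (m, s) pairs", call. = FALSE)
  }
  if (length(s) != length(m)) stop("m and s must match in length", call. = FALSE)
  if (method == "squared") {
    co <- stats::coef(stats::lm(I(s^2) ~ m + I(m^2)))
    if (co[3] <= 0) stop("degenerate spectrum: fitted omega^2 <= 0", call. = FALSE)
    M <- unname(-co[2] / (2 * co[3]))
    omega2 <- unname(co[3])
    s02 <- unname(co[1] - co[2]^2 / (4 * co[3]))
    if (s02 < 0) {
      warning("fitted s0^2 < 0; clamped to 0", call. = FALSE)
      s02 <- 0
    }
    s0 <- sqrt(s02)
  } else {
    resid_fn <- function(p) sqrt(p[2]^2 + p[3]^2 * (m - p[1])^2) - s
    start <- c(M = m[which.min(s)], s0 = max(min(s), 1e-6), om = 0.3)
    best <- NULL
    for (om0 in c(0.05, 0.3, 1)) {
      start["om"] <- om0
      o <- suppressWarnings(
        minpack.lm::nls.lm(start, fn = resid_fn,
                           lower = c(min(m), 0, 0),
                           upper = c(max(m), max(s), Inf)))
      if (is.null(best) || o$deviance < best$deviance) best <- o
    }
    p <- stats::coef(best)
    M <- unname(p[1]); s0 <- unname(p[2]); omega2 <- unname(p[3])^2
  }
  fitted <- sqrt(s0^2 + omega2 * (m - M)^2)
  res <- fitted - s
  list(M = M, s0 = s0, omega2 = omega2, fitted = fitted,
       rmse = sqrt(mean(res^2)) / max(s) * 100,
       r2 = if (stats::sd(fitted) > 0) stats::cor(s, fitted)^2 else NA_real_,
       method = method)
}

# ---- series fitting ----------------------------------------------------

# parameter packing: weights enter through positive factors v_i with the last
# fixed at 1 (interior parameterization of the simplex), so sum(w) = 1 holds
# by construction for any admissible point.
#' @noRd
series_pack <- function(model, share_char) {
  n <- length(model$w)
  v <- model$w / model$w[n]
  p <- c(if (n > 1) stats::setNames(log(v[-n]), paste0("lv", seq_len(n - 1))),
         if (share_char) c(a = model$a[1], b = model$b[1], c = model$c[1])
         else c(stats::setNames(model$a, paste0("a", seq_len(n))),
                stats::setNames(model$b, paste0("b", seq_len(n))),
                stats::setNames(model$c, paste0("c", seq_len(n)))),
         stats::setNames(model$m, paste0("m", seq_len(n))),
         stats::setNames(model$s, paste0("s", seq_len(n))))
  p
}

#' @noRd
series_unpack <- function(p, n, share_char, u0, units) {
  lv <- if (n > 1) p[paste0("lv", seq_len(n - 1))] else numeric(0)
  v <- c(exp(unname(lv)), 1)
  w <- v / sum(v)
  if (share_char) {
    a <- rep(p[["a"]], n); b <- rep(p[["b"]], n); c <- rep(p[["c"]], n)
  } else {
    a <- unname(p[paste0("a", seq_len(n))])
    b <- unname(p[paste0("b", seq_len(n))])
    c <- unname(p[paste0("c", seq_len(n))])
  }
  m <- unname(p[paste0("m", seq_len(n))])
  s <- pmax(unname(p[paste0("s", seq_len(n))]), 0)
  o <- order(m)
  suppressWarnings(series_model(w[o], a[o], b[o], c[o], m[o], s[o],
                                u0 = u0, units = units))
}

#' Decompose a curve into a series of nonlinear E-bundles
#'
#' Bounded least-squares fit of [series_force()] to a measured curve over the
#' free parameters (weights, characteristic parameters, breaking-strain means
#' and SDs).  Weights are parameterized on the interior of the simplex so
#' they always sum to one.  A deterministic multi-start (seeded Latin
#' hypercube perturbations of the initial guess) guards against local
#' minima; the best run is polished and returned.  With `share_char = TRUE`
#' all components share one `(a, b, c)` characteristic, which removes the
#' scale indeterminacy between weights and force scale (see the vignette).
#'
#' @param curve an [fbc_curve()] with non-negative force values.
#' @param n_components number of E-bundle components (>= 1).
#' @param init optional [series_model()] used as initial guess; when absent a
#'   heuristic from the curve's peaks/drops is used.
#' @param fixed character vector of parameter names to hold at their initial
#'   values (e.g. `c("a", "b")` with `share_char = TRUE`).
#' @param share_char use one common fiber characteristic for all components.
#' @param n_starts number of multi-start perturbations (1 = local fit only).
#' @param seed integer seed driving the multi-start.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @return list with `model` (the fitted [series_model()]), `rmse` (percent
#'   of the maximum measured force), `r2`, `objective` (residual sum of
#'   squares), `converged`, and `n_starts`.
#' @export
fit_series <- function(curve, n_components, init = NULL, fixed = character(),
                       share_char = FALSE, n_starts = 8L, seed = 1L,
                       max_iter = 200L) {
  stopifnot(inherits(curve, "fbc_curve"))
  if (any(curve$y < -1e-12)) stop("curve must be non-negative", call. = FALSE)
  n <- as.integer(n_components)
  if (n < 1) stop("n_components must be >= 1", call. = FALSE)
  if (is.null(init)) init <- series_init_heuristic(curve, n)
  if (length(init$w) != n) stop("init has the wrong number of components", call. = FALSE)
  u <- curve$x; y <- curve$y
  u0 <- init$u0; units <- init$units
  p0 <- series_pack(init, share_char)
  free <- setdiff(names(p0), fixed)
  resid_fn <- function(pf) {
    p <- p0; p[free] <- pf
    mod <- try(series_unpack(p, n, share_char, u0, units), silent = TRUE)
    if (inherits(mod, "try-error")) return(rep(1e6, length(y)))
    series_force(mod, u)$y - y
  }
  lower <- rep(-Inf, length(free)); upper <- rep(Inf, length(free))
  names(lower) <- names(upper) <- free
  lower[grepl("^m", free)] <- max(min(u), 1e-9)
  upper[grepl("^m", free)] <- max(u) * 1.5
  lower[grepl("^s", free)] <- 1e-6
  upper[grepl("^s", free)] <- diff(range(u))
  lower[grepl("^lv", free)] <- -12
  upper[grepl("^lv", free)] <- 12
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter,
                                     maxfev = 100 * max_iter)
  set.seed(seed)
  starts <- list(p0[free])
  if (n_starts > 1) {
    lhs_mat <- lhs::randomLHS(n_starts - 1L, length(free))
    for (r in seq_len(n_starts - 1L)) {
      pert <- p0[free] * (0.7 + 0.6 * lhs_mat[r, ])
      pert[grepl("^lv", free)] <- p0[free][grepl("^lv", free)] +
        (lhs_mat[r, grepl("^lv", free)] - 0.5) * 2
      starts[[r + 1L]] <- pmin(pmax(pert, lower), upper)
    }
  }
  best <- NULL
  for (st in starts) {
    o <- try(suppressWarnings(
      minpack.lm::nls.lm(st, fn = resid_fn, lower = lower,
                         upper = upper, control = ctrl)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$deviance < best$deviance) best <- o
  }
  if (is.null(best)) stop("series fit failed from every start", call. = FALSE)
  # stationarity check: restart once from the best point; converged when the
  # optimizer either meets its own tolerances or can no longer improve
  polish <- try(suppressWarnings(minpack.lm::nls.lm(
    stats::coef(best), fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 100, maxfev = 10000))),
    silent = TRUE)
  converged <- best$info %in% 1:4
  if (!inherits(polish, "try-error")) {
    converged <- converged || polish$info %in% 1:4 ||
      (best$deviance - polish$deviance) <= 1e-8 * max(best$deviance, 1e-12)
    if (polish$deviance <= best$deviance) best <- polish
  }
  p <- p0; p[free] <- stats::coef(best)
  model <- series_unpack(p, n, share_char, u0, units)
  fit_y <- series_force(model, u)$y
  g <- goodness(fit_y, y)
  list(model = model, rmse = g$rmse, r2 = g$r2,
       objective = sum((fit_y - y)^2),
       converged = converged, n_starts = length(starts))
}

# crude peak/drop heuristic: place component means at the largest drops of
# the curve and at the final decay, equal weights, linear characteristic
# scaled to the observed secant stiffness
#' @noRd
series_init_heuristic <- function(curve, n) {
  u <- curve$x; y <- curve$y
  peak <- which.max(y)
  slope <- max(y) / max(u[peak], diff(range(u)) / 4)
  m <- seq(u[max(peak, 2)] * 0.7, max(u) * 0.9, length.out = n)
  if (is.unsorted(m, strictly = TRUE)) m <- m + seq_len(n) * 1e-6
  series_model(w = rep(1 / n, n), a = -slope * 0.3, b = 1 / max(u),
               c = slope, m = m, s = rep(diff(range(u)) / 10, n),
               units = curve$meta$units)
}
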