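#' Parallel series of nonlinear E-bundles
#'
#' A measured tensile force-strain curve can be decomposed into the weighted
#' sum of E-bundle responses in product form,
#' \deqn{\bar f(u) = \sum_i w_i\, k_i(u)\, R_i(u), \qquad \sum_i w_i = 1,}
#' where each component has its own fiber characteristic \eqn{k_i}
#' (parameters `a_i, b_i, c_i`), and \eqn{R_i} is the Gaussian survival
#' function of the component breaking strain with mean `m_i` and SD `s_i`.
#' The representation is the law of total expectation: `w_i` is the
#' probability that a fiber belongs to sub-bundle i and `k_i R_i` its
#' conditional expected force.  The component means must form a strictly
#' increasing sequence; inputs violating this are reordered with a warning.
#'
#' Unlike the normalized single-bundle forms, the series operates directly on
#' the measured axes (strain or elongation vs force); units are metadata.
#'
#' @param w weights in (0, 1], summing to 1 (tolerance 1e-9).
#' @param a,b,c per-component characteristic parameters (recycled if scalar).
#' @param m,s per-component breaking-strain mean (> 0) and SD (>= 0).
#' @param u0 optional per-component strain shift (>= 0, recycled).
#' @param units optional `c(strain, force)` labels.
#' @return object of class `fbc_series`.
#' @examples
#' sm <- series_model(w = c(0.3, 0.7), a = -1, b = 1, c = 1,
#'                    m = c(0.8, 1.4), s = c(0.1, 0.2))
#' sf <- series_force(sm, seq(0, 2, 0.01))
#' @export
series_model <- function(w, a, b, c, m, s, u0 = 0, units = NULL) {
  n <- length(w)
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  u0 <- rep_len(u0, n)
  if (length(m) != n || length(s) != n) {
    stop("w, m, s must have equal length", call. = FALSE)
  }
  if (!all(is.finite(c(w, a, b, c, m, s, u0)))) {
    stop("series parameters must be finite", call. = FALSE)
  }
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) {
    stop("weights must be positive and sum to 1", call. = FALSE)
  }
  if (any(m <= 0) || any(s < 0) || any(u0 < 0)) {
    stop("need m > 0, s >= 0, u0 >= 0", call. = FALSE)
  }
  if (is.unsorted(m, strictly = TRUE)) {
    warning("component means m are not strictly increasing; reordering",
            call. = FALSE)
    o <- order(m)
    w <- w[o]; a <- a[o]; b <- b[o]; c <- c[o]; m <- m[o]; s <- s[o]
    u0 <- u0[o]
    if (is.unsorted(m, strictly = TRUE)) {
      stop("duplicated component means", call. = FALSE)
    }
  }
  structure(list(w = w, a = a, b = b, c = c, m = m, s = s, u0 = u0,
                 units = units),
            class = "fbc_series")
}

#' @export
print.fbc_series <- function(x, ...) {
  cat(sprintf("<fbc_series> %d E-bundle components\n", length(x$w)))
  print(series_component_table(x), digits = 4)
  invisible(x)
}

#' Component table in the conventional layout
#'
#' Returns one row per component with the stored parameters plus the derived
#' columns `K0 = c + a*b` (initial stiffness) and `V = s/m * 100` (percent
#' coefficient of variation of the breaking strain), which are always
#' recomputed, never trusted from input.
#'
#' @param model an [series_model()].
#' @export
series_component_table <- function(model) {
  stopifnot(inherits(model, "fbc_series"))
  data.frame(component = seq_along(model$w),
             w = model$w, a = model$a, b = model$b, c = model$c,
             K0 = model$c + model$a * model$b,
             m = model$m, s = model$s,
             V = model$s / model$m * 100)
}

# per-component product-form response k_i(u - u0) R_i(u - u0)
#' @noRd
series_component_force <- function(model, i, u) {
  v <- u - model$u0[i]
  ch <- fbc_characteristic(model$a[i], model$b[i], model$c[i])
  positive_part_characteristic(ch, v) * normal_survival(v, model$m[i], model$s[i])
}

#' Expected force of an E-bundle series
#'
#' Evaluates \eqn{\bar f(u) = \sum w_i k_i(u) R_i(u)} on a strain grid.  The
#' returned object also carries the expected tensile characteristic
#' \eqn{\bar k(u) = \sum w_i k_i(u)} (attribute `"kbar"`) and the
#' per-component weighted responses (attribute `"components"`, a matrix);
#' always `f(u) <= kbar(u)` since the survivals are at most one.
#'
#' @param model an [series_model()].
#' @param u strain grid.
#' @return an [fbc_curve()] with attributes `kbar` and `components`.
#' @export
series_force <- function(model, u) {
  stopifnot(inherits(model, "fbc_series"))
  n <- length(model$w)
  comp <- matrix(0, length(u), n)
  kbar <- numeric(length(u))
  for (i in seq_len(n)) {
    comp[, i] <- model$w[i] * series_component_force(model, i, u)
    ch <- fbc_characteristic(model$a[i], model$b[i], model$c[i])
    kbar <- kbar + model$w[i] *
      positive_part_characteristic(ch, u - model$u0[i])
  }
  out <- fbc_curve(u, rowSums(comp), normalized = FALSE, units = model$units)
  attr(out, "kbar") <- kbar
  attr(out, "components") <- comp
  out
}

#' Integral form of the series model
#'
#' As the component means refine to a continuum, the series becomes
#' \eqn{F(u) \approx \int k(u; m) R(u; m)\, dW(m)} with `W` the distribution
#' of the conditional mean breaking strain.  With a discrete `W` carried on
#' the component means this reproduces [series_force()] exactly; with a
#' continuous (Gaussian) `W` the integral is evaluated by quadrature.
#'
#' @param k_family function `k(u, m)` giving the characteristic at mean `m`
#'   (vectorized over `u`).
#' @param s_fun function `s(m)` giving the breaking-strain SD at `m`.
#' @param W either `list(type = "discrete", m = ..., w = ...)` or
#'   `list(type = "gaussian", mean = ..., sd = ...)`.
#' @param u strain grid.
#' @param quad_n quadrature order for a continuous `W`.
#' @return an [fbc_curve()].
#' @export
series_integral_form <- function(k_family, s_fun, W, u, quad_n = 64L) {
  if (identical(W$type, "discrete")) {
    nodes <- W$m; wts <- W$w
  } else if (identical(W$type, "gaussian")) {
    nd <- normal_nodes(W$mean, W$sd, n = quad_n)
    nodes <- nd$x; wts <- nd$w
  } else {
    stop("W must be a discrete or gaussian distribution spec", call. = FALSE)
  }
  out <- numeric(length(u))
  for (j in seq_along(nodes)) {
    m <- nodes[j]
    kv <- pmax(k_family(u, m), 0)
    out <- out + wts[j] * kv * normal_survival(u, m, s_fun(m))
  }
  fbc_curve(u, out, normalized = NA)
}

#' Per-component and resultant breaking-strain densities
#'
#' The component breaking strains are Gaussian `N(m_i, s_i^2)` with weights
#' `w_i`; the resultant (unconditional) density is taken Gaussian `N(M, S^2)`
#' with `M` the weighted mean and, unless given, `S` the smallest value
#' bracketing all component means inside `M +/- 3S`, i.e.
#' `S = max(max(m) - M, M - min(m)) / 3`.
#'
#' @param model an [series_model()].
#' @param M optional resultant mean (defaults to the weighted mean of `m`).
#' @param S optional resultant SD (defaults to the 3-sigma bracketing rule).
#' @return list with `components` (data.frame of `m`, `s`, `w`), `M`, `S`,
#'   and a function `density(x, i = NULL)` returning the resultant (or i-th
#'   conditional) density.
#' @export
breaking_strain_densities <- function(model, M = NULL, S = NULL) {
  stopifnot(inherits(model, "fbc_series"))
  if (is.null(M)) M <- sum(model$w * model$m)
  if (is.null(S)) S <- max(max(model$m) - M, M - min(model$m)) / 3
  dens <- function(x, i = NULL) {
    if (is.null(i)) stats::dnorm(x, M, S)
    else stats::dnorm(x, model$m[i], model$s[i])
  }
  list(components = data.frame(m = model$m, s = model$s, w = model$w),
       M = M, S = S, density = dens)
}
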