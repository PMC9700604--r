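#' Nonlinear tensile characteristic of a single fiber
#'
#' The failureless force-strain law of a model fiber is the three-parameter
#' exponential-plus-linear curve
#' \deqn{k(\varepsilon) = c\,\varepsilon + a\,(1 - e^{-b\varepsilon}),}
#' the ramp response of a Standard-Solid (Zener) viscoelastic model.  The sign
#' of `a` selects the shape: `a = 0` is linear with slope `c`, `a > 0` concave
#' from above (asymptote `c*eps + a` for `b > 0`), `a < 0` convex from below;
#' `b < 0` gives a steep exponential rise useful for large initial curved arcs.
#' The initial stiffness is \eqn{K_0 = c + ab}.
#'
#' No sign restrictions are imposed on the parameters.  Monotonicity of `k` on
#' a working range is not guaranteed for all parameter combinations; use
#' [is_monotone_characteristic()] to check before relying on it.
#'
#' @param a force-scale parameter (same unit as the force axis).
#' @param b inverse-strain rate constant (1/strain unit).
#' @param c asymptotic stiffness (force per strain unit).
#' @param units optional two-element character vector `c(strain, force)` kept
#'   as metadata; never used for conversion.
#' @return an object of class `fbc_characteristic`.
#' @examples
#' ch <- fbc_characteristic(a = -1, b = 1, c = 1)
#' tensile_characteristic(ch, 0.5)
#' stiffness0(ch)
#' @export
fbc_characteristic <- function(a, b, c, units = NULL) {
  vals <- c(a = a, b = b, c = c)
  if (!all(is.finite(vals))) {
    stop("fiber characteristic parameters must be finite numbers", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, units = units),
            class = "fbc_characteristic")
}

#' @export
print.fbc_characteristic <- function(x, ...) {
  cat(sprintf("<fbc_characteristic> k(e) = %g*e + %g*(1 - exp(-%g*e)),  K0 = %g\n",
              x$c, x$a, x$b, stiffness0(x)))
  if (!is.null(x$units)) {
    cat("  units:", paste(x$units, collapse = " / "), "\n")
  }
  invisible(x)
}

#' Evaluate the fiber tensile characteristic
#'
#' @param char an [fbc_characteristic()].
#' @param eps strain (any real; see [positive_part_characteristic()] for the
#'   clamped version used in bundle integrals).
#' @return force value(s), same length as `eps`.
#' @export
tensile_characteristic <- function(char, eps) {
  stopifnot(inherits(char, "fbc_characteristic"))
  char$c * eps + char$a * (1 - exp(-char$b * eps))
}

#' Positive part of the tensile characteristic
#'
#' Perfectly flexible fibers transmit no compressive force, so the
#' characteristic is evaluated on the positive part of the strain:
#' `k(eps)` for `eps > 0`, zero otherwise.
#'
#' @inheritParams tensile_characteristic
#' @export
positive_part_characteristic <- function(char, eps) {
  out <- numeric(length(eps))
  pos <- eps > 0
  out[pos] <- tensile_characteristic(char, eps[pos])
  out
}

#' Initial tensile stiffness K0 = c + a*b
#' @inheritParams tensile_characteristic
#' @export
stiffness0 <- function(char) {
  stopifnot(inherits(char, "fbc_characteristic"))
  char$c + char$a * char$b
}

#' Check strict monotonicity of k on a strain range
#'
#' `k'(eps) = c + a*b*exp(-b*eps)` is itself monotone in `eps`, so strict
#' increase on `[0, upper]` is equivalent to positivity of the derivative at
#' both endpoints.
#'
#' @inheritParams tensile_characteristic
#' @param upper upper end of the strain range to check.
#' @return `TRUE`/`FALSE`.
#' @export
is_monotone_characteristic <- function(char, upper) {
  # k' is monotone in eps, so its minimum over [0, upper] is at an endpoint;
  # K0 = k'(0) = 0 (a common calibration) still gives strict increase
  dk <- function(e) char$c + char$a * char$b * exp(-char$b * e)
  lo <- min(dk(0), dk(upper))
  hi <- max(dk(0), dk(upper))
  lo >= -1e-12 && hi > 0
}

# warn (once per call site pattern) when a characteristic is used on a range
# where it is not strictly increasing; bundle formulas assume monotone k.
#' @noRd
check_monotone <- function(char, upper) {
  if (!is_monotone_characteristic(char, upper)) {
    warning(sprintf(
      "fiber characteristic (a=%g, b=%g, c=%g) is not strictly increasing on [0, %g]",
      char$a, char$b, char$c, upper), call. = FALSE)
  }
  invisible(NULL)
}

#' Crosswise contraction factor of the specimen
#'
#' \deqn{W(u) = (1 + c_a u)^{-c_b} \approx 1 - c_a c_b u \ (u \to 0)}
#' so the product `ca*cb` plays the role of a small-strain Poisson
#' coefficient.  `ca = 0` or `cb = 0` short-circuits to `W == 1` (avoiding the
#' `0^0` ambiguity at the pole).
#'
#' @param u bundle strain.
#' @param ca,cb contraction constants (non-negative in typical use).
#' @export
contraction <- function(u, ca, cb) {
  if (ca == 0 || cb == 0) {
    return(rep(1, length(u)))
  }
  base <- 1 + ca * u
  if (any(base <= 0)) {
    stop("contraction pole: 1 + ca*u must be positive", call. = FALSE)
  }
  base^(-cb)
}

#' Fiber strain as a function of bundle strain
#'
#' The geometric relation between the bundle strain `u` and the strain of a
#' fiber with initial strain `eps0` (negative: crimped/wavy; positive:
#' pre-strained) and obliquity tangent `T0`:
#' \deqn{\varepsilon(u) = (1+\varepsilon_0)\sqrt{\frac{(1+u)^2 + T_0^2 W^2(u)}
#'   {1+T_0^2}} - 1.}
#' Special cases: `eps0 = T0 = 0` gives the identity `eps(u) = u`; `T0 = 0`
#' gives `(1+eps0)(1+u) - 1`; `eps0 = 0` the oblique-fiber relation.
#'
#' @param u bundle strain, `u > -1`.
#' @param eps0 initial fiber strain.
#' @param T0 obliquity tangent (`tan` of the initial orientation angle).
#' @param ca,cb contraction constants, see [contraction()].
#' @export
fiber_strain <- function(u, eps0 = 0, T0 = 0, ca = 0, cb = 0) {
  if (any(u <= -1)) {
    stop("bundle strain must satisfy u > -1", call. = FALSE)
  }
  if (T0 == 0) {
    if (eps0 == 0) return(u)   # exact identity, no float round trip
    return((1 + eps0) * (1 + u) - 1)
  }
  W <- contraction(u, ca, cb)
  (1 + eps0) * sqrt(((1 + u)^2 + T0^2 * W^2) / (1 + T0^2)) - 1
}

#' Map Standard-Solid viscoelastic parameters to a fiber characteristic
#'
#' A Standard-Solid model (spring E0 in parallel with a Maxwell branch E, eta)
#' subjected to a constant strain rate responds with
#' \eqn{\sigma(\varepsilon) = E_0\varepsilon + E\varepsilon_0^*(1 -
#' e^{-\varepsilon/\varepsilon_0^*})}, \eqn{\varepsilon_0^* = \dot\varepsilon_0
#' \tau}, \eqn{\tau = \eta/E}.  Multiplying by the fiber cross-section `A0`
#' gives the force law, so `c = A0*E0`, `a = A0*E*eps0*`, `b = 1/eps0*`.  The
#' inverse-strain constant therefore encodes the relaxation time:
#' `1/b = strain_rate * tau`.
#'
#' @param E0 parallel spring modulus (> 0).
#' @param E Maxwell spring modulus (> 0).
#' @param eta dashpot viscosity (> 0); together with `E` defines
#'   `tau = eta / E`.
#' @param strain_rate engineering strain rate (> 0).  May instead be supplied
#'   as `elongation_rate / gauge_length`.
#' @param elongation_rate,gauge_length optional alternative to `strain_rate`.
#' @param area fiber cross-sectional area A0 (default 1).
#' @return an [fbc_characteristic()] with attribute `"tau"`.
#' @export
standard_solid_characteristic <- function(E0, E, eta,
                                          strain_rate = NULL,
                                          elongation_rate = NULL,
                                          gauge_length = NULL,
                                          area = 1) {
  if (is.null(strain_rate)) {
    if (is.null(elongation_rate) || is.null(gauge_length)) {
      stop("supply strain_rate or both elongation_rate and gauge_length",
           call. = FALSE)
    }
    strain_rate <- elongation_rate / gauge_length
  }
  if (any(c(E0, E, eta, strain_rate, area) <= 0) ||
      !all(is.finite(c(E0, E, eta, strain_rate, area)))) {
    stop("Standard-Solid parameters must be positive finite numbers",
         call. = FALSE)
  }
  tau <- eta / E
  eps0_star <- strain_rate * tau
  out <- fbc_characteristic(a = area * E * eps0_star,
                            b = 1 / eps0_star,
                            c = area * E0)
  attr(out, "tau") <- tau
  out
}
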