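#' Specification of a statistical fiber bundle cell (FBC)
#'
#' An FBC is an idealized class of fibers sharing one tensile characteristic
#' and one set of stochastic parameters.  Four kinds are supported:
#' \describe{
#'   \item{E}{ideal bundle: straight, parallel, perfectly gripped fibers that
#'     break at a random strain.}
#'   \item{EH}{fibers with a random initial strain (negative: crimped/wavy,
#'     positive: pre-strained).}
#'   \item{ES}{fibers that may slip out of their grip at a random threshold
#'     strain for a random slip length instead of breaking.}
#'   \item{ET}{fibers with random obliquity (tangent of the orientation
#'     angle), with optional crosswise contraction of the specimen.}
#' }
#' Parameter naming follows the conventional bundle-analysis shorthand: `AE = E(epsB)` is the
#' mean breaking strain, `VE = D(epsB)/AE` its relative SD, `EH = E(eps0)/AE`,
#' `VH = D(eps0)/AE` the normalized initial-strain law, `ES, VS` the
#' normalized slip threshold, `EL, VL` the normalized slip length,
#' `ET = E(T0)`, `ST = D(T0)` the obliquity law and `Ca, Cb` the contraction
#' constants.  All laws are Gaussian; an SD of zero denotes a point mass.
#'
#' @param kind one of `"E"`, `"EH"`, `"ES"`, `"ET"`.
#' @param char an [fbc_characteristic()].
#' @param AE mean fiber breaking strain (> 0); also the strain normalizer.
#' @param VE relative SD of the breaking strain (>= 0).
#' @param EH,VH normalized mean / SD of the initial strain (EH-bundles).
#' @param ES,VS normalized mean / SD of the slip threshold (ES-bundles).
#' @param EL,VL normalized mean / SD of the slip length (ES-bundles).
#' @param ET,ST mean / SD of the obliquity tangent (ET-bundles).
#' @param Ca,Cb contraction constants (ET-bundles), see [contraction()].
#' @param u0 optional normalized strain shift (>= 0): the response is
#'   evaluated at `z - u0` and is zero below the shift ("shifted bundle").
#' @param n_fibers,mean_break_force optional bookkeeping for denormalization.
#' @return object of class `fbc_bundle`.
#' @examples
#' e <- bundle_spec("E", fbc_characteristic(-1, 1, 1), AE = 1, VE = 0.2)
#' fh(e, c(0, 0.5, 1))
#' @export
bundle_spec <- function(kind = c("E", "EH", "ES", "ET"), char,
                        AE, VE,
                        EH = 0, VH = 0,
                        ES = NULL, VS = 0,
                        EL = NULL, VL = 0,
                        ET = 0, ST = 0, Ca = 0, Cb = 0,
                        u0 = 0, n_fibers = NULL, mean_break_force = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(char, "fbc_characteristic"))
  if (!is.finite(AE) || AE <= 0) stop("AE must be positive", call. = FALSE)
  if (VE < 0 || VH < 0 || VS < 0 || VL < 0 || ST < 0) {
    stop("SD parameters must be non-negative", call. = FALSE)
  }
  if (u0 < 0) stop("u0 must be non-negative", call. = FALSE)
  if (kind == "ES" && (is.null(ES) || is.null(EL))) {
    stop("ES-bundles need ES and EL", call. = FALSE)
  }
  structure(list(kind = kind, char = char, AE = AE, VE = VE,
                 EH = EH, VH = VH, ES = ES, VS = VS, EL = EL, VL = VL,
                 ET = ET, ST = ST, Ca = Ca, Cb = Cb, u0 = u0,
                 n_fibers = n_fibers, mean_break_force = mean_break_force),
            class = "fbc_bundle")
}

#' @export
print.fbc_bundle <- function(x, ...) {
  extras <- switch(x$kind,
    E  = "",
    EH = sprintf(", EH=%g, VH=%g", x$EH, x$VH),
    ES = sprintf(", ES=%g, VS=%g, EL=%g, VL=%g", x$ES, x$VS, x$EL, x$VL),
    ET = sprintf(", ET=%g, ST=%g, Ca=%g, Cb=%g", x$ET, x$ST, x$Ca, x$Cb))
  cat(sprintf("<fbc_bundle %s> AE=%g, VE=%g%s%s\n", x$kind, x$AE, x$VE, extras,
              if (x$u0 > 0) sprintf(", u0=%g", x$u0) else ""))
  print(x$char)
  invisible(x)
}

#' Expected breaking force of a fiber
#'
#' \eqn{\bar F_B = E(k(\varepsilon_B))}, the expectation of the tensile
#' characteristic under the breaking-strain law, computed by Gauss-Legendre
#' quadrature over the full Gaussian window.  For a linear characteristic this
#' equals `c * AE` exactly (symmetry of the Gaussian about its mean); for a
#' point mass (`VE = 0`) it is `k(AE)`.
#'
#' @param spec an [bundle_spec()], or an [fbc_characteristic()] when `AE`,
#'   `VE` are given explicitly.
#' @param AE,VE breaking-strain law (used when `spec` is a characteristic).
#' @param quad_n quadrature order.
#' @export
mean_breaking_force <- function(spec, AE = NULL, VE = NULL, quad_n = 96L) {
  if (inherits(spec, "fbc_bundle")) {
    char <- spec$char; AE <- spec$AE; VE <- spec$VE
  } else {
    char <- spec
    stopifnot(inherits(char, "fbc_characteristic"), !is.null(AE), !is.null(VE))
  }
  # wide window + high order: the expectation is used as a normalizer, so
  # it is computed a notch more accurately than the curve integrals
  nd <- normal_nodes(AE, VE * AE, n = quad_n, span = 8)
  sum(nd$w * tensile_characteristic(char, nd$x))
}

# shared pre-computation for the FH/kH evaluators
#' @noRd
bundle_env <- function(spec, quad_n) {
  list(Ek = mean_breaking_force(spec),
       sdB = spec$VE * spec$AE,
       quad_n = quad_n)
}

#' Normalized expected tensile force of a bundle
#'
#' `fh()` evaluates the normalized expected tensile force process `FH(z)` of a
#' single FBC at normalized strains `z = u / AE`.  The component formulas are:
#' E-bundle, the product of the normalized characteristic and the
#' breaking-strain survival function; EH-bundle, its integral over the
#' initial-strain law with the fiber strain `(1+eps0)(1+u) - 1` and the
#' positive-part characteristic; ES-bundle, the intact-fiber term (survival of
#' both breaking and slip onset) plus the slip-memory integral in which a
#' fiber that started slipping at threshold `w` keeps its frozen force `k(w)`
#' until its slip completes; ET-bundle, the longitudinal projection integrated
#' over the obliquity law with the oblique fiber strain and contraction.
#'
#' Slip completion (`ES` only): slippage ends at the strain level
#' `epsSL = epsS + epsL`, i.e. a fiber that starts slipping at `epsS = w`
#' slips for a further strain interval `epsL`.  `slip_completion =
#' "onset_plus_length"` (default) uses that conditional duration law;
#' `"as_printed"` draws the duration from the unconditional `epsS + epsL` law
#' instead (see the package vignette for why both exist).
#'
#' @param spec a [bundle_spec()].
#' @param z normalized strain grid (>= 0).
#' @param slip_completion slip-duration semantics for ES-bundles.
#' @param quad_n Gauss-Legendre order for the parameter-law integrals.
#' @param warn_monotone check the characteristic for monotonicity on the used
#'   strain range and warn if it fails.
#' @return numeric vector of normalized forces, same length as `z`.
#' @export
fh <- function(spec, z, slip_completion = c("onset_plus_length", "as_printed"),
               quad_n = 48L, warn_monotone = TRUE) {
  stopifnot(inherits(spec, "fbc_bundle"))
  slip_completion <- match.arg(slip_completion)
  if (any(z < 0)) stop("normalized strain z must be >= 0", call. = FALSE)
  if (warn_monotone) check_monotone(spec$char, spec$AE * (1 + 6 * spec$VE))
  zeff <- z - spec$u0
  out <- numeric(length(z))
  # z = 0 is included when there is no shift: a pre-strained EH-bundle
  # carries force already at zero bundle strain
  pos <- if (spec$u0 == 0) zeff >= 0 else zeff > 0
  if (!any(pos)) return(out)
  fun <- switch(spec$kind, E = fh_e_raw, EH = fh_eh_raw,
                ES = function(s, zz, env) fh_es_raw(s, zz, env, slip_completion),
                ET = function(s, zz, env) fh_et_raw(s, zz, env)$longitudinal)
  out[pos] <- fun(spec, zeff[pos], bundle_env(spec, quad_n))
  out
}

#' @noRd
fh_e_raw <- function(spec, z, env) {
  u <- z
  positive_part_characteristic(spec$char, u) *
    normal_survival(u, spec$AE, env$sdB) / env$Ek
}

#' @noRd
fh_eh_raw <- function(spec, z, env) {
  m0 <- spec$EH * spec$AE
  s0 <- spec$VH * spec$AE
  vapply(z, function(zi) {
    u <- zi
    # fibers with eps0 <= 1/(1+u) - 1 carry no force (positive part): the
    # integrand vanishes below the kink, so truncate the window there
    nd <- normal_nodes(m0, s0, lower = 1 / (1 + u) - 1, n = env$quad_n)
    if (!length(nd$x)) return(0)
    y <- (1 + nd$x) * (1 + u) - 1
    sum(nd$w * positive_part_characteristic(spec$char, y) *
          normal_survival(y, spec$AE, env$sdB))
  }, 0) / env$Ek
}

#' @noRd
slip_duration_law <- function(spec, slip_completion) {
  if (slip_completion == "onset_plus_length") {
    c(mean = spec$EL * spec$AE, sd = spec$VL * spec$AE)
  } else {
    c(mean = (spec$ES + spec$EL) * spec$AE,
      sd = sqrt(spec$VS^2 + spec$VL^2) * spec$AE)
  }
}

#' @noRd
fh_es_raw <- function(spec, z, env, slip_completion) {
  mS <- spec$ES * spec$AE
  sS <- spec$VS * spec$AE
  dur <- slip_duration_law(spec, slip_completion)
  vapply(z, function(zi) {
    u <- zi
    intact <- positive_part_characteristic(spec$char, u) *
      normal_survival(u, spec$AE, env$sdB) * normal_survival(u, mS, sS)
    nd <- normal_nodes(mS, sS, lower = 0, upper = u, n = env$quad_n)
    frozen <- if (length(nd$x)) {
      sum(nd$w * tensile_characteristic(spec$char, nd$x) *
            normal_survival(nd$x, spec$AE, env$sdB) *
            normal_survival(u - nd$x, dur["mean"], dur["sd"]))
    } else 0
    intact + frozen
  }, 0) / env$Ek
}

#' @noRd
fh_et_raw <- function(spec, z, env, failureless = FALSE) {
  long <- numeric(length(z))
  trans <- numeric(length(z))
  for (i in seq_along(z)) {
    u <- z[i]
    W <- contraction(u, spec$Ca, spec$Cb)
    # oblique fiber strain g is positive only where
    # t^2 (1 - W^2) < (1+u)^2 - 1; truncate the obliquity window accordingly
    lim <- if (W < 1) sqrt(((1 + u)^2 - 1) / (1 - W^2)) else Inf
    nd <- normal_nodes(spec$ET, spec$ST, lower = -lim, upper = lim,
                       n = env$quad_n)
    if (!length(nd$x)) next
    denom <- sqrt((1 + u)^2 + nd$x^2 * W^2)
    g <- denom / sqrt(1 + nd$x^2) - 1
    f <- positive_part_characteristic(spec$char, g)
    if (!failureless) f <- f * normal_survival(g, spec$AE, env$sdB)
    long[i] <- sum(nd$w * f * (1 + u) / denom)
    trans[i] <- sum(nd$w * f * nd$x * W / denom)
  }
  list(longitudinal = long / env$Ek, transverse = trans / env$Ek)
}

#' Longitudinal and transverse force components of an ET-bundle
#'
#' @inheritParams fh
#' @return list with elements `longitudinal` and `transverse`.
#' @export
fh_et_components <- function(spec, z, quad_n = 48L) {
  stopifnot(inherits(spec, "fbc_bundle"), spec$kind == "ET")
  zeff <- pmax(z - spec$u0, 0)
  res <- fh_et_raw(spec, zeff, bundle_env(spec, quad_n))
  res$longitudinal[zeff <= 0] <- 0
  res$transverse[zeff <= 0] <- 0
  res
}

#' Normalized failureless tensile characteristic of a bundle
#'
#' `kh()` is the expected tensile characteristic with all damage-variable
#' survival factors replaced by one: the force the bundle would carry if no
#' fiber broke or slipped out.  For E- and ES-bundles this is the normalized
#' fiber characteristic itself; for EH- and ET-bundles the initial-strain or
#' obliquity integral remains.  Always `fh(z) <= kh(z)`.
#'
#' @inheritParams fh
#' @export
kh <- function(spec, z, quad_n = 48L) {
  stopifnot(inherits(spec, "fbc_bundle"))
  if (any(z < 0)) stop("normalized strain z must be >= 0", call. = FALSE)
  env <- bundle_env(spec, quad_n)
  zeff <- z - spec$u0
  out <- numeric(length(z))
  pos <- if (spec$u0 == 0) zeff >= 0 else zeff > 0
  if (!any(pos)) return(out)
  zp <- zeff[pos]
  out[pos] <- switch(spec$kind,
    E = ,
    ES = positive_part_characteristic(spec$char, zp) / env$Ek,
    EH = {
      m0 <- spec$EH * spec$AE
      s0 <- spec$VH * spec$AE
      vapply(zp, function(zi) {
        u <- zi
        nd <- normal_nodes(m0, s0, lower = 1 / (1 + u) - 1, n = quad_n)
        if (!length(nd$x)) return(0)
        y <- (1 + nd$x) * (1 + u) - 1
        sum(nd$w * positive_part_characteristic(spec$char, y))
      }, 0) / env$Ek
    },
    ET = fh_et_raw(spec, zp, env, failureless = TRUE)$longitudinal)
  out
}

#' Reliability characteristic of a bundle
#'
#' `rh(z) = fh(z) / kh(z)`, the surviving fraction of the failureless force.
#' For an E-bundle it equals the breaking-strain survival function exactly.
#' At `z = 0` (and anywhere the failureless force vanishes at the start of
#' the process) it is defined as 1 by continuity; if `kh` vanishes at interior
#' points the last finite value is carried forward and the result is flagged
#' with attribute `"extrapolated"`.
#'
#' @inheritParams fh
#' @export
rh <- function(spec, z, slip_completion = c("onset_plus_length", "as_printed"),
               quad_n = 48L) {
  slip_completion <- match.arg(slip_completion)
  f <- fh(spec, z, slip_completion = slip_completion, quad_n = quad_n)
  k <- kh(spec, z, quad_n = quad_n)
  guarded_ratio(f, k, z)
}

# division fh/kh with the z = 0 continuity convention
#' @noRd
guarded_ratio <- function(f, k, z) {
  r <- rep(NA_real_, length(z))
  ok <- k > .Machine$double.eps^0.5
  r[ok] <- pmin(f[ok] / k[ok], 1)
  r[!ok & z <= min(z[ok], Inf)] <- 1   # leading zero-force range: reliability 1
  extrap <- FALSE
  if (anyNA(r)) {
    extrap <- TRUE
    for (i in seq_along(r)) if (is.na(r[i])) r[i] <- if (i > 1) r[i - 1] else 1
  }
  if (extrap) attr(r, "extrapolated") <- TRUE
  r
}
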