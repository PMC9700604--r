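#' Monte-Carlo simulation of a fiber bundle cell
#'
#' Draws `n_fibers` independent fibers according to the bundle's stochastic
#' parameter laws, applies the per-fiber force rule along the strain grid
#' (break at the random breaking strain; EH: fiber strain
#' `(1+eps0)(1+u) - 1`; ES: frozen force during slip, zero after completion;
#' ET: oblique fiber strain with longitudinal projection), and returns the
#' mean normalized force with its per-point standard error.  This realizes
#' the stochastic definitions behind the quadrature formulas and serves as an
#' independent oracle for them: the quadrature curve should lie within a few
#' standard errors of the simulation at every grid point.
#'
#' All random draws are taken up front from one stream, so the result depends
#' only on `(spec, n_fibers, z, seed)`, not on the chunking.
#'
#' @param spec a [bundle_spec()].
#' @param n_fibers number of fibers (>= 1).
#' @param z normalized strain grid.
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @param slip_completion see [fh()]; the oracle matches the selected
#'   semantics.
#' @param chunk_size fibers per block (memory control only).
#' @return list with `curve` (an [fbc_curve()] of mean normalized force) and
#'   `se` (standard errors, same length as the grid).
#' @export
mc_simulate_bundle <- function(spec, n_fibers, z = default_grid(), seed = 1L,
                               slip_completion = c("onset_plus_length",
                                                   "as_printed"),
                               chunk_size = 20000L) {
  stopifnot(inherits(spec, "fbc_bundle"))
  slip_completion <- match.arg(slip_completion)
  if (n_fibers < 1) stop("n_fibers must be >= 1", call. = FALSE)
  n <- as.integer(n_fibers)
  set.seed(seed)
  Ek <- mean_breaking_force(spec)
  u <- pmax(z - spec$u0, 0)
  shifted_off <- (z - spec$u0) < 0 & spec$u0 > 0
  nz <- length(u)

  # one draw per fiber and stochastic parameter, in a fixed order
  epsB <- stats::rnorm(n, spec$AE, spec$VE * spec$AE)
  draws <- switch(spec$kind,
    E  = list(),
    EH = list(eps0 = stats::rnorm(n, spec$EH * spec$AE, spec$VH * spec$AE)),
    ES = {
      dur <- slip_duration_law(spec, slip_completion)
      list(epsS = stats::rnorm(n, spec$ES * spec$AE, spec$VS * spec$AE),
           epsDur = stats::rnorm(n, dur["mean"], dur["sd"]))
    },
    ET = list(T0 = stats::rnorm(n, spec$ET, spec$ST)))

  sum1 <- numeric(nz)
  sum2 <- numeric(nz)
  done <- 0L
  while (done < n) {
    nc <- min(n - done, as.integer(chunk_size))
    idx <- done + seq_len(nc)
    done <- done + nc
    eB <- epsB[idx]
    force <- switch(spec$kind,
      E = {
        ku <- positive_part_characteristic(spec$char, u)
        outer(eB, u, ">") * rep(ku, each = nc)
      },
      EH = {
        y <- outer(1 + draws$eps0[idx], 1 + u) - 1
        f <- matrix(positive_part_characteristic(spec$char, as.vector(y)),
                    nrow = nc)
        f * (y < eB)
      },
      ES = {
        eS <- draws$epsS[idx]
        eD <- draws$epsDur[idx]
        ku <- positive_part_characteristic(spec$char, u)
        kS <- positive_part_characteristic(spec$char, pmax(eS, 0))
        breaks_first <- eB <= eS
        U <- matrix(u, nrow = nc, ncol = nz, byrow = TRUE)
        intact <- U < pmin(eB, eS)
        slipping <- !breaks_first & U >= eS & U < eS + eD
        intact * rep(ku, each = nc) + slipping * kS
      },
      ET = {
        T0 <- draws$T0[idx]
        W <- contraction(u, spec$Ca, spec$Cb)
        denom <- sqrt(outer(T0^2, W^2) + rep((1 + u)^2, each = nc))
        g <- denom / sqrt(1 + T0^2) - 1
        f <- matrix(positive_part_characteristic(spec$char, as.vector(g)),
                    nrow = nc)
        f * (g < eB) * rep(1 + u, each = nc) / denom
      })
    force <- force / Ek
    sum1 <- sum1 + colSums(force)
    sum2 <- sum2 + colSums(force^2)
  }
  mean_f <- sum1 / n
  varf <- pmax(sum2 / n - mean_f^2, 0)
  se <- sqrt(varf / n)
  mean_f[shifted_off] <- 0
  se[shifted_off] <- 0
  list(curve = fbc_curve(z, mean_f, normalized = TRUE), se = se)
}
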