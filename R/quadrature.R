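# Internal quadrature helpers for integrals against Gaussian parameter laws.
#
# All stochastic bundle parameters are Gaussian (or a point mass when sd = 0),
# so every expectation reduces to an integral of a smooth function against a
# normal density over a finite window.  Fixed-order Gauss-Legendre on
# [mean - span*sd, mean + span*sd] (span = 6 by default) integrates these to
# well below 1e-8 absolute for the node counts used here; integrand kinks from
# the positive-part operator are handled by truncating the window at the kink
# (the integrand is identically zero on one side), never by splitting panels.

#' @noRd
normal_nodes <- function(mean, sd, lower = -Inf, upper = Inf,
                         n = 48L, span = 6) {
  if (sd <= 0) {
    if (mean < lower || mean > upper) {
      return(list(x = numeric(0), w = numeric(0)))
    }
    return(list(x = mean, w = 1))
  }
  lo <- max(mean - span * sd, lower)
  hi <- min(mean + span * sd, upper)
  if (lo >= hi) {
    return(list(x = numeric(0), w = numeric(0)))
  }
  gl <- pracma::gaussLegendre(n, lo, hi)
  list(x = gl$x, w = gl$w * stats::dnorm(gl$x, mean, sd))
}

# Survival function 1 - Q_X(q) of a Gaussian / point-mass parameter law.
#' @noRd
normal_survival <- function(q, mean, sd) {
  if (sd <= 0) {
    return(as.numeric(q < mean))
  }
  stats::pnorm(q, mean, sd, lower.tail = FALSE)
}
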