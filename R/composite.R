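#' Weighted parallel connection of fiber bundle cells
#'
#' A composite bundle connects up to four FBCs in parallel; its normalized
#' expected force is the weight-sum of the component forces,
#' \eqn{FH(z) = \sum_k w_k FH_k(z)}, \eqn{\sum w_k = 1}, where the weights
#' are fiber-number fractions.  Weights may be given directly or derived from
#' non-negative integer counts via [weights_from_counts()].  Zero-weight
#' components are retained in the model but skipped during evaluation.
#'
#' @param components list of [bundle_spec()] objects.
#' @param weights numeric weights summing to 1 (tolerance 1e-9).
#' @param counts optional non-negative integers from which weights are
#'   derived; overrides `weights`.
#' @param norm optional normalization record `list(u_N, F_N, n, FB)`.
#' @return object of class `fbc_composite`.
#' @export
composite_model <- function(components, weights = NULL, counts = NULL,
                            norm = NULL) {
  stopifnot(is.list(components),
            all(vapply(components, inherits, TRUE, "fbc_bundle")))
  if (!is.null(counts)) {
    weights <- weights_from_counts(counts)
  }
  if (is.null(weights)) stop("supply weights or counts", call. = FALSE)
  if (length(weights) != length(components)) {
    stop("one weight per component required", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(components = components, weights = weights,
                 counts = counts, norm = norm),
            class = "fbc_composite")
}

#' @export
print.fbc_composite <- function(x, ...) {
  cat(sprintf("<fbc_composite> %d components, weights: %s\n",
              length(x$components),
              paste(sprintf("%s=%.3g", vapply(x$components, `[[`, "", "kind"),
                            x$weights), collapse = ", ")))
  invisible(x)
}

#' Fiber-number weights from component counts
#'
#' `w_k = S_k / (Se + Sh + Ss + St)`; the last weight is computed as the
#' complement so the weights sum to 1 exactly.
#'
#' @param Se count for the E component, or a vector of all counts.
#' @param Sh,Ss,St counts for the EH, ES, ET components.
#' @export
weights_from_counts <- function(Se, Sh = NULL, Ss = NULL, St = NULL) {
  counts <- if (is.null(Sh)) Se else c(Se, Sh, Ss, St)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("at least one count must be positive", call. = FALSE)
  w <- counts / tot
  w[length(w)] <- 1 - sum(w[-length(w)])
  w
}

# weighted sum of a per-component evaluator, skipping zero weights
#' @noRd
composite_sum <- function(model, z, eval_one) {
  out <- numeric(length(z))
  for (k in seq_along(model$components)) {
    if (model$weights[k] == 0) next
    out <- out + model$weights[k] * eval_one(model$components[[k]])
  }
  out
}

#' Expected force, failureless characteristic and reliability of a composite
#'
#' `composite_fh()` evaluates the weight-sum of the component normalized
#' forces; `composite_kh()` the weight-sum of the failureless
#' characteristics; `composite_rh()` their ratio `FH(z)/kH(z)` (guarded as in
#' [rh()]).
#'
#' @param model an [composite_model()].
#' @param z normalized strain grid.
#' @param ... passed to the component evaluators ([fh()] / [kh()]).
#' @return an [fbc_curve()].
#' @export
composite_fh <- function(model, z = default_grid(), ...) {
  stopifnot(inherits(model, "fbc_composite"))
  fbc_curve(z, composite_sum(model, z, function(s) fh(s, z, ...)),
            normalized = TRUE)
}

#' @rdname composite_fh
#' @export
composite_kh <- function(model, z = default_grid(), ...) {
  stopifnot(inherits(model, "fbc_composite"))
  fbc_curve(z, composite_sum(model, z, function(s) kh(s, z, ...)),
            normalized = TRUE)
}

#' @rdname composite_fh
#' @export
composite_rh <- function(model, z = default_grid(), ...) {
  stopifnot(inherits(model, "fbc_composite"))
  f <- composite_fh(model, z, ...)$y
  k <- composite_kh(model, z)$y
  r <- guarded_ratio(f, k, z)
  out <- fbc_curve(z, as.numeric(r), normalized = TRUE)
  attr(out, "extrapolated") <- attr(r, "extrapolated")
  out
}

#' Damage map: cumulative component force curves
#'
#' The gradual addition of the weighted component forces decomposes the
#' resultant curve into ranges showing each component's fraction as a
#' function of strain: the n-th map curve is
#' \eqn{FH(z)_n = \sum_{i \le n} w_i FH_i(z)}; the last curve equals the
#' composite force.  The normalized variant divides by the total so the last
#' curve is identically 1 wherever the total force is positive (masked `NA`
#' elsewhere).  Component order follows the input order and is never sorted.
#'
#' @inheritParams composite_fh
#' @param normalized return the fraction map instead of the force map.
#' @return data.frame with column `z` and one cumulative column per
#'   component (`cum_1` ... `cum_N`).
#' @export
damage_map <- function(model, z = default_grid(), normalized = FALSE, ...) {
  stopifnot(inherits(model, "fbc_composite"))
  curves <- lapply(model$components, function(s) fh(s, z, ...))
  cum <- matrix(0, length(z), length(curves))
  acc <- numeric(length(z))
  for (k in seq_along(curves)) {
    acc <- acc + model$weights[k] * curves[[k]]
    cum[, k] <- acc
  }
  if (normalized) {
    tot <- cum[, ncol(cum)]
    cum <- sweep(cum, 1, ifelse(tot > 0, tot, NA), "/")
  }
  out <- data.frame(z = z, cum)
  names(out) <- c("z", paste0("cum_", seq_along(curves)))
  out
}

#' Reliability map: cumulative component reliability curves
#'
#' \eqn{RH(z)_n = \sum_{i \le n} w_i FH_i(z) / kH(z)} with `kH` the resultant
#' failureless characteristic; the last curve equals [composite_rh()].
#'
#' @inheritParams damage_map
#' @export
reliability_map <- function(model, z = default_grid(), ...) {
  stopifnot(inherits(model, "fbc_composite"))
  ktot <- composite_kh(model, z)$y
  curves <- lapply(model$components, function(s) fh(s, z, ...))
  cum <- matrix(0, length(z), length(curves))
  acc <- numeric(length(z))
  ok <- ktot > .Machine$double.eps^0.5
  for (k in seq_along(curves)) {
    acc <- acc + model$weights[k] * curves[[k]]
    r <- rep(NA_real_, length(z))
    r[ok] <- acc[ok] / ktot[ok]
    # where kH vanishes (start of the process) extend by continuity
    if (anyNA(r) && any(ok)) {
      first <- which(ok)[1]
      if (first > 1) r[seq_len(first - 1)] <- r[first]
      for (i in seq_along(r)) if (is.na(r[i])) r[i] <- r[i - 1]
    }
    cum[, k] <- r
  }
  out <- data.frame(z = z, cum)
  names(out) <- c("z", paste0("cum_", seq_along(curves)))
  out
}
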