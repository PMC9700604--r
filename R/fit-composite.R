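# Composite-bundle least-squares fitting.
#
# The free parameter vector can span the component weights (through a
# simplex-interior logit transform, so the weights always sum to one), the
# twelve bundle statistics (AE, VE, EH, VH, ES, VS, EL, VL, ET, ST per kind),
# the per-component characteristic parameters (a, b, c) and shifts, plus an
# optional global force scale B for curves whose normalizer n*FB is unknown.

#' @noRd
composite_pack <- function(model) {
  n <- length(model$components)
  p <- numeric(0)
  if (n > 1) {
    ref <- model$weights[n]
    if (ref <= 0) ref <- 1e-8
    lg <- log(pmax(model$weights[-n], 1e-8) / ref)
    p <- c(p, stats::setNames(lg, paste0("w", seq_len(n - 1))))
  }
  for (k in seq_len(n)) {
    sp <- model$components[[k]]
    vals <- c(AE = sp$AE, VE = sp$VE, EH = sp$EH, VH = sp$VH,
              ES = if (is.null(sp$ES)) NA else sp$ES, VS = sp$VS,
              EL = if (is.null(sp$EL)) NA else sp$EL, VL = sp$VL,
              ET = sp$ET, ST = sp$ST, a = sp$char$a, b = sp$char$b,
              c = sp$char$c, u0 = sp$u0)
    vals <- vals[!is.na(vals)]
    p <- c(p, stats::setNames(vals, paste0(names(vals), k)))
  }
  p
}

#' @noRd
composite_unpack <- function(p, template) {
  n <- length(template$components)
  w <- if (n > 1) {
    lg <- c(unname(p[paste0("w", seq_len(n - 1))]), 0)
    exp(lg) / sum(exp(lg))
  } else 1
  comps <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- template$components[[k]]
    get <- function(nm, default) {
      key <- paste0(nm, k)
      if (key %in% names(p)) unname(p[[key]]) else default
    }
    comps[[k]] <- bundle_spec(sp$kind,
      fbc_characteristic(get("a", sp$char$a), get("b", sp$char$b),
                         get("c", sp$char$c), units = sp$char$units),
      AE = get("AE", sp$AE), VE = max(get("VE", sp$VE), 0),
      EH = get("EH", sp$EH), VH = max(get("VH", sp$VH), 0),
      ES = if (is.null(sp$ES)) NULL else get("ES", sp$ES),
      VS = max(get("VS", sp$VS), 0),
      EL = if (is.null(sp$EL)) NULL else get("EL", sp$EL),
      VL = max(get("VL", sp$VL), 0),
      ET = get("ET", sp$ET), ST = max(get("ST", sp$ST), 0),
      Ca = sp$Ca, Cb = sp$Cb, u0 = max(get("u0", sp$u0), 0))
  }
  composite_model(comps, weights = w)
}

#' Fit a composite FBC model to a normalized curve
#'
#' Minimizes the least-squares functional
#' \eqn{\Psi(p) = \sum_i (F(z_i)/B - FH(z_i, p))^2} over the selected free
#' parameters by bounded Levenberg-Marquardt with a deterministic,
#' seeded Latin-hypercube multi-start.  The returned objective never exceeds
#' the objective at the initialization.
#'
#' @param curve normalized [fbc_curve()] on the `[0, Z0]` partition.
#' @param init an [composite_model()] providing structure and initial values.
#' @param free character vector naming free parameters: bare names
#'   (`"w"`, `"AE"`, `"VE"`, `"a"`, ...) free that quantity in every
#'   component that has it; suffixed names (`"AE2"`) free it in one.
#'   `"B"` adds a global force-scale factor.
#' @param shared character vector of bare names fitted as one value common
#'   to all components (e.g. `shared = "AE"` when the fibers of every FBC
#'   share their mechanical properties); overrides `free` for those names.
#' @param lower,upper optional named bound overrides.
#' @param n_starts multi-start count (1 = single local fit).
#' @param seed integer seed for the multi-start.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param quad_n quadrature order used during fitting.
#' @param ... further arguments to [fh()] (e.g. `slip_completion`).
#' @return list with `model`, `B`, `rmse` (percent of max measured force),
#'   `r2`, `objective`, `objective_init`, `converged`.
#' @export
fit_composite <- function(curve, init, free = c("w", "AE", "VE"),
                          shared = character(), lower = NULL, upper = NULL,
                          n_starts = 4L, seed = 1L, max_iter = 100L,
                          quad_n = 32L, ...) {
  stopifnot(inherits(curve, "fbc_curve"), inherits(init, "fbc_composite"))
  z <- curve$x; y <- curve$y
  p_all <- composite_pack(init)
  fit_B <- "B" %in% free
  if (fit_B) p_all <- c(p_all, B = 1)
  n <- length(init$components)
  for (nm in shared) {
    keys <- grep(paste0("^", nm, "[0-9]+$"), names(p_all), value = TRUE)
    if (!length(keys)) stop("no component has parameter ", nm, call. = FALSE)
    p_all[paste0(nm, "_s")] <- mean(p_all[keys])
  }
  expand <- function(nm) {
    if (nm == "B") return("B")
    if (nm %in% names(p_all)) return(nm)
    if (nm == "w") return(grep("^w[0-9]+$", names(p_all), value = TRUE))
    grep(paste0("^", nm, "[0-9]+$"), names(p_all), value = TRUE)
  }
  free_names <- unique(unlist(lapply(setdiff(free, shared), expand)))
  free_names <- c(intersect(free_names, names(p_all)),
                  paste0(shared, "_s"))
  if (!length(free_names)) stop("no free parameters selected", call. = FALSE)
  eval_model <- function(pf) {
    p <- p_all; p[free_names] <- pf
    for (nm in shared) {
      keys <- grep(paste0("^", nm, "[0-9]+$"), names(p), value = TRUE)
      p[keys] <- p[[paste0(nm, "_s")]]
    }
    mod <- try(composite_unpack(p, init), silent = TRUE)
    if (inherits(mod, "try-error")) return(NULL)
    B <- if (fit_B) p[["B"]] else 1
    list(fh = composite_fh(mod, z, quad_n = quad_n,
                           warn_monotone = FALSE, ...)$y,
         mod = mod, B = B)
  }
  resid_fn <- function(pf) {
    ev <- eval_model(pf)
    if (is.null(ev) || ev$B <= 0) return(rep(1e6, length(y)))
    y / ev$B - ev$fh
  }
  lo <- rep(-Inf, length(free_names)); hi <- rep(Inf, length(free_names))
  names(lo) <- names(hi) <- free_names
  lo[grepl("^w[0-9]+$", free_names)] <- -12
  hi[grepl("^w[0-9]+$", free_names)] <- 12
  lo[grepl("^AE", free_names)] <- 1e-6
  hi[grepl("^AE", free_names)] <- max(z) * 2
  lo[grepl("^V[EHSL]", free_names)] <- 1e-6
  hi[grepl("^V[EHSL]", free_names)] <- 2
  lo[grepl("^ST", free_names)] <- 0
  lo[grepl("^u0", free_names)] <- 0
  if (fit_B) { lo["B"] <- 1e-6 }
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter,
                                     maxfev = 100 * max_iter)
  set.seed(seed)
  starts <- list(p_all[free_names])
  if (n_starts > 1) {
    lhs_mat <- lhs::randomLHS(n_starts - 1L, length(free_names))
    for (r in seq_len(n_starts - 1L)) {
      base <- p_all[free_names]
      pert <- base * (0.8 + 0.4 * lhs_mat[r, ])
      zero <- abs(base) < 1e-12
      pert[zero] <- (lhs_mat[r, zero] - 0.5) * 0.2
      starts[[r + 1L]] <- pmin(pmax(pert, lo), hi)
    }
  }
  obj0 <- sum(resid_fn(p_all[free_names])^2)
  best <- NULL
  for (st in starts) {
    o <- try(suppressWarnings(
      minpack.lm::nls.lm(st, fn = resid_fn, lower = lo, upper = hi,
                         control = ctrl)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$deviance < best$deviance) best <- o
  }
  if (is.null(best)) stop("composite fit failed from every start", call. = FALSE)
  converged <- best$info %in% 1:4
  if (!converged) {
    # stationarity check by a short restart from the best point
    polish <- try(suppressWarnings(minpack.lm::nls.lm(
      stats::coef(best), fn = resid_fn, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 30, maxfev = 5000))),
      silent = TRUE)
    if (!inherits(polish, "try-error")) {
      converged <- polish$info %in% 1:4 ||
        (best$deviance - polish$deviance) <= 1e-8 * max(best$deviance, 1e-12)
      if (polish$deviance <= best$deviance) best <- polish
    }
  }
  ev <- eval_model(stats::coef(best))
  g <- goodness(ev$fh * ev$B, y)
  list(model = ev$mod, B = ev$B, rmse = g$rmse, r2 = g$r2,
       objective = best$deviance, objective_init = obj0,
       converged = converged)
}
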