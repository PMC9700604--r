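#' Built-in model fixtures reconstructed from printed parameters
#'
#' Every fixture stores verbatim the model parameters of one of the
#' demonstration figures or application tables (captions of the single-bundle
#' and composite illustration figures; the facial-nerve composite table; the
#' facial-nerve and tendon E-bundle series tables; the two E-bundle
#' approximation panels), so that each processing stage can be exercised
#' without any external data.  The measured raw specimen curves are not part
#' of any fixture: reconstructed model curves from the printed parameters
#' stand in for them, and assertions about the real specimens are restricted
#' to what the printed tables support.
#'
#' Available names: `fig9a_e`, `fig9b_eh`, `fig10a_es`, `fig10b_et`,
#' `fig12_composite`, `table4_nerve`, `table5_nerve_series`,
#' `table6_tendon_series`, `fig13a`, `fig13b`.
#'
#' For the facial-nerve composite table the AE/VE cells are printed only for
#' the E row (1.01 / 0.19); the ES and ET rows reuse AE = 1.0, VE = 0.19
#' (flagged here because the printed table is ambiguous about them).
#'
#' @param name fixture identifier (see Details).
#' @param grid evaluation grid `list(Z0, N)`.
#' @param noise_sd relative force noise used by [generate_curve()].
#' @param seed integer seed for noise generation.
#' @return object of class `fbc_fixture`: list with `name`, `model`
#'   (and `reference` for the approximation fixtures), `grid`, `noise_sd`,
#'   `seed`.
#' @export
paper_fixture <- function(name, grid = list(Z0 = 2, N = 201L),
                          noise_sd = 0, seed = 1L) {
  nl_char <- fbc_characteristic(a = -1, b = 1, c = 1)
  eh_ref <- bundle_spec("EH", nl_char, AE = 1.0, VE = 0.2,
                        EH = -0.15, VH = 0.05)
  es_ref <- bundle_spec("ES", nl_char, AE = 1.0, VE = 0.2,
                        ES = 0.8, VS = 0.1, EL = 0.55, VL = 0.1)
  model <- NULL; reference <- NULL
  switch(name,
    fig9a_e = {
      model <- bundle_spec("E", nl_char, AE = 1.0, VE = 0.2)
    },
    fig9b_eh = {
      model <- eh_ref
    },
    fig10a_es = {
      model <- es_ref
    },
    fig10b_et = {
      model <- bundle_spec("ET", nl_char, AE = 1.0, VE = 0.2,
                           ET = 0.4, ST = 0.35, Ca = 0, Cb = 0)
    },
    fig12_composite = {
      model <- composite_model(
        list(bundle_spec("E", nl_char, AE = 1.0, VE = 0.2),
             eh_ref, es_ref,
             bundle_spec("ET", nl_char, AE = 1.0, VE = 0.2,
                         ET = 0.4, ST = 0.35, Ca = 0, Cb = 0)),
        counts = c(10, 30, 50, 10))
    },
    table4_nerve = {
      # facial-nerve composite: E 27.3% (AE=1.01, VE=0.19),
      # ES 33.3% (ES=1.50, VS=0.40, EL=2.00, VL=0.05),
      # ET 39.4% (ET=0.37, ST=0.25); char a=-1, b=1, c=1, ET contraction 5/5
      model <- composite_model(
        list(bundle_spec("E", nl_char, AE = 1.01, VE = 0.19),
             bundle_spec("ES", nl_char, AE = 1.0, VE = 0.19,
                         ES = 1.50, VS = 0.40, EL = 2.00, VL = 0.05),
             bundle_spec("ET", nl_char, AE = 1.0, VE = 0.19,
                         ET = 0.37, ST = 0.25, Ca = 5, Cb = 5)),
        weights = c(0.273, 0.333, 0.394))
    },
    table5_nerve_series = {
      model <- series_model(
        w = c(3.0, 30.0, 41.0, 17.0, 9.0) / 100,
        a = c(-1.78, -3.69, -14.47, -4.00, -4.00),
        b = c(0.325, 0.325, -0.095, 0.325, 0.325),
        c = c(0.58, 1.20, -1.25, 1.30, 1.30),
        m = c(6.0, 9.8, 12.3, 15.5, 19.5),
        s = c(2.0, 1.0, 0.9, 0.4, 1.8),
        units = c("elongation_mm", "force_N"))
    },
    table6_tendon_series = {
      model <- series_model(
        w = c(16.0, 70.0, 7.6, 6.4) / 100,
        a = c(26.5, 26.0, -13.5, -11.4),
        b = c(1.00, 1.00, -0.14, -0.12),
        c = c(28.4, 124.4, 13.5, 11.4),
        m = c(15.0, 22.2, 31.9, 41.5),
        s = c(5.0, 1.8, 1.3, 2.4),
        units = c("strain_pct", "force_N"))
    },
    fig13a = {
      # shifted E-bundle approximation of the EH reference
      model <- bundle_spec("E", fbc_characteristic(-1, 1.5, 1.5),
                           AE = 0.67, VE = 0.2 / 0.67, u0 = 0.2)
      reference <- eh_ref
    },
    fig13b = {
      # two-E-bundle approximation of the ES reference
      model <- composite_model(
        list(bundle_spec("E", fbc_characteristic(-0.8, 2.125, 1.7),
                         AE = 0.83, VE = 0.11 / 0.83),
             bundle_spec("E", fbc_characteristic(-0.55, 2.09, 1.15),
                         AE = 1.3, VE = 0.17 / 1.3)),
        weights = c(0.4, 0.6))
      reference <- es_ref
    },
    stop("unknown fixture name: ", name, call. = FALSE))
  if (name == "table5_nerve_series") grid <- list(Z0 = 25, N = 251L)
  if (name == "table6_tendon_series") grid <- list(Z0 = 50, N = 251L)
  structure(list(name = name, model = model, reference = reference,
                 grid = grid, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fbc_fixture")
}

#' Generate the (optionally noisy) curve of a fixture
#'
#' Evaluates the fixture's model on its grid.  With `with_noise = TRUE`,
#' seeded Gaussian noise with SD `noise_sd * max(force)` is added, so a
#' `noise_sd` of 0.01 corresponds to 1 percent relative noise at the curve
#' scale.  Regeneration with identical fields is bit-identical.
#'
#' @param fixture an [paper_fixture()].
#' @param with_noise add the fixture's noise (default: only if
#'   `noise_sd > 0`).
#' @param path optional CSV output path ([write_curve()]).
#' @return an [fbc_curve()].
#' @export
generate_curve <- function(fixture, with_noise = fixture$noise_sd > 0,
                           path = NULL) {
  stopifnot(inherits(fixture, "fbc_fixture"))
  g <- seq(0, fixture$grid$Z0, length.out = fixture$grid$N)
  m <- fixture$model
  curve <- if (inherits(m, "fbc_composite")) {
    composite_fh(m, g)
  } else if (inherits(m, "fbc_series")) {
    series_force(m, g)
  } else {
    fbc_curve(g, fh(m, g), normalized = TRUE)
  }
  if (with_noise && fixture$noise_sd > 0) {
    set.seed(fixture$seed)
    curve$y <- curve$y +
      stats::rnorm(length(g), 0, fixture$noise_sd * max(curve$y))
  }
  if (!is.null(path)) write_curve(curve, path)
  curve
}
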