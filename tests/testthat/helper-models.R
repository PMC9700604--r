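# shared model objects; every fixture is built in code

nl_char <- fbc_characteristic(a = -1, b = 1, c = 1)

e_bundle  <- bundle_spec("E", nl_char, AE = 1, VE = 0.2)
eh_bundle <- bundle_spec("EH", nl_char, AE = 1, VE = 0.2,
                         EH = -0.15, VH = 0.05)
es_bundle <- bundle_spec("ES", nl_char, AE = 1, VE = 0.2,
                         ES = 0.8, VS = 0.1, EL = 0.55, VL = 0.1)
et_bundle <- bundle_spec("ET", nl_char, AE = 1, VE = 0.2,
                         ET = 0.4, ST = 0.35)

z_grid <- default_grid()

# oracle comparison: quadrature within `factor` standard errors of the
# simulation at every grid point, with a small absolute floor for far-tail
# grid points where the empirical SE underestimates rare-event mass
# (unobserved breaks/slips in the sample).  The full-size oracle uses
# factor = 3; reduced-size smoke runs use a family-wise-corrected multiplier
# (201 simultaneous pointwise comparisons).
expect_oracle_agreement <- function(spec, n_fibers, seed, factor = 3, ...) {
  q <- fh(spec, z_grid, warn_monotone = FALSE, ...)
  m <- mc_simulate_bundle(spec, n_fibers, z_grid, seed = seed, ...)
  floor_abs <- 5e-4 * max(q)
  expect_true(all(abs(m$curve$y - q) <= factor * m$se + floor_abs),
              label = sprintf("quadrature within %g SE of %d-fiber MC (%s)",
                              factor, n_fibers, spec$kind))
}
mc_smoke_factor <- qnorm(1 - pnorm(-3) / 201)  # about 4.05

table5_pairs <- data.frame(m = c(6.0, 9.8, 12.3, 15.5, 19.5),
                           s = c(2.0, 1.0, 0.9, 0.4, 1.8))
table6_pairs <- data.frame(m = c(15.0, 22.2, 31.9, 41.5),
                           s = c(5.0, 1.8, 1.3, 2.4))
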