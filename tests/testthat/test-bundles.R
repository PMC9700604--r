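test_that("E-bundle force is the characteristic times the breaking survival", {
  expect_equal(fh(e_bundle, 0), 0)
  # linear fibers, survival at the mean is one half
  lin <- bundle_spec("E", fbc_characteristic(0, 0, 1), AE = 1, VE = 0.2)
  expect_equal(fh(lin, 1), 0.5)
  # closed form asserted across the whole grid
  expect_equal(fh(lin, z_grid),
               z_grid * pnorm(z_grid, 1, 0.2, lower.tail = FALSE),
               tolerance = 1e-12)
  # nonlinear case against the direct formula
  Ek <- mean_breaking_force(e_bundle)
  expect_equal(fh(e_bundle, 0.7),
               tensile_characteristic(nl_char, 0.7) *
                 pnorm(0.7, 1, 0.2, lower.tail = FALSE) / Ek,
               tolerance = 1e-12)
})

test_that("mean breaking force is exact for linear and point-mass laws", {
  lin <- fbc_characteristic(0, 0, 2)
  expect_equal(mean_breaking_force(lin, AE = 1.5, VE = 0.2), 3.0,
               tolerance = 1e-10)
  expect_equal(mean_breaking_force(lin, AE = 1.5, VE = 0.7), 3.0,
               tolerance = 1e-10)
  expect_equal(mean_breaking_force(nl_char, AE = 1, VE = 0),
               tensile_characteristic(nl_char, 1))
  # closed form for the exponential term of a Gaussian law
  expect_equal(mean_breaking_force(nl_char, AE = 1, VE = 0.2),
               1 - 1 + exp(-1 + 0.02), tolerance = 1e-9)
})

test_that("degenerate EH/ES/ET bundles reduce to the E-bundle", {
  eh0 <- bundle_spec("EH", nl_char, AE = 1, VE = 0.2)           # eps0 == 0
  es0 <- bundle_spec("ES", nl_char, AE = 1, VE = 0.2,
                     ES = 1e6, VS = 0, EL = 1, VL = 0)          # never slips
  et0 <- bundle_spec("ET", nl_char, AE = 1, VE = 0.2)           # T0 == 0
  ref <- fh(e_bundle, z_grid)
  expect_lt(max(abs(fh(eh0, z_grid) - ref)), 1e-6)
  expect_lt(max(abs(fh(es0, z_grid) - ref)), 1e-6)
  expect_lt(max(abs(fh(et0, z_grid) - ref)), 1e-6)
})

test_that("every bundle force starts at zero, stays non-negative, decays, and is bounded by kh", {
  for (spec in list(e_bundle, eh_bundle, es_bundle, et_bundle)) {
    f <- fh(spec, z_grid)
    k <- kh(spec, z_grid)
    expect_lt(f[1], 1e-6)   # at most the pre-strained tail mass of eps0
    expect_true(all(f >= 0))
    expect_lt(f[length(f)], 0.05 * max(f))       # far tail has decayed
    expect_true(all(f <= k + 1e-12))
    expect_true(all(f <= 1))                     # normalized bound
  }
})

test_that("quadrature is converged at the default order", {
  for (spec in list(eh_bundle, es_bundle, et_bundle)) {
    expect_lt(max(abs(fh(spec, z_grid, quad_n = 48) -
                        fh(spec, z_grid, quad_n = 128))), 1e-8)
  }
})

test_that("failureless characteristic has the stated special forms", {
  lin <- bundle_spec("E", fbc_characteristic(0, 0, 1), AE = 1, VE = 0.2)
  expect_equal(kh(lin, z_grid), z_grid, tolerance = 1e-10)
  # ES failureless equals the E form
  expect_equal(kh(es_bundle, z_grid), kh(e_bundle, z_grid))
  # degenerate initial strain reduces the EH form to the E form
  eh0 <- bundle_spec("EH", nl_char, AE = 1, VE = 0.2)
  expect_equal(kh(eh0, z_grid), kh(e_bundle, z_grid), tolerance = 1e-8)
})

test_that("reliability equals the breaking survival for E-bundles and is monotone", {
  r <- rh(e_bundle, z_grid)
  expect_equal(r[1], 1)   # z = 0 continuity convention
  expect_equal(as.numeric(r)[-1],
               pnorm(z_grid, 1, 0.2, lower.tail = FALSE)[-1],
               tolerance = 1e-9)
  expect_true(all(diff(r) <= 1e-12))
  expect_equal(as.numeric(rh(e_bundle, 1)), 0.5)
  # general bundles stay within [0, 1]
  for (spec in list(eh_bundle, es_bundle, et_bundle)) {
    r <- rh(spec, z_grid)
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("far-below-threshold ES-bundle matches the E-bundle, slip semantics differ beyond", {
  # below the slip onset window the slip factors are 1/0
  low <- z_grid[z_grid < 0.8 - 6 * 0.1]
  expect_lt(max(abs(fh(es_bundle, low) - fh(e_bundle, low))), 1e-10)
  # the printed duration law keeps frozen force much longer
  f_len <- fh(es_bundle, z_grid)
  f_prt <- fh(es_bundle, z_grid, slip_completion = "as_printed")
  expect_gt(f_prt[z_grid == 1.8], f_len[z_grid == 1.8])
})

test_that("ET transverse component vanishes for a symmetric obliquity law", {
  sym <- bundle_spec("ET", nl_char, AE = 1, VE = 0.2, ET = 0, ST = 0.3)
  comp <- fh_et_components(sym, z_grid)
  expect_lt(max(abs(comp$transverse)), 1e-10)
  expect_equal(comp$longitudinal, fh(sym, z_grid))
  # asymmetric law transmits transverse force
  comp2 <- fh_et_components(et_bundle, z_grid)
  expect_gt(max(abs(comp2$transverse)), 1e-3)
})

test_that("shifted bundle is the unshifted response displaced in strain", {
  sh <- bundle_spec("E", nl_char, AE = 1, VE = 0.2, u0 = 0.3)
  expect_equal(fh(sh, z_grid[z_grid <= 0.3]),
               rep(0, sum(z_grid <= 0.3)))
  expect_equal(fh(sh, 1.0), fh(e_bundle, 0.7), tolerance = 1e-12)
})

test_that("crimped fibers delay the onset; pre-strained fibers advance it", {
  small <- c(0.05, 0.1, 0.2)
  expect_true(all(fh(eh_bundle, small) <= fh(e_bundle, small)))
  pre <- bundle_spec("EH", nl_char, AE = 1, VE = 0.2, EH = 0.15, VH = 0.05)
  expect_true(all(fh(pre, small) >= fh(e_bundle, small)))
})
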