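test_that("a single sharp component is the characteristic cut at its breaking mean", {
  sm <- series_model(w = 1, a = -1, b = 1, c = 1.2, m = 1, s = 0)
  u <- seq(0, 2, by = 0.01)
  f <- series_force(sm, u)$y
  ch <- fbc_characteristic(-1, 1, 1.2)
  expect_equal(f[u < 1], tensile_characteristic(ch, u[u < 1]))
  expect_equal(f[u > 1], rep(0, sum(u > 1)))
})

test_that("series force is bounded by the expected tensile characteristic", {
  for (name in c("table5_nerve_series", "table6_tendon_series")) {
    fx <- paper_fixture(name)
    u <- seq(0, fx$grid$Z0, length.out = fx$grid$N)
    sf <- series_force(fx$model, u)
    expect_true(all(sf$y <= attr(sf, "kbar") + 1e-12))
    expect_true(all(sf$y >= 0))
  }
})

test_that("the tendon reconstruction peaks near the dominant component", {
  fx <- paper_fixture("table6_tendon_series")
  u <- seq(0, 50, length.out = 1001)
  sf <- series_force(fx$model, u)
  peak_u <- u[which.max(sf$y)]
  # the dominant (70 %) component breaks around 22 % strain and carries the
  # global maximum
  expect_gt(peak_u, 15); expect_lt(peak_u, 25)
  comp <- attr(sf, "components")
  expect_gt(comp[which.max(sf$y), 2] / max(sf$y), 0.5)
})

test_that("component table recomputes K0 and V from the stored parameters", {
  fx <- paper_fixture("table6_tendon_series")
  tab <- series_component_table(fx$model)
  expect_equal(tab$K0, fx$model$c + fx$model$a * fx$model$b)
  expect_equal(tab$V, fx$model$s / fx$model$m * 100)
  expect_equal(tab$K0[1:2], c(54.9, 150.4), tolerance = 1e-3)
  nerve <- series_component_table(paper_fixture("table5_nerve_series")$model)
  expect_equal(nerve$V[1], 33.3, tolerance = 1e-2)
})

test_that("misordered component means are reordered with a warning", {
  expect_warning(
    sm <- series_model(w = c(0.6, 0.4), a = -1, b = 1, c = 1,
                       m = c(1.5, 0.8), s = c(0.1, 0.1)),
    "reordering")
  expect_equal(sm$m, c(0.8, 1.5))
  expect_equal(sm$w, c(0.4, 0.6))
  expect_error(suppressWarnings(
    series_model(w = c(0.5, 0.5), a = -1, b = 1, c = 1,
                 m = c(1, 1), s = c(0.1, 0.1))))
})

test_that("discrete integral form reproduces the sum exactly; gaussian form converges", {
  fx <- paper_fixture("table5_nerve_series")
  u <- seq(0, 25, length.out = 251)
  sm <- fx$model
  k_family <- function(uu, m) {
    i <- which.min(abs(sm$m - m))
    tensile_characteristic(fbc_characteristic(sm$a[i], sm$b[i], sm$c[i]), uu)
  }
  s_fun <- function(m) sm$s[which.min(abs(sm$m - m))]
  disc <- series_integral_form(k_family, s_fun,
                               list(type = "discrete", m = sm$m, w = sm$w), u)
  expect_equal(disc$y, series_force(sm, u)$y, tolerance = 1e-10)
  # continuous law: quadrature refinement converges
  kg <- function(uu, m) tensile_characteristic(nl_char, uu)
  sg <- function(m) 0.1 + 0.02 * (m - 1)^2
  W <- list(type = "gaussian", mean = 1, sd = 0.25)
  g1 <- series_integral_form(kg, sg, W, z_grid, quad_n = 128)
  g2 <- series_integral_form(kg, sg, W, z_grid, quad_n = 256)
  expect_lt(max(abs(g1$y - g2$y)), 1e-6)
  # bounded by the mean characteristic
  expect_true(all(g1$y <= pmax(tensile_characteristic(nl_char, z_grid), 0) +
                    1e-12))
})

test_that("series model equals the weight-mixture fiber simulation", {
  sm <- series_model(w = c(0.3, 0.7), a = -1, b = 1, c = 1.2,
                     m = c(0.8, 1.4), s = c(0.1, 0.15))
  u <- z_grid
  set.seed(55)
  n <- 4e4
  comp_draw <- sample.int(2, n, replace = TRUE, prob = sm$w)
  epsB <- rnorm(n, sm$m[comp_draw], sm$s[comp_draw])
  ch <- fbc_characteristic(-1, 1, 1.2)
  acc <- numeric(length(u)); acc2 <- numeric(length(u))
  for (j in seq_along(u)) {
    f <- positive_part_characteristic(ch, rep(u[j], n)) * (epsB > u[j])
    acc[j] <- mean(f); acc2[j] <- sd(f) / sqrt(n)
  }
  q <- series_force(sm, u)$y
  expect_true(all(abs(acc - q) <= 3 * acc2 + 5e-4 * max(q)))
})

test_that("breaking-strain densities normalize and bracket the component means", {
  fx <- paper_fixture("table6_tendon_series")
  bd <- breaking_strain_densities(fx$model, M = 31)
  expect_equal(integrate(bd$density, 31 - 12 * bd$S, 31 + 12 * bd$S)$value,
               1, tolerance = 1e-8)
  for (i in seq_along(fx$model$m)) {
    mi <- fx$model$m[i]; si <- fx$model$s[i]
    expect_equal(integrate(function(x) bd$density(x, i),
                           mi - 12 * si, mi + 12 * si)$value,
                 1, tolerance = 1e-8)
  }
  # bracketing rule: all component means inside M +/- 3S
  expect_lt(31 - 3 * bd$S, min(fx$model$m) + 1e-9)
  expect_gt(31 + 3 * bd$S, max(fx$model$m))
  # the resultant scale printed alongside the tendon decomposition also
  # satisfies the rule: 31 - 18 < 15 and 41.5 < 49
  expect_true(31 - 3 * 6 < 15 && 41.5 < 31 + 3 * 6)
  # single component: resultant mean collapses onto it
  one <- series_model(w = 1, a = -1, b = 1, c = 1, m = 1.2, s = 0.1)
  expect_equal(breaking_strain_densities(one)$M, 1.2)
})
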