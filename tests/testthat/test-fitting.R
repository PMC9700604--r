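test_that("goodness returns the stated values for identical and offset curves", {
  y <- fh(e_bundle, z_grid)
  g <- goodness(y, y)
  expect_equal(g$rmse, 0)
  expect_equal(g$r2, 1)
  g2 <- goodness(y + 0.05, y)
  expect_equal(g2$rmse, 0.05 / max(y) * 100, tolerance = 1e-10)
  expect_equal(g2$r2, 1)
  expect_warning(gc_ <- goodness(rep(1, 5), rep(2, 5)), "constant")
  expect_true(is.na(gc_$r2))
  expect_error(goodness(1:3, 1:4), "grid")
})

test_that("normalization roundtrip is exact and identity scales do nothing", {
  cv <- fbc_curve(z_grid, fh(eh_bundle, z_grid))
  expect_equal(normalize_curve(cv, 1, 1)$y, cv$y)
  phys <- denormalize_curve(cv, 12.8, 12.69)
  back <- normalize_curve(phys, 12.8, 12.69)
  expect_equal(back$y, cv$y, tolerance = 1e-12)
  expect_equal(back$x, cv$x, tolerance = 1e-12)
  expect_error(normalize_curve(cv, 0, 1), "positive")
})

test_that("normalization estimation recovers the virtual breaking strain", {
  u <- seq(0, 30, length.out = 301)
  gen <- bundle_spec("E", fbc_characteristic(0, 0, 1.3), AE = 12.8, VE = 0.18)
  cv <- fbc_curve(u, fh(gen, u) * 9.7, normalized = FALSE)
  est <- estimate_normalization(cv, "e_bundle_fit")
  expect_equal(est$eps_N, 12.8, tolerance = 0.02 * 12.8)
  expect_true(est$bounds_ok)
  expect_lt(est$u_star, est$u_N)
  expect_lte(est$u_N, est$u1)
  # monotone curve has no peak to anchor the estimate
  mono <- fbc_curve(u, u * 0.3)
  expect_error(estimate_normalization(mono), "peak")
})

test_that("the printed nerve tangent arithmetic gives the printed force scale", {
  tangent <- function(x) 4.65 + 1.3 * (x - 6.61)
  expect_equal(tangent(12.80), 12.697, tolerance = 1e-3)
})

test_that("tangent-method bounds hold on a peaked synthetic curve", {
  u <- seq(0, 30, length.out = 601)
  gen <- bundle_spec("E", fbc_characteristic(-4, 0.3, 1.3), AE = 14,
                     VE = 0.15)
  cv <- fbc_curve(u, fh(gen, u) * 8, normalized = FALSE)
  est <- estimate_normalization(cv, "inflection_tangent")
  expect_true(est$u_star < est$u_N && est$u_N <= est$u1)
})

test_that("Fourier regression is exact on its own basis functions", {
  g <- default_grid()
  const <- fbc_curve(g, rep(0.7, length(g)))
  fd <- fourier_descriptor(const)
  expect_equal(fd$a0, 0.7, tolerance = 1e-12)
  expect_lt(max(abs(c(fd$a, fd$b))), 1e-12)
  cosc <- fbc_curve(g, cos(2 * pi * g / 2))
  fd2 <- fourier_descriptor(cosc)
  expect_equal(fd2$a[1], 1, tolerance = 1e-10)
  expect_lt(max(abs(c(fd2$a0, fd2$a[-1], fd2$b))), 1e-10)
  # 8 harmonics approximate a bundle curve closely; the reconstruction
  # reproduces the reported residual
  y <- fh(e_bundle, g)
  fd3 <- fourier_descriptor(fbc_curve(g, y))
  expect_lt(fd3$residual_rms, 0.02)
  expect_equal(sqrt(mean((fourier_reconstruct(fd3, g) - y)^2)),
               fd3$residual_rms, tolerance = 1e-12)
  expect_error(fourier_descriptor(fbc_curve(g[1:10], y[1:10])), "fewer")
})

test_that("descriptors separate bundle types beyond the noise level", {
  g <- default_grid()
  base <- fh(e_bundle, g)
  set.seed(31)
  noisy <- base + rnorm(length(g), 0, 0.01 * max(base))
  other <- fh(es_bundle, g)
  d <- function(a, b) sqrt(sum((fourier_vector_test(a) -
                                  fourier_vector_test(b))^2))
  fourier_vector_test <- function(y) {
    fd <- fourier_descriptor(fbc_curve(g, pmax(y, 0)))
    c(fd$a0, fd$a, fd$b)
  }
  expect_lt(d(base, noisy), d(base, other))
})

test_that("database lookup returns the nearest record and learning is gated", {
  g <- default_grid()
  fd_e <- fourier_descriptor(fbc_curve(g, fh(e_bundle, g)))
  fd_es <- fourier_descriptor(fbc_curve(g, fh(es_bundle, g)))
  db <- model_db()
  expect_null(nn_initialize(db, fd_e))
  db <- db_learn(db, fd_e, list(kind = "E"), rmse = 1)
  db <- db_learn(db, fd_es, list(kind = "ES"), rmse = 2)
  expect_length(db$records, 2)
  expect_equal(nn_initialize(db, fd_e)$kind, "E")
  expect_equal(nn_initialize(db, fd_es)$kind, "ES")
  # single-record database answers every query with that record
  db1 <- db_learn(model_db(), fd_e, list(kind = "only"), rmse = 1)
  expect_equal(nn_initialize(db1, fd_es)$kind, "only")
  # acceptance gating
  expect_length(db_learn(db, fd_e, list(), rmse = 9,
                         accept_threshold = 5)$records, 2)
  expect_length(db_learn(db, fd_e, list(), rmse = 1,
                         accept_threshold = 0)$records, 2)
  # persistence roundtrip
  path <- withr::local_tempfile(fileext = ".jsonl")
  dbp <- model_db(path)
  dbp <- db_learn(dbp, fd_e, list(kind = "E"), rmse = 1)
  expect_equal(nn_initialize(model_db(path), fd_e)$kind, "E")
})

test_that("series fit is a fixed point at the truth and recovers from noise", {
  u <- seq(0, 2, length.out = 201)
  truth <- series_model(w = c(0.2, 0.5, 0.3), a = -1, b = 1, c = 1.2,
                        m = c(0.6, 1.0, 1.5), s = c(0.08, 0.12, 0.10))
  cv <- series_force(truth, u)
  r0 <- fit_series(cv, 3, init = truth, share_char = TRUE, n_starts = 1)
  expect_lt(r0$objective, 1e-10)
  expect_equal(r0$model$w, truth$w, tolerance = 1e-5)
  # refit from the recovered optimum leaves the objective unchanged
  r00 <- fit_series(cv, 3, init = r0$model, share_char = TRUE, n_starts = 1)
  expect_lt(abs(r00$objective - r0$objective), 1e-10)
  # 1 % noise, perturbed initialization
  set.seed(7)
  noisy <- cv
  noisy$y <- pmax(cv$y + rnorm(length(u), 0, 0.01 * max(cv$y)), 0)
  init <- series_model(w = c(0.3, 0.4, 0.3), a = -0.8, b = 0.9, c = 1.35,
                       m = c(0.5, 1.1, 1.4), s = c(0.1, 0.1, 0.12))
  r1 <- fit_series(noisy, 3, init = init, share_char = TRUE,
                   n_starts = 4, seed = 3)
  expect_lt(r1$rmse, 2)
  expect_lt(max(abs(r1$model$w - truth$w)), 0.05)
  expect_lt(max(abs(r1$model$m / truth$m - 1)), 0.05)
})

test_that("composite fit never worsens the objective and recovers weights", {
  fx <- paper_fixture("fig12_composite")
  cv <- generate_curve(fx)
  # fixed point from the true initialization
  r0 <- fit_composite(cv, fx$model, free = "w", shared = "AE",
                      n_starts = 1, seed = 1)
  expect_lt(r0$objective, 1e-10)
  expect_lte(r0$objective, r0$objective_init + 1e-12)
  # perturbed start on a noisy curve
  set.seed(11)
  noisy <- cv
  noisy$y <- pmax(cv$y + rnorm(length(cv$y), 0, 0.01 * max(cv$y)), 0)
  pert <- fx$model
  pert$weights <- weights_from_counts(c(15, 25, 45, 15))
  for (k in seq_along(pert$components)) {
    pert$components[[k]]$AE <- 1 + c(0.1, -0.1, 0.08, -0.08)[k]
  }
  r1 <- fit_composite(noisy, pert, free = "w", shared = "AE",
                      n_starts = 1, seed = 5, max_iter = 150)
  expect_lte(r1$objective, r1$objective_init + 1e-12)
  expect_lt(max(abs(r1$model$weights - fx$model$weights)), 0.05)
  expect_lt(abs(r1$model$components[[1]]$AE - 1), 0.05)
})
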