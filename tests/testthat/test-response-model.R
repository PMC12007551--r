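## helper: wrap a raw threshold array as a grid object
make_grid <- function(th, theta = c(0, 90, 180), phi = 0, delta = 0) {
  structure(list(thresholds = th, theta_axis = theta, phi_axis = phi,
                 delta_axis = delta, cell_ids = paste0("c", seq_len(dim(th)[1])),
                 waveform_kind = "monophasic", precision = 0.05),
            class = "tms_threshold_grid")
}

test_that("default sweep axes match the published grid resolution", {
  f <- formals(build_threshold_grid)
  expect_length(eval(f$theta_axis), 61L)   # 0:3:180
  expect_length(eval(f$phi_axis), 60L)     # 0:6:354, 360 excluded
  expect_length(eval(f$delta_axis), 21L)   # -100:10:100
})

test_that("a one-configuration grid reproduces find_threshold exactly", {
  cm <- discretize(small_active_cell())
  w <- make_waveform("monophasic")
  g <- build_threshold_grid(list(cm), theta_axis = 30, phi_axis = 12,
                            delta_axis = -20, waveform = w)
  direct <- find_threshold(cm, membrane_model(), field_params(30, 12, -20),
                           w, sim_config())
  expect_equal(as.numeric(g$thresholds[1, 1, 1, 1]), direct$threshold)
})

test_that("an axisymmetric cell yields azimuth-independent thresholds", {
  cm <- discretize(generate_ball_and_stick(300, 2, soma_diameter = 12))
  w <- make_waveform("monophasic")
  g <- build_threshold_grid(list(cm), theta_axis = 45,
                            phi_axis = seq(0, 300, by = 60),
                            delta_axis = 0, waveform = w)
  th <- g$thresholds[1, 1, , 1]
  expect_lt(max(th) - min(th), 0.05 + 1e-9)   # within search precision
  ## averaged map of the symmetric cell equals any single-phi slice
  m <- average_map(g)
  expect_equal(m$mean[1, 1], th[1], tolerance = 0.05 / th[1])
})

test_that("averaging reduces cells and azimuths with CI and exclusion bookkeeping", {
  ## single cell, single azimuth: mean equals the grid values
  th1 <- array(c(110, 120, 130), dim = c(1, 3, 1, 1))
  m1 <- average_map(make_grid(th1))
  expect_equal(as.numeric(m1$mean), c(110, 120, 130))

  ## two cells at 100 and 200 V/m everywhere: mean 150, CI = 1.96 SE
  th2 <- array(rep(c(100, 200), 3), dim = c(2, 3, 1, 1))
  m2 <- average_map(make_grid(th2))
  expect_equal(as.numeric(m2$mean), rep(150, 3))
  expect_equal(as.numeric(m2$ci95_halfwidth),
               rep(1.96 * sd(c(100, 200)) / sqrt(2), 3))
  expect_equal(as.numeric(m2$n_samples), rep(2L, 3))

  ## not-excitable sentinels are excluded and counted
  th3 <- th2; th3[2, 1, 1, 1] <- NA
  m3 <- average_map(make_grid(th3))
  expect_equal(m3$mean[1, 1], 100)
  expect_equal(m3$n_excluded[1, 1], 1L)
  ## an all-sentinel bin stays a sentinel
  th4 <- th2; th4[, 2, 1, 1] <- NA
  m4 <- average_map(make_grid(th4))
  expect_true(is.na(m4$mean[2, 1]))
  expect_equal(m4$n_samples[2, 1], 0L)
})

test_that("the confidence halfwidth shrinks like 1/sqrt(n) on i.i.d. thresholds", {
  set.seed(5)
  mk <- function(n) array(rnorm(n, 150, 30), dim = c(n, 1, 1, 1))
  ci5 <- replicate(200, average_map(make_grid(mk(5), theta = 0))$ci95_halfwidth[1, 1])
  ci45 <- replicate(200, average_map(make_grid(mk(45), theta = 0))$ci95_halfwidth[1, 1])
  expect_equal(mean(ci5) / mean(ci45), 3, tolerance = 0.2)
})

test_that("map interpolation is exact at nodes and linear between them", {
  m <- structure(list(theta_axis = c(0, 90, 180), delta_axis = c(-20, 0, 20),
                      mean = outer(c(100, 150, 200), c(1, 1.2, 1.4)),
                      ci95_halfwidth = matrix(0, 3, 3),
                      n_samples = matrix(1, 3, 3),
                      n_excluded = matrix(0, 3, 3),
                      waveform_kind = "monophasic", ci_rule = "test"),
                 class = "tms_average_threshold_map")
  expect_equal(interpolate_threshold(m, 90, 0), 150 * 1.2)
  expect_equal(interpolate_threshold(m, 45, 0), mean(c(100, 150)) * 1.2)
  expect_equal(interpolate_threshold(m, 90, 10), 150 * mean(c(1.2, 1.4)))
  expect_equal(interpolate_threshold(m, c(0, 180), c(-20, 20)),
               c(100, 200 * 1.4))
  expect_tms_error(interpolate_threshold(m, 200, 0), "tms_range_error")
  expect_tms_error(interpolate_threshold(m, 90, 30), "tms_range_error")
})

test_that("the empirical recruitment rate is the pooled threshold CDF", {
  th <- array(150, dim = c(4, 1, 3, 1))
  g <- make_grid(th, theta = 90, phi = c(0, 120, 240), delta = 0)
  f <- empirical_recruitment(g, 90, 0)
  expect_equal(f(149.99), 0)
  expect_equal(f(150), 1)

  th2 <- array(c(100, 200), dim = c(2, 1, 1, 1))
  g2 <- make_grid(th2, theta = 0, phi = 0)
  f2 <- empirical_recruitment(g2, 0, 0)
  expect_equal(f2(150), 0.5)
  expect_equal(f2(99), 0)
  expect_equal(f2(1000), 1)

  gNA <- make_grid(array(NA_real_, dim = c(1, 1, 1, 1)), theta = 0, phi = 0)
  expect_tms_error(empirical_recruitment(gNA, 0, 0), "tms_empty_bin")
  expect_tms_error(empirical_recruitment(g2, 7, 0), "tms_range_error")
})

test_that("sigmoid fitting recovers known parameters", {
  E <- seq(50, 250, length.out = 60)
  f <- 1 / (1 + exp(-0.05 * (E - 150)))
  fit <- fit_sigmoid(E, f)
  expect_true(fit$converged)
  expect_equal(fit$r, 0.05, tolerance = 1e-4)     # 4 significant digits
  expect_equal(fit$E0, 150, tolerance = 1e-4 * 150)
  ## f(E0) = 0.5 identically
  expect_equal(predict(fit, fit$E0), 0.5)
  expect_tms_error(fit_sigmoid(c(100, 200), c(0, 1)), "tms_config_error")

  ## noisy recovery at the documented accuracy
  set.seed(12)
  E2 <- seq(80, 220, length.out = 50)
  f2 <- 1 / (1 + exp(-0.05 * (E2 - 150))) + rnorm(50, 0, 0.01)
  fit2 <- fit_sigmoid(E2, f2)
  expect_lt(abs(fit2$r - 0.05) / 0.05, 0.10)
  expect_lt(abs(fit2$E0 - 150) / 150, 0.02)
})

test_that("the recruitment surface matches per-bin fits and handles degenerate bins", {
  set.seed(9)
  th <- array(rlnorm(10 * 2 * 12 * 2, log(150), 0.2), dim = c(10, 2, 12, 2))
  g <- make_grid(th, theta = c(0, 90), phi = seq(0, 330, 30), delta = c(-10, 10))
  s <- recruitment_surface(g)
  expect_true(all(s$converged))
  pooled <- sort(th[, 2, , 1])
  direct <- fit_sigmoid(pooled, seq_along(pooled) / length(pooled))
  expect_equal(s$r[2, 1], direct$r)
  expect_equal(s$E0[2, 1], direct$E0)
  expect_true(all(s$rms_residual < 0.05, na.rm = TRUE))

  ## constant thresholds: step-like sigmoid, E0 at the step, steep slope
  thc <- array(120, dim = c(5, 1, 6, 1))
  sc <- recruitment_surface(make_grid(thc, theta = 0, phi = seq(0, 300, 60)))
  expect_true(all(sc$converged))
  expect_equal(sc$E0[1, 1], 120)
  expect_gt(sc$r[1, 1], 10)   # rises over ~the search precision
})

test_that("directional sensitivity flattens with increasing intensity", {
  set.seed(21)
  theta <- seq(0, 180, by = 30)
  ## synthetic surface: tangential fields need ~40% higher intensity
  E0 <- 100 * (1 + 0.4 * sin(theta * pi / 180)^2)
  r <- rep(0.08, length(theta))
  s <- structure(list(theta_axis = theta, delta_axis = 0,
                      r = matrix(r), E0 = matrix(E0),
                      rms_residual = matrix(0, length(theta), 1),
                      converged = matrix(TRUE, length(theta), 1),
                      waveform_kind = "monophasic"),
                 class = "tms_recruitment_surface")
  cur <- polar_sensitivity_curve(s, c(1, 1.1, 1.2, 1.4, 1.6), delta = 0,
                                 theta_ref = 0)
  raw <- attr(cur, "raw")
  ## intensity ratio 1 at the reference angle gives exactly 0.5 pre-normalization
  expect_equal(raw[1, 1], 0.5)
  ## higher intensities recruit at least as much everywhere
  for (j in 2:ncol(raw)) expect_true(all(raw[, j] >= raw[, j - 1]))
  ## modulation depth (max - min)/max decreases with intensity
  depth <- apply(raw, 2, function(x) (max(x) - min(x)) / max(x))
  expect_true(all(diff(depth) < 0))
  expect_tms_error(polar_sensitivity_curve(s, c(-1)), "tms_config_error")
})
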