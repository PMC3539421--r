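w4 <- waveform(amplitude = 1, period = 4)

# helper: sampled trace of a function over n cycles at step dt
sampled <- function(f, n_cycles = 3, dt = 0.02) {
  t <- seq(0, n_cycles * 4, by = dt)
  data.frame(t = t, value = f(t))
}

test_that("hysteresis lag recovers constructed shifts over a grid", {
  for (delta in seq(-0.9, 0.9, by = 0.3)) {
    tr <- sampled(function(t) waveform_value(w4, t - delta))
    for (cyc in 2:3) {
      lag <- hysteresis_lag(tr, w4, cyc)
      expect_equal(lag, delta, tolerance = 5e-3)
    }
  }
  # the waveform itself has zero lag; a flat trace has none
  expect_equal(hysteresis_lag(sampled(function(t) waveform_value(w4, t)),
                              w4, 2), 0, tolerance = 1e-9)
  expect_true(is.na(hysteresis_lag(sampled(function(t) 0 * t), w4, 2)))
  # coarse sampling is rejected
  tr_coarse <- sampled(function(t) waveform_value(w4, t), dt = 0.5)
  expect_error(hysteresis_lag(tr_coarse, w4, 2), "sampling")
})

test_that("cross-correlation lag agrees with peak lag on smooth shifts", {
  tr <- sampled(function(t) waveform_value(w4, t - 0.4))
  expect_equal(xcorr_lag(tr, w4, 2), 0.4, tolerance = 0.02)
})

test_that("cycle stability finds the first settled cycle", {
  # exactly periodic from the start
  tr <- sampled(function(t) waveform_value(w4, t), n_cycles = 4)
  expect_identical(cycle_stability(tr, w4), 1L)
  # constructed transient dying below tolerance in cycle 3:
  # per-cycle peaks 1.5, 1.2, 1.02, 1.0, 1.0, ...
  fac <- c(1.5, 1.2, 1.02, 1.0, 1.0)
  tr2 <- sampled(function(t) {
    cyc <- pmin(floor(t / 4) + 1, 5)
    fac[cyc] * waveform_value(w4, t)
  }, n_cycles = 5)
  expect_identical(cycle_stability(tr2, w4), 3L)
  expect_error(cycle_stability(sampled(function(t) t, n_cycles = 2), w4),
               "3 full cycles")
})

test_that("trajectory loop gap measures loop translation exactly", {
  t <- seq(0, 8, by = 0.02)
  circle <- data.frame(t = t,
                       x = sin(pi * t / 2) * 1e-3,
                       y = (1 - cos(pi * t / 2)) * 1e-3,
                       z = 0 * t)
  expect_equal(unname(trajectory_loop_gap(circle, w4)), 0, tolerance = 1e-12)
  d <- c(2e-3, -1e-3, 5e-4)
  shifted <- circle
  sel <- circle$t > 4 + 1e-9
  shifted$x[sel] <- shifted$x[sel] + d[1]
  shifted$y[sel] <- shifted$y[sel] + d[2]
  shifted$z[sel] <- shifted$z[sel] + d[3]
  expect_equal(unname(trajectory_loop_gap(shifted, w4)),
               sqrt(sum(d^2)), tolerance = 1e-6)
})

test_that("super-cycle periodicity is detected and absent when constant", {
  # per-cycle peaks following a 4-cycle pattern over 12 cycles -> 16 s
  tr <- sampled(function(t) {
    cyc <- floor(t / 4)
    (1 + 0.3 * cos(2 * pi * cyc / 4)) * waveform_value(w4, t)
  }, n_cycles = 12)
  expect_equal(long_periodicity(tr, w4), 16)
  # constant per-cycle peaks: no super-period
  flat <- sampled(function(t) waveform_value(w4, t), n_cycles = 8)
  expect_true(is.na(long_periodicity(flat, w4)))
  expect_error(long_periodicity(sampled(function(t) t, n_cycles = 4), w4),
               "8 full cycles")
})

test_that("target deformation error has the metric properties", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  cc <- matrix(rnorm(30), 10, 3)
  expect_equal(compute_tde(a, a), data.frame(mean_tde = 0, max_tde = 0))
  # uniform offset of 2 mm in x
  off <- sweep(a, 2, c(2, 0, 0), `+`)
  expect_equal(compute_tde(a, off), data.frame(mean_tde = 2, max_tde = 2),
               tolerance = 1e-12)
  # symmetry
  expect_equal(compute_tde(a, b), compute_tde(b, a))
  # triangle inequality landmark-wise implies it for mean and max
  dab <- compute_tde(a, b)
  dbc <- compute_tde(b, cc)
  dac <- compute_tde(a, cc)
  expect_lte(dac$mean_tde, dab$mean_tde + dbc$mean_tde + 1e-12)
  expect_lte(dac$max_tde, dab$max_tde + dbc$max_tde + 1e-12)
  expect_error(compute_tde(a, b[1:5, ]), "identical shape")
})

test_that("landmark traces are exact copies of the solver output", {
  mesh <- coarse_mesh_fixture()
  mat <- material_field(mesh, ym = 178)
  res <- run_simulation(mesh, mat, waveform(),
                        solver_config(dt = 0.05, n_cycles = 1))
  lm <- default_landmarks(mesh)
  tr <- landmark_series(res, lm)
  node <- lm$node_index[2]
  expect_identical(tr$B$x, res$displacement[, node, 1])
  expect_identical(tr$B$z, res$displacement[, node, 3])
  # a landmark on the fixed patch yields a zero trace and a warning
  lm_fixed <- data.frame(id = "F", node_index = mesh$boundary$fixed[1])
  expect_warning(trf <- landmark_series(res, lm_fixed), "fixed patch")
  expect_identical(max(abs(as.matrix(trf$F[, c("x", "y", "z")]))), 0)
  # unknown node index errors
  expect_error(landmark_series(res, data.frame(id = "X", node_index = 1e6)),
               "unknown")
})
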