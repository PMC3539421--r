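# time integration and coupling: nullity, linearity, scheme agreement, and
# the 1-D consolidation benchmark with its independent series oracle

test_that("zero drive and zero body force give exactly zero states", {
  mesh <- coarse_mesh_fixture()
  mat <- material_field(mesh, ym = 178)
  cfg <- solver_config(dt = 0.2, n_cycles = 1)
  res <- run_simulation(mesh, mat, waveform(amplitude = 0), cfg)
  expect_identical(max(abs(res$pressure)), 0)
  expect_identical(max(abs(res$displacement)), 0)
})

test_that("the isotropic response is linear in the drive amplitude", {
  mesh <- coarse_mesh_fixture()
  mat <- material_field(mesh, ym = 178)
  cfg <- solver_config(dt = 0.05, n_cycles = 1)
  r1 <- run_simulation(mesh, mat, waveform(amplitude = 150), cfg)
  r2 <- run_simulation(mesh, mat, waveform(amplitude = 300), cfg)
  scale <- max(abs(r2$displacement))
  expect_gt(scale, 0)
  expect_lt(max(abs(2 * r1$displacement - r2$displacement)) / scale, 1e-8)
})

test_that("staggered and monolithic coupling agree on the same problem", {
  mesh <- coarse_mesh_fixture()
  mat <- material_field(mesh, ym = 178)
  w <- waveform()
  cfg_m <- solver_config(dt = 0.05, n_cycles = 1)
  cfg_s <- solver_config(dt = 0.05, n_cycles = 1, coupling = "staggered",
                         coupling_tol = 1e-8, max_coupling_iters = 200)
  rm_ <- run_simulation(mesh, mat, w, cfg_m)
  rs_ <- run_simulation(mesh, mat, w, cfg_s)
  scale <- max(abs(rm_$displacement))
  expect_lt(max(abs(rm_$displacement - rs_$displacement)) / scale, 1e-5)
  expect_gt(max(rs_$coupling_iterations), 1L)
})

test_that("loosening the staggered coupling tolerance stays self-consistent", {
  mesh <- box_mesh(nx = 6)
  mat <- material_field(mesh, ym = 178)
  w <- waveform()
  run_tol <- function(tol) {
    cfg <- solver_config(dt = 0.1, n_cycles = 1, coupling = "staggered",
                         coupling_tol = tol, max_coupling_iters = 300,
                         fixed_dofs = lateral_roller_dofs(mesh))
    run_simulation(mesh, mat, w, cfg)
  }
  loose <- run_tol(1e-4)
  tight <- run_tol(1e-6)
  scale <- max(abs(tight$displacement))
  expect_lt(max(abs(loose$displacement - tight$displacement)) / scale, 10 * 1e-4)
})

test_that("pore-pressure transient matches the 1D consolidation series", {
  # laterally confined column, drained (driven) at x = 0, no-flux and fixed
  # at x = L, constant boundary pressure: the independent Terzaghi-type
  # series oracle gives p(x, t)
  L <- 0.02
  P <- 100
  mesh <- box_mesh(nx = 16, lx = L)
  mat <- material_field(mesh, ym = 178, branch_radii = 1e-4)
  g <- 178 / 2.8
  lam <- 2 * g * 0.4 / 0.2
  s_eff <- mat$porosity[1] * mat$air_compressibility + 1 / (lam + 2 * g)
  c_v <- (mat$permeability[1] / mat$air_viscosity) / s_eff
  cfg <- solver_config(dt = 0.005, n_cycles = 1, fixed_patch = "fixed",
                       fixed_dofs = lateral_roller_dofs(mesh))
  res <- run_simulation(mesh, mat, function(t) P, cfg)

  for (t_chk in c(0.2, 0.5, 1.0)) {
    i <- which.min(abs(res$times - t_chk))
    p_num <- res$pressure[i, ]
    p_ref <- terzaghi_pressure(mesh$nodes[, 1], res$times[i], P, c_v, L)
    err <- sqrt(mean((p_num - p_ref)^2)) / P
    expect_lt(err, 0.02)   # within discretization error
  }

  # full consolidation: uniform pressure and the closed-form tip displacement
  iend <- length(res$times)
  expect_equal(unname(res$pressure[iend, ]), rep(P, nrow(mesh$nodes)),
               tolerance = 1e-3)
  ux_tip <- mean(res$displacement[iend, mesh$boundary$inlet, 1])
  expect_equal(ux_tip, -P * L / (lam + 2 * g), tolerance = 1e-3)
})

test_that("the consolidation error shrinks under space-time refinement", {
  L <- 0.02
  P <- 100
  run_err <- function(nx, dt) {
    mesh <- box_mesh(nx = nx, lx = L)
    mat <- material_field(mesh, ym = 178, branch_radii = 1e-4)
    g <- 178 / 2.8
    lam <- 2 * g * 0.4 / 0.2
    s_eff <- mat$porosity[1] * mat$air_compressibility + 1 / (lam + 2 * g)
    c_v <- (mat$permeability[1] / mat$air_viscosity) / s_eff
    cfg <- solver_config(dt = dt, n_cycles = 1, fixed_patch = "fixed",
                         fixed_dofs = lateral_roller_dofs(mesh))
    res <- run_simulation(mesh, mat, function(t) P, cfg)
    i <- which.min(abs(res$times - 0.2))
    p_ref <- terzaghi_pressure(mesh$nodes[, 1], res$times[i], P, c_v, L)
    sqrt(mean((res$pressure[i, ] - p_ref)^2)) / P
  }
  e_coarse <- run_err(8, 0.02)
  e_fine <- run_err(16, 0.005)
  expect_lt(e_fine, e_coarse / 2)
})

test_that("waveform under-resolution and missing anchoring are rejected", {
  mesh <- coarse_mesh_fixture()
  mat <- material_field(mesh, ym = 178)
  expect_error(run_simulation(mesh, mat, waveform(),
                              solver_config(dt = 0.5)), "under-resolves")
  bad <- mesh
  bad$boundary$fixed <- integer()
  expect_error(run_simulation(bad, mat, waveform(),
                              solver_config(dt = 0.02,
                                            fixed_patch = "fixed")),
               "fixed patch")
})

test_that("single steps through step_coupled match run_simulation", {
  mesh <- box_mesh(nx = 4)
  mat <- material_field(mesh, ym = 178)
  w <- waveform()
  cfg <- solver_config(dt = 0.1, n_cycles = 1)
  res <- run_simulation(mesh, mat, w, cfg)
  n <- nrow(mesh$nodes)
  state <- list(t = 0, p = numeric(n), u = matrix(0, n, 3))
  for (s in 1:3) state <- step_coupled(state, mesh, mat, w, cfg)
  expect_equal(state$p, unname(res$pressure[4L, ]), tolerance = 1e-12)
  expect_equal(state$u, unname(res$displacement[4L, , ]), tolerance = 1e-12)
})
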