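# discrete operator checks on small meshes with closed-form oracles

test_that("a uniform pressure lies in the kernel of the Darcy operator", {
  mesh <- box_mesh()
  mat <- material_field(mesh, ym = 178)
  fs <- assemble_flow_system(mesh, mat)
  p <- rep(7.3, nrow(mesh$nodes))
  expect_lt(max(abs(fs$K %*% p)), 1e-18)
})

test_that("steady Darcy flow through a bar gives a linear pressure profile", {
  mesh <- box_mesh(nx = 10)
  mat <- material_field(mesh, ym = 178)
  fs <- assemble_flow_system(mesh, mat)
  # Dirichlet p = 100 at x = 0 and p = 0 at x = lx, no storage: the steady
  # solution is linear in x (constant discrete Darcy flux)
  n <- nrow(mesh$nodes)
  d0 <- mesh$boundary$inlet
  d1 <- mesh$boundary$fixed
  fd <- porolung:::factor_dirichlet(fs$K, c(d0, d1))
  p <- porolung:::solve_dirichlet(fd, numeric(n),
                                  fixed_vals = c(rep(100, length(d0)),
                                                 rep(0, length(d1))),
                                  tol = 1e-8)
  p_exact <- 100 * (1 - mesh$nodes[, 1] / 0.02)
  expect_equal(p, p_exact, tolerance = 1e-8)
})

test_that("the elasticity operator passes the linear patch test", {
  mesh <- box_mesh(nx = 4, ny = 3, nz = 3)
  mat <- material_field(mesh, ym = 178)
  err <- porolung:::patch_test_error(mesh, mat)
  expect_lt(err, 1e-10)   # machine precision relative to the field scale
})

test_that("a uniform pore pressure exerts zero net force on a closed body", {
  mesh <- coarse_mesh_fixture()
  mat <- material_field(mesh, ym = 178)
  es <- assemble_elastic_system(mesh, mat,
                                pressure = rep(42, nrow(mesh$nodes)))
  fnet <- vapply(1:3, function(i)
    sum(es$rhs[seq(i, length(es$rhs), by = 3L)]), numeric(1))
  expect_lt(max(abs(fnet)), 1e-12)
  # zero pressure and zero body force give a zero load vector
  es0 <- assemble_elastic_system(mesh, mat)
  expect_identical(max(abs(es0$rhs)), 0)
})

test_that("uniform pressure on a confined bar matches the 1D closed form", {
  # laterally confined column, fixed at x = L, total-traction-free at x = 0:
  # uniform p gives strain p/(lambda + 2G) and tip displacement
  # u(0) = -p L / (lambda + 2G)
  mesh <- box_mesh(nx = 12)
  mat <- material_field(mesh, ym = 178)
  n <- nrow(mesh$nodes)
  P <- 50
  es <- assemble_elastic_system(mesh, mat, pressure = rep(P, n))
  rollers <- lateral_roller_dofs(mesh)
  fixed_x <- (mesh$boundary$fixed - 1L) * 3L + 1L
  fd <- porolung:::factor_dirichlet(es$K, sort(unique(c(rollers, fixed_x))))
  u <- porolung:::solve_dirichlet(fd, es$rhs, fixed_vals = 0, tol = 1e-8)
  ux <- u[seq(1, 3 * n, by = 3)]
  g <- 178 / 2.8
  lam <- 2 * g * 0.4 / 0.2
  u_exact <- -P * (0.02 - mesh$nodes[, 1]) / (lam + 2 * g)
  expect_equal(ux, u_exact, tolerance = 1e-8)
})

test_that("orthotropic plane moduli enter the expected stiffness blocks", {
  # pure xy shear of a confined block must feel only G_xy: doubling G_xy
  # doubles the reaction, while G_yz and G_xz leave it unchanged
  mesh <- box_mesh(nx = 3, ny = 3, nz = 3, lx = 0.01, ly = 0.01, lz = 0.01)
  n <- nrow(mesh$nodes)
  shear_energy <- function(contrast) {
    mat <- material_field(mesh, ym = cbind(rep(100 * contrast[1], nrow(mesh$elements)),
                                           rep(100 * contrast[2], nrow(mesh$elements)),
                                           rep(100 * contrast[3], nrow(mesh$elements))))
    es <- assemble_elastic_system(mesh, mat)
    # impose u_x = gamma * y on every node (simple xy shear), u_y = u_z = 0
    u <- numeric(3 * n)
    u[seq(1, 3 * n, by = 3)] <- 1e-3 * mesh$nodes[, 2]
    as.numeric(u %*% (es$K %*% u))
  }
  e_ref <- shear_energy(c(1, 1, 1))
  e_xy2 <- shear_energy(c(2, 1, 1))
  e_yzxz2 <- shear_energy(c(1, 2, 2))
  # a simple xy shear has no normal strain, so the volumetric (mean-G) and
  # normal terms vanish and the energy is exactly proportional to G_xy
  expect_equal(e_xy2 / e_ref, 2, tolerance = 1e-10)
  expect_equal(e_yzxz2 / e_ref, 1, tolerance = 1e-10)
})
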