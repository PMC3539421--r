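test_that("shear modulus follows G = E / (2 (1 + nu))", {
  expect_equal(shear_modulus(178, 0.4), 178 / 2.8, tolerance = 1e-15)
  expect_equal(shear_modulus(500, 0.4), 500 / 2.8, tolerance = 1e-15)
  expect_identical(shear_modulus(0, 0.4), 0)
  expect_error(shear_modulus(100, 0.5), "0.5")
  expect_error(shear_modulus(-1, 0.4), ">= 0")
})

test_that("permeability profile implements k = phi R^2 / 8 zone-wise", {
  mesh <- coarse_mesh_fixture()
  # single value per zone, strictly decreasing outward
  k <- permeability_profile(mesh, c(0.04, 0.02, 0.01), porosity = 0.5)
  kz <- tapply(k, mesh$zone, unique)
  expect_equal(unname(kz[["1"]]), 0.5 * 0.04^2 / 8, tolerance = 1e-15)
  # zone permeabilities in the ratio 16:4:1 for radii 4:2:1
  expect_equal(unname(kz[["1"]] / kz[["3"]]), 16, tolerance = 1e-12)
  expect_equal(unname(kz[["2"]] / kz[["3"]]), 4, tolerance = 1e-12)
  # strictly decreasing with zone label
  expect_true(all(diff(unlist(kz)) < 0))
  # the worked single-zone example: phi = 0.5, R = 0.02 -> k = 2.5e-5
  single <- build_multizone_phantom(
    phantom_spec(n_shells = 1, shell_fractions = 1,
                 target_edge_length = 0.04), seed = 1)
  expect_equal(unique(permeability_profile(single, 0.02, 0.5)), 2.5e-5,
               tolerance = 1e-15)
  # rejects zero radii, non-decreasing radii, zone-count mismatch
  expect_error(permeability_profile(mesh, c(0.04, 0.02, 0), 0.5), "> 0")
  expect_error(permeability_profile(mesh, c(0.01, 0.02, 0.04), 0.5),
               "decrease strictly")
  expect_error(permeability_profile(mesh, c(0.04, 0.02), 0.5), "per zone")
})

test_that("isotropic mode gives the homogeneous mean-stiffness field", {
  mesh <- coarse_mesh_fixture()
  mat <- generate_elasticity_field(mesh,
    elasticity_field_spec(mode = "isotropic"))
  g <- 178 / 2.8
  expect_true(all(abs(mat$g_xy - g) < 1e-12))
  expect_identical(mat$g_xy, mat$g_yz)
  expect_identical(mat$g_xy, mat$g_xz)
  expect_equal(mean_ym(mesh, mat), 178, tolerance = 1e-12)
})

test_that("synthetic anisotropic field matches the prescribed statistics", {
  mesh <- coarse_mesh_fixture()
  spec <- elasticity_field_spec(mode = "anisotropic_synthetic", seed = 11)
  mat <- generate_elasticity_field(mesh, spec)
  ym <- attr(mat, "base_ym")
  expect_gte(min(ym), 10)
  expect_lte(max(ym), 500)
  # volume-weighted mean matched to 178 Pa within 1 %
  expect_equal(mean_ym(mesh, mat), 178, tolerance = 0.01)
  # determinism: identical spec and seed reproduce the field exactly
  mat2 <- generate_elasticity_field(mesh, spec)
  expect_identical(attr(mat2, "base_ym"), ym)
  # a different seed gives a different field
  mat3 <- generate_elasticity_field(mesh,
    elasticity_field_spec(mode = "anisotropic_synthetic", seed = 12))
  expect_false(identical(attr(mat3, "base_ym"), ym))
})

test_that("axis contrast (1,1,1) collapses to heterogeneous-isotropic", {
  mesh <- coarse_mesh_fixture()
  mat <- generate_elasticity_field(mesh,
    elasticity_field_spec(mode = "anisotropic_synthetic",
                          axis_contrast = c(1, 1, 1), seed = 5))
  expect_identical(mat$g_xy, mat$g_yz)
  expect_identical(mat$g_xy, mat$g_xz)
})

test_that("larger correlation length raises spatial autocorrelation", {
  mesh <- coarse_mesh_fixture()
  adj <- porolung:::element_adjacency(mesh)
  neigh_corr <- function(cl, seed) {
    mat <- generate_elasticity_field(mesh,
      elasticity_field_spec(mode = "anisotropic_synthetic",
                            correlation_length = cl, seed = seed))
    ym <- attr(mat, "base_ym")
    tm <- methods::as(adj, "TsparseMatrix")  # face-neighbour pairs, lag ~ h
    stats::cor(ym[tm@i + 1L], ym[tm@j + 1L])
  }
  seeds <- 1:4
  c_short <- vapply(seeds, function(s) neigh_corr(0.01, s), numeric(1))
  c_long <- vapply(seeds, function(s) neigh_corr(0.08, s), numeric(1))
  expect_gt(mean(c_long), mean(c_short))
})

test_that("a tumor inclusion pins enclosed elements at maximum stiffness", {
  mesh <- coarse_mesh_fixture()
  ctr <- c(0.0, 0.0, 0.04)
  mat <- generate_elasticity_field(mesh,
    elasticity_field_spec(mode = "anisotropic_synthetic",
                          tumor_center = ctr, tumor_radius = 0.02, seed = 2))
  cent <- (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
           mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
  inside <- sqrt(rowSums(sweep(cent, 2, ctr, `-`)^2)) <= 0.02
  expect_gt(sum(inside), 0)
  expect_true(all(attr(mat, "base_ym")[inside] == 500))
})

test_that("per-element elasticity tables are read and validated", {
  mesh <- coarse_mesh_fixture()
  m <- nrow(mesh$elements)
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  ym <- runif(m, 50, 300)
  utils::write.csv(data.frame(element_id = seq_len(m), ym = ym), f,
                   row.names = FALSE)
  mat <- generate_elasticity_field(mesh,
    elasticity_field_spec(mode = "anisotropic_file", path = f))
  expect_equal(attr(mat, "base_ym"), ym, tolerance = 1e-12)
  # row-count mismatch rejected
  utils::write.csv(data.frame(element_id = 1:10, ym = ym[1:10]), f,
                   row.names = FALSE)
  expect_error(generate_elasticity_field(mesh,
    elasticity_field_spec(mode = "anisotropic_file", path = f)), "rows")
})

test_that("material invariants are enforced", {
  mesh <- coarse_mesh_fixture()
  expect_error(material_field(mesh, ym = 178, poisson = 0.55), "poisson")
  expect_error(material_field(mesh, ym = 178, porosity = 1.2), "porosity")
  expect_error(material_field(mesh, ym = -5), "> 0")
  expect_error(elasticity_field_spec(ym_mean = 600), "ym_min < ym_mean < ym_max")
})
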