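test_that("multizone phantom satisfies the structural invariants", {
  mesh <- coarse_mesh_fixture()
  expect_s3_class(mesh, "zoned_mesh")
  # positive volumes under the fixed orientation convention
  vol <- tet_signed_volumes(mesh$nodes, mesh$elements)
  expect_true(all(vol > 0))
  # contiguous zone labels 1..3, one per element
  expect_identical(sort(unique(mesh$zone)), 1:3)
  expect_length(mesh$zone, nrow(mesh$elements))
  # total volume close to the ellipsoid volume (faceting makes it smaller)
  v_ell <- 4 / 3 * pi * prod(c(0.06, 0.08, 0.12))
  expect_lt(sum(vol), v_ell)
  expect_gt(sum(vol), 0.9 * v_ell)
  # zone volumes partition the total exactly (same volume formula)
  expect_equal(sum(tapply(vol, mesh$zone, sum)), sum(vol), tolerance = 1e-14)
  # watertight + tags only on surface nodes, inlet and fixed disjoint
  expect_silent(validate_zoned_mesh(mesh))
  expect_length(intersect(mesh$boundary$inlet, mesh$boundary$fixed), 0)
  # inlet patch is the contiguous set of surface nodes nearest the
  # configured inlet location (at least the nearest node plus its ring)
  spec <- coarse_phantom_spec()
  surf <- mesh$boundary$surface
  d_all <- sqrt(colSums((t(mesh$nodes[surf, , drop = FALSE]) -
                         spec$inlet_location)^2))
  names(d_all) <- surf
  d_in <- d_all[as.character(mesh$boundary$inlet)]
  d_out <- d_all[!(surf %in% mesh$boundary$inlet)]
  expect_gte(length(d_in), 1L)
  expect_lt(max(d_in), min(d_out) + 1e-12)
})

test_that("zone labels are monotone in the scaled ellipsoidal radius", {
  mesh <- coarse_mesh_fixture()
  cent <- (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
           mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
  rho <- sqrt(rowSums(sweep(cent, 2, c(0.06, 0.08, 0.12), `/`)^2))
  o <- order(rho)
  expect_true(all(diff(mesh$zone[o]) >= 0))
  # and the core is refined relative to uniform sizing: the core element
  # share exceeds the core volume share
  vol <- tet_signed_volumes(mesh$nodes, mesh$elements)
  core_share_n <- mean(mesh$zone == 1L)
  core_share_v <- sum(vol[mesh$zone == 1L]) / sum(vol)
  expect_gt(core_share_n, core_share_v)
})

test_that("single-shell spec degenerates to a homogeneous unzoned ellipsoid", {
  mesh <- build_multizone_phantom(
    phantom_spec(n_shells = 1, shell_fractions = 1,
                 target_edge_length = 0.035), seed = 1)
  expect_identical(unique(mesh$zone), 1L)
  expect_silent(validate_zoned_mesh(mesh))
})

test_that("halving target edge lengths refines as expected", {
  spec1 <- coarse_phantom_spec()
  spec2 <- coarse_phantom_spec(target_edge_length =
                                 spec1$target_edge_length / 2)
  m1 <- coarse_mesh_fixture()
  m2 <- build_multizone_phantom(spec2, seed = 1)
  ratio <- nrow(m2$elements) / nrow(m1$elements)
  expect_gte(ratio, 4)
  expect_lte(ratio, 16)
  # independent mesh-quality checker: max circumradius at most ~halves
  r1 <- max(tet_circumradii(m1))
  r2 <- max(tet_circumradii(m2))
  expect_lt(r2 / r1, 0.55)
})

test_that("phantom construction is deterministic for identical spec and seed", {
  spec <- coarse_phantom_spec()
  m1 <- build_multizone_phantom(spec, seed = 42)
  m2 <- build_multizone_phantom(spec, seed = 42)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$zone, m2$zone)
  expect_identical(m1$boundary, m2$boundary)
})

test_that("invalid phantom specs are rejected with clear errors", {
  expect_error(phantom_spec(n_shells = 0), "n_shells")
  expect_error(phantom_spec(shell_fractions = c(0.7, 0.4, 1.0)),
               "increasing")
  expect_error(phantom_spec(shell_fractions = c(0.4, 0.7, 0.9)),
               "equal 1")
  expect_error(phantom_spec(semi_axes = c(0.06, -0.08, 0.12)), "positive")
  expect_error(phantom_spec(target_edge_length = c(0.03, 0.02, 0.02)),
               "non-decreasing")
})
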