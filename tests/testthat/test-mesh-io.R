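# round-trips use a deliberately small phantom so file parsing stays fast
small_mesh <- build_multizone_phantom(
  phantom_spec(n_shells = 2, shell_fractions = c(0.5, 1.0),
               target_edge_length = c(0.030, 0.040)), seed = 3)

test_that("legacy VTK export round-trips to an equal mesh", {
  f <- withr::local_tempfile(fileext = ".vtk")
  export_mesh(small_mesh, f)
  back <- load_mesh(f)
  expect_equal(back$nodes, small_mesh$nodes, tolerance = 0)   # full precision
  expect_identical(back$elements, small_mesh$elements)
  expect_identical(back$zone, small_mesh$zone)
  expect_identical(back$boundary$inlet, small_mesh$boundary$inlet)
  expect_identical(back$boundary$fixed, small_mesh$boundary$fixed)
})

test_that("Gmsh 2.2 export round-trips to an equal mesh", {
  f <- withr::local_tempfile(fileext = ".msh")
  export_mesh(small_mesh, f)
  back <- load_mesh(f)
  expect_equal(back$nodes, small_mesh$nodes, tolerance = 0)
  expect_identical(back$elements, small_mesh$elements)
  expect_identical(back$zone, small_mesh$zone)
  expect_identical(back$boundary$inlet, small_mesh$boundary$inlet)
})

test_that("missing zone field falls back to a single zone with a warning", {
  f <- withr::local_tempfile(fileext = ".vtk")
  export_mesh(small_mesh, f)
  lines <- readLines(f)
  i0 <- grep("^CELL_DATA", lines)
  i1 <- grep("^POINT_DATA", lines)
  writeLines(c(lines[seq_len(i0 - 1L)], lines[i1:length(lines)]), f)
  expect_warning(back <- load_mesh(f), "single zone")
  expect_identical(unique(back$zone), 1L)
})

test_that("an inverted tetrahedron is rejected with its element index", {
  f <- withr::local_tempfile(fileext = ".vtk")
  broken <- small_mesh
  # swapping two node indices of one tet flips its orientation
  broken$elements[17L, c(3L, 4L)] <- broken$elements[17L, c(4L, 3L)]
  porolung:::write_vtk_mesh(broken, f)
  expect_error(load_mesh(f), "inverted tetrahedron.*17")
})

test_that("non-tetrahedral cells and unknown formats are rejected", {
  f <- withr::local_tempfile(fileext = ".vtk")
  export_mesh(small_mesh, f)
  lines <- readLines(f)
  it <- grep("^CELL_TYPES", lines)[1L]
  lines[it + 1L] <- "12"   # hexahedron type
  writeLines(lines, f)
  expect_error(load_mesh(f), "[Nn]on-tetrahedral")

  g <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid junk", "endsolid junk"), g)
  expect_error(load_mesh(g), "unsupported mesh format")
})
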