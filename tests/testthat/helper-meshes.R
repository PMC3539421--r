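# Shared fixtures and independent geometric checkers, all built in code.

# small box mesh [0,lx] x [0,ly] x [0,lz], nx*ny*nz cells split into 6 tets
# each; written independently of the package's ellipsoid mesher so it can
# serve the 1-D verification problems.  "inlet" = x = 0 face, "fixed" =
# x = lx face.
box_mesh <- function(nx = 8, ny = 2, nz = 2, lx = 0.02, ly = 0.004,
                     lz = 0.004) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  id <- function(i, j, k) i + (nx + 1) * (j - 1) + (nx + 1) * (ny + 1) * (k - 1)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  els <- list()
  for (ci in 1:nx) for (cj in 1:ny) for (ck in 1:nz) {
    corner <- c(ci, cj, ck)
    for (p in 1:6) {
      e1 <- diag(3)[perms[p, 1], ]
      e12 <- e1 + diag(3)[perms[p, 2], ]
      v <- rbind(corner, corner + e1, corner + e12, corner + 1)
      els[[length(els) + 1L]] <- c(id(v[1, 1], v[1, 2], v[1, 3]),
                                   id(v[2, 1], v[2, 2], v[2, 3]),
                                   id(v[3, 1], v[3, 2], v[3, 3]),
                                   id(v[4, 1], v[4, 2], v[4, 3]))
    }
  }
  elements <- do.call(rbind, els)
  vol <- porolung::tet_signed_volumes(nodes, elements)
  flip <- vol < 0
  tmp <- elements[flip, 3L]
  elements[flip, 3L] <- elements[flip, 4L]
  elements[flip, 4L] <- tmp
  mesh0 <- porolung:::new_zoned_mesh(nodes, elements, rep(1L, nrow(elements)),
                                     list(inlet = integer(), fixed = integer(),
                                          surface = integer()))
  surf <- porolung::surface_nodes(mesh0)
  inlet <- intersect(which(abs(nodes[, 1]) < 1e-12), surf)
  fixed <- intersect(which(abs(nodes[, 1] - lx) < 1e-12), surf)
  porolung:::new_zoned_mesh(nodes, elements, rep(1L, nrow(elements)),
                            list(inlet = inlet, fixed = fixed, surface = surf))
}

# interleaved displacement-DOF indices for the y and z components of every
# node: lateral roller confinement for the 1-D column problems
lateral_roller_dofs <- function(mesh) {
  n <- nrow(mesh$nodes)
  sort(c((seq_len(n) - 1L) * 3L + 2L, (seq_len(n) - 1L) * 3L + 3L))
}

# circumscribed-sphere radius of every tetrahedron (independent mesh-quality
# checker: direct solve of the circumcentre equations per element)
tet_circumradii <- function(mesh) {
  el <- mesh$elements
  vapply(seq_len(nrow(el)), function(e) {
    v <- mesh$nodes[el[e, ], ]
    a <- v[1, ]
    M <- 2 * (v[2:4, ] - matrix(a, 3, 3, byrow = TRUE))
    b <- rowSums(v[2:4, ]^2) - sum(a^2)
    ctr <- tryCatch(solve(M, b), error = function(err) rep(NA_real_, 3))
    sqrt(sum((ctr - a)^2))
  }, numeric(1))
}

# Terzaghi consolidation series: pore pressure at depth x from the drained
# face (drainage path L, no-flux at x = L) under a step boundary pressure P,
# independent closed-form oracle
terzaghi_pressure <- function(x, t, P, c_v, L, n_terms = 60) {
  Tv <- c_v * t / L^2
  xi <- x / L
  q <- 0
  for (m in seq_len(n_terms) - 1) {
    M <- pi * (2 * m + 1) / 2
    q <- q + (2 / M) * sin(M * xi) * exp(-M^2 * Tv)
  }
  P * (1 - q)
}

# default-condition coarse phantom shared across test files (built once)
coarse_mesh_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- porolung::build_multizone_phantom(
        porolung::coarse_phantom_spec(), seed = 1L)
    cache
  }
})
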