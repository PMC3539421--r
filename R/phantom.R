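#' Multizone ellipsoidal phantom specification
#'
#' Describes the lung-like phantom geometry: a bounding ellipsoid partitioned
#' into concentric scaled-ellipsoidal shells (zone 1 = core, increasing
#' outward).  The shells stand in for the core-to-periphery organisation of the
#' airway tree in the porous-continuum picture: the core carries the large
#' branches (high permeability, steep gradients, fine mesh), the periphery the
#' tip branches.  All units are SI (m).
#'
#' @param semi_axes Numeric length 3, semi-axes of the bounding ellipsoid in
#'   metres.  Default \code{c(0.06, 0.08, 0.12)}, human-lung scale
#'   (x = anteroposterior, y = mediolateral, z = craniocaudal).
#' @param n_shells Integer >= 1, number of concentric zones.
#' @param shell_fractions Strictly increasing radial fractions in (0, 1], one
#'   per shell, last exactly 1: shell i occupies scaled ellipsoidal radii in
#'   (\code{shell_fractions[i-1]}, \code{shell_fractions[i]}].
#' @param target_edge_length Per-shell characteristic edge length (m),
#'   non-decreasing outward (the core is meshed finer).
#' @param inlet_location Point on the ellipsoid surface defining the centre of
#'   the circular inlet patch.  Default: the superior-medial pole (trachea
#'   side), computed from the semi-axes.
#' @param inlet_radius Radius (m) of the inlet patch.  Default 0.01.
#' @param fixed_radius Radius (m) of the anchoring patch around the inlet
#'   (nodes within this radius but outside the inlet patch are tagged
#'   \code{"fixed"}).  Default \code{2.5 * inlet_radius}.
#' @return An object of class \code{phantom_spec}.
#' @seealso [build_multizone_phantom()], [coarse_phantom_spec()]
#' @export
phantom_spec <- function(semi_axes = c(0.06, 0.08, 0.12),
                         n_shells = 3L,
                         shell_fractions = c(0.4, 0.7, 1.0),
                         target_edge_length = c(0.010, 0.014, 0.018),
                         inlet_location = NULL,
                         inlet_radius = 0.01,
                         fixed_radius = 2.5 * inlet_radius) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("'semi_axes' must be 3 strictly positive lengths (m)")
  n_shells <- as.integer(n_shells)
  if (is.na(n_shells) || n_shells < 1L)
    stop("'n_shells' must be an integer >= 1")
  if (length(shell_fractions) != n_shells)
    stop("'shell_fractions' must have one entry per shell")
  if (any(diff(c(0, shell_fractions)) <= 0))
    stop("'shell_fractions' must be strictly increasing and positive")
  if (abs(shell_fractions[n_shells] - 1) > 1e-12)
    stop("last shell fraction must equal 1")
  if (length(target_edge_length) != n_shells || any(target_edge_length <= 0))
    stop("'target_edge_length' needs one positive value per shell")
  if (any(diff(target_edge_length) < 0))
    stop("'target_edge_length' must be non-decreasing outward (core meshed finest)")
  if (!is.numeric(inlet_radius) || inlet_radius <= 0)
    stop("'inlet_radius' must be > 0")
  if (fixed_radius <= inlet_radius)
    stop("'fixed_radius' must exceed 'inlet_radius'")
  if (is.null(inlet_location)) {
    # superior-medial pole: direction (0, -y, +z), projected onto the surface
    w <- c(0, -0.4, 0.9165151)
    inlet_location <- ellipsoid_surface_point(w, semi_axes)
  } else {
    if (length(inlet_location) != 3L)
      stop("'inlet_location' must be a 3D point")
    rho <- sqrt(sum((inlet_location / semi_axes)^2))
    if (abs(rho - 1) > 0.05)
      stop("'inlet_location' must lie on the ellipsoid surface")
  }
  structure(list(semi_axes = as.numeric(semi_axes),
                 n_shells = n_shells,
                 shell_fractions = as.numeric(shell_fractions),
                 target_edge_length = as.numeric(target_edge_length),
                 inlet_location = as.numeric(inlet_location),
                 inlet_radius = inlet_radius,
                 fixed_radius = fixed_radius),
            class = "phantom_spec")
}

#' Coarse phantom preset
#'
#' The default resolution used by the fast demonstration runs and the
#' verification suite (~5000 tetrahedra): same geometry as [phantom_spec()]
#' but with coarser per-shell edge lengths.
#'
#' @param ... Overrides passed on to [phantom_spec()].
#' @return A \code{phantom_spec}.
#' @export
coarse_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(target_edge_length = c(0.015, 0.020, 0.025))
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# point on the ellipsoid surface in direction w (from the centre)
ellipsoid_surface_point <- function(w, semi_axes) {
  t <- 1 / sqrt(sum((w / semi_axes)^2))
  t * w
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Multizone ellipsoid phantom spec\n")
  cat("  semi-axes (m):", format(x$semi_axes), "\n")
  cat("  shells:", x$n_shells, "at fractions", format(x$shell_fractions), "\n")
  cat("  target edge length (m):", format(x$target_edge_length), "\n")
  cat("  inlet radius (m):", x$inlet_radius,
      " fixed radius (m):", x$fixed_radius, "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## mesh construction: graded radial extrusion of a subdivided-octahedron
## sphere triangulation.  Every zone interface is an exact node shell; the
## layers between consecutive shells are prisms split into three tetrahedra
## each (smallest-global-vertex diagonal rule, which makes the split
## conforming across neighbouring prisms); the innermost shell closes onto
## the centre node.  No tetrahedron has all four nodes on the outer surface,
## so element circumradii scale with the target edge length.
## ---------------------------------------------------------------------------

# triangulated unit sphere: octahedron subdivided `level` times, midpoints
# projected onto the sphere; shared edges reuse shared midpoint vertices
octasphere <- function(level) {
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  faces <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                 c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (l in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    vlist <- list(verts)
    nv <- nrow(verts)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      m <- verts[a, ] + verts[b, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, 4L * nrow(faces), 3L)
    for (f in seq_len(nrow(faces))) {
      v1 <- faces[f, 1L]; v2 <- faces[f, 2L]; v3 <- faces[f, 3L]
      m12 <- midpoint(v1, v2)
      m23 <- midpoint(v2, v3)
      m31 <- midpoint(v3, v1)
      newf[4L * f - 3L, ] <- c(v1, m12, m31)
      newf[4L * f - 2L, ] <- c(v2, m23, m12)
      newf[4L * f - 1L, ] <- c(v3, m31, m23)
      newf[4L * f, ] <- c(m12, m23, m31)
    }
    verts <- do.call(rbind, c(list(verts),
                              lapply(vlist[-1L], matrix, nrow = 1L)))
    faces <- newf
  }
  list(verts = verts, faces = faces)
}

# per-shell radial layer counts and the resulting shell radii (zone
# boundaries land exactly on node shells)
radial_layers <- function(spec) {
  rbar <- mean(spec$semi_axes)
  fr <- c(0, spec$shell_fractions)
  radii <- 0
  for (i in seq_len(spec$n_shells)) {
    nl <- max(1L, as.integer(round((fr[i + 1L] - fr[i]) * rbar /
                                     spec$target_edge_length[i])))
    radii <- c(radii, seq(fr[i], fr[i + 1L], length.out = nl + 1L)[-1L])
  }
  radii
}

# split one prism (bottom b1 b2 b3, top t1 t2 t3, bi below ti) into 3 tets.
# Standard smallest-vertex diagonal rule: relabel (rotation, optional
# bottom/top swap) so V1 is the prism's smallest global index; the quads
# adjacent to V1 then split through V1, and the opposite quad splits through
# its own smallest vertex.  Every quad diagonal therefore depends only on
# the global indices of that quad, which makes the split conforming across
# neighbouring prisms.  Orientation is normalized later by signed volume.
split_prism <- function(bot, top) {
  best <- NULL
  for (r in 0:2) {
    ord <- ((r + 0:2) %% 3L) + 1L
    for (cand in list(list(b = bot[ord], t = top[ord]),
                      list(b = top[ord], t = bot[ord]))) {
      if (is.null(best) || cand$b[1L] < best$b[1L]) best <- cand
    }
  }
  v1 <- best$b[1L]; v2 <- best$b[2L]; v3 <- best$b[3L]
  v4 <- best$t[1L]; v5 <- best$t[2L]; v6 <- best$t[3L]
  if (min(v2, v6) < min(v3, v5)) {
    rbind(c(v1, v2, v3, v6), c(v1, v2, v6, v5), c(v1, v5, v6, v4))
  } else {
    rbind(c(v1, v2, v3, v5), c(v1, v5, v3, v6), c(v1, v5, v6, v4))
  }
}

#' Build a multizone tetrahedral lung phantom
#'
#' Generates a watertight tetrahedral mesh of the phantom ellipsoid with
#' per-element zone labels (1 = core shell, increasing outward) and tagged
#' boundary node sets (\code{inlet}, \code{fixed}, \code{surface}).  A graded
#' structured cube grid is mapped onto the ellipsoid with an exact
#' spherified-cube transformation; radial node density follows the per-shell
#' target edge lengths, so the core is refined relative to uniform sizing.
#' Each cube cell is split into six tetrahedra (Freudenthal subdivision),
#' which makes the mesh conforming and watertight by construction.
#'
#' The construction is fully deterministic: identical \code{(spec, seed)}
#' yield an identical mesh (the seed is recorded in the provenance and fixes
#' any randomized meshing step; the current scheme has none).
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed recorded with the mesh.
#' @return A \code{zoned_mesh}: list with \code{nodes} (N x 3 matrix, m),
#'   \code{elements} (M x 4 integer matrix, positively oriented),
#'   \code{zone} (length-M integer labels), \code{boundary} (named node-index
#'   sets \code{inlet}, \code{fixed}, \code{surface}) and provenance.
#' @export
build_multizone_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  rbar <- mean(spec$semi_axes)
  # tangential resolution from the outermost target edge; radial layering
  # from the per-shell targets (zone interfaces land exactly on node shells)
  h_outer <- spec$target_edge_length[spec$n_shells]
  level <- max(1L, min(6L, as.integer(ceiling(log2(pi / 2 * rbar / h_outer) - 1e-9))))
  sph <- octasphere(level)
  radii <- radial_layers(spec)[-1L]      # drop the centre (radius 0)
  nv <- nrow(sph$verts)
  m <- length(radii)

  nodes <- matrix(0, 1L + m * nv, 3L)
  for (k in seq_len(m)) {
    nodes[1L + (k - 1L) * nv + seq_len(nv), ] <-
      sweep(sph$verts * radii[k], 2, spec$semi_axes, `*`)
  }
  sid <- function(k, j) 1L + (k - 1L) * nv + j   # node id on shell k

  tris <- sph$faces
  core <- cbind(1L, sid(1L, tris[, 1L]), sid(1L, tris[, 2L]),
                sid(1L, tris[, 3L]))
  layers <- vector("list", m - 1L)
  for (k in seq_len(m - 1L)) {
    tets <- matrix(0L, 3L * nrow(tris), 4L)
    for (f in seq_len(nrow(tris))) {
      tets[(3L * f - 2L):(3L * f), ] <-
        split_prism(sid(k, tris[f, ]), sid(k + 1L, tris[f, ]))
    }
    layers[[k]] <- tets
  }
  elements <- do.call(rbind, c(list(core), layers))
  storage.mode(elements) <- "integer"

  vol <- tet_signed_volumes(nodes, elements)
  flip <- which(vol < 0)
  if (length(flip)) {
    tmp <- elements[flip, 3L]
    elements[flip, 3L] <- elements[flip, 4L]
    elements[flip, 4L] <- tmp
    vol <- tet_signed_volumes(nodes, elements)
  }
  if (any(vol <= 0))
    stop("meshing produced inverted/degenerate tetrahedra at elements: ",
         paste(utils::head(which(vol <= 0), 5L), collapse = ", "))

  cent <- tet_centroids(nodes, elements)
  crho <- sqrt(rowSums(sweep(cent, 2, spec$semi_axes, `/`)^2))
  zone <- zone_from_radius(crho, spec$shell_fractions)

  surface <- 1L + (m - 1L) * nv + seq_len(nv)
  boundary <- tag_boundary(nodes, surface, spec)

  mesh <- new_zoned_mesh(nodes, elements, zone, boundary,
                         provenance = list(spec = spec, seed = as.integer(seed)))
  validate_zoned_mesh(mesh)
  mesh
}

zone_from_radius <- function(rho, fractions) {
  lab <- rowSums(outer(rho, fractions + 1e-12, `>`)) + 1L
  as.integer(pmin(lab, length(fractions)))
}

tag_boundary <- function(nodes, surface, spec) {
  ds <- sqrt(rowSums(sweep(nodes[surface, , drop = FALSE], 2,
                           spec$inlet_location, `-`)^2))
  inlet <- surface[ds <= spec$inlet_radius]
  if (length(inlet) < 4L) {
    # under-resolved orifice: never smaller than the nearest surface node
    # plus its one-ring, so the Dirichlet patch is resolved at any mesh
    # resolution and converges to the physical radius under refinement
    n0 <- surface[which.min(ds)]
    d0 <- sqrt(rowSums(sweep(nodes[surface, , drop = FALSE], 2,
                             nodes[n0, ], `-`)^2))
    ring <- 1.35 * min(d0[d0 > 0])
    inlet <- sort(unique(c(inlet, surface[d0 <= ring])))
  }
  fixed <- setdiff(surface[ds <= spec$fixed_radius], inlet)
  r <- spec$fixed_radius
  while (length(fixed) < 3L && r < 10 * spec$fixed_radius) {
    r <- 1.5 * r
    fixed <- setdiff(surface[ds <= r], inlet)
  }
  list(inlet = sort(inlet), fixed = sort(fixed), surface = sort(surface))
}

## ---------------------------------------------------------------------------
## zoned_mesh class and validators
## ---------------------------------------------------------------------------

new_zoned_mesh <- function(nodes, elements, zone, boundary, provenance = NULL) {
  structure(list(nodes = unname(as.matrix(nodes)),
                 elements = unname(as.matrix(elements)),
                 zone = as.integer(zone),
                 boundary = boundary,
                 n_zones = max(as.integer(zone)),
                 provenance = provenance),
            class = "zoned_mesh")
}

#' Validate a zoned mesh
#'
#' Checks the structural invariants: strictly positive signed tetrahedron
#' volumes, contiguous zone labels starting at 1, watertightness (every
#' interior triangular face shared by exactly two tetrahedra), boundary tags
#' restricted to surface nodes, and disjoint inlet/fixed patches.
#'
#' @param mesh A \code{zoned_mesh}.
#' @param watertight Also run the (more expensive) face-count check.
#' @return The mesh, invisibly; stops with a diagnostic message on violation.
#' @export
validate_zoned_mesh <- function(mesh, watertight = TRUE) {
  stopifnot(inherits(mesh, "zoned_mesh"))
  if (ncol(mesh$nodes) != 3L) stop("nodes must be an N x 3 matrix")
  if (ncol(mesh$elements) != 4L) stop("elements must be an M x 4 matrix")
  if (max(mesh$elements) > nrow(mesh$nodes) || min(mesh$elements) < 1L)
    stop("element node indices out of range")
  vol <- tet_signed_volumes(mesh$nodes, mesh$elements)
  if (any(vol <= 0))
    stop("non-positive tetrahedron volume at element(s): ",
         paste(utils::head(which(vol <= 0), 5L), collapse = ", "))
  z <- sort(unique(mesh$zone))
  if (!identical(z, seq_len(max(z))))
    stop("zone labels must be contiguous integers 1..Nzones")
  if (length(mesh$zone) != nrow(mesh$elements))
    stop("one zone label per element required")
  surf <- surface_nodes(mesh)
  for (tag in names(mesh$boundary)) {
    if (!all(mesh$boundary[[tag]] %in% surf))
      stop("boundary tag '", tag, "' contains non-surface nodes")
  }
  if (length(intersect(mesh$boundary$inlet, mesh$boundary$fixed)))
    stop("inlet and fixed patches must be disjoint")
  if (watertight) {
    fc <- face_counts(mesh)
    bad <- fc$count > 2L
    if (any(bad))
      stop("mesh not watertight: face(s) shared by >2 tetrahedra, e.g. nodes ",
           paste(fc$faces[which(bad)[1L], ], collapse = "-"))
  }
  invisible(mesh)
}

#' @export
print.zoned_mesh <- function(x, ...) {
  cat("Zoned tetrahedral mesh:", nrow(x$nodes), "nodes,",
      nrow(x$elements), "tetrahedra,", x$n_zones, "zones\n")
  cat("  zone element counts:",
      paste(tabulate(x$zone, x$n_zones), collapse = ", "), "\n")
  cat("  boundary nodes: inlet", length(x$boundary$inlet),
      "| fixed", length(x$boundary$fixed),
      "| surface", length(x$boundary$surface), "\n")
  cat("  total volume (m^3):",
      format(sum(tet_signed_volumes(x$nodes, x$elements)), digits = 6), "\n")
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param nodes N x 3 coordinate matrix.
#' @param elements M x 4 integer connectivity.
#' @return Numeric vector of signed volumes (m^3), positive for correctly
#'   oriented elements.
#' @export
tet_signed_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  b <- nodes[elements[, 2L], , drop = FALSE] - a
  cc <- nodes[elements[, 3L], , drop = FALSE] - a
  d <- nodes[elements[, 4L], , drop = FALSE] - a
  (b[, 1] * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
   b[, 2] * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
   b[, 3] * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1])) / 6
}

tet_centroids <- function(nodes, elements) {
  (nodes[elements[, 1L], , drop = FALSE] +
   nodes[elements[, 2L], , drop = FALSE] +
   nodes[elements[, 3L], , drop = FALSE] +
   nodes[elements[, 4L], , drop = FALSE]) / 4
}

# all 4 faces of every tet, nodes sorted within a face; counts per unique face
face_counts <- function(mesh) {
  el <- mesh$elements
  f <- rbind(el[, c(1L, 2L, 3L)], el[, c(1L, 2L, 4L)],
             el[, c(1L, 3L, 4L)], el[, c(2L, 3L, 4L)])
  lo <- pmin(f[, 1L], f[, 2L], f[, 3L])
  hi <- pmax(f[, 1L], f[, 2L], f[, 3L])
  md <- f[, 1L] + f[, 2L] + f[, 3L] - lo - hi
  fs <- cbind(lo, md, hi, deparse.level = 0)
  key <- paste(fs[, 1L], fs[, 2L], fs[, 3L])
  tab <- table(key)
  uk <- names(tab)
  parts <- matrix(as.integer(unlist(strsplit(uk, " ", fixed = TRUE))),
                  ncol = 3L, byrow = TRUE)
  list(faces = parts, count = as.integer(tab), key = key, all_faces = fs)
}

#' Surface nodes of a tetrahedral mesh
#'
#' Nodes lying on boundary faces (faces belonging to exactly one
#' tetrahedron).
#'
#' @param mesh A \code{zoned_mesh}.
#' @return Sorted integer node indices.
#' @export
surface_nodes <- function(mesh) {
  fc <- face_counts(mesh)
  sort(unique(as.vector(fc$faces[fc$count == 1L, , drop = FALSE])))
}

# element-element adjacency over shared faces, as a sparse (M x M) pattern
element_adjacency <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  fc <- face_counts(mesh)
  eid <- rep(seq_len(m), times = 4L)
  o <- order(fc$key)
  k <- fc$key[o]; e <- eid[o]
  same <- which(k[-1L] == k[-length(k)])
  Matrix::sparseMatrix(i = c(e[same], e[same + 1L]),
                       j = c(e[same + 1L], e[same]),
                       x = 1, dims = c(m, m))
}

# node-node adjacency over shared edges (used for boundary-patch growth)
node_adjacency_list <- function(mesh) {
  el <- mesh$elements
  pairs <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                 el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  pairs <- rbind(pairs, pairs[, 2:1])
  split(pairs[, 2L], pairs[, 1L])
}
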