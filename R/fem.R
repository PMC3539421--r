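## Linear-tetrahedron Galerkin assembly for the coupled poroelastic model.
##
## Flow (pore pressure p, Pa):
##   phi*beta dp/dt = div[ (k/mu) (grad p + rho_air g) ] - d/dt(div u)
## Elasticity (displacement u, m), quasi-static Navier form:
##   G lap(u) + G/(1-2 nu) grad(div u) = grad p - f
## which for the weak form is assembled as the standard elasticity operator
## with Lame lambda = 2 G nu/(1-2 nu); orthotropy enters through distinct
## plane shear moduli G_xy, G_yz, G_xz (the volumetric term uses their mean).

# per-element shape-function gradients and volumes for linear tets
tet_shape_gradients <- function(mesh) {
  el <- mesh$elements
  x1 <- mesh$nodes[el[, 1L], , drop = FALSE]
  b <- mesh$nodes[el[, 2L], , drop = FALSE] - x1
  cc <- mesh$nodes[el[, 3L], , drop = FALSE] - x1
  d <- mesh$nodes[el[, 4L], , drop = FALSE] - x1
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  cxd <- cross3(cc, d)
  det <- rowSums(b * cxd)           # 6 V
  if (any(det <= 0)) stop("degenerate or inverted tetrahedron in mesh")
  g2 <- cxd / det
  g3 <- cross3(d, b) / det
  g4 <- cross3(b, cc) / det
  g1 <- -(g2 + g3 + g4)
  list(vol = det / 6,
       grads = list(g1, g2, g3, g4))   # each n_el x 3: grad of N_a
}

# scatter element (a,b) node-pair contributions into a sparse N x N matrix
scatter_pairs <- function(mesh, entry_fun, ndof_per_node = 1L) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 16L * ndof_per_node^2)
  pos <- 1L
  for (a in 1:4) for (b in 1:4) {
    blocks <- entry_fun(a, b)   # list over (i,j) dof pairs, each length n_el
    for (comp in seq_along(blocks)) {
      i <- blocks[[comp]]$i; j <- blocks[[comp]]$j
      ii[[pos]] <- (el[, a] - 1L) * ndof_per_node + i
      jj[[pos]] <- (el[, b] - 1L) * ndof_per_node + j
      xx[[pos]] <- blocks[[comp]]$v
      pos <- pos + 1L
    }
  }
  Matrix::sparseMatrix(i = unlist(ii[seq_len(pos - 1L)]),
                       j = unlist(jj[seq_len(pos - 1L)]),
                       x = unlist(xx[seq_len(pos - 1L)]),
                       dims = c(n * ndof_per_node, n * ndof_per_node))
}

#' Assemble the pore-pressure (flow) system
#'
#' Galerkin discretization of the Richards-type pore-pressure equation on
#' linear tetrahedra: lumped storage \eqn{\phi\beta}, Darcy diffusion with
#' element-wise conductivity \eqn{k/\mu}, gravity source, and the
#' dilatation-rate sink coupling the skeleton deformation into the flow.
#' The semi-discrete system is
#' \deqn{M \dot p + K p = b_{grav} + b_{dil},}
#' with \code{M} the lumped storage diagonal and \code{b_dil = -Q u_dot}
#' (returned when a displacement rate is supplied).
#'
#' @param mesh A \code{zoned_mesh}.
#' @param mat A \code{material_field}.
#' @param displacement_rate Optional per-node displacement rate: an N x 3
#'   matrix or interleaved length-3N vector (m/s).
#' @param gravity Gravity vector (m/s^2), default zero.
#' @return List with sparse stiffness \code{K} (N x N), lumped storage
#'   diagonal \code{M} (length N), gravity load \code{rhs_grav}, dilatation
#'   load \code{rhs_dil} (zero vector when no rate is given), and the
#'   coupling matrix \code{Q} (N x 3N, maps interleaved nodal displacement
#'   to integrated dilatation).
#' @export
assemble_flow_system <- function(mesh, mat, displacement_rate = NULL,
                                 gravity = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "zoned_mesh"), inherits(mat, "material_field"))
  sg <- tet_shape_gradients(mesh)
  vol <- sg$vol
  cond <- mat$permeability / mat$air_viscosity       # k/mu per element
  el <- mesh$elements
  n <- nrow(mesh$nodes)

  K <- scatter_pairs(mesh, function(a, b) {
    ga <- sg$grads[[a]]; gb <- sg$grads[[b]]
    list(list(i = 1L, j = 1L, v = vol * cond * rowSums(ga * gb)))
  })

  # lumped storage: element phi*beta*V/4 to each node
  st <- mat$porosity * mat$air_compressibility * vol / 4
  Mdiag <- accumulate_vector(as.vector(el), rep(st, 4L), n)

  rhs_grav <- numeric(n)
  if (any(gravity != 0)) {
    gv <- mat$air_density * cond * vol
    contrib <- lapply(1:4, function(a) {
      ga <- sg$grads[[a]]
      -gv * (ga[, 1] * gravity[1] + ga[, 2] * gravity[2] + ga[, 3] * gravity[3])
    })
    rhs_grav <- accumulate_vector(as.vector(el), unlist(contrib), n)
  }

  Q <- dilatation_matrix(mesh, sg)
  rhs_dil <- numeric(n)
  if (!is.null(displacement_rate)) {
    ud <- as_interleaved(displacement_rate, n)
    rhs_dil <- -as.numeric(Q %*% ud)
  }
  list(K = K, M = Mdiag, rhs_grav = rhs_grav, rhs_dil = rhs_dil, Q = Q)
}

# Q[a, (b,j)] = integral N_a d(N_b)/dx_j = (V/4) * grad(N_b)_j
dilatation_matrix <- function(mesh, sg = tet_shape_gradients(mesh)) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  vol4 <- sg$vol / 4
  ii <- jj <- xx <- vector("list", 48L)
  pos <- 1L
  for (a in 1:4) for (b in 1:4) for (j in 1:3) {
    ii[[pos]] <- el[, a]
    jj[[pos]] <- (el[, b] - 1L) * 3L + j
    xx[[pos]] <- vol4 * sg$grads[[b]][, j]
    pos <- pos + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, 3L * n))
}

#' Assemble the poroelastic Navier (elasticity) system
#'
#' Linear-tetrahedron assembly of the quasi-static momentum balance.  The
#' shear contribution in each coordinate plane uses that plane's modulus
#' (\code{g_xy}, \code{g_yz}, \code{g_xz}); the volumetric term uses the
#' element-mean shear modulus with the \eqn{1/(1-2\nu)} factor (Lame
#' \eqn{\lambda = 2 \bar G \nu / (1 - 2\nu)}).
#'
#' The pressure-gradient load \eqn{-\nabla p} is applied in its integrated-
#' by-parts form \eqn{\int p\, \nabla\!\cdot\! v\, d\Omega}, so the natural
#' boundary condition on the unconstrained surface is zero \emph{total}
#' traction (the pore pressure pushes on the skeleton at the free surface,
#' as in the standard total-stress porous-media formulation).  This choice
#' makes the discrete flow/elasticity coupling blocks exactly adjoint and
#' the coupled time stepping unconditionally dissipative; the point-wise
#' \eqn{-\nabla p} quadrature with an effective-traction-free surface is
#' not energy-stable on a free body.  A consequence worth knowing: a
#' \emph{uniform} pore pressure inflates the organ (its net force still
#' vanishes exactly, which is the tested invariant).
#'
#' Degrees of freedom are interleaved: node i occupies rows
#' \code{3(i-1) + (1,2,3)} for (x, y, z).
#'
#' @param mesh A \code{zoned_mesh}.
#' @param mat A \code{material_field}.
#' @param pressure Optional per-node pore pressure (Pa).
#' @param body_force Body force density f (N/m^3), 3-vector, default zero.
#' @return List with the sparse symmetric stiffness \code{K} (3N x 3N) and
#'   load vector \code{rhs} (length 3N).
#' @export
assemble_elastic_system <- function(mesh, mat, pressure = NULL,
                                    body_force = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "zoned_mesh"), inherits(mat, "material_field"))
  if (any(mat$poisson >= 0.5))
    stop("Poisson ratio 0.5 (incompressible limit) not admissible")
  sg <- tet_shape_gradients(mesh)
  vol <- sg$vol
  gxy <- mat$g_xy; gyz <- mat$g_yz; gxz <- mat$g_xz
  gbar <- (gxy + gyz + gxz) / 3
  lam <- 2 * gbar * mat$poisson / (1 - 2 * mat$poisson)
  el <- mesh$elements
  n <- nrow(mesh$nodes)

  K <- scatter_pairs(mesh, ndof_per_node = 3L, entry_fun = function(a, b) {
    ga <- sg$grads[[a]]; gb <- sg$grads[[b]]
    gax <- ga[, 1]; gay <- ga[, 2]; gaz <- ga[, 3]
    gbx <- gb[, 1]; gby <- gb[, 2]; gbz <- gb[, 3]
    blk <- list()
    blk[[1]] <- list(i = 1L, j = 1L, v = vol * ((lam + 2 * gbar) * gax * gbx +
                                                gxy * gay * gby + gxz * gaz * gbz))
    blk[[2]] <- list(i = 1L, j = 2L, v = vol * (lam * gax * gby + gxy * gay * gbx))
    blk[[3]] <- list(i = 1L, j = 3L, v = vol * (lam * gax * gbz + gxz * gaz * gbx))
    blk[[4]] <- list(i = 2L, j = 1L, v = vol * (lam * gay * gbx + gxy * gax * gby))
    blk[[5]] <- list(i = 2L, j = 2L, v = vol * ((lam + 2 * gbar) * gay * gby +
                                                gxy * gax * gbx + gyz * gaz * gbz))
    blk[[6]] <- list(i = 2L, j = 3L, v = vol * (lam * gay * gbz + gyz * gaz * gby))
    blk[[7]] <- list(i = 3L, j = 1L, v = vol * (lam * gaz * gbx + gxz * gax * gbz))
    blk[[8]] <- list(i = 3L, j = 2L, v = vol * (lam * gaz * gby + gyz * gay * gbz))
    blk[[9]] <- list(i = 3L, j = 3L, v = vol * ((lam + 2 * gbar) * gaz * gbz +
                                                gxz * gax * gbx + gyz * gay * gby))
    blk
  })

  rhs <- numeric(3L * n)
  if (!is.null(pressure) || any(body_force != 0)) {
    pbar <- 0
    if (!is.null(pressure)) {
      if (length(pressure) != n) stop("'pressure' must have one value per node")
      pbar <- (pressure[el[, 1L]] + pressure[el[, 2L]] +
               pressure[el[, 3L]] + pressure[el[, 4L]]) / 4
    }
    ii <- xx <- vector("list", 4L)
    for (a in 1:4) {
      # int_e p dN_a/dx_i = V * pbar * grad(N_a)_i  (+ body force V/4 f_i)
      ga <- sg$grads[[a]]
      dof <- (el[, a] - 1L) * 3L
      ii[[a]] <- c(dof + 1L, dof + 2L, dof + 3L)
      xx[[a]] <- c(vol * pbar * ga[, 1] + vol / 4 * body_force[1],
                   vol * pbar * ga[, 2] + vol / 4 * body_force[2],
                   vol * pbar * ga[, 3] + vol / 4 * body_force[3])
    }
    rhs <- accumulate_vector(unlist(ii), unlist(xx), 3L * n)
  }
  list(K = K, rhs = rhs)
}

# sum values into a dense vector, adding duplicate indices
accumulate_vector <- function(idx, vals, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

## ------------------------- Dirichlet / linear solve -------------------------

as_interleaved <- function(u, n) {
  if (is.matrix(u)) {
    stopifnot(nrow(u) == n, ncol(u) == 3L)
    as.numeric(t(u))
  } else {
    stopifnot(length(u) == 3L * n)
    as.numeric(u)
  }
}

interleaved_to_matrix <- function(u) {
  matrix(u, ncol = 3L, byrow = TRUE)
}

# prefactor a symmetric positive-definite system restricted to free dofs
factor_dirichlet <- function(K, fixed_idx) {
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), fixed_idx)
  Kff <- K[free, free, drop = FALSE]
  Kfc <- K[free, fixed_idx, drop = FALSE]
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Kff), "CsparseMatrix"),
                          LDL = FALSE, perm = TRUE)
  list(K = K, free = free, fixed = fixed_idx, Kff = Kff, Kfc = Kfc, fac = fac)
}

# solve K x = b with x[fixed] = vals, using a prefactored system;
# verifies the free-row residual against `tol` (relative)
solve_dirichlet <- function(fd, b, fixed_vals = 0, tol = 1e-8,
                            context = "linear solve") {
  rhs <- b[fd$free]
  if (length(fd$fixed)) {
    vals <- rep_len(fixed_vals, length(fd$fixed))
    if (any(vals != 0)) rhs <- rhs - as.numeric(fd$Kfc %*% vals)
  } else vals <- numeric(0)
  xf <- as.numeric(Matrix::solve(fd$fac, rhs, system = "A"))
  res <- as.numeric(fd$Kff %*% xf) - rhs
  denom <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  rel <- sqrt(sum(res^2)) / denom
  if (!is.finite(rel) || rel > tol)
    stop(context, " failed: relative residual ", format(rel, digits = 3),
         " exceeds tolerance ", tol)
  x <- numeric(nrow(fd$K))
  x[fd$free] <- xf
  x[fd$fixed] <- vals
  x
}
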