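#' Solver configuration
#'
#' Settings for the implicit (backward Euler) time integration of the
#' coupled pore-pressure / deformation system.
#'
#' Two coupling schemes are available.  The default, \code{"monolithic"},
#' solves each implicit step's linear block system (pressure and
#' displacement together) with a sparse LU factorization computed once per
#' run; it is exact per step and robust at any coupling strength.  The
#' alternative \code{"staggered"} scheme is a fixed-point iteration between
#' the flow and elastic solves with fixed-stress stabilization and
#' under-relaxation; it is provided for weakly coupled or laterally
#' confined configurations, but for very soft tissue (where the skeleton
#' compliance dwarfs the air compressibility) its convergence degrades and
#' the monolithic path should be used.
#'
#' @param dt Time step (s), default 0.02 (200 steps per 4 s cycle).
#' @param n_cycles Number of breathing cycles to integrate, default 3.
#' @param coupling One of \code{"monolithic"} (default) or
#'   \code{"staggered"}.
#' @param coupling_tol Relative tolerance of the staggered coupling loop,
#'   default 1e-6 (unused by the monolithic scheme).
#' @param max_coupling_iters Staggered iteration cap, default 50 (a warning
#'   is logged on non-convergence; the step is still accepted).
#' @param relaxation Under-relaxation factor in (0, 1] for the staggered
#'   displacement update, default 0.7.
#' @param body_force External body force f (N/m^3), default zero.
#' @param gravity Gravity vector (m/s^2), default zero (the rho*g Darcy
#'   term is retained in the discretization and switches on with this
#'   value).
#' @param fixed_patch Boundary tag name(s) whose nodes are
#'   displacement-fixed (all components).  Default \code{c("fixed",
#'   "inlet")}: the hilum region around the inlet anchors the organ and
#'   removes rigid-body modes.
#' @param linear_solver_tol Relative residual bound verified after each
#'   sparse direct solve, default 1e-8.
#' @param record_every Record the state every this many steps, default 1.
#' @param fixed_dofs Optional extra interleaved displacement DOF indices to
#'   constrain to zero (advanced; enables roller conditions for
#'   verification problems).
#' @return An object of class \code{solver_config}.
#' @export
solver_config <- function(dt = 0.02, n_cycles = 3L,
                          coupling = c("monolithic", "staggered"),
                          coupling_tol = 1e-6,
                          max_coupling_iters = 50L, relaxation = 0.7,
                          body_force = c(0, 0, 0), gravity = c(0, 0, 0),
                          fixed_patch = c("fixed", "inlet"),
                          linear_solver_tol = 1e-8, record_every = 1L,
                          fixed_dofs = integer()) {
  coupling <- match.arg(coupling)
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (coupling_tol <= 0) stop("'coupling_tol' must be > 0")
  if (relaxation <= 0 || relaxation > 1) stop("'relaxation' must lie in (0, 1]")
  if (max_coupling_iters < 1) stop("'max_coupling_iters' must be >= 1")
  if (length(body_force) != 3L || length(gravity) != 3L)
    stop("'body_force' and 'gravity' must be 3-vectors")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("'n_cycles' must be >= 1")
  structure(list(dt = dt, n_cycles = n_cycles, coupling = coupling,
                 coupling_tol = coupling_tol,
                 max_coupling_iters = as.integer(max_coupling_iters),
                 relaxation = relaxation, body_force = as.numeric(body_force),
                 gravity = as.numeric(gravity), fixed_patch = fixed_patch,
                 linear_solver_tol = linear_solver_tol,
                 record_every = as.integer(record_every),
                 fixed_dofs = as.integer(fixed_dofs)),
            class = "solver_config")
}

# assemble operators, boundary sets and factorizations reused by every step
build_operators <- function(mesh, mat, cfg) {
  n <- nrow(mesh$nodes)
  flow <- assemble_flow_system(mesh, mat, gravity = cfg$gravity)
  ela <- assemble_elastic_system(mesh, mat, body_force = cfg$body_force)

  inlet <- mesh$boundary$inlet
  if (!length(inlet)) stop("mesh has no inlet nodes (pressure drive undefined)")
  fixed_nodes <- sort(unique(unlist(mesh$boundary[cfg$fixed_patch])))
  fixed_dofs <- sort(unique(c(as.vector(t(cbind((fixed_nodes - 1L) * 3L + 1L,
                                                (fixed_nodes - 1L) * 3L + 2L,
                                                (fixed_nodes - 1L) * 3L + 3L))),
                              cfg$fixed_dofs)))
  if (!length(fixed_dofs))
    stop("empty displacement fixed patch: the elastic operator would be singular")

  sg <- tet_shape_gradients(mesh)
  dt <- cfg$dt
  Qt <- Matrix::t(flow$Q)     # adjoint pressure-coupling block (rhs_e = Qt p)

  ops <- list(n = n, flow = flow, ela = ela, Qt = Qt, inlet = inlet,
              fixed_dofs = fixed_dofs, sg = sg, dt = dt,
              elements = mesh$elements)

  if (cfg$coupling == "monolithic") {
    # block system: [ M0/dt + K   Q/dt ] [p]   [ (M0 p^n + Q u^n)/dt + g ]
    #               [ -Q^T        K_e  ] [u] = [ f_body                  ]
    Af <- flow$K + Matrix::Diagonal(n, flow$M / dt)
    A <- rbind(cbind(Af, flow$Q / dt), cbind(-Qt, ela$K))
    fixed_all <- c(inlet, n + fixed_dofs)
    free <- setdiff(seq_len(4L * n), fixed_all)
    Aff <- A[free, free, drop = FALSE]
    ops$mono <- list(free = free, fixed = fixed_all,
                     Afc = A[free, fixed_all, drop = FALSE],
                     Aff = Aff,
                     lu = Matrix::lu(methods::as(Aff, "CsparseMatrix")),
                     f_body = ela$rhs)
  } else {
    # fixed-stress stabilization: lumped skeleton-compliance storage
    gbar <- (mat$g_xy + mat$g_yz + mat$g_xz) / 3
    lam <- 2 * gbar * mat$poisson / (1 - 2 * mat$poisson)
    kdr <- lam + 2 * gbar / 3                 # drained bulk modulus
    mfs_el <- sg$vol / 4 / kdr
    Mfs <- accumulate_vector(as.vector(mesh$elements), rep(mfs_el, 4L), n)
    Aflow <- flow$K + Matrix::Diagonal(n, (flow$M + Mfs) / dt)
    ops$Mfs <- Mfs
    ops$flow_fd <- factor_dirichlet(Aflow, inlet)
    ops$ela_fd <- factor_dirichlet(ela$K, fixed_dofs)
  }
  ops
}

# one monolithic implicit step; state$u interleaved length 3N
monolithic_step <- function(state, ops, cfg, drive_value) {
  n <- ops$n
  dt <- ops$dt
  rhs <- c((ops$flow$M * state$p + as.numeric(ops$flow$Q %*% state$u)) / dt +
             ops$flow$rhs_grav,
           ops$mono$f_body)
  fixed_vals <- c(rep(drive_value, length(ops$inlet)),
                  numeric(length(ops$fixed_dofs)))
  b <- rhs[ops$mono$free]
  if (any(fixed_vals != 0))
    b <- b - as.numeric(ops$mono$Afc %*% fixed_vals)
  xf <- as.numeric(Matrix::solve(ops$mono$lu, b))
  # one round of iterative refinement tightens the badly scaled block solve
  res <- as.numeric(ops$mono$Aff %*% xf) - b
  xf <- xf - as.numeric(Matrix::solve(ops$mono$lu, res))
  res <- as.numeric(ops$mono$Aff %*% xf) - b
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
  if (!is.finite(rel) || rel > cfg$linear_solver_tol)
    stop("monolithic solve failed at t = ", state$t + dt,
         ": relative residual ", format(rel, digits = 3))
  x <- numeric(4L * n)
  x[ops$mono$free] <- xf
  x[ops$mono$fixed] <- fixed_vals
  list(t = state$t + dt, p = x[seq_len(n)], u = x[n + seq_len(3L * n)],
       iterations = 1L, converged = TRUE)
}

# one staggered fixed-stress step
staggered_step <- function(state, ops, mat, cfg, drive_value) {
  dt <- ops$dt
  p_old <- state$p
  u_old <- state$u
  p_k <- p_old
  u_k <- u_old
  M0 <- ops$flow$M
  Mfs <- ops$Mfs
  iters <- 0L
  converged <- FALSE
  for (k in seq_len(cfg$max_coupling_iters)) {
    iters <- k
    rhs <- (M0 * p_old + Mfs * p_k) / dt -
      as.numeric(ops$flow$Q %*% (u_k - u_old)) / dt + ops$flow$rhs_grav
    p_new <- solve_dirichlet(ops$flow_fd, rhs, fixed_vals = drive_value,
                             tol = cfg$linear_solver_tol,
                             context = "flow solve")
    es_rhs <- ops$ela$rhs + as.numeric(ops$Qt %*% p_new)
    u_sol <- solve_dirichlet(ops$ela_fd, es_rhs, fixed_vals = 0,
                             tol = cfg$linear_solver_tol,
                             context = "elastic solve")
    u_new <- cfg$relaxation * u_sol + (1 - cfg$relaxation) * u_k
    du <- sqrt(sum((u_new - u_k)^2)) / max(sqrt(sum(u_new^2)), 1e-300)
    dp <- sqrt(sum((p_new - p_k)^2)) / max(sqrt(sum(p_new^2)), 1e-300)
    p_k <- p_new
    u_k <- u_new
    if (max(du, dp) < cfg$coupling_tol ||
        (sqrt(sum(u_new^2)) == 0 && sqrt(sum(p_new^2)) == 0)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("coupling loop did not converge at t = ", state$t + dt,
            " after ", iters, " iterations (step accepted)")
  list(t = state$t + dt, p = p_k, u = u_k, iterations = iters,
       converged = converged)
}

coupled_step <- function(state, ops, mat, cfg, drive_value) {
  if (!is.null(ops$mono)) monolithic_step(state, ops, cfg, drive_value)
  else staggered_step(state, ops, mat, cfg, drive_value)
}

#' Advance the coupled state by one time step
#'
#' Single implicit (backward Euler) step of the coupled pore-pressure /
#' deformation system, using the coupling scheme selected in
#' [solver_config()].  This is the one-step entry point; [run_simulation()]
#' drives it over whole breathing cycles with cached factorizations.
#'
#' @param state List with \code{t} (s), \code{p} (per-node pressure) and
#'   \code{u} (per-node displacement, N x 3 matrix or interleaved vector).
#' @param mesh A \code{zoned_mesh}.
#' @param mat A \code{material_field}.
#' @param w A [waveform()] (or a function of time returning the inlet gauge
#'   pressure).
#' @param cfg A [solver_config()].
#' @param t Current time (s); defaults to \code{state$t}.
#' @param ops Optional prebuilt operator set (internal; rebuilt if missing).
#' @return Updated state list (\code{t, p, u, iterations, converged}) with
#'   \code{u} in the same layout as supplied.
#' @export
step_coupled <- function(state, mesh, mat, w, cfg, t = state$t, ops = NULL) {
  if (is.null(ops)) ops <- build_operators(mesh, mat, cfg)
  n <- nrow(mesh$nodes)
  was_matrix <- is.matrix(state$u)
  st <- list(t = t, p = state$p, u = as_interleaved(state$u, n))
  drive <- drive_function(w)
  out <- coupled_step(st, ops, mat, cfg, drive(t + cfg$dt))
  if (was_matrix) out$u <- interleaved_to_matrix(out$u)
  out
}

drive_function <- function(w) {
  if (is.function(w)) return(w)
  stopifnot(inherits(w, "waveform"))
  function(t) waveform_value(w, t)
}

#' Run a full breathing-cycle simulation
#'
#' Integrates the coupled poroelastic system from a zero initial state
#' (zero gauge pressure, zero displacement) over \code{n_cycles} breathing
#' cycles of the inlet drive, recording the nodal pressure and displacement
#' time series.  The run is deterministic for fixed inputs.
#'
#' @param mesh A \code{zoned_mesh}.
#' @param mat A \code{material_field}.
#' @param w A [waveform()] (or a function of time, for non-phasic
#'   verification drives; the cycle bookkeeping then assumes a 4 s period).
#' @param cfg A [solver_config()].
#' @return A \code{simulation_result}: \code{times} (recorded instants, s),
#'   \code{pressure} (n_times x N matrix, Pa), \code{displacement}
#'   (n_times x N x 3 array, m), \code{coupling_iterations} (per step),
#'   the configuration echo, waveform and mesh.
#' @export
run_simulation <- function(mesh, mat, w, cfg = solver_config()) {
  stopifnot(inherits(mesh, "zoned_mesh"), inherits(mat, "material_field"),
            inherits(cfg, "solver_config"))
  period <- if (inherits(w, "waveform")) w$period else 4
  if (cfg$dt > period / 20)
    stop("dt = ", cfg$dt, " under-resolves the waveform (need dt <= period/20)")
  drive <- drive_function(w)
  nsteps <- as.integer(round(cfg$n_cycles * period / cfg$dt))
  ops <- build_operators(mesh, mat, cfg)
  n <- ops$n

  rec_steps <- seq.int(0L, nsteps, by = cfg$record_every)
  is_rec <- logical(nsteps + 1L)
  is_rec[rec_steps + 1L] <- TRUE
  nt <- length(rec_steps)
  times <- numeric(nt)
  pressure <- matrix(0, nt, n)
  displacement <- array(0, dim = c(nt, n, 3L))
  iters <- integer(nsteps)

  state <- list(t = 0, p = numeric(n), u = numeric(3L * n))
  state$p[ops$inlet] <- drive(0)
  rec <- 1L
  times[rec] <- 0
  pressure[rec, ] <- state$p
  displacement[rec, , ] <- interleaved_to_matrix(state$u)

  n_warn <- 0L
  for (s in seq_len(nsteps)) {
    t_new <- s * cfg$dt
    out <- withCallingHandlers(
      coupled_step(state, ops, mat, cfg, drive(t_new)),
      warning = function(wn) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
    state <- list(t = t_new, p = out$p, u = out$u)
    iters[s] <- out$iterations
    if (is_rec[s + 1L]) {
      rec <- rec + 1L
      times[rec] <- t_new
      pressure[rec, ] <- out$p
      displacement[rec, , ] <- interleaved_to_matrix(out$u)
    }
  }
  if (n_warn > 0L)
    warning(n_warn, " of ", nsteps, " steps hit the coupling iteration cap")

  structure(list(times = times, pressure = pressure,
                 displacement = displacement,
                 coupling_iterations = iters,
                 config = cfg, waveform = if (inherits(w, "waveform")) w else NULL,
                 period = period, mesh = mesh),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Coupled poroelastic simulation result\n")
  cat("  ", length(x$times), "recorded states over",
      format(max(x$times)), "s (dt =", x$config$dt, "s)\n")
  cat("  mesh:", dim(x$pressure)[2L], "nodes\n")
  umax <- max(abs(x$displacement))
  cat("  max |displacement|:", format(umax, digits = 4), "m;",
      "max pressure:", format(max(x$pressure), digits = 4), "Pa\n")
  cat("  coupling iterations: median",
      stats::median(x$coupling_iterations), ", max",
      max(x$coupling_iterations), "\n")
  invisible(x)
}
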