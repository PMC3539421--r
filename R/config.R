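#' Default run configuration
#'
#' The full nested configuration of a simulation run: phantom geometry,
#' material/elasticity settings, inlet waveform, solver settings, landmark
#' selection, output directory and seed.  Defaults encode the reference
#' conditions: Poisson ratio 0.4, lung density 700 kg/m^3, breathing period
#' 4 s, Young's-modulus statistics 10-500 Pa with mean 178 Pa.
#'
#' @param output_dir Output directory for reports.
#' @param seed Integer master seed (recorded in every output header).
#' @return A nested list of class \code{run_config}.
#' @seealso [load_config()], [run_comparison()]
#' @export
default_config <- function(output_dir = "porolung-out", seed = 1L) {
  structure(list(
    phantom = list(
      semi_axes = c(0.06, 0.08, 0.12),
      n_shells = 3L,
      shell_fractions = c(0.4, 0.7, 1.0),
      target_edge_length = c(0.015, 0.020, 0.025),
      inlet_radius = 0.01,
      fixed_radius = 0.025),
    material = list(
      ym_mean = 178, ym_min = 10, ym_max = 500,
      poisson = 0.4, porosity = 0.5,
      correlation_length = 0.08,
      axis_contrast = c(1.25, 1.0, 0.8),
      branch_radii = NULL,              # NULL: default_branch_radii(n_shells)
      permeability_factor = 0.0316,
      tissue_density = 700,
      air_density = 1.2, air_viscosity = 1.8e-5,
      air_compressibility = 1 / 101325),
    waveform = list(amplitude = 300, period = 4, phase_offset = 0),
    solver = list(dt = 0.02, n_cycles = 3L, coupling = "monolithic",
                  coupling_tol = 1e-6, max_coupling_iters = 50L,
                  relaxation = 0.7, record_every = 1L),
    landmarks = "default",
    output_dir = output_dir,
    seed = as.integer(seed),
    log_level = "info"),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys from [default_config()],
#' rejects unknown keys (with their key paths), and validates the physical
#' ranges by constructing the underlying objects.
#'
#' @param path YAML file path.
#' @return A validated \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- unclass(default_config())
  check_unknown_keys(user, base, "")
  cfg <- modify_nested(base, user)
  cfg$seed <- as.integer(cfg$seed)
  cfg$phantom$n_shells <- as.integer(cfg$phantom$n_shells)
  cfg$solver$n_cycles <- as.integer(cfg$solver$n_cycles)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: \code{load_config(dump_config(cfg, f))}
#' reproduces an equal configuration.
#'
#' @param cfg A \code{run_config}.
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

check_unknown_keys <- function(user, base, prefix) {
  if (!is.list(user)) return(invisible())
  extra <- setdiff(names(user), names(base))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(prefix, extra, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      check_unknown_keys(user[[k]], base[[k]], paste0(prefix, k, "."))
  }
  invisible()
}

modify_nested <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]]))
      base[k] <- list(modify_nested(base[[k]], user[[k]]))
    else
      base[k] <- list(user[[k]])   # keeps explicit NULLs as NULL entries
  }
  base
}

#' Validate a run configuration
#'
#' Builds every underlying object (phantom spec, material constants,
#' waveform, solver config) so that all physical-range violations surface
#' with the offending value.
#'
#' @param cfg A \code{run_config}.
#' @return The configuration, invisibly.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$phantom
  phantom_spec(semi_axes = p$semi_axes, n_shells = p$n_shells,
               shell_fractions = p$shell_fractions,
               target_edge_length = p$target_edge_length,
               inlet_radius = p$inlet_radius, fixed_radius = p$fixed_radius)
  m <- cfg$material
  if (m$poisson >= 0.5 || m$poisson <= 0)
    stop("Poisson ratio must lie in (0, 0.5); got ", m$poisson)
  if (m$porosity <= 0 || m$porosity >= 1)
    stop("porosity must lie in (0, 1); got ", m$porosity)
  if (!(m$ym_min < m$ym_mean && m$ym_mean < m$ym_max))
    stop("need ym_min < ym_mean < ym_max; got ",
         paste(m$ym_min, m$ym_mean, m$ym_max))
  if (m$permeability_factor <= 0)
    stop("permeability_factor must be > 0; got ", m$permeability_factor)
  if (m$tissue_density <= 0)
    stop("tissue_density must be > 0; got ", m$tissue_density)
  waveform(amplitude = cfg$waveform$amplitude, period = cfg$waveform$period,
           phase_offset = cfg$waveform$phase_offset)
  s <- cfg$solver
  solver_config(dt = s$dt, n_cycles = s$n_cycles, coupling = s$coupling,
                coupling_tol = s$coupling_tol,
                max_coupling_iters = s$max_coupling_iters,
                relaxation = s$relaxation, record_every = s$record_every)
  invisible(cfg)
}

# stable hash of a configuration (md5 of its canonical YAML)
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}
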