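#' Shear modulus from Young's modulus
#'
#' Standard isotropic relation \eqn{G = E / (2 (1 + \nu))}.  Applied
#' plane-wise when the tissue is orthotropic (distinct moduli in the xy, yz
#' and xz planes).
#'
#' @param ym Young's modulus (Pa), scalar or vector, >= 0.
#' @param poisson Poisson ratio in `[0, 0.5)`.  The incompressible limit 0.5
#'   is rejected: the volumetric \eqn{1/(1 - 2\nu)} coupling diverges there.
#' @return Shear modulus (Pa), same shape as \code{ym}.
#' @examples
#' shear_modulus(178, 0.4)   # 63.571... Pa
#' @export
shear_modulus <- function(ym, poisson) {
  if (any(!is.finite(ym)) || any(ym < 0)) stop("'ym' must be >= 0")
  if (any(!is.finite(poisson)) || any(poisson < 0) || any(poisson >= 0.5))
    stop("'poisson' must lie in [0, 0.5); nu >= 0.5 breaks the 1/(1-2nu) volumetric term")
  ym / (2 * (1 + poisson))
}

#' Zone-wise permeability profile
#'
#' Maps a normalized airway branch radius per zone to a per-element
#' permeability through \eqn{k = \phi R^2 / 8}.  Radii must decrease strictly
#' from the core (zone 1) outward, mirroring the shrinking branch calibre of
#' the airway tree, so the resulting field decreases strictly with zone
#' label.
#'
#' @param mesh A \code{zoned_mesh}.
#' @param branch_radius_per_zone One branch radius per zone (length units of
#'   the normalized parameterization; metres under the package defaults),
#'   strictly decreasing, all > 0.
#' @param porosity Tissue porosity \eqn{\phi} in (0, 1).
#' @return Numeric per-element permeability vector.
#' @export
permeability_profile <- function(mesh, branch_radius_per_zone, porosity) {
  stopifnot(inherits(mesh, "zoned_mesh"))
  r <- branch_radius_per_zone
  if (length(r) != mesh$n_zones)
    stop("need exactly one branch radius per zone (", mesh$n_zones, ")")
  if (any(!is.finite(r)) || any(r <= 0))
    stop("branch radii must be > 0 (permeability k must be positive)")
  if (any(diff(r) >= 0))
    stop("branch radii must decrease strictly from core to periphery")
  if (!is.numeric(porosity) || porosity <= 0 || porosity >= 1)
    stop("'porosity' must lie in (0, 1)")
  k_zone <- porosity * r^2 / 8
  k_zone[mesh$zone]
}

#' Default branch radii for the multizone permeability profile
#'
#' Radii halve from one shell to the next going outward, so zone
#' permeabilities fall in the ratio 16 : 4 : 1 for three shells.  These are
#' \emph{normalized} branch radii of the porous-continuum parameterization,
#' not anatomical airway calibres: combined with the default normalized
#' permeability factor they set the homogeneous tissue's consolidation time
#' to a few milliseconds — small against the 4 s breathing period — which
#' places the reference (mean-stiffness) phantom in the quasi-static,
#' in-phase response regime, while soft heterogeneous patches (stiffness
#' near the lower bound) consolidate ~20x slower and develop visible
#' hysteresis lags.  See the methods vignette for the timescale analysis.
#'
#' @param n_zones Number of zones.
#' @param outer Radius of the outermost zone (m).
#' @return Numeric vector of length \code{n_zones}, strictly decreasing.
#' @export
default_branch_radii <- function(n_zones, outer = 1e-2) {
  outer * 2^(rev(seq_len(n_zones)) - 1L)
}

#' Elasticity field specification
#'
#' Describes how the per-element Young's-modulus field is produced:
#' homogeneous (\code{"isotropic"}), a seeded smooth random field with
#' prescribed range and volume-weighted mean (\code{"anisotropic_synthetic"},
#' standing in for an image-derived stiffness map), or read from a CSV table
#' (\code{"anisotropic_file"}).
#'
#' @param mode One of \code{"isotropic"}, \code{"anisotropic_synthetic"},
#'   \code{"anisotropic_file"}.
#' @param ym_mean Target volume-weighted mean Young's modulus (Pa).
#'   Default 178 Pa (lung-wide average stiffness).
#' @param ym_min,ym_max Field range bounds (Pa).  Defaults 10 and 500 Pa.
#' @param correlation_length Spatial smoothness of the random field (m);
#'   larger values give larger coherent soft/stiff patches.  Default 0.08 m
#'   (lobe-scale regional variation, as in image-derived stiffness maps
#'   where soft parenchyma abuts rigid tumor or large-airway structures).
#' @param axis_contrast Three positive multipliers applied to the xy, yz and
#'   xz plane moduli (orthotropy strength); \code{c(1, 1, 1)} reduces to a
#'   heterogeneous isotropic field.
#' @param tumor_center Optional 3D point; elements within
#'   \code{tumor_radius} of it are set to \code{ym_max} (rigid inclusion).
#' @param tumor_radius Radius (m) of the rigid inclusion.
#' @param path CSV path for \code{mode = "anisotropic_file"}; columns
#'   \code{element_id, ym} or \code{element_id, ym_xy, ym_yz, ym_xz}.
#' @param seed Integer seed for the random field.
#' @return An object of class \code{elasticity_field_spec}.
#' @export
elasticity_field_spec <- function(mode = c("anisotropic_synthetic", "isotropic",
                                           "anisotropic_file"),
                                  ym_mean = 178, ym_min = 10, ym_max = 500,
                                  correlation_length = 0.08,
                                  axis_contrast = c(1.25, 1.0, 0.8),
                                  tumor_center = NULL, tumor_radius = 0.015,
                                  path = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!(ym_min < ym_mean && ym_mean < ym_max))
    stop("require ym_min < ym_mean < ym_max")
  if (ym_min <= 0) stop("'ym_min' must be > 0")
  if (length(axis_contrast) != 3L || any(axis_contrast <= 0))
    stop("'axis_contrast' must be 3 positive multipliers")
  if (!is.null(tumor_center) && length(tumor_center) != 3L)
    stop("'tumor_center' must be a 3D point")
  if (correlation_length < 0) stop("'correlation_length' must be >= 0")
  if (mode == "anisotropic_file" && is.null(path))
    stop("mode 'anisotropic_file' requires 'path'")
  structure(list(mode = mode, ym_mean = ym_mean, ym_min = ym_min,
                 ym_max = ym_max, correlation_length = correlation_length,
                 axis_contrast = as.numeric(axis_contrast),
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 path = path, seed = as.integer(seed)),
            class = "elasticity_field_spec")
}

#' Per-element poroelastic material field
#'
#' Bundles every material coefficient of the coupled model: plane-wise shear
#' moduli (from the Young's-modulus input), Poisson ratio, porosity,
#' permeability (via the zone profile \eqn{k = \phi R^2/8} times the
#' normalized permeability factor), tissue density, and the air constants
#' (density, viscosity, isothermal compressibility).
#'
#' @param mesh A \code{zoned_mesh}.
#' @param ym Young's modulus (Pa): a scalar, a per-element vector, or a
#'   per-element 3-column matrix (xy, yz, xz plane values).
#' @param poisson Poisson ratio (scalar or per element), default 0.4.
#' @param porosity Porosity in (0,1), default 0.5.
#' @param branch_radii Branch radius per zone (m); default
#'   [default_branch_radii()].
#' @param permeability_factor Normalized permeability scale multiplying the
#'   reference profile; the sensitivity range studied is 0.01-0.1 and the
#'   default 0.0316 is its geometric midpoint.
#' @param tissue_density Lung tissue density (kg/m^3), default 700.
#' @param air_density Air density (kg/m^3), default 1.2.
#' @param air_viscosity Air dynamic viscosity (Pa s), default 1.8e-5.
#' @param air_compressibility Air isothermal compressibility (1/Pa),
#'   default 1/101325.
#' @return An object of class \code{material_field} with per-element vectors
#'   \code{g_xy, g_yz, g_xz, poisson, porosity, permeability,
#'   tissue_density}, the per-element \code{ym} matrix, and the air scalars.
#' @export
material_field <- function(mesh, ym = 178, poisson = 0.4, porosity = 0.5,
                           branch_radii = default_branch_radii(mesh$n_zones),
                           permeability_factor = 0.0316,
                           tissue_density = 700, air_density = 1.2,
                           air_viscosity = 1.8e-5,
                           air_compressibility = 1 / 101325) {
  stopifnot(inherits(mesh, "zoned_mesh"))
  m <- nrow(mesh$elements)
  if (is.matrix(ym)) {
    if (ncol(ym) != 3L || nrow(ym) != m)
      stop("'ym' matrix must be n_elements x 3 (xy, yz, xz planes)")
    ym_mat <- ym
  } else {
    ym_v <- if (length(ym) == 1L) rep(ym, m) else ym
    if (length(ym_v) != m) stop("'ym' must be scalar or one value per element")
    ym_mat <- cbind(ym_v, ym_v, ym_v)
  }
  if (any(ym_mat <= 0)) stop("all Young's moduli must be > 0")
  nu <- if (length(poisson) == 1L) rep(poisson, m) else poisson
  if (length(nu) != m) stop("'poisson' must be scalar or per element")
  if (any(nu <= 0) || any(nu >= 0.5)) stop("'poisson' must lie in (0, 0.5)")
  phi <- if (length(porosity) == 1L) rep(porosity, m) else porosity
  if (any(phi <= 0) || any(phi >= 1)) stop("'porosity' must lie in (0, 1)")
  if (permeability_factor <= 0) stop("'permeability_factor' must be > 0")
  k <- permeability_factor * permeability_profile(mesh, branch_radii, porosity[1L])
  rho_s <- if (length(tissue_density) == 1L) rep(tissue_density, m) else tissue_density
  if (any(rho_s <= 0)) stop("'tissue_density' must be > 0")
  g <- shear_modulus(ym_mat, nu)
  structure(list(g_xy = g[, 1L], g_yz = g[, 2L], g_xz = g[, 3L],
                 ym = unname(ym_mat), poisson = nu, porosity = phi,
                 permeability = k, tissue_density = rho_s,
                 air_density = air_density, air_viscosity = air_viscosity,
                 air_compressibility = air_compressibility,
                 branch_radii = branch_radii,
                 permeability_factor = permeability_factor),
            class = "material_field")
}

#' @export
print.material_field <- function(x, ...) {
  cat("Poroelastic material field:", length(x$g_xy), "elements\n")
  cat("  G (Pa): xy", format(range(x$g_xy), digits = 4),
      "| yz", format(range(x$g_yz), digits = 4),
      "| xz", format(range(x$g_xz), digits = 4), "\n")
  cat("  nu:", format(range(x$poisson)), " porosity:", format(range(x$porosity)),
      "\n  permeability (m^2):", format(range(x$permeability), digits = 3), "\n")
  cat("  tissue density:", format(range(x$tissue_density)),
      "kg/m^3 | air: rho", x$air_density, "mu", x$air_viscosity,
      "beta", format(x$air_compressibility, digits = 4), "\n")
  invisible(x)
}

#' Generate a (possibly anisotropic) elasticity field
#'
#' Produces the full [material_field()] for a mesh from an
#' [elasticity_field_spec()]:
#' \itemize{
#'   \item \code{isotropic}: every element gets \code{ym_mean} in all three
#'     planes (the homogeneous reference case).
#'   \item \code{anisotropic_synthetic}: seeded white noise on elements is
#'     smoothed by iterated face-neighbour averaging until the requested
#'     correlation length is reached, then affinely rescaled and clipped to
#'     \code{[ym_min, ym_max]}, with the affine location solved by root
#'     finding so the element-volume-weighted mean matches \code{ym_mean}
#'     to numerical precision (the range bounds hold exactly; clipped
#'     regions sit at the bounds, emulating soft parenchyma against rigid
#'     structures).  Plane-wise values are the scalar field times
#'     \code{axis_contrast}.  An optional rigid inclusion
#'     (\code{tumor_center}/\code{tumor_radius}) is set to \code{ym_max}.
#'   \item \code{anisotropic_file}: per-element values read from a CSV
#'     table with columns \code{element_id, ym} (or three plane columns).
#' }
#' The result is deterministic for a fixed \code{(spec, seed)}.
#'
#' @param mesh A \code{zoned_mesh}.
#' @param spec An [elasticity_field_spec()].
#' @param ... Further arguments (porosity, branch radii, densities, ...)
#'   passed to [material_field()].
#' @return A \code{material_field}; the base scalar Young's-modulus field is
#'   attached as attribute \code{"base_ym"}.
#' @export
generate_elasticity_field <- function(mesh, spec, ...) {
  stopifnot(inherits(mesh, "zoned_mesh"), inherits(spec, "elasticity_field_spec"))
  m <- nrow(mesh$elements)
  base <- switch(spec$mode,
    isotropic = rep(spec$ym_mean, m),
    anisotropic_synthetic = synthetic_ym_field(mesh, spec),
    anisotropic_file = read_ym_table(mesh, spec$path))
  if (is.matrix(base)) {           # file with 3 plane columns
    ym_mat <- base
    base_scalar <- rowMeans(base)
  } else {
    base_scalar <- base
    ym_mat <- if (spec$mode == "isotropic")
      cbind(base, base, base)
    else
      cbind(base * spec$axis_contrast[1L], base * spec$axis_contrast[2L],
            base * spec$axis_contrast[3L])
  }
  out <- material_field(mesh, ym = ym_mat, ...)
  attr(out, "base_ym") <- base_scalar
  attr(out, "elasticity_spec") <- spec
  out
}

# smooth seeded random scalar field with exact range and matched mean
synthetic_ym_field <- function(mesh, spec) {
  m <- nrow(mesh$elements)
  z <- with_local_seed(spec$seed, stats::rnorm(m))
  n_iter <- smoothing_iterations(mesh, spec$correlation_length)
  if (n_iter > 0L) {
    adj <- element_adjacency(mesh)
    deg <- Matrix::rowSums(adj)
    for (it in seq_len(n_iter)) {
      z <- (z + as.numeric(adj %*% z)) / (1 + deg)
    }
  }
  if (stats::sd(z) < .Machine$double.eps)
    stop("degenerate random field (no variance); increase mesh size")
  z <- (z - mean(z)) / stats::sd(z)
  vol <- tet_signed_volumes(mesh$nodes, mesh$elements)
  w <- vol / sum(vol)
  dr <- spec$ym_max - spec$ym_min
  # affine rescale + clipping to [ym_min, ym_max]; the location is solved so
  # the element-volume-weighted mean matches ym_mean to numerical precision.
  # Clipping leaves coherent regions pinned at the bounds, mimicking soft
  # parenchyma next to rigid structures (tumor, large-airway walls).
  spread <- dr / 3
  clipped_mean <- function(m) {
    sum(w * pmin(spec$ym_max, pmax(spec$ym_min, m + spread * z)))
  }
  m <- stats::uniroot(function(m) clipped_mean(m) - spec$ym_mean,
                      lower = spec$ym_min - 4 * spread,
                      upper = spec$ym_max + 4 * spread, tol = 1e-10)$root
  ym <- pmin(spec$ym_max, pmax(spec$ym_min, m + spread * z))
  if (!is.null(spec$tumor_center)) {
    cent <- tet_centroids(mesh$nodes, mesh$elements)
    d <- sqrt(rowSums(sweep(cent, 2, spec$tumor_center, `-`)^2))
    ym[d <= spec$tumor_radius] <- spec$ym_max
  }
  ym
}

# number of neighbour-averaging sweeps emulating a correlation length:
# each sweep diffuses over roughly one inter-centroid spacing
smoothing_iterations <- function(mesh, correlation_length) {
  if (correlation_length <= 0) return(0L)
  vol <- tet_signed_volumes(mesh$nodes, mesh$elements)
  h <- mean(vol^(1 / 3))  # characteristic element size
  as.integer(round((correlation_length / h)^2))
}

read_ym_table <- function(mesh, path) {
  if (!file.exists(path)) stop("elasticity table not found: ", path)
  tab <- utils::read.csv(path)
  m <- nrow(mesh$elements)
  if (nrow(tab) != m)
    stop("elasticity table has ", nrow(tab), " rows but the mesh has ", m,
         " elements")
  if (!("element_id" %in% names(tab)))
    stop("elasticity table must have an 'element_id' column")
  o <- order(tab$element_id)
  tab <- tab[o, ]
  if (!identical(as.integer(tab$element_id), seq_len(m)))
    stop("'element_id' must enumerate 1..n_elements")
  if (all(c("ym_xy", "ym_yz", "ym_xz") %in% names(tab))) {
    as.matrix(tab[, c("ym_xy", "ym_yz", "ym_xz")])
  } else if ("ym" %in% names(tab)) {
    tab$ym
  } else {
    stop("elasticity table needs column 'ym' or columns 'ym_xy','ym_yz','ym_xz'")
  }
}

#' Volume-weighted mean Young's modulus
#'
#' Element-volume-weighted average of the scalar Young's-modulus field
#' underlying a material field (the quantity the lung-wide mean stiffness
#' refers to).
#'
#' @param mesh A \code{zoned_mesh}.
#' @param mat A \code{material_field} (from [generate_elasticity_field()]).
#' @return Scalar (Pa).
#' @export
mean_ym <- function(mesh, mat) {
  base <- attr(mat, "base_ym")
  if (is.null(base)) base <- rowMeans(mat$ym)
  vol <- tet_signed_volumes(mesh$nodes, mesh$elements)
  sum(vol * base) / sum(vol)
}

# run code with a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
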