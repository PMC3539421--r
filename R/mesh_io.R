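#' Export a zoned mesh to a standard mesh file
#'
#' Writes the mesh in legacy ASCII VTK (unstructured grid) or Gmsh 2.2 ASCII
#' format.  The zone labels go out as an integer cell field named
#' \code{"zone"}; the boundary node sets are written as 0/1 integer point
#' fields (\code{inlet}, \code{fixed}, \code{surface}).  Coordinates are
#' printed with 17 significant digits so that [load_mesh()] round-trips to
#' full double precision.
#'
#' @param mesh A \code{zoned_mesh}.
#' @param path Output file path.
#' @param format \code{"vtk"} (default, inferred from a \code{.vtk}
#'   extension) or \code{"gmsh"} (\code{.msh}).
#' @return \code{path}, invisibly.
#' @seealso [load_mesh()]
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "zoned_mesh"))
  if (is.null(format)) {
    format <- if (grepl("\\.msh$", path, ignore.case = TRUE)) "gmsh" else "vtk"
  }
  format <- match.arg(format, c("vtk", "gmsh"))
  if (format == "vtk") write_vtk_mesh(mesh, path) else write_gmsh_mesh(mesh, path)
  invisible(path)
}

#' Load a zoned mesh from a standard mesh file
#'
#' Reads a tetrahedral mesh from a legacy ASCII VTK unstructured-grid file or
#' a Gmsh 2.2 ASCII file.  Node indices are re-based to 1..N; the integer
#' cell field \code{zone_field_name} supplies zone labels (missing field:
#' single zone with a warning); boundary node sets are taken from 0/1 point
#' fields named \code{inlet} / \code{fixed} when present, otherwise derived
#' from the surface.  The mesh is fully validated: non-tetrahedral cells,
#' inverted elements and watertightness violations are rejected.
#'
#' @param path Input file path.
#' @param zone_field_name Name of the integer cell field carrying zone
#'   labels.  Default \code{"zone"}.
#' @return A validated \code{zoned_mesh}.
#' @export
load_mesh <- function(path, zone_field_name = "zone") {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  head1 <- readLines(path, n = 5L, warn = FALSE)
  raw <- if (any(grepl("\\$MeshFormat", head1))) {
    read_gmsh_mesh(path, zone_field_name)
  } else if (any(grepl("vtk DataFile", head1, ignore.case = TRUE))) {
    read_vtk_mesh(path, zone_field_name)
  } else {
    stop("unsupported mesh format (expect legacy ASCII VTK or Gmsh 2.2): ", path)
  }
  assemble_loaded_mesh(raw, zone_field_name, path)
}

assemble_loaded_mesh <- function(raw, zone_field_name, path) {
  nodes <- raw$nodes
  elements <- raw$elements
  # re-index nodes contiguously in case the file skips ids
  used <- sort(unique(as.vector(elements)))
  if (length(used) != nrow(nodes) || any(used != seq_len(nrow(nodes)))) {
    remap <- integer(max(used))
    remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    elements <- matrix(remap[elements], ncol = 4L)
  }
  vol <- tet_signed_volumes(nodes, elements)
  if (any(vol <= 0))
    stop("inverted tetrahedron in file at element index ",
         which(vol <= 0)[1L], " (signed volume <= 0)")
  if (is.null(raw$zone)) {
    warning("no cell field '", zone_field_name, "' in ", path,
            "; assuming a single zone")
    zone <- rep(1L, nrow(elements))
  } else {
    zone <- as.integer(raw$zone)
    u <- sort(unique(zone))
    if (!identical(u, seq_len(max(u)))) {
      zone <- match(zone, u)  # compress to contiguous labels
    }
  }
  mesh0 <- new_zoned_mesh(nodes, elements, zone,
                          boundary = list(inlet = integer(), fixed = integer(),
                                          surface = integer()))
  fcx <- face_counts(mesh0)
  if (any(fcx$count > 2L)) {
    bad <- fcx$faces[which(fcx$count > 2L)[1L], ]
    stop("mesh not watertight: face ", paste(bad, collapse = "-"),
         " belongs to ", max(fcx$count), " tetrahedra")
  }
  surf <- sort(unique(as.vector(fcx$faces[fcx$count == 1L, , drop = FALSE])))
  boundary <- list(inlet = integer(), fixed = integer(), surface = surf)
  for (tag in c("inlet", "fixed")) {
    if (!is.null(raw$point_sets[[tag]]))
      boundary[[tag]] <- intersect(which(raw$point_sets[[tag]] != 0), surf)
  }
  mesh <- new_zoned_mesh(nodes, elements, zone, boundary,
                         provenance = list(source = path))
  validate_zoned_mesh(mesh)
  mesh
}

## -------------------------------- legacy VTK --------------------------------

write_vtk_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "porolung zoned tetrahedral mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(mesh$nodes, 1L, function(p)
    paste(sprintf("%.17g", p), collapse = " ")), con)
  writeLines(paste("CELLS", m, 5L * m), con)
  writeLines(apply(mesh$elements, 1L, function(e)
    paste(c(4L, e - 1L), collapse = " ")), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(paste("CELL_DATA", m),
               "SCALARS zone int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$zone), con)
  writeLines(paste("POINT_DATA", n), con)
  for (tag in c("inlet", "fixed", "surface")) {
    mask <- integer(n)
    mask[mesh$boundary[[tag]]] <- 1L
    writeLines(c(paste("SCALARS", tag, "int 1"), "LOOKUP_TABLE default"), con)
    writeLines(as.character(mask), con)
  }
  invisible(path)
}

read_vtk_mesh <- function(path, zone_field_name) {
  lines <- readLines(path, warn = FALSE)
  tok <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1L]]
  i <- grep("^DATASET", lines)
  if (!length(i) || tok(lines[i[1L]])[2L] != "UNSTRUCTURED_GRID")
    stop("unsupported VTK dataset (need UNSTRUCTURED_GRID): ", path)

  # numeric scan helper: values may wrap over lines; collect count numbers
  scan_numbers <- function(start, count) {
    vals <- numeric(0)
    j <- start
    while (length(vals) < count && j <= length(lines)) {
      v <- suppressWarnings(as.numeric(tok(lines[j])))
      vals <- c(vals, v)
      j <- j + 1L
    }
    if (length(vals) < count || anyNA(vals))
      stop("malformed VTK numeric block near line ", start)
    list(values = vals[seq_len(count)], next_line = j)
  }

  ip <- grep("^POINTS", lines)[1L]
  np <- as.integer(tok(lines[ip])[2L])
  pts <- scan_numbers(ip + 1L, 3L * np)
  nodes <- matrix(pts$values, ncol = 3L, byrow = TRUE)

  ic <- grep("^CELLS", lines)[1L]
  hc <- tok(lines[ic])
  ncell <- as.integer(hc[2L]); ntot <- as.integer(hc[3L])
  cl <- scan_numbers(ic + 1L, ntot)
  it <- grep("^CELL_TYPES", lines)[1L]
  types <- scan_numbers(it + 1L, ncell)$values
  if (any(types != 10))
    stop("non-tetrahedral cell (VTK type ", types[which(types != 10)[1L]],
         ") at cell ", which(types != 10)[1L])
  conn <- cl$values
  elements <- matrix(0L, ncell, 4L)
  pos <- 1L
  for (e in seq_len(ncell)) {
    k <- conn[pos]
    if (k != 4) stop("non-tetrahedral cell with ", k, " nodes at cell ", e)
    elements[e, ] <- as.integer(conn[pos + 1:4]) + 1L
    pos <- pos + 5L
  }

  read_scalar_field <- function(section_start, section_n, wanted) {
    out <- list()
    j <- section_start
    while (j <= length(lines)) {
      t <- tok(lines[j])
      if (length(t) && t[1L] %in% c("CELL_DATA", "POINT_DATA") &&
          j > section_start) break
      if (length(t) && t[1L] == "SCALARS") {
        nm <- t[2L]
        sk <- if (j + 1L <= length(lines) &&
                  grepl("^LOOKUP_TABLE", lines[j + 1L])) 2L else 1L
        sc <- scan_numbers(j + sk, section_n)
        out[[nm]] <- sc$values
        j <- sc$next_line
      } else j <- j + 1L
    }
    out
  }

  zone <- NULL
  icd <- grep("^CELL_DATA", lines)
  if (length(icd)) {
    cf <- read_scalar_field(icd[1L] + 1L, ncell)
    if (!is.null(cf[[zone_field_name]])) zone <- cf[[zone_field_name]]
  }
  point_sets <- list()
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd)) {
    point_sets <- read_scalar_field(ipd[1L] + 1L, np)
  }
  list(nodes = nodes, elements = elements, zone = zone,
       point_sets = point_sets)
}

## -------------------------------- Gmsh 2.2 ---------------------------------

write_gmsh_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  # element type 4 = 4-node tetrahedron; tags: physical = zone, geometric = zone
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(m), mesh$zone,
                     mesh$zone, mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4]), con)
  writeLines("$EndElements", con)
  for (tag in c("inlet", "fixed")) {
    ids <- mesh$boundary[[tag]]
    if (!length(ids)) next
    writeLines(c("$NodeData", "1", paste0("\"", tag, "\""), "1", "0.0", "3",
                 "0", "1", as.character(length(ids))), con)
    writeLines(sprintf("%d 1", ids), con)
    writeLines("$EndNodeData", con)
  }
  invisible(path)
}

read_gmsh_mesh <- function(path, zone_field_name) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    s <- match(paste0("$", name), trimws(lines))
    e <- match(paste0("$End", name), trimws(lines))
    if (is.na(s) || is.na(e)) return(NULL)
    lines[(s + 1L):(e - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt) || !startsWith(trimws(fmt[1L]), "2."))
    stop("unsupported Gmsh format version (need 2.x ASCII): ", path)
  nb <- sec("Nodes")
  nn <- as.integer(nb[1L])
  nm <- matrix(as.numeric(unlist(strsplit(trimws(nb[1L + seq_len(nn)]),
                                          "[[:space:]]+"))),
               ncol = 4L, byrow = TRUE)
  ids <- as.integer(nm[, 1L])
  nodes <- matrix(0, max(ids), 3L)
  nodes[ids, ] <- nm[, 2:4]

  eb <- sec("Elements")
  ne <- as.integer(eb[1L])
  elements <- matrix(0L, ne, 4L)
  zone <- integer(ne)
  for (e in seq_len(ne)) {
    v <- as.integer(strsplit(trimws(eb[1L + e]), "[[:space:]]+")[[1L]])
    if (v[2L] != 4L)
      stop("non-tetrahedral Gmsh element (type ", v[2L], ") at element ", e)
    ntags <- v[3L]
    zone[e] <- if (ntags >= 1L) v[4L] else 1L
    elements[e, ] <- v[(4L + ntags):(7L + ntags)]
  }

  point_sets <- list()
  starts <- which(trimws(lines) == "$NodeData")
  ends <- which(trimws(lines) == "$EndNodeData")
  for (b in seq_along(starts)) {
    blk <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    nstr <- as.integer(blk[1L])
    nm_tag <- gsub("\"", "", trimws(blk[2L]))
    nreal <- as.integer(blk[2L + nstr])
    hdr <- 2L + nstr + nreal + 1L  # counts line after integer-tag count line
    nint <- as.integer(blk[hdr])
    nvals <- as.integer(blk[hdr + nint])
    rows <- blk[(hdr + nint + 1L):(hdr + nint + nvals)]
    vm <- matrix(as.numeric(unlist(strsplit(trimws(rows), "[[:space:]]+"))),
                 ncol = 2L, byrow = TRUE)
    mask <- numeric(nrow(nodes))
    mask[as.integer(vm[, 1L])] <- vm[, 2L]
    point_sets[[nm_tag]] <- mask
  }
  list(nodes = nodes, elements = elements, zone = zone,
       point_sets = point_sets)
}
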