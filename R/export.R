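#' Export a simulation result as a VTK time series
#'
#' Writes one legacy ASCII VTK file per recorded instant (point data: pore
#' pressure scalar, displacement vector), suitable for animation in
#' ParaView-style viewers, plus a simple \code{.series} index file.
#'
#' @param result A \code{simulation_result}.
#' @param dir Output directory.
#' @param basename File stem, default \code{"state"}.
#' @param stride Write every \code{stride}-th recorded state, default 1.
#' @return The directory, invisibly.
#' @export
export_vtk_series <- function(result, dir, basename = "state", stride = 1L) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- result$mesh
  idx <- seq(1L, length(result$times), by = stride)
  files <- character(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    f <- sprintf("%s_%05d.vtk", basename, q - 1L)
    files[q] <- f
    path <- file.path(dir, f)
    con <- file(path, "w")
    n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("porolung state t=%.6f s", result$times[i]),
                 "ASCII", "DATASET UNSTRUCTURED_GRID",
                 paste("POINTS", n, "double")), con)
    writeLines(apply(mesh$nodes, 1L, function(p)
      paste(sprintf("%.9g", p), collapse = " ")), con)
    writeLines(paste("CELLS", m, 5L * m), con)
    writeLines(apply(mesh$elements, 1L, function(e)
      paste(c(4L, e - 1L), collapse = " ")), con)
    writeLines(paste("CELL_TYPES", m), con)
    writeLines(rep("10", m), con)
    writeLines(c(paste("POINT_DATA", n),
                 "SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", result$pressure[i, ]), con)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.9g %.9g %.9g", result$displacement[i, , 1],
                       result$displacement[i, , 2],
                       result$displacement[i, , 3]), con)
    close(con)
  }
  series <- file.path(dir, paste0(basename, ".series"))
  writeLines(c("{ \"file-series-version\" : \"1.0\", \"files\" : [",
               paste0("  { \"name\" : \"", files, "\", \"time\" : ",
                      sprintf("%.6f", result$times[idx]), " }",
                      c(rep(",", length(idx) - 1L), "")),
               "] }"), series)
  invisible(dir)
}

#' Export landmark trajectories as VTK polylines
#'
#' One legacy VTK polyline per landmark tracing its 3D displacement path
#' over all recorded cycles (visualizes loop non-closure directly).
#'
#' @param result A \code{simulation_result}.
#' @param landmarks Landmark data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
export_trajectories_vtk <- function(result, landmarks, path) {
  traces <- suppressWarnings(landmark_series(result, landmarks))
  npts <- sum(vapply(traces, nrow, integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "porolung landmark trajectories",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", npts, "double")), con)
  offset <- 0L
  lines_spec <- character(length(traces))
  for (q in seq_along(traces)) {
    tr <- traces[[q]]
    node <- landmarks$node_index[q]
    base <- result$mesh$nodes[node, ]
    writeLines(sprintf("%.9g %.9g %.9g", base[1] + tr$x, base[2] + tr$y,
                       base[3] + tr$z), con)
    lines_spec[q] <- paste(c(nrow(tr), seq_len(nrow(tr)) - 1L + offset),
                           collapse = " ")
    offset <- offset + nrow(tr)
  }
  writeLines(paste("LINES", length(traces),
                   length(traces) + npts), con)
  writeLines(lines_spec, con)
  invisible(path)
}

#' Write landmark traces as CSV
#'
#' @param result A \code{simulation_result}.
#' @param landmarks Landmark data frame.
#' @param path Output CSV path.
#' @param header Optional comment lines (e.g. seed / config hash) placed
#'   before the CSV header.
#' @return \code{path}, invisibly.
#' @export
write_traces_csv <- function(result, landmarks, path, header = character()) {
  traces <- suppressWarnings(landmark_series(result, landmarks))
  long <- do.call(rbind, lapply(names(traces), function(id)
    cbind(landmark = id, traces[[id]])))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}
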