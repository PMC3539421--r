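#' Surface landmarks for motion analysis
#'
#' A landmark is a tracked surface node summarizing the organ's motion,
#' mirroring the classic A / B / C monitoring points: A at the top (apex) of
#' the lobe, B on the outer (lateral, rib-cage side) surface at mid-height,
#' C on the interior (medial) surface at mid-height.
#'
#' @param mesh A \code{zoned_mesh}.
#' @return A data frame with columns \code{id}, \code{node_index},
#'   \code{description}; all nodes are free surface nodes (outside the
#'   displacement-fixed patches).
#' @export
default_landmarks <- function(mesh) {
  surf <- mesh$boundary$surface
  fixed <- unique(c(mesh$boundary$fixed, mesh$boundary$inlet))
  free <- setdiff(surf, fixed)
  if (!length(free)) stop("no free surface nodes available for landmarks")
  xyz <- mesh$nodes[free, , drop = FALSE]
  bb <- apply(abs(mesh$nodes), 2, max)
  pick <- function(target) free[which.min(colSums((t(xyz) - target)^2))]
  a <- free[which.max(xyz[, 3])]                  # apex: highest z
  b <- pick(c(0,  bb[2], 0))                      # lateral mid-height
  cc <- pick(c(0, -bb[2], 0))                     # medial mid-height
  data.frame(id = c("A", "B", "C"),
             node_index = c(a, b, cc),
             description = c("top surface of the lobe (apex)",
                             "outer lateral surface, mid-height",
                             "interior medial surface, mid-height"),
             stringsAsFactors = FALSE)
}

#' Validate landmarks against a mesh
#'
#' @param mesh A \code{zoned_mesh}.
#' @param landmarks Data frame with \code{id} and \code{node_index}.
#' @return The landmark data frame, invisibly; errors on unknown or
#'   non-surface node indices.
#' @export
validate_landmarks <- function(mesh, landmarks) {
  if (!all(c("id", "node_index") %in% names(landmarks)))
    stop("landmarks need 'id' and 'node_index' columns")
  idx <- landmarks$node_index
  if (any(idx < 1L | idx > nrow(mesh$nodes)))
    stop("unknown landmark node index: ",
         idx[which(idx < 1L | idx > nrow(mesh$nodes))[1L]])
  if (!all(idx %in% mesh$boundary$surface))
    stop("landmark node ", setdiff(idx, mesh$boundary$surface)[1L],
         " is not a surface node")
  invisible(landmarks)
}

#' Extract landmark displacement traces
#'
#' Pulls the per-component displacement time series of each landmark from a
#' simulation result (an exact copy of the solver output at those nodes).
#' Landmarks on a displacement-fixed patch yield an identically zero trace
#' and a warning.
#'
#' @param result A \code{simulation_result}.
#' @param landmarks Data frame from [default_landmarks()] (or user-built,
#'   with \code{id} and \code{node_index}).
#' @return A named list (per landmark id) of data frames with columns
#'   \code{t, x, y, z} (s, m).
#' @export
landmark_series <- function(result, landmarks) {
  stopifnot(inherits(result, "simulation_result"))
  validate_landmarks(result$mesh, landmarks)
  fixed <- unique(unlist(result$mesh$boundary[result$config$fixed_patch]))
  out <- list()
  for (r in seq_len(nrow(landmarks))) {
    node <- landmarks$node_index[r]
    if (node %in% fixed)
      warning("landmark ", landmarks$id[r],
              " sits on a displacement-fixed patch; trace is identically zero")
    out[[landmarks$id[r]]] <- data.frame(
      t = result$times,
      x = result$displacement[, node, 1L],
      y = result$displacement[, node, 2L],
      z = result$displacement[, node, 3L])
  }
  out
}

# samples of one cycle: rows of `trace` with t in [(cycle-1)T, cycle*T]
cycle_window <- function(t, w, cycle) {
  t0 <- w$phase_offset + (cycle - 1) * w$period
  which(t >= t0 - 1e-9 & t <= t0 + w$period + 1e-9)
}

#' Hysteresis lag of a displacement trace
#'
#' Time by which the within-cycle peak of |value| lags the mid-cycle peak of
#' the inlet drive.  The discrete peak is refined by a local quadratic fit
#' through the three samples around it; ties break toward the earliest peak.
#' A positive lag means the tissue peaks after the drive; a negative lag
#' means it leads.
#'
#' @param trace Data frame (or list) with \code{t} and \code{value} (any
#'   single displacement component, m), covering the requested cycle at a
#'   sampling step of at most period/40.
#' @param w The driving [waveform()].
#' @param cycle 1-based cycle index.
#' @return Lag in seconds, or \code{NA} for a flat (all-zero) trace.
#' @export
hysteresis_lag <- function(trace, w, cycle) {
  t <- trace$t
  v <- if (!is.null(trace$value)) trace$value else trace[[2L]]
  idx <- cycle_window(t, w, cycle)
  if (length(idx) < 5L)
    stop("trace does not cover cycle ", cycle)
  if (max(diff(t[idx])) > w$period / 40 + 1e-12)
    stop("sampling step too coarse for lag estimation (need <= period/40)")
  tt <- t[idx]
  av <- abs(v[idx])
  if (max(av) <= 0) return(NA_real_)
  pk <- which(av == max(av))[1L]          # earliest on ties
  t_peak <- quadratic_peak(tt, av, pk)
  t_peak - drive_peak_time(w, cycle)
}

# vertex of the parabola through the 3 samples around the discrete peak
quadratic_peak <- function(tt, av, pk) {
  if (pk == 1L || pk == length(av)) return(tt[pk])
  y1 <- av[pk - 1L]; y2 <- av[pk]; y3 <- av[pk + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps * max(abs(c(y1, y2, y3)), 1))
    return(tt[pk])
  h <- (tt[pk + 1L] - tt[pk - 1L]) / 2
  delta <- 0.5 * (y1 - y3) / denom
  tt[pk] + max(-1, min(1, delta)) * h
}

#' Cross-correlation lag of a trace against the drive
#'
#' Secondary, robustness-oriented lag estimate: the shift (within a half
#' period) maximizing the correlation between the within-cycle trace and
#' the drive waveform, on a resampled uniform grid.
#'
#' @inheritParams hysteresis_lag
#' @return Lag in seconds (positive = trace delayed), or \code{NA} for a
#'   flat trace.
#' @export
xcorr_lag <- function(trace, w, cycle) {
  t <- trace$t
  v <- if (!is.null(trace$value)) trace$value else trace[[2L]]
  idx <- cycle_window(t, w, cycle)
  tt <- t[idx]; vv <- v[idx]
  if (max(abs(vv)) <= 0) return(NA_real_)
  m <- 200L
  tg <- seq(tt[1L], tt[length(tt)], length.out = m)
  vg <- stats::approx(tt, vv, xout = tg)$y
  vg <- vg - mean(vg)
  shifts <- seq(-w$period / 2, w$period / 2, by = w$period / 400)
  best <- vapply(shifts, function(s) {
    dg <- waveform_value(w, tg - s)
    dg <- dg - mean(dg)
    sum(vg * dg)
  }, numeric(1))
  shifts[which.max(best)]
}

#' Cycle-stability index of a displacement trace
#'
#' Smallest cycle index c such that the peak |value| of every later cycle
#' stays within a relative tolerance of cycle c's peak — the cycle after
#' which the breathing pattern has stabilized.
#'
#' @param trace Data frame with \code{t} and \code{value}.
#' @param w The driving [waveform()].
#' @param rel_tol Relative tolerance, default 0.05.
#' @return Integer cycle index, or \code{NA} if the trace never stabilizes.
#' @export
cycle_stability <- function(trace, w, rel_tol = 0.05) {
  t <- trace$t
  v <- if (!is.null(trace$value)) trace$value else trace[[2L]]
  ncyc <- floor((max(t) - w$phase_offset) / w$period + 1e-9)
  if (ncyc < 3L) stop("cycle_stability needs at least 3 full cycles")
  peaks <- vapply(seq_len(ncyc), function(cyc) {
    max(abs(v[cycle_window(t, w, cyc)]))
  }, numeric(1))
  for (cyc in seq_len(ncyc)) {
    ref <- peaks[cyc]
    later <- peaks[cyc:ncyc]
    dev <- if (ref > 0) abs(later - ref) / ref else abs(later)
    if (all(dev < rel_tol)) return(cyc)
  }
  NA_integer_
}

#' Trajectory loop-closure gap between consecutive cycles
#'
#' Resamples the 3D landmark trajectory of each pair of consecutive cycles
#' at matched cycle phases and returns the maximum pointwise distance — a
#' direct measure of how far the motion loops are from coinciding
#' (hysteresis path non-closure).
#'
#' @param trace3d Data frame with \code{t, x, y, z}.
#' @param w The driving [waveform()].
#' @param n_phase Number of matched phase samples, default 200.
#' @return Numeric vector of per-pair gaps (m), named "c1-c2", ....
#' @export
trajectory_loop_gap <- function(trace3d, w, n_phase = 200L) {
  t <- trace3d$t
  ncyc <- floor((max(t) - w$phase_offset) / w$period + 1e-9)
  if (ncyc < 2L) stop("loop gap needs at least 2 full cycles")
  phases <- seq(0, 1, length.out = n_phase)
  resample <- function(cyc) {
    t0 <- w$phase_offset + (cyc - 1) * w$period
    tq <- t0 + phases * w$period
    vapply(c("x", "y", "z"), function(comp)
      stats::approx(t, trace3d[[comp]], xout = tq)$y, numeric(n_phase))
  }
  loops <- lapply(seq_len(ncyc), resample)
  gaps <- vapply(seq_len(ncyc - 1L), function(cyc) {
    d <- loops[[cyc]] - loops[[cyc + 1L]]
    max(sqrt(rowSums(d^2)))
  }, numeric(1))
  names(gaps) <- paste0("c", seq_len(ncyc - 1L), "-c", 2:ncyc)
  gaps
}

#' Super-cycle periodicity of per-cycle peaks
#'
#' Detects a long-period modulation of the breathing response: the per-cycle
#' peak magnitudes are autocorrelated, and the dominant lag (in cycles) is
#' returned as a period in seconds when its autocorrelation exceeds the
#' significance threshold.  Constant per-cycle peaks (no modulation) give
#' \code{NA}.
#'
#' @param trace Data frame with \code{t} and \code{value}.
#' @param w The driving [waveform()].
#' @param threshold Minimum normalized autocorrelation, default 0.3.
#' @return Period in seconds, or \code{NA} when no significant super-period
#'   exists.
#' @export
long_periodicity <- function(trace, w, threshold = 0.3) {
  t <- trace$t
  v <- if (!is.null(trace$value)) trace$value else trace[[2L]]
  ncyc <- floor((max(t) - w$phase_offset) / w$period + 1e-9)
  if (ncyc < 8L) stop("long_periodicity needs at least 8 full cycles")
  peaks <- vapply(seq_len(ncyc), function(cyc)
    max(abs(v[cycle_window(t, w, cyc)])), numeric(1))
  x <- peaks - mean(peaks)
  s2 <- sum(x^2)
  if (s2 < .Machine$double.eps * max(peaks, 1)^2) return(NA_real_)
  max_lag <- floor(ncyc / 2)
  ac <- vapply(seq_len(max_lag), function(l)
    sum(x[seq_len(ncyc - l)] * x[(l + 1):ncyc]) / s2, numeric(1))
  best <- which.max(ac)
  if (ac[best] < threshold) return(NA_real_)
  best * w$period
}

#' Target deformation error (TDE)
#'
#' Landmark-wise Euclidean distance between predicted and reference
#' displacement vectors at one breathing phase, summarized by its mean and
#' maximum over landmarks.  Symmetric in its arguments and satisfying the
#' triangle inequality landmark-wise.
#'
#' @param predicted,reference Landmark x 3 matrices (mm) of displacement
#'   vectors, same shape.
#' @return A one-row data frame with \code{mean_tde} and \code{max_tde}
#'   (mm).
#' @export
compute_tde <- function(predicted, reference) {
  predicted <- as.matrix(predicted)
  reference <- as.matrix(reference)
  if (!identical(dim(predicted), dim(reference)))
    stop("'predicted' and 'reference' must have identical shape")
  if (ncol(predicted) != 3L) stop("displacement matrices must have 3 columns")
  d <- sqrt(rowSums((predicted - reference)^2))
  data.frame(mean_tde = mean(d), max_tde = max(d))
}

#' Full hysteresis report for a simulation
#'
#' Per landmark and component: the per-cycle interpolated peak displacement
#' and hysteresis lag (with a cross-correlation lag as the robustness
#' cross-check); per landmark: the consecutive-cycle trajectory loop gaps,
#' the cycle-stability index of the displacement magnitude, and — when at
#' least 8 cycles are available — the super-cycle period.
#'
#' @param result A \code{simulation_result} driven by a [waveform()].
#' @param landmarks Landmark data frame; default [default_landmarks()] of
#'   the result's mesh.
#' @param rel_tol Stability tolerance, see [cycle_stability()].
#' @return An object of class \code{hysteresis_report}: list with data
#'   frames \code{components} (landmark x component x cycle rows) and
#'   \code{landmarks} (per-landmark summaries).
#' @export
hysteresis_report <- function(result, landmarks = default_landmarks(result$mesh),
                              rel_tol = 0.05) {
  stopifnot(inherits(result, "simulation_result"))
  w <- result$waveform
  if (is.null(w)) stop("hysteresis analysis requires a waveform-driven run")
  traces <- suppressWarnings(landmark_series(result, landmarks))
  ncyc <- floor((max(result$times) - w$phase_offset) / w$period + 1e-9)
  comp_rows <- list()
  lm_rows <- list()
  for (id in names(traces)) {
    tr <- traces[[id]]
    for (comp in c("x", "y", "z")) {
      sub <- data.frame(t = tr$t, value = tr[[comp]])
      for (cyc in seq_len(ncyc)) {
        win <- cycle_window(tr$t, w, cyc)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          landmark = id, component = comp, cycle = cyc,
          peak_displacement = max(abs(sub$value[win])),
          lag = hysteresis_lag(sub, w, cyc),
          xcorr_lag = xcorr_lag(sub, w, cyc))
      }
    }
    mag <- data.frame(t = tr$t, value = sqrt(tr$x^2 + tr$y^2 + tr$z^2))
    gaps <- if (ncyc >= 2L) trajectory_loop_gap(tr, w) else numeric(0)
    lm_rows[[length(lm_rows) + 1L]] <- data.frame(
      landmark = id,
      node_index = landmarks$node_index[match(id, landmarks$id)],
      peak_magnitude = max(mag$value),
      stabilization_cycle = if (ncyc >= 3L) cycle_stability(mag, w, rel_tol)
                            else NA_integer_,
      max_loop_gap = if (length(gaps)) max(gaps) else NA_real_,
      final_loop_gap = if (length(gaps)) gaps[length(gaps)] else NA_real_,
      long_period = if (ncyc >= 8L) long_periodicity(mag, w) else NA_real_)
  }
  structure(list(components = do.call(rbind, comp_rows),
                 landmarks = do.call(rbind, lm_rows),
                 n_cycles = ncyc, waveform = w),
            class = "hysteresis_report")
}

#' @export
print.hysteresis_report <- function(x, ...) {
  cat("Hysteresis report over", x$n_cycles, "breathing cycles\n")
  last <- x$components[x$components$cycle == x$n_cycles, ]
  cat("Final-cycle per-component lags (s):\n")
  print(stats::reshape(last[, c("landmark", "component", "lag")],
                       idvar = "landmark", timevar = "component",
                       direction = "wide"), row.names = FALSE)
  cat("Per-landmark summary:\n")
  print(x$landmarks, row.names = FALSE, digits = 4)
  invisible(x)
}
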