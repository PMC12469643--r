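# RMSD time series, plateau-based segment selection, per-residue RMSF.

#' Backbone RMSD time series
#'
#' Per-frame best-fit (superposed) RMSD of the backbone heavy atoms of the
#' chosen residues against a reference structure.
#'
#' @param traj an \code{md_traj} object.
#' @param reference \code{"first"} (frame 1), \code{"mean"} (mean structure
#'   after superposition onto frame 1), or a numeric xyz vector.
#' @param selection residues over which the RMSD is computed (ranges string,
#'   numeric vector, or NULL for all); backbone heavy atoms N, CA, C, O.
#' @return Data frame with columns \code{time_ns} and \code{rmsd} (Angstrom).
#' @export
compute_rmsd_series <- function(traj, reference = "first", selection = NULL) {
  stopifnot(inherits(traj, "md_traj"))
  inds <- .rigid_xyz_inds(traj$pdb, selection)
  xyz <- traj$xyz
  ref <- if (is.numeric(reference)) {
    reference
  } else if (identical(reference, "first")) {
    xyz[1, ]
  } else if (identical(reference, "mean")) {
    colMeans(suppressWarnings(
      bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                     fixed.inds = inds, mobile.inds = inds)))
  } else stop("'reference' must be \"first\", \"mean\", or an xyz vector")
  r <- suppressWarnings(
    bio3d::rmsd(ref, xyz, a.inds = inds, b.inds = inds, fit = TRUE))
  data.frame(time_ns = traj$times_ns, rmsd = as.numeric(r))
}

#' Detect RMSD plateau segments
#'
#' Scans an RMSD time series with a sliding window and flags windows that
#' behave like a conformational plateau: the RMSD standard deviation within
#' the window is at most \code{sd_max} and no frame-to-frame jump exceeds
#' \code{jump_max}.  Overlapping candidate windows are merged into plateau
#' regions; each merged region is reported with its earliest start.  An
#' equilibration prefix can be excluded.
#'
#' @param series data frame with \code{time_ns} and \code{rmsd} columns (as
#'   from \code{\link{compute_rmsd_series}}).
#' @param window_ns window length in ns (default 500, the segment length
#'   used for back-calculation).
#' @param sd_max maximum within-window RMSD standard deviation, Angstrom
#'   (default 0.3).
#' @param jump_max maximum frame-to-frame RMSD jump within a window,
#'   Angstrom (default 1.0).
#' @param equil_ns equilibration cutoff in ns; windows starting earlier are
#'   not considered (default 0; use e.g. 700 for full production runs).
#' @param stride_ns scan stride in ns (default: one frame).
#' @return Data frame of merged plateau regions with columns \code{start_ns},
#'   \code{end_ns}, \code{rmsd_mean}, \code{rmsd_sd}, \code{label}, plus the
#'   detection thresholds as attributes \code{"window_ns"}, \code{"sd_max"},
#'   \code{"jump_max"}.  Candidate windows (all exactly \code{window_ns}
#'   long) are attached as attribute \code{"windows"}.  Empty when no window
#'   qualifies.
#' @export
detect_plateau_segments <- function(series, window_ns = 500, sd_max = 0.3,
                                    jump_max = 1.0, equil_ns = 0,
                                    stride_ns = NULL) {
  stopifnot(is.data.frame(series),
            all(c("time_ns", "rmsd") %in% names(series)))
  t <- series$time_ns; r <- series$rmsd
  dt <- if (length(t) > 1) t[2] - t[1] else stop("series too short")
  if (max(t) - min(t) < window_ns)
    stop("series duration (", max(t) - min(t),
         " ns) is shorter than the window (", window_ns, " ns)")
  wlen <- round(window_ns / dt)            # frames per window (end-exclusive)
  stride <- if (is.null(stride_ns)) 1L else max(1L, round(stride_ns / dt))
  n <- length(r)
  starts <- seq(1L, n - wlen, by = stride)
  starts <- starts[t[starts] >= equil_ns]
  ok <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; idx <- s:(s + wlen)
    w <- r[idx]
    ok[i] <- stats::sd(w) <= sd_max && max(abs(diff(w))) <= jump_max
  }
  empty <- data.frame(start_ns = numeric(0), end_ns = numeric(0),
                      rmsd_mean = numeric(0), rmsd_sd = numeric(0),
                      label = character(0))
  windows <- if (any(ok))
    data.frame(start_ns = t[starts[ok]], end_ns = t[starts[ok] + wlen])
  else empty[0, 1:2]
  if (!any(ok)) {
    out <- empty
  } else {
    # merge overlapping/adjacent candidate windows into plateau regions
    sel <- starts[ok]
    gaps <- which(diff(sel) > wlen)          # break where windows disjoint
    grp_start <- c(1L, gaps + 1L)
    grp_end <- c(gaps, length(sel))
    out <- do.call(rbind, lapply(seq_along(grp_start), function(g) {
      s0 <- sel[grp_start[g]]
      s1 <- sel[grp_end[g]] + wlen
      idx <- s0:s1
      data.frame(start_ns = t[s0], end_ns = t[s1],
                 rmsd_mean = mean(r[idx]), rmsd_sd = stats::sd(r[idx]),
                 label = sprintf("plateau_%d", g))
    }))
  }
  attr(out, "window_ns") <- window_ns
  attr(out, "sd_max") <- sd_max
  attr(out, "jump_max") <- jump_max
  attr(out, "windows") <- windows
  out
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of each residue about its mean position in
#' an aligned trajectory, averaged over the selected atoms (default: the
#' C-alpha atom).
#'
#' @param traj an aligned \code{md_traj} object (see
#'   \code{\link{align_trajectory}}).
#' @param elety atom names over which to average (default \code{"CA"}).
#' @param unit \code{"angstrom"} (default) or \code{"nm"}.
#' @return Data frame with columns \code{residue} and \code{rmsf}.
#' @export
compute_rmsf <- function(traj, elety = "CA", unit = c("angstrom", "nm")) {
  stopifnot(inherits(traj, "md_traj"))
  unit <- match.arg(unit)
  sel <- bio3d::atom.select(traj$pdb, elety = elety, verbose = FALSE)
  if (length(sel$atom) == 0) stop("atom selection '", elety, "' is empty")
  f <- bio3d::rmsf(traj$xyz[, sel$xyz, drop = FALSE])
  resno <- traj$pdb$atom$resno[sel$atom]
  agg <- tapply(f, resno, mean)
  out <- data.frame(residue = as.integer(names(agg)),
                    rmsf = as.numeric(agg))
  out <- out[order(out$residue), , drop = FALSE]
  if (unit == "nm") out$rmsf <- out$rmsf / 10
  rownames(out) <- NULL
  out
}
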