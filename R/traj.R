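# Trajectory handling: reading, alignment, N-H vector extraction.
# Coordinates are handled as bio3d xyz matrices (frames x 3*natoms, Angstrom).

#' Read an MD trajectory
#'
#' Loads a topology PDB and, optionally, coordinates from a DCD file or a
#' multi-model PDB.  When \code{traj} is \code{NULL} and the topology itself
#' contains multiple MODEL records, those models are the frames.
#'
#' @param top path to the topology PDB.
#' @param traj optional path to coordinates: a \code{.dcd} file or a
#'   multi-model PDB.  XTC/TRR are not supported; convert to DCD or PDB
#'   upstream.
#' @param dt_ns time step between stored frames, in ns.
#' @return An object of class \code{md_traj}: list with \code{pdb} (bio3d
#'   pdb object), \code{xyz} (frames x 3N matrix, Angstrom), \code{dt_ns},
#'   and \code{times_ns}.
#' @export
read_trajectory <- function(top, traj = NULL, dt_ns = 1) {
  if (!file.exists(top)) stop("topology file not found: ", top)
  pdb <- bio3d::read.pdb(top, multi = TRUE)
  if (is.null(traj)) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    if (!file.exists(traj)) stop("trajectory file not found: ", traj)
    if (grepl("\\.dcd$", traj, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(traj, verbose = FALSE)
    } else if (grepl("\\.(pdb|ent)$", traj, ignore.case = TRUE)) {
      xyz <- bio3d::read.pdb(traj, multi = TRUE)$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    } else {
      stop("unsupported trajectory format (use DCD or multi-model PDB): ",
           traj)
    }
    if (ncol(xyz) != 3 * nrow(pdb$atom))
      stop("trajectory atom count (", ncol(xyz) / 3,
           ") does not match topology (", nrow(pdb$atom), ")")
  }
  structure(list(pdb = pdb, xyz = unclass(xyz), dt_ns = dt_ns,
                 times_ns = (seq_len(nrow(xyz)) - 1) * dt_ns),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("MD trajectory: %d frames x %d atoms, dt = %g ns (%.4g ns)\n",
              nrow(x$xyz), ncol(x$xyz) / 3, x$dt_ns,
              x$dt_ns * (nrow(x$xyz) - 1)))
  invisible(x)
}

# Parse residue ranges given as "131-152,162-193", a numeric vector of
# residue numbers, or a list of c(start, end) pairs.
.parse_ranges <- function(ranges) {
  if (is.null(ranges)) return(NULL)
  if (is.numeric(ranges)) return(sort(unique(as.integer(ranges))))
  if (is.list(ranges))
    return(sort(unique(unlist(lapply(ranges, function(r)
      seq(r[1], r[2]))))))
  if (is.character(ranges)) {
    parts <- unlist(strsplit(paste(ranges, collapse = ","), ","))
    parts <- trimws(parts[nzchar(trimws(parts))])
    out <- unlist(lapply(parts, function(p) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (anyNA(ab)) stop("cannot parse residue range: '", p, "'")
      if (length(ab) == 1) ab else seq(ab[1], ab[2])
    }))
    return(sort(unique(out)))
  }
  stop("'ranges' must be a string like \"131-152,162-193\", a numeric ",
       "vector, or a list of c(start, end) pairs")
}

# xyz indices of backbone heavy atoms (N, CA, C, O) of the given residues
.rigid_xyz_inds <- function(pdb, rigid_ranges) {
  resnos <- .parse_ranges(rigid_ranges)
  sel <- if (is.null(resnos))
    bio3d::atom.select(pdb, elety = c("N", "CA", "C", "O"), verbose = FALSE)
  else
    bio3d::atom.select(pdb, elety = c("N", "CA", "C", "O"), resno = resnos,
                       verbose = FALSE)
  if (length(sel$atom) < 3)
    stop("rigid-range selection yields fewer than 3 atoms")
  sel$xyz
}

#' Align trajectory frames onto the mean structure
#'
#' Least-squares (Kabsch) superposition of every frame onto the iterated
#' mean structure, using the backbone heavy atoms (N, CA, CO carbon, O) of
#' the configured rigid residue ranges.  Two passes are performed: frames
#' are first superposed onto the first frame, the mean structure of that
#' pass is computed, and all frames are re-superposed onto the mean.  This
#' removes overall rotation and translation so that the remaining N-H
#' vector motion is internal.
#'
#' @param traj an \code{md_traj} object.
#' @param rigid_ranges residues whose backbone heavy atoms define the
#'   superposition, e.g. \code{"131-152,162-193"}; \code{NULL} uses all
#'   residues.
#' @return The aligned \code{md_traj}.
#' @export
align_trajectory <- function(traj, rigid_ranges = NULL) {
  stopifnot(inherits(traj, "md_traj"))
  inds <- .rigid_xyz_inds(traj$pdb, rigid_ranges)
  xyz <- traj$xyz
  # suppressWarnings: bio3d's Kabsch eigendecomposition emits benign NaN
  # warnings from sqrt() round-off on degenerate eigenvalues
  fit1 <- suppressWarnings(
    bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                   fixed.inds = inds, mobile.inds = inds))
  mean_xyz <- colMeans(fit1)
  fit2 <- suppressWarnings(
    bio3d::fit.xyz(fixed = mean_xyz, mobile = fit1,
                   fixed.inds = inds, mobile.inds = inds))
  traj$xyz <- unclass(fit2)
  traj
}

#' Extract backbone N-H unit vectors
#'
#' For every residue with both a backbone nitrogen and an amide proton
#' (atom name \code{H} or \code{HN}), computes the normalized N-to-H vector
#' in every frame.  Prolines and residues lacking an amide proton (e.g. the
#' N-terminus) are skipped and reported.
#'
#' @param traj an (aligned) \code{md_traj} object.
#' @return An object of class \code{nh_vectors}: list with \code{vectors}
#'   (array frames x 3 x residues), \code{residues} (residue numbers),
#'   \code{resid} (residue names), \code{dt_ns}, and \code{skipped} (data
#'   frame of skipped residues with reasons).
#' @export
extract_nh_vectors <- function(traj) {
  stopifnot(inherits(traj, "md_traj"))
  at <- traj$pdb$atom
  key <- paste(at$chain, at$resno, sep = ":")
  res_keys <- unique(key)
  n_frames <- nrow(traj$xyz)
  vec_list <- list(); res_ids <- integer(0); res_names <- character(0)
  skipped <- data.frame(residue = integer(0), resid = character(0),
                        reason = character(0))
  for (rk in res_keys) {
    rows <- which(key == rk)
    resno <- at$resno[rows[1]]
    resid <- at$resid[rows[1]]
    if (identical(resid, "PRO")) {
      skipped <- rbind(skipped, data.frame(residue = resno, resid = resid,
                                           reason = "proline"))
      next
    }
    i_n <- rows[at$elety[rows] == "N"]
    i_h <- rows[at$elety[rows] %in% c("H", "HN")]
    if (length(i_n) != 1 || length(i_h) != 1) {
      skipped <- rbind(skipped, data.frame(residue = resno, resid = resid,
                                           reason = "no amide N-H pair"))
      next
    }
    nx <- traj$xyz[, 3 * (i_n - 1) + 1:3, drop = FALSE]
    hx <- traj$xyz[, 3 * (i_h - 1) + 1:3, drop = FALSE]
    v <- hx - nx
    nv <- sqrt(rowSums(v^2))
    if (any(!is.finite(nv)) || any(nv == 0))
      stop("degenerate N-H geometry in residue ", resno)
    vec_list[[length(vec_list) + 1]] <- v / nv
    res_ids <- c(res_ids, resno)
    res_names <- c(res_names, resid)
  }
  if (length(vec_list) == 0) stop("no residues with extractable N-H vectors")
  vectors <- array(NA_real_, dim = c(n_frames, 3, length(vec_list)))
  for (j in seq_along(vec_list)) vectors[, , j] <- vec_list[[j]]
  structure(list(vectors = vectors, residues = res_ids, resid = res_names,
                 dt_ns = traj$dt_ns, skipped = skipped),
            class = "nh_vectors")
}

#' @export
print.nh_vectors <- function(x, ...) {
  cat(sprintf("N-H unit vectors: %d residues x %d frames (dt = %g ns)\n",
              dim(x$vectors)[3], dim(x$vectors)[1], x$dt_ns))
  if (nrow(x$skipped) > 0)
    cat("  skipped:", paste0(x$skipped$residue, " (", x$skipped$reason, ")",
                             collapse = ", "), "\n")
  invisible(x)
}
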