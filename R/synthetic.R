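# Synthetic-data generators with analytic ground truth: restricted-diffusion
# N-H vector trajectories, noisy relaxation tables, intensity decay series.

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# rotation matrix about unit axis u by angle a (Rodrigues)
.rot_axis <- function(u, a) {
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

.normalize <- function(v) v / sqrt(sum(v^2))

#' Analytic order parameter of diffusion in a cone
#'
#' For a vector diffusing uniformly within a cone of semi-angle
#' \eqn{\theta_0}, \eqn{S^2 = [\cos\theta_0 (1+\cos\theta_0)/2]^2}.
#'
#' @param theta0_deg cone semi-angle in degrees, in (0, 90].
#' @return The order parameter \eqn{S^2}.
#' @examples
#' cone_s2(60)   # 0.140625
#' @export
cone_s2 <- function(theta0_deg) {
  if (any(theta0_deg <= 0 | theta0_deg > 90))
    stop("cone semi-angle must lie in (0, 90] degrees")
  ct <- cos(theta0_deg * pi / 180)
  (ct * (1 + ct) / 2)^2
}

#' Analytic order parameter of a two-site jump
#'
#' For exchange between two orientations separated by angle \eqn{\beta}
#' with equal populations, \eqn{S^2 = (1 + P_2(\cos\beta))/2}.
#'
#' @param angle_deg jump angle in degrees.
#' @return The order parameter \eqn{S^2}.
#' @export
jump_s2 <- function(angle_deg) {
  cb <- cos(angle_deg * pi / 180)
  (1 + (3 * cb^2 - 1) / 2) / 2
}

# One cone-diffusion path: Metropolis random walk inside the cone.  The
# spherical-Gaussian proposal depends only on the angle between current and
# proposed vector, hence is symmetric; rejecting proposals outside the cone
# leaves the uniform distribution on the spherical cap exactly invariant,
# so the long-run order parameter equals the analytic cone S2 with no
# step-size discretization bias (step size only sets the mixing time, i.e.
# the effective internal correlation time).
.walk_cone <- function(n_frames, theta0, step_sd, axis = c(0, 0, 1)) {
  V <- matrix(NA_real_, n_frames, 3)
  v <- .normalize(axis + c(1e-3, 0, 0))   # start just off the axis
  steps <- matrix(stats::rnorm(3 * n_frames, sd = step_sd), n_frames, 3)
  cos_t0 <- cos(theta0)
  for (i in seq_len(n_frames)) {
    prop <- .normalize(v + steps[i, ])
    if (sum(prop * axis) >= cos_t0) v <- prop
    V[i, ] <- v
  }
  V
}

# two-site jump path: Poisson switching between orientations
.walk_jump <- function(n_frames, angle, rate_per_frame, axis = c(0, 0, 1)) {
  v1 <- axis
  v2 <- as.numeric(.rot_axis(c(1, 0, 0), angle) %*% axis)
  state <- cumsum(c(0, stats::rbinom(n_frames - 1, 1,
                                     min(rate_per_frame, 1)))) %% 2
  V <- matrix(NA_real_, n_frames, 3)
  V[state == 0, ] <- matrix(v1, sum(state == 0), 3, byrow = TRUE)
  V[state == 1, ] <- matrix(v2, sum(state == 1), 3, byrow = TRUE)
  V
}

#' Simulate N-H unit-vector trajectories with known ground truth
#'
#' Generates per-residue unit-vector paths under simple internal-motion
#' models, optionally superimposed on isotropic overall tumbling.  Models:
#' \describe{
#'   \item{rigid}{a static vector; \eqn{S^2 = 1}.}
#'   \item{cone}{Metropolis angular random walk inside a cone of semi-angle
#'     \code{theta0_deg} (proposals leaving the cone are rejected; the
#'     stationary distribution is exactly uniform on the cap, so the
#'     analytic \eqn{S^2} of \code{\link{cone_s2}} applies); \code{step_sd}
#'     sets the per-frame angular step and thereby the effective internal
#'     correlation time, which has no closed form and is calibrated
#'     numerically from the fitted ACF when needed.}
#'   \item{jump}{two-site jump by \code{angle_deg} with per-frame switching
#'     probability \code{rate}; \eqn{S^2} from \code{\link{jump_s2}}.}
#' }
#' Overall tumbling multiplies all residue vectors by a common random-walk
#' rotation with per-frame angular variance \eqn{2 D_r \Delta t} per axis,
#' \eqn{D_r = 1/(6\tau_c)}.
#'
#' @param models list of per-residue model specs, each a list with element
#'   \code{type} ("rigid", "cone", or "jump") and model parameters
#'   (\code{theta0_deg}, \code{step_sd}; \code{angle_deg}, \code{rate}).
#' @param n_frames number of frames.
#' @param dt_ns frame spacing in ns (default 0.001, i.e. 1 ps).
#' @param tumbling \code{NA} (none) or an overall correlation time tau_c in
#'   seconds for isotropic tumbling.
#' @param seed RNG seed (required).
#' @return An \code{nh_vectors} object with attribute \code{"truth"}: data
#'   frame of per-residue \code{model} and analytic \code{s2}.
#' @examples
#' v <- simulate_nh_vectors(list(list(type = "cone", theta0_deg = 60,
#'                                    step_sd = 0.05)),
#'                          n_frames = 2000, seed = 1)
#' attr(v, "truth")$s2
#' @export
simulate_nh_vectors <- function(models, n_frames, dt_ns = 0.001,
                                tumbling = NA, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  stopifnot(is.list(models), length(models) >= 1, n_frames >= 2)
  .with_seed(seed, {
    nres <- length(models)
    vectors <- array(NA_real_, dim = c(n_frames, 3, nres))
    s2 <- numeric(nres); types <- character(nres)
    for (j in seq_len(nres)) {
      m <- models[[j]]
      types[j] <- m$type
      if (m$type == "rigid") {
        ax <- .normalize(c(0.3, -0.2, 1))
        vectors[, , j] <- matrix(ax, n_frames, 3, byrow = TRUE)
        s2[j] <- 1
      } else if (m$type == "cone") {
        vectors[, , j] <- .walk_cone(n_frames, m$theta0_deg * pi / 180,
                                     m$step_sd)
        s2[j] <- cone_s2(m$theta0_deg)
      } else if (m$type == "jump") {
        vectors[, , j] <- .walk_jump(n_frames, m$angle_deg * pi / 180,
                                     m$rate)
        s2[j] <- jump_s2(m$angle_deg)
      } else stop("unknown model type: ", m$type)
    }
    if (!is.na(tumbling)) {
      dr <- 1 / (6 * tumbling)                       # rad^2/s per axis
      ang_sd <- sqrt(2 * dr * dt_ns * 1e-9)
      R <- diag(3)
      for (i in seq_len(n_frames)) {
        ax <- .normalize(stats::rnorm(3))
        R <- .rot_axis(ax, stats::rnorm(1, sd = ang_sd * sqrt(3))) %*% R
        vectors[i, , ] <- R %*% matrix(vectors[i, , ], nrow = 3)
      }
    }
    structure(list(vectors = vectors,
                   residues = seq_len(nres), resid = rep("ALA", nres),
                   dt_ns = dt_ns,
                   skipped = data.frame(residue = integer(0),
                                        resid = character(0),
                                        reason = character(0))),
              class = "nh_vectors",
              truth = data.frame(residue = seq_len(nres), model = types,
                                 s2 = s2))
  })
}

#' Write a synthetic trajectory realizing given N-H vectors
#'
#' Builds a poly-alanine-like backbone (N, CA, C, O, H per residue, spaced
#' along x) in which each residue's N-H geometry reproduces the supplied
#' unit vectors, and writes a topology PDB plus a multi-model PDB
#' trajectory readable by \code{\link{read_trajectory}}.  Optionally applies
#' a rigid whole-body rotation ramp to every frame, which
#' \code{\link{align_trajectory}} must remove.  Residues listed in
#' \code{prolines} are written as PRO without an amide proton (exercising
#' the extraction skip list).
#'
#' @param vec an \code{nh_vectors} object (e.g. from
#'   \code{\link{simulate_nh_vectors}}).
#' @param out_prefix path prefix; writes \code{<prefix>_top.pdb} and
#'   \code{<prefix>_traj.pdb}.
#' @param rotate logical: apply a whole-body rotation (default FALSE).
#' @param prolines residue indices to emit as proline (default none).
#' @return Invisibly, a list with \code{top} and \code{traj} paths.
#' @export
build_synthetic_trajectory_files <- function(vec, out_prefix,
                                             rotate = FALSE,
                                             prolines = integer(0)) {
  stopifnot(inherits(vec, "nh_vectors"))
  n_frames <- dim(vec$vectors)[1]
  nres <- dim(vec$vectors)[3]
  spacing <- 6.0; r_nh <- 1.02
  base <- list(N = c(0, 0, 0), CA = c(1.45, 0, 0), C = c(2.4, 1.1, 0),
               O = c(2.1, 2.28, 0))
  atom_names <- function(j) {
    if (j %in% prolines) c("N", "CA", "C", "O") else c("N", "CA", "C", "O", "H")
  }
  coords_frame <- function(i) {
    M <- NULL
    for (j in seq_len(nres)) {
      off <- c((j - 1) * spacing, 0, 0)
      for (nm in atom_names(j)) {
        p <- if (nm == "H") base$N + r_nh * vec$vectors[i, , j] else base[[nm]]
        M <- rbind(M, p + off)
      }
    }
    if (rotate) {
      # steady whole-body rotation about a fixed skew axis
      R <- .rot_axis(.normalize(c(1, 2, 3)), 2 * pi * (i - 1) / n_frames)
      M <- M %*% t(R)
    }
    M
  }
  pdb_lines_frame <- function(i) {
    M <- coords_frame(i)
    lines <- character(nrow(M)); serial <- 0L
    for (j in seq_len(nres)) {
      resid <- if (j %in% prolines) "PRO" else "ALA"
      for (nm in atom_names(j)) {
        serial <- serial + 1L
        p <- M[serial, ]
        lines[serial] <- sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", nm), resid, "A", j, p[1], p[2], p[3],
          1.0, 0.0, substr(nm, 1, 1))
      }
    }
    lines
  }
  top <- paste0(out_prefix, "_top.pdb")
  traj <- paste0(out_prefix, "_traj.pdb")
  writeLines(c(pdb_lines_frame(1), "END"), top)
  con <- file(traj, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames))
    writeLines(c(sprintf("MODEL     %4d", i), pdb_lines_frame(i), "ENDMDL"),
               con)
  writeLines("END", con)
  invisible(list(top = top, traj = traj))
}

#' Synthetic per-residue relaxation table
#'
#' Forward-computes R1, NOE and eta_xy from per-residue simple Lipari-Szabo
#' ground truth (S2, tau_c) and adds Gaussian noise with matching error
#' columns, producing a table in the standard rates schema.
#'
#' @param s2 numeric vector of per-residue order parameters.
#' @param tau_c overall correlation time in seconds (scalar or per-residue).
#' @param k an \code{\link{interaction_constants}} object.
#' @param noise_pct relative noise (and reported error), in percent
#'   (default 0).
#' @param seed RNG seed (required when \code{noise_pct > 0}).
#' @param residues residue numbers (default \code{seq_along(s2)}).
#' @return Data frame with columns \code{residue}, \code{r1}, \code{r1_err},
#'   \code{noe}, \code{noe_err}, \code{eta_xy}, \code{eta_xy_err}, plus the
#'   truth columns \code{s2_true}, \code{tau_c_true_ns}.
#' @export
synth_relaxation_table <- function(s2, tau_c, k, noise_pct = 0, seed = NULL,
                                   residues = seq_along(s2)) {
  stopifnot(noise_pct >= 0)
  tau_c <- rep(tau_c, length.out = length(s2))
  r1 <- noe <- eta <- numeric(length(s2))
  for (i in seq_along(s2)) {
    p <- model_free_params(s2_fast = s2[i], tau_c = tau_c[i])
    r <- relaxation_rates(p, k)
    r1[i] <- r$r1; noe[i] <- r$noe; eta[i] <- r$eta_xy
  }
  if (noise_pct > 0) {
    if (is.null(seed)) stop("'seed' is required when noise_pct > 0")
    .with_seed(seed, {
      f <- noise_pct / 100
      r1 <- r1 * (1 + stats::rnorm(length(r1), sd = f))
      noe <- noe * (1 + stats::rnorm(length(noe), sd = f))
      eta <- eta * (1 + stats::rnorm(length(eta), sd = f))
    })
  }
  f <- noise_pct / 100
  data.frame(residue = residues,
             r1 = r1, r1_err = abs(r1) * f,
             noe = noe, noe_err = abs(noe) * f,
             eta_xy = eta, eta_xy_err = abs(eta) * f,
             s2_true = s2, tau_c_true_ns = tau_c * 1e9)
}

#' Synthetic peak-intensity decay series
#'
#' Generates the exponential intensity series underlying the rate
#' experiments: \code{mode = "r1"} gives \eqn{I(t) = I_0 e^{-R t}} on the
#' standard R1 delay grid; \code{mode = "eta"} gives the constant-time
#' modulation \eqn{I(\zeta) = e^{-4\eta\zeta}} on a symmetric zeta grid.
#'
#' @param rate decay rate in s^-1.
#' @param mode \code{"r1"} or \code{"eta"}.
#' @param delays delay grid in seconds; defaults to the standard lists
#'   (R1: 10...1444 ms; eta: -50...+50 ms).
#' @param noise_pct relative Gaussian noise in percent (default 0).
#' @param seed RNG seed (required when \code{noise_pct > 0}).
#' @param i0 amplitude (default 100).
#' @param ct_exponent_factor exponent factor for eta mode (default 4).
#' @return Data frame with columns \code{delay} and \code{intensity}.
#' @export
synth_intensity_series <- function(rate, mode = c("r1", "eta"),
                                   delays = NULL, noise_pct = 0,
                                   seed = NULL, i0 = 100,
                                   ct_exponent_factor = 4) {
  mode <- match.arg(mode)
  if (is.null(delays)) {
    delays <- if (mode == "r1")
      c(10, 90, 192, 260, 380, 480, 690, 980, 1220, 1444) / 1000
    else
      c(-0.05, -0.0375, -0.025, -0.0125, 0, 0.0125, 0.025, 0.0375, 0.05)
  }
  I <- if (mode == "r1") i0 * exp(-rate * delays)
       else i0 * exp(-ct_exponent_factor * rate * delays)
  if (noise_pct > 0) {
    if (is.null(seed)) stop("'seed' is required when noise_pct > 0")
    I <- .with_seed(seed,
                    I * (1 + stats::rnorm(length(I), sd = noise_pct / 100)))
  }
  data.frame(delay = delays, intensity = I)
}
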