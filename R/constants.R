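# Physical constants (CODATA 2018)
.GAMMA_H <- 2.6752218744e8   # 1H gyromagnetic ratio, rad s^-1 T^-1
.GAMMA_N <- -2.7126e7        # 15N gyromagnetic ratio, rad s^-1 T^-1 (negative)
.HBAR    <- 1.054571817e-34  # reduced Planck constant, J s
.MU0     <- 1.25663706212e-6 # vacuum permeability, N A^-2

#' Interaction constants for amide 15N relaxation
#'
#' Bundles the physical constants and interaction parameters that enter the
#' dipolar and chemical-shift-anisotropy (CSA) contributions to backbone
#' amide \eqn{^{15}}N relaxation: the gyromagnetic ratios of \eqn{^1}H and
#' \eqn{^{15}}N, the N-H bond length, the \eqn{^{15}}N CSA \eqn{\Delta\sigma},
#' its projection \eqn{\Delta\sigma P_2(\cos\theta)} onto the N-H vector (the
#' quantity that drives CSA/dipole-dipole cross-correlation), and the
#' spectrometer field expressed as the \eqn{^1}H frequency.
#'
#' Larmor angular frequencies are derived as \eqn{\omega_H = 2\pi\nu_H} and
#' \eqn{\omega_N = \omega_H \gamma_N/\gamma_H}; all spectral densities are
#' evaluated at magnitudes of (combinations of) these frequencies, so the
#' stored \code{omega_H}, \code{omega_N} are positive.  The dipolar coupling
#' constant \eqn{d = (\mu_0/4\pi)\,\hbar\,\gamma_H\gamma_N / r_{NH}^3} is
#' precomputed (stored as a magnitude, in rad/s).
#'
#' @param field_mhz spectrometer \eqn{^1}H frequency in MHz (default 600.13).
#' @param r_nh N-H bond length in Angstrom (default 1.023).
#' @param delta_sigma \eqn{^{15}}N CSA in ppm (default -166).
#' @param delta_sigma_p2 CSA projected on the N-H vector,
#'   \eqn{\Delta\sigma P_2(\cos\theta)}, in ppm (default -145).
#'
#' @return An object of class \code{interaction_constants}: a list with the
#'   inputs plus \code{gamma_H}, \code{gamma_N} (rad s^-1 T^-1),
#'   \code{omega_H}, \code{omega_N} (rad/s, magnitudes), and \code{d_dip}
#'   (rad/s, magnitude).
#' @examples
#' k <- interaction_constants(field_mhz = 600.13)
#' k$omega_N / (2 * pi) / 1e6   # 15N frequency, MHz
#' @export
interaction_constants <- function(field_mhz = 600.13, r_nh = 1.023,
                                  delta_sigma = -166, delta_sigma_p2 = -145) {
  if (!is.numeric(field_mhz) || field_mhz <= 0)
    stop("'field_mhz' must be a positive number")
  if (!is.numeric(r_nh) || r_nh <= 0)
    stop("'r_nh' must be a positive bond length in Angstrom")
  omega_H <- 2 * pi * field_mhz * 1e6
  omega_N <- omega_H * abs(.GAMMA_N / .GAMMA_H)
  r_m <- r_nh * 1e-10
  d_dip <- (.MU0 / (4 * pi)) * .HBAR * abs(.GAMMA_H * .GAMMA_N) / r_m^3
  structure(list(
    field_mhz      = field_mhz,
    r_nh           = r_nh,
    delta_sigma    = delta_sigma,
    delta_sigma_p2 = delta_sigma_p2,
    gamma_H        = .GAMMA_H,
    gamma_N        = .GAMMA_N,
    omega_H        = omega_H,
    omega_N        = omega_N,
    d_dip          = d_dip
  ), class = "interaction_constants")
}

#' @export
print.interaction_constants <- function(x, ...) {
  cat("Amide 15N relaxation interaction constants\n")
  cat(sprintf("  field:            %.2f MHz (1H); 15N %.2f MHz\n",
              x$field_mhz, x$omega_N / (2 * pi) / 1e6))
  cat(sprintf("  r(N-H):           %.3f A\n", x$r_nh))
  cat(sprintf("  CSA:              %.0f ppm;  CSA.P2(cos theta): %.0f ppm\n",
              x$delta_sigma, x$delta_sigma_p2))
  cat(sprintf("  dipolar constant: %.4g rad/s\n", x$d_dip))
  invisible(x)
}

# CSA frequency |omega_N * delta_sigma| in rad/s for a ppm value
.csa_omega <- function(k, ppm) k$omega_N * abs(ppm) * 1e-6
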