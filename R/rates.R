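#' Longitudinal relaxation rate R1
#'
#' Back-calculates the amide \eqn{^{15}}N longitudinal relaxation rate from a
#' spectral density:
#' \deqn{R_1 = \frac{d^2}{10}\left[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)\right] +
#'   \frac{2}{15}\omega_N^2\Delta\sigma^2 J(\omega_N)}
#' with dipolar constant \eqn{d = (\mu_0/4\pi)\hbar\gamma_H\gamma_N/r_{NH}^3}.
#' The spectral density uses the convention \eqn{J(0) = S^2\tau_c} (no 2/5
#' prefactor); the 2/5 is absorbed into the numerical factors shown.
#'
#' @param J spectral density: a function of omega (rad/s) returning seconds,
#'   or a \code{\link{model_free_params}} / \code{\link{multiexp_spectrum}}
#'   object.
#' @param k an \code{\link{interaction_constants}} object.
#' @return Rate in s^-1 (magnitude).
#' @examples
#' k <- interaction_constants()
#' rate_R1(model_free_params(s2_fast = 0.85, tau_c = 14.7e-9), k)
#' @export
rate_R1 <- function(J, k) {
  stopifnot(inherits(k, "interaction_constants"))
  Jf <- .as_J(J)
  wH <- k$omega_H; wN <- k$omega_N
  dip <- (k$d_dip^2 / 10) *
    (Jf(wH - wN) + 3 * Jf(wN) + 6 * Jf(wH + wN))
  csa <- (2 / 15) * .csa_omega(k, k$delta_sigma)^2 * Jf(wN)
  dip + csa
}

#' Transverse relaxation rate R2
#'
#' \deqn{R_2 = \frac{d^2}{20}\left[4J(0) + 3J(\omega_N) +
#'   J(\omega_H-\omega_N) + 6J(\omega_H) + 6J(\omega_H+\omega_N)\right] +
#'   \frac{\omega_N^2\Delta\sigma^2}{45}\left[4J(0) + 3J(\omega_N)\right]}
#'
#' @inheritParams rate_R1
#' @return Rate in s^-1 (magnitude).
#' @export
rate_R2 <- function(J, k) {
  stopifnot(inherits(k, "interaction_constants"))
  Jf <- .as_J(J)
  wH <- k$omega_H; wN <- k$omega_N
  dip <- (k$d_dip^2 / 20) *
    (4 * Jf(0) + 3 * Jf(wN) + Jf(wH - wN) + 6 * Jf(wH) + 6 * Jf(wH + wN))
  csa <- (.csa_omega(k, k$delta_sigma)^2 / 45) * (4 * Jf(0) + 3 * Jf(wN))
  dip + csa
}

#' Steady-state heteronuclear NOE
#'
#' \deqn{NOE = 1 + \frac{\gamma_H}{\gamma_N}\,\frac{d^2}{10\,R_1}
#'   \left[6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)\right]}
#' Because \eqn{\gamma_N < 0} the cross-relaxation term is negative for fast
#' internal motion; in the extreme-narrowing limit (dipolar-only relaxation)
#' the NOE tends to \eqn{1 + \gamma_H/(2\gamma_N) \approx -3.93}.
#'
#' @inheritParams rate_R1
#' @param r1 the R1 rate (s^-1) entering the denominator; computed from
#'   \code{J} and \code{k} when \code{NULL}.  Pass a dipolar-only R1 (CSA set
#'   to zero in \code{k}) to study the pure dipolar limit.
#' @return Dimensionless NOE (signed).
#' @export
rate_NOE <- function(J, k, r1 = NULL) {
  stopifnot(inherits(k, "interaction_constants"))
  Jf <- .as_J(J)
  if (is.null(r1)) r1 <- rate_R1(Jf, k)
  if (r1 <= 0) stop("'r1' must be positive")
  wH <- k$omega_H; wN <- k$omega_N
  sigma <- (k$d_dip^2 / 10) * (6 * Jf(wH + wN) - Jf(wH - wN))
  1 + (k$gamma_H / k$gamma_N) * sigma / r1
}

#' CSA/dipole-dipole transverse cross-correlated relaxation rate eta_xy
#'
#' Cross-correlation between the \eqn{^{15}}N CSA and the N-H dipolar
#' interaction, the R2-like observable free of chemical-exchange (Rex)
#' contributions:
#' \deqn{\eta_{xy} = \frac{1}{15}\, d\; \omega_N\,
#'   |\Delta\sigma P_2(\cos\theta)| \left[4J(0) + 3J(\omega_N)\right]}
#' The default evaluates the secular combination \eqn{4J(0) + 3J(\omega_N)},
#' which reproduces the observed rigid-limit plateau (about 14 s^-1 at
#' \eqn{\tau_c} = 14.7 ns, 600 MHz) and gives eta_xy the same \eqn{(\tau_e,
#' S^2)} profile shape as R2.  Setting \code{j_zero = FALSE} replaces
#' \eqn{J(0)} by \eqn{J(\omega_H-\omega_N)}, for comparison with variant
#' formulations in the literature; at slow tumbling that combination is two
#' orders of magnitude smaller.
#'
#' @inheritParams rate_R1
#' @param j_zero logical; evaluate \eqn{4J(0)} (default) rather than
#'   \eqn{4J(\omega_H-\omega_N)}.
#' @return Rate in s^-1 (magnitude; positive for the default constants).
#' @examples
#' k <- interaction_constants()
#' rate_eta_xy(model_free_params(s2_fast = 0.87, tau_c = 14.7e-9), k)
#' @export
rate_eta_xy <- function(J, k, j_zero = TRUE) {
  stopifnot(inherits(k, "interaction_constants"))
  Jf <- .as_J(J)
  wN <- k$omega_N
  w0 <- if (j_zero) 0 else (k$omega_H - wN)
  (1 / 15) * k$d_dip * .csa_omega(k, k$delta_sigma_p2) *
    (4 * Jf(w0) + 3 * Jf(wN))
}

#' All four relaxation observables at once
#'
#' Convenience wrapper evaluating \code{\link{rate_R1}}, \code{\link{rate_NOE}},
#' \code{\link{rate_eta_xy}} and \code{\link{rate_R2}} for one spectral
#' density.
#'
#' @inheritParams rate_eta_xy
#' @return Named list with elements \code{r1}, \code{noe}, \code{eta_xy},
#'   \code{r2} (rates in s^-1, NOE dimensionless).
#' @export
relaxation_rates <- function(J, k, j_zero = TRUE) {
  Jf <- .as_J(J)
  r1 <- rate_R1(Jf, k)
  list(r1 = r1,
       noe = rate_NOE(Jf, k, r1 = r1),
       eta_xy = rate_eta_xy(Jf, k, j_zero = j_zero),
       r2 = rate_R2(Jf, k))
}
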