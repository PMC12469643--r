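#' Lipari-Szabo model-free parameters
#'
#' Container for the extended model-free description of an N-H bond vector:
#' fast and slow internal order parameters \eqn{S^2_{fast}}, \eqn{S^2_{slow}},
#' an internal correlation time \eqn{\tau_e}, and a single isotropic overall
#' tumbling time \eqn{\tau_c}.  The simple (single-S2) model corresponds to
#' \code{s2_slow = 1} (or \code{tau_e = 0}), in which case
#' \eqn{S^2 = S^2_{fast}}.
#'
#' @param s2_fast fast-motion order parameter in [0, 1].
#' @param s2_slow slow-motion order parameter in [0, 1] (default 1).
#' @param tau_e internal correlation time in seconds (default 0).
#' @param tau_c overall rotational correlation time in seconds.
#' @return An object of class \code{model_free_params}.
#' @examples
#' model_free_params(s2_fast = 0.9, s2_slow = 0.5, tau_e = 1e-9,
#'                   tau_c = 14.7e-9)
#' @export
model_free_params <- function(s2_fast, s2_slow = 1, tau_e = 0, tau_c) {
  stopifnot(is.numeric(s2_fast), is.numeric(s2_slow),
            is.numeric(tau_e), is.numeric(tau_c))
  if (s2_fast < 0 || s2_fast > 1 || s2_slow < 0 || s2_slow > 1)
    stop("order parameters must lie in [0, 1]")
  if (tau_c <= 0) stop("'tau_c' must be positive (seconds)")
  if (tau_e < 0) stop("'tau_e' must be non-negative (seconds)")
  structure(list(s2_fast = s2_fast, s2_slow = s2_slow,
                 tau_e = tau_e, tau_c = tau_c),
            class = "model_free_params")
}

#' @export
print.model_free_params <- function(x, ...) {
  cat(sprintf(
    "Model-free parameters: S2_fast = %.3f, S2_slow = %.3f (S2 = %.3f)\n",
    x$s2_fast, x$s2_slow, x$s2_fast * x$s2_slow))
  cat(sprintf("  tau_e = %.4g ns, tau_c = %.4g ns\n",
              x$tau_e * 1e9, x$tau_c * 1e9))
  invisible(x)
}

#' Multi-exponential spectral-density parameterization
#'
#' Represents the spectral density obtained from a multi-exponential fit of
#' an internal P2 autocorrelation function,
#' \eqn{C_I(t) = A_0 + \sum_j A_j e^{-t/\tau_j}}, combined with isotropic
#' overall tumbling at \eqn{\tau_c}:
#' \deqn{J(\omega) = \frac{A_0 \tau_c}{1 + (\omega\tau_c)^2} +
#'   \sum_j \frac{A_j \tau_j'}{1 + (\omega\tau_j')^2}, \qquad
#'   \tau_j' = \frac{\tau_c \tau_j}{\tau_c + \tau_j}.}
#'
#' @param a0 plateau amplitude (the internal order parameter), >= 0.
#' @param a numeric vector of exponential amplitudes \eqn{A_j} (may be empty).
#' @param tau numeric vector of internal time constants \eqn{\tau_j} in
#'   seconds, same length as \code{a}, all > 0.
#' @param tau_c overall correlation time in seconds.
#' @param normalize_tol tolerance on \eqn{A_0 + \sum A_j = 1} (default 1e-6).
#' @return An object of class \code{multiexp_spectrum} with fields \code{a0},
#'   \code{a}, \code{tau}, \code{tau_prime} (effective times), \code{tau_c}.
#' @examples
#' multiexp_spectrum(a0 = 0.85, a = 0.15, tau = 0.5e-9, tau_c = 14.7e-9)
#' @export
multiexp_spectrum <- function(a0, a = numeric(0), tau = numeric(0), tau_c,
                              normalize_tol = 1e-6) {
  stopifnot(length(a) == length(tau))
  if (a0 < -normalize_tol || any(a < -normalize_tol))
    stop("amplitudes must be non-negative")
  if (abs(a0 + sum(a) - 1) > normalize_tol)
    stop("amplitudes must sum to 1 (within 'normalize_tol')")
  if (tau_c <= 0 || any(tau <= 0)) stop("time constants must be positive")
  structure(list(a0 = a0, a = a, tau = tau,
                 tau_prime = tau_c * tau / (tau_c + tau),
                 tau_c = tau_c),
            class = "multiexp_spectrum")
}

# single Lorentzian: tau/(1 + (omega tau)^2); units of seconds
.lorentzian <- function(omega, tau) tau / (1 + (omega * tau)^2)

#' Simple Lipari-Szabo spectral density
#'
#' \eqn{J(\omega) = S^2 \tau_c / (1 + (\omega\tau_c)^2)}: a single-Lorentzian
#' spectral density in which internal motion only scales the amplitude.  This
#' normalization carries no 2/5 prefactor; the rate expressions absorb it.
#'
#' @param omega angular frequency in rad/s (vectorized).
#' @param s2 generalized order parameter in [0, 1].
#' @param tau_c overall correlation time in seconds.
#' @return Spectral density in seconds, same length as \code{omega}.
#' @examples
#' J_simple(0, s2 = 1, tau_c = 14.7e-9)  # J(0) = tau_c
#' @export
J_simple <- function(omega, s2, tau_c) {
  if (tau_c <= 0) stop("'tau_c' must be positive")
  if (s2 < 0 || s2 > 1) stop("'s2' must lie in [0, 1]")
  s2 * .lorentzian(omega, tau_c)
}

#' Extended Lipari-Szabo spectral density
#'
#' Two-Lorentzian model-free spectral density
#' \deqn{J(\omega) = S^2_{f} S^2_{s} \frac{\tau_c}{1+(\omega\tau_c)^2}
#'  + S^2_{f} (1 - S^2_{s}) \frac{\tau_e'}{1+(\omega\tau_e')^2},\qquad
#'  \tau_e' = \frac{\tau_c\tau_e}{\tau_c+\tau_e}.}
#' Reduces to \code{\link{J_simple}} with \eqn{S^2 = S^2_{fast}} when
#' \code{s2_slow = 1} or \code{tau_e = 0}.
#'
#' @param omega angular frequency in rad/s (vectorized).
#' @param params a \code{\link{model_free_params}} object.
#' @return Spectral density in seconds.
#' @export
J_extended <- function(omega, params) {
  stopifnot(inherits(params, "model_free_params"))
  tau_ep <- params$tau_c * params$tau_e / (params$tau_c + params$tau_e)
  if (params$tau_e == 0) tau_ep <- 0
  s2f <- params$s2_fast; s2s <- params$s2_slow
  out <- s2f * s2s * .lorentzian(omega, params$tau_c)
  if (tau_ep > 0 && s2s < 1)
    out <- out + s2f * (1 - s2s) * .lorentzian(omega, tau_ep)
  out
}

#' Multi-exponential spectral density
#'
#' Evaluates the spectral density of a \code{\link{multiexp_spectrum}}: a sum
#' of Lorentzians at \eqn{\tau_c} (weight \eqn{A_0}) and at the effective
#' internal times \eqn{\tau_j' = \tau_c\tau_j/(\tau_c+\tau_j)} (weights
#' \eqn{A_j}).  With no internal terms and \eqn{A_0 = 1} this is the rigid
#' single-Lorentzian limit.
#'
#' @param omega angular frequency in rad/s (vectorized).
#' @param spec a \code{\link{multiexp_spectrum}} object.
#' @return Spectral density in seconds.
#' @export
J_multiexp <- function(omega, spec) {
  stopifnot(inherits(spec, "multiexp_spectrum"))
  out <- spec$a0 * .lorentzian(omega, spec$tau_c)
  for (j in seq_along(spec$a))
    out <- out + spec$a[j] * .lorentzian(omega, spec$tau_prime[j])
  out
}

# Coerce any of the J parameterizations (or a bare function of omega) to a
# function omega -> J(omega).
.as_J <- function(J) {
  if (is.function(J)) return(J)
  if (inherits(J, "model_free_params")) return(function(w) J_extended(w, J))
  if (inherits(J, "multiexp_spectrum")) return(function(w) J_multiexp(w, J))
  stop("'J' must be a function of omega, model_free_params, or ",
       "multiexp_spectrum")
}
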