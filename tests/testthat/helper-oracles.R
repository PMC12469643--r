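# Shared fixtures and independent oracles used across the test files.

k600 <- interaction_constants(field_mhz = 600.13)

# Independent scalar spectral density (plain arithmetic, no package code)
oracle_J <- function(omega, s2, tau_c) s2 * tau_c / (1 + (omega * tau_c)^2)

# Independent quadrature spectral density for a time-domain correlation
# function C(t) = exp(-t/tau_c) * (a0 + sum_j a_j exp(-t/tau_j)).
# Integrates in ns units so the oscillation count stays moderate.
oracle_J_quadrature <- function(omega, a0, a, tau, tau_c) {
  tc_ns <- tau_c * 1e9
  tj_ns <- tau * 1e9
  C <- function(t_ns) {
    out <- rep(a0, length(t_ns))
    for (j in seq_along(a)) out <- out + a[j] * exp(-t_ns / tj_ns[j])
    exp(-t_ns / tc_ns) * out
  }
  w_ns <- omega * 1e-9
  1e-9 * stats::integrate(function(t) C(t) * cos(w_ns * t),
                          0, 60 * tc_ns, subdivisions = 5000L,
                          rel.tol = 1e-10)$value
}

# Independent rate formulas from a J function (plain arithmetic)
oracle_rates <- function(Jf, field_mhz = 600.13, r_nh = 1.023,
                         dsig = -166, dsig_p2 = -145) {
  gH <- 2.6752218744e8; gN <- -2.7126e7
  hbar <- 1.054571817e-34; mu0 <- 1.25663706212e-6
  wH <- 2 * pi * field_mhz * 1e6
  wN <- wH * abs(gN / gH)
  d <- (mu0 / (4 * pi)) * hbar * abs(gH * gN) / (r_nh * 1e-10)^3
  csa <- wN * abs(dsig) * 1e-6
  csa_p2 <- wN * abs(dsig_p2) * 1e-6
  r1 <- d^2 / 10 * (Jf(wH - wN) + 3 * Jf(wN) + 6 * Jf(wH + wN)) +
    2 / 15 * csa^2 * Jf(wN)
  r2 <- d^2 / 20 * (4 * Jf(0) + 3 * Jf(wN) + Jf(wH - wN) + 6 * Jf(wH) +
                      6 * Jf(wH + wN)) +
    csa^2 / 45 * (4 * Jf(0) + 3 * Jf(wN))
  noe <- 1 + (gH / gN) * (d^2 / 10) * (6 * Jf(wH + wN) - Jf(wH - wN)) / r1
  eta <- d * csa_p2 / 15 * (4 * Jf(0) + 3 * Jf(wN))
  list(r1 = r1, r2 = r2, noe = noe, eta_xy = eta)
}

# Brute-force Mann-Whitney: enumerate every assignment of the pooled sample
# to the two groups; two-sided p from the exact U null distribution.
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- colSums(matrix(rk[combos], nrow = n)) - n * (n + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# tiny synthetic trajectory written to a temp prefix; returns file paths
write_tiny_traj <- function(vec, rotate = FALSE, prolines = integer(0)) {
  prefix <- tempfile("traj")
  build_synthetic_trajectory_files(vec, prefix, rotate = rotate,
                                   prolines = prolines)
}
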