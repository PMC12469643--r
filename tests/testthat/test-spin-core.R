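# Spectral densities and the four relaxation-rate expressions.

test_that("spectral densities obey their closed-form limits", {
  # J(0) = S2 * tau_c; fully disordered limit is zero
  expect_equal(J_simple(0, s2 = 1, tau_c = 14.7e-9), 14.7e-9)
  expect_equal(J_simple(0, s2 = 0, tau_c = 5e-9), 0)
  expect_equal(J_simple(c(0, 1e9), s2 = 0, tau_c = 3e-9), c(0, 0))

  # hand-evaluated scalar value at omega_N
  wN <- k600$omega_N
  expect_equal(J_simple(wN, s2 = 0.85, tau_c = 14.7e-9),
               oracle_J(wN, 0.85, 14.7e-9), tolerance = 1e-12)

  # rigid multi-exponential spectrum equals the rigid Lorentzian
  rigid <- multiexp_spectrum(a0 = 1, tau_c = 10e-9)
  expect_equal(J_multiexp(0, rigid), 1e-8)
  # a vanishing internal time constant kills the second Lorentzian
  near0 <- multiexp_spectrum(a0 = 0.6, a = 0.4, tau = 1e-16, tau_c = 10e-9)
  expect_equal(J_multiexp(0, near0), 0.6 * 1e-8, tolerance = 1e-6)

  # extended model reduces to the simple model when the slow motion is off
  p_red <- model_free_params(s2_fast = 0.9, s2_slow = 1, tau_e = 3e-9,
                             tau_c = 14.7e-9)
  w <- c(0, 1e8, 5e8, 4e9)
  expect_equal(J_extended(w, p_red), J_simple(w, 0.9, 14.7e-9))

  # term-by-term hand computation of the two-Lorentzian form at omega = 0
  p <- model_free_params(s2_fast = 0.9, s2_slow = 0.5, tau_e = 1e-9,
                         tau_c = 14.7e-9)
  tau_ep <- 14.7e-9 * 1e-9 / (14.7e-9 + 1e-9)
  expect_equal(J_extended(0, p), 0.9 * 0.5 * 14.7e-9 + 0.9 * 0.5 * tau_ep)

  expect_error(J_simple(0, s2 = 0.5, tau_c = -1e-9), "tau_c")
  expect_error(model_free_params(s2_fast = 1.2, tau_c = 1e-8))
})

test_that("every J variant is even, non-negative, and non-increasing in |omega|", {
  w <- seq(0, 6e9, length.out = 40)
  specs <- list(
    function(x) J_simple(x, 0.7, 9e-9),
    function(x) J_extended(x, model_free_params(0.9, 0.6, 0.8e-9, 14.7e-9)),
    function(x) J_multiexp(x, multiexp_spectrum(a0 = 0.5, a = c(0.3, 0.2),
                                                tau = c(0.1e-9, 2e-9),
                                                tau_c = 12e-9)))
  for (Jf in specs) {
    vals <- Jf(w)
    expect_true(all(vals >= 0))
    expect_true(all(diff(vals) <= 1e-20))       # monotone non-increasing
    expect_equal(Jf(-w), vals)                  # even
  }
})

test_that("rates vanish for J = 0 and respond correctly to the CSA", {
  zeroJ <- function(w) 0 * w
  expect_equal(rate_R1(zeroJ, k600), 0)
  expect_equal(rate_R2(zeroJ, k600), 0)
  expect_equal(rate_eta_xy(zeroJ, k600), 0)

  # doubling the CSA scales only the CSA term of R1, by a factor of 4
  p <- model_free_params(s2_fast = 0.85, tau_c = 14.7e-9)
  k_no_csa <- interaction_constants(delta_sigma = 0)
  k_2csa <- interaction_constants(delta_sigma = -332)
  dip <- rate_R1(p, k_no_csa)
  csa1 <- rate_R1(p, k600) - dip
  csa2 <- rate_R1(p, k_2csa) - dip
  expect_equal(csa2 / csa1, 4, tolerance = 1e-12)
})

test_that("hand-evaluated rates match at the Fig.-1-style reference point", {
  p <- model_free_params(s2_fast = 0.85, tau_c = 14.7e-9)
  Jf <- function(w) oracle_J(w, 0.85, 14.7e-9)
  o <- oracle_rates(Jf)
  expect_equal(rate_R1(p, k600), o$r1, tolerance = 1e-12)
  expect_equal(rate_R2(p, k600), o$r2, tolerance = 1e-12)
  expect_equal(rate_NOE(p, k600), o$noe, tolerance = 1e-12)
  expect_equal(rate_eta_xy(p, k600), o$eta_xy, tolerance = 1e-12)

  # slow-tumbling regime: transverse rates dominated by J(0)
  expect_gt(rate_R2(p, k600), rate_R1(p, k600))

  # rigid residues at tau_c = 14.7 ns sit near the observed plateaus
  p9 <- model_free_params(s2_fast = 0.87, tau_c = 14.7e-9)
  expect_equal(rate_eta_xy(p9, k600), 14, tolerance = 0.03)
  expect_gt(rate_NOE(p9, k600), 0.75)
})

test_that("NOE reaches the extreme-narrowing limit with the CSA off", {
  k0 <- interaction_constants(delta_sigma = 0, delta_sigma_p2 = 0)
  p <- model_free_params(s2_fast = 1, tau_c = 1e-12)
  limit <- 1 + k0$gamma_H / (2 * k0$gamma_N)
  expect_equal(rate_NOE(p, k0), limit, tolerance = 1e-4 / abs(limit))
  expect_error(rate_NOE(p, k600, r1 = -1), "positive")
})

test_that("rates are linear in J (NOE invariant to J scaling)", {
  p <- model_free_params(s2_fast = 0.8, tau_c = 10e-9)
  Jf <- function(w) J_extended(w, p)
  J3 <- function(w) 3 * Jf(w)
  expect_equal(rate_R1(J3, k600), 3 * rate_R1(Jf, k600))
  expect_equal(rate_R2(J3, k600), 3 * rate_R2(Jf, k600))
  expect_equal(rate_eta_xy(J3, k600), 3 * rate_eta_xy(Jf, k600))
  expect_equal(rate_NOE(J3, k600), rate_NOE(Jf, k600))
})

test_that("eta_xy follows the R2-like secular combination by default", {
  p <- model_free_params(s2_fast = 0.87, tau_c = 14.7e-9)
  eta_default <- rate_eta_xy(p, k600)
  eta_literal <- rate_eta_xy(p, k600, j_zero = FALSE)
  # the literal J(wH - wN) variant collapses at slow tumbling
  expect_lt(eta_literal, 0.5)
  expect_gt(eta_default / eta_literal, 20)
  # same profile driver as R2: both increase with S2 at fixed tau_e
  s2s <- c(0.4, 0.6, 0.8)
  etas <- vapply(s2s, function(s)
    rate_eta_xy(model_free_params(1, s, 0.5e-9, 14.7e-9), k600), numeric(1))
  r2s <- vapply(s2s, function(s)
    rate_R2(model_free_params(1, s, 0.5e-9, 14.7e-9), k600), numeric(1))
  expect_true(all(diff(etas) > 0) && all(diff(r2s) > 0))
})

test_that("analytic multi-exponential rates agree with the quadrature oracle", {
  spec <- multiexp_spectrum(a0 = 0.55, a = c(0.25, 0.2),
                            tau = c(0.05e-9, 1.2e-9), tau_c = 12e-9)
  Jq <- function(w) vapply(w, function(wi)
    oracle_J_quadrature(wi, spec$a0, spec$a, spec$tau, spec$tau_c),
    numeric(1))
  for (ratefun in list(rate_R1, rate_R2, rate_eta_xy)) {
    analytic <- ratefun(spec, k600)
    numeric_ <- ratefun(Jq, k600)
    expect_equal(numeric_, analytic, tolerance = 1e-4)
  }
})
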