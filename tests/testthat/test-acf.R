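# P2 autocorrelation estimation and its multi-exponential reduction.

make_vec <- function(V_list, dt_ns = 0.001) {
  n <- nrow(V_list[[1]])
  vectors <- array(NA_real_, dim = c(n, 3, length(V_list)))
  for (j in seq_along(V_list)) vectors[, , j] <- V_list[[j]]
  structure(list(vectors = vectors, residues = seq_along(V_list),
                 resid = rep("ALA", length(V_list)), dt_ns = dt_ns,
                 skipped = data.frame()),
            class = "nh_vectors")
}

test_that("static and decorrelated vectors give the limiting ACFs", {
  n <- 2000
  static <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  withr::local_seed(5)
  g <- matrix(stats::rnorm(3 * n), n, 3)
  iid <- g / sqrt(rowSums(g^2))
  vec <- make_vec(list(static, iid))
  acf <- compute_p2_acf(vec, lag_max_ns = 0.5)
  expect_equal(acf$values[, 1], rep(1, nrow(acf$values)))
  expect_equal(acf$values[1, 2], 1)            # C(0) = 1 exactly
  tail_vals <- acf$values[-1, 2]
  expect_true(all(abs(tail_vals) < 3 / sqrt(acf$n_pairs[-1])))
})

test_that("FFT and direct all-origin paths agree to round-off", {
  v <- simulate_nh_vectors(list(list(type = "cone", theta0_deg = 50,
                                     step_sd = 0.08)),
                           n_frames = 3000, seed = 9)
  a_dir <- compute_p2_acf(v, lag_max_ns = 1, method = "direct")
  a_fft <- compute_p2_acf(v, lag_max_ns = 1, method = "fft")
  expect_lt(max(abs(a_dir$values - a_fft$values)), 1e-10)
  expect_equal(a_dir$n_pairs, a_fft$n_pairs)
})

test_that("the ACF estimator is invariant to time reversal", {
  v <- simulate_nh_vectors(list(list(type = "cone", theta0_deg = 30,
                                     step_sd = 0.05)),
                           n_frames = 2500, seed = 13)
  vr <- v
  vr$vectors <- v$vectors[rev(seq_len(2500)), , , drop = FALSE]
  a1 <- compute_p2_acf(v, lag_max_ns = 0.8)
  a2 <- compute_p2_acf(vr, lag_max_ns = 0.8)
  expect_equal(a1$values, a2$values, tolerance = 1e-12)
})

test_that("lag bounds and short segments are policed", {
  v <- simulate_nh_vectors(list(list(type = "rigid")), n_frames = 100,
                           seed = 1)
  expect_error(compute_p2_acf(v, lag_max_ns = 10), "exceeds")
  expect_warning(compute_p2_acf(v, lag_max_ns = 0.05, tau_c_ns = 5),
                 "10 x tau_c")
})

test_that("diffusion in a cone plateaus at the analytic order parameter", {
  v <- simulate_nh_vectors(list(list(type = "cone", theta0_deg = 60,
                                     step_sd = 0.1)),
                           n_frames = 60000, seed = 21)
  a <- compute_p2_acf(v, lag_max_ns = 5, method = "fft")
  plateau <- mean(a$values[a$lags_ns > 2.5, 1])
  expect_equal(plateau, cone_s2(60), tolerance = 0.03)
})

test_that("multi-exponential fits recover exact and noisy models", {
  lags <- seq(0, 10, by = 0.01)
  # exact model class, noise free
  f1 <- fit_acf_multiexp(list(lags_ns = lags,
                              values = 0.8 + 0.2 * exp(-lags / 1)))
  expect_equal(f1$m, 1L)
  expect_equal(f1$a0, 0.8, tolerance = 1e-4)
  expect_equal(f1$tau_ns, 1, tolerance = 1e-4)
  expect_equal(f1$a0 + sum(f1$a), 1, tolerance = 1e-12)  # simplex exact
  expect_equal(unname(coef(f1)["a0"]), f1$a0)
  expect_equal(predict(f1), f1$fitted, tolerance = 1e-12)

  # constant ACF selects the rigid model with no terms
  f2 <- fit_acf_multiexp(list(lags_ns = lags, values = rep(1, length(lags))))
  expect_equal(f2$m, 0L)
  expect_equal(f2$a0, 1)

  # two exponentials with 1% noise: amplitudes within 0.03
  withr::local_seed(17)
  truth <- 0.6 + 0.25 * exp(-lags / 0.3) + 0.15 * exp(-lags / 3)
  noisy <- truth + stats::rnorm(length(lags), sd = 0.01)
  f3 <- fit_acf_multiexp(list(lags_ns = lags, values = noisy), m_max = 3)
  expect_equal(f3$a0, 0.6, tolerance = 0.03)
  expect_gte(f3$m, 2)
  expect_error(fit_acf_multiexp(list(lags_ns = 1:5, values = rep(1, 5))),
               "10 lag")
})

test_that("rigid back-calculated rates equal the analytic S2 = 1 values", {
  f <- fit_acf_multiexp(list(lags_ns = seq(0, 10, 0.01),
                             values = rep(1, 1001)))
  rates <- backcalc_segment_rates(list(`7` = f), tau_c = 14.7e-9, k = k600,
                                  include_r2 = TRUE)
  p1 <- model_free_params(s2_fast = 1, tau_c = 14.7e-9)
  expect_equal(rates$residue, 7L)
  expect_equal(rates$r1, rate_R1(p1, k600), tolerance = 1e-10)
  expect_equal(rates$eta_xy, rate_eta_xy(p1, k600), tolerance = 1e-10)
  expect_equal(rates$r2, rate_R2(p1, k600), tolerance = 1e-10)
  expect_equal(rates$noe, rate_NOE(p1, k600), tolerance = 1e-10)
})

test_that("the moving-block bootstrap is seeded, and degenerate on static input", {
  v <- simulate_nh_vectors(list(list(type = "rigid"),
                                list(type = "cone", theta0_deg = 45,
                                     step_sd = 0.1)),
                           n_frames = 20000, seed = 3)
  b1 <- bootstrap_rate_errors(v, 10e-9, k600, lag_max_ns = 2, n_boot = 8,
                              seed = 99)
  b2 <- bootstrap_rate_errors(v, 10e-9, k600, lag_max_ns = 2, n_boot = 8,
                              seed = 99)
  expect_identical(b1$errors, b2$errors)       # same seed, same SDs
  expect_equal(b1$errors$eta_xy_err[1], 0)     # static residue: zero spread
  expect_gt(b1$errors$eta_xy_err[2], 0)
  expect_error(bootstrap_rate_errors(v, 10e-9, k600, lag_max_ns = 2,
                                     block_ns = 10, n_boot = 2, seed = 1),
               "block length")
})
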