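# Delta/sigma analysis, Mann-Whitney U, and segment ranking.

fake_rates <- function(residues, eta, eta_err = 0.5) {
  data.frame(residue = residues, r1 = NA_real_, r1_err = NA_real_,
             noe = NA_real_, noe_err = NA_real_,
             eta_xy = eta, eta_xy_err = eta_err)
}

test_that("delta/sigma is zero for identical sets and localizes offsets", {
  exp_tab <- fake_rates(1:20, eta = rep(10, 20), eta_err = 1)
  calc_tab <- fake_rates(1:20, eta = rep(10, 20))
  d <- delta_in_sigma(exp_tab, calc_tab)
  expect_equal(d$table$z, rep(0, 20))
  expect_equal(d$max_abs_z, 0)
  expect_equal(nrow(d$stretches$`1sigma`), 0L)

  # a single residue offset by 3.5 sigma: one run of length 1 at every level
  calc1 <- calc_tab
  calc1$eta_xy[7] <- 10 + 3.5
  d1 <- delta_in_sigma(exp_tab, calc1)
  for (lev in c("1sigma", "2sigma", "3sigma")) {
    expect_equal(nrow(d1$stretches[[lev]]), 1L)
    expect_equal(d1$stretches[[lev]]$start, 7)
    expect_equal(d1$stretches[[lev]]$length, 1L)
  }

  # a contiguous 5-residue 2.5-sigma stretch, plus an isolated 2.5-sigma hit
  calc2 <- calc_tab
  calc2$eta_xy[9:13] <- 10 + 2.5
  calc2$eta_xy[17] <- 10 - 2.5
  d2 <- delta_in_sigma(exp_tab, calc2)
  runs2 <- d2$stretches$`2sigma`
  expect_equal(nrow(runs2), 2L)
  expect_equal(runs2$start[1], 9); expect_equal(runs2$end[1], 13)
  expect_equal(runs2$length[1], 5L)
  expect_equal(runs2$length[2], 1L)
  expect_equal(nrow(d2$stretches$`3sigma`), 0L)

  # only matched residues enter; a numbering gap breaks runs
  exp_gap <- fake_rates(c(1:5, 8:12), eta = rep(10, 10), eta_err = 1)
  calc_gap <- fake_rates(c(1:5, 8:12), eta = rep(13, 10))
  d3 <- delta_in_sigma(exp_gap, calc_gap)
  expect_equal(nrow(d3$table), 10L)
  expect_equal(nrow(d3$stretches$`2sigma`), 2L)

  expect_error(delta_in_sigma(fake_rates(1:3, 1), fake_rates(7:9, 1)),
               "no residues")
})

test_that("combined-error mode widens sigma in quadrature", {
  exp_tab <- fake_rates(1:5, eta = rep(10, 5), eta_err = 3)
  calc_tab <- fake_rates(1:5, eta = rep(14, 5), eta_err = 4)
  d_exp <- delta_in_sigma(exp_tab, calc_tab, sigma = "experimental")
  d_comb <- delta_in_sigma(exp_tab, calc_tab, sigma = "combined")
  expect_equal(d_exp$table$sigma, rep(3, 5))
  expect_equal(d_comb$table$sigma, rep(5, 5))
  expect_equal(d_comb$table$z, rep(4 / 5, 5))
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  withr::local_seed(23)
  for (n in c(2, 3, 5, 8)) {
    for (m in c(2, 4, 8)) {
      x <- stats::rnorm(n)
      y <- stats::rnorm(m, mean = 0.5)
      got <- mann_whitney_u(x, y)
      ref <- oracle_mw_exact(x, y)
      expect_equal(got$U, ref$U)
      expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
      expect_equal(got$method, "exact")
    }
  }
  # fully separated samples, n = m = 3: exact two-sided p = 2/20
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)
  # symmetry in the two samples
  ab <- mann_whitney_u(c(1, 5, 9), c(2, 3, 11))
  ba <- mann_whitney_u(c(2, 3, 11), c(1, 5, 9))
  expect_equal(ab$p_value, ba$p_value)
  # identical multisets cannot be distinguished
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)
  # large / tied samples take the corrected normal approximation
  big <- mann_whitney_u(stats::rnorm(30), stats::rnorm(30))
  expect_equal(big$method, "normal approximation")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("segment ranking orders candidates by agreement with experiment", {
  withr::local_seed(27)
  res <- 1:60
  eta_true <- 10 + 4 * sin(res / 6)
  exp_tab <- fake_rates(res, eta = eta_true, eta_err = 0.5)
  good <- fake_rates(res, eta = eta_true + stats::rnorm(60, sd = 0.1))
  bad <- good
  bad$eta_xy[20:40] <- bad$eta_xy[20:40] + 2.5      # one misfit region
  rk <- rank_segments(exp_tab, list(good = good, bad = bad))
  expect_equal(rk$table$segment[1], "good")
  expect_gt(rk$table$p_value[1], rk$table$p_value[2])
  expect_true(rk$table$accepted[1])
  expect_equal(rk$table$n_pairs, rep(60L, 2))
  expect_equal(rk$pairwise["good", "bad"], rk$pairwise["bad", "good"])

  # perfect agreement ranks first with p ~ 1
  rk2 <- rank_segments(exp_tab, list(perfect = exp_tab, bad = bad))
  expect_equal(rk2$table$segment[1], "perfect")
  expect_gte(rk2$table$p_value[1], 0.99)

  # ordering invariant to residue order and common rescaling
  perm <- sample(60)
  rk3 <- rank_segments(exp_tab[perm, ], list(good = good[rev(perm), ],
                                             bad = bad))
  expect_equal(rk3$table$segment, rk$table$segment)
  scale2 <- function(df) { df$eta_xy <- df$eta_xy * 2
                           df$eta_xy_err <- df$eta_xy_err * 2; df }
  rk4 <- rank_segments(scale2(exp_tab), list(good = scale2(good),
                                             bad = scale2(bad)))
  expect_equal(rk4$table$segment, rk$table$segment)
})
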