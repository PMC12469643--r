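# RMSD series, plateau detection, and RMSF.

test_that("RMSD of a static or rigidly rotated trajectory is zero", {
  v <- simulate_nh_vectors(rep(list(list(type = "rigid")), 3),
                           n_frames = 20, seed = 12)
  f_static <- write_tiny_traj(v)
  tr <- read_trajectory(f_static$top, f_static$traj, dt_ns = 1)
  s <- compute_rmsd_series(tr)
  expect_equal(s$rmsd, rep(0, 20), tolerance = 1e-3)

  f_rot <- write_tiny_traj(v, rotate = TRUE)
  tr_rot <- read_trajectory(f_rot$top, f_rot$traj, dt_ns = 1)
  s_rot <- compute_rmsd_series(tr_rot)     # fit = TRUE removes the rotation
  expect_equal(s_rot$rmsd, rep(0, 20), tolerance = 1e-2)
})

test_that("a two-state trajectory yields an RMSD step of known height", {
  v <- simulate_nh_vectors(rep(list(list(type = "rigid")), 4),
                           n_frames = 40, seed = 14)
  files <- write_tiny_traj(v)
  tr <- read_trajectory(files$top, files$traj, dt_ns = 1)
  # displace residues by (+2, -2, -2, +2) A along y in the second half:
  # zero net translation and zero net torque, so the best-fit superposition
  # cannot absorb it and every atom moves by exactly 2 A
  resno <- tr$pdb$atom$resno
  sign_by_res <- c(1, -1, -1, 1)
  y_cols <- seq(2, ncol(tr$xyz), by = 3)
  for (a in seq_along(resno))
    tr$xyz[21:40, y_cols[a]] <- tr$xyz[21:40, y_cols[a]] +
      2 * sign_by_res[resno[a]]
  s <- compute_rmsd_series(tr, reference = "first")
  expect_equal(s$rmsd[1:20], rep(0, 20), tolerance = 1e-2)
  expect_equal(s$rmsd[21:40], rep(2, 20), tolerance = 1e-2)
})

test_that("plateau detection finds flat regions and respects thresholds", {
  t <- seq(0, 2000, by = 10)
  # constant series: one merged plateau covering the scanned range
  s_const <- data.frame(time_ns = t, rmsd = rep(1, length(t)))
  segs <- detect_plateau_segments(s_const, window_ns = 500, sd_max = 0.3,
                                  jump_max = 1)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_ns, 0)
  expect_equal(segs$end_ns, 2000)
  expect_gte(segs$end_ns - segs$start_ns, 500)

  # clean step: two plateaus, neither spanning the step
  s_step <- data.frame(time_ns = t, rmsd = ifelse(t < 1000, 0.5, 3.5))
  segs2 <- detect_plateau_segments(s_step, window_ns = 500, sd_max = 0.3,
                                   jump_max = 1)
  expect_equal(nrow(segs2), 2L)
  expect_lte(segs2$end_ns[1], 1000)
  expect_gte(segs2$start_ns[2], 1000)
  win <- attr(segs2, "windows")
  expect_true(all(abs((win$end_ns - win$start_ns) - 500) < 10))

  # white noise with SD above sd_max: nothing qualifies
  withr::local_seed(15)
  s_noise <- data.frame(time_ns = t, rmsd = stats::rnorm(length(t), 2, 1))
  segs3 <- detect_plateau_segments(s_noise, window_ns = 500, sd_max = 0.3,
                                   jump_max = 10)
  expect_equal(nrow(segs3), 0L)

  # equilibration cutoff excludes early windows
  segs4 <- detect_plateau_segments(s_const, window_ns = 500, sd_max = 0.3,
                                   jump_max = 1, equil_ns = 700)
  expect_gte(segs4$start_ns[1], 700)

  expect_error(detect_plateau_segments(s_const[1:10, ], window_ns = 500),
               "shorter than the window")
})

test_that("plateau detection is time-translation invariant", {
  t <- seq(0, 1500, by = 5)
  r <- ifelse(t < 800, 1, 4) + 0.01 * sin(t)
  a <- detect_plateau_segments(data.frame(time_ns = t, rmsd = r),
                               window_ns = 400, sd_max = 0.3, jump_max = 1)
  b <- detect_plateau_segments(data.frame(time_ns = t + 250, rmsd = r),
                               window_ns = 400, sd_max = 0.3, jump_max = 1)
  expect_equal(b$start_ns, a$start_ns + 250)
  expect_equal(b$end_ns, a$end_ns + 250)
})

test_that("RMSF is zero for static atoms and a/sqrt(2) for an oscillator", {
  v <- simulate_nh_vectors(rep(list(list(type = "rigid")), 2),
                           n_frames = 200, seed = 16)
  files <- write_tiny_traj(v)
  tr <- read_trajectory(files$top, files$traj, dt_ns = 1)
  f0 <- compute_rmsf(tr)
  expect_equal(f0$rmsf, rep(0, 2), tolerance = 1e-3)

  # oscillate residue 2's CA along x with uniform phase sampling
  sel <- bio3d::atom.select(tr$pdb, elety = "CA", resno = 2,
                            verbose = FALSE)
  amp <- 1.5
  phases <- 2 * pi * (seq_len(200) - 1) / 200
  tr2 <- tr
  tr2$xyz[, sel$xyz[1]] <- tr2$xyz[, sel$xyz[1]] + amp * sin(phases)
  f1 <- compute_rmsf(tr2)
  expect_equal(f1$rmsf[f1$residue == 2], amp / sqrt(2), tolerance = 0.01)
  expect_equal(f1$rmsf[f1$residue == 1], 0, tolerance = 1e-6)

  # frame order does not matter
  tr3 <- tr2
  tr3$xyz <- tr3$xyz[rev(seq_len(200)), ]
  f2 <- compute_rmsf(tr3)
  expect_equal(f2$rmsf, f1$rmsf, tolerance = 1e-12)

  # nm output is Angstrom / 10
  f_nm <- compute_rmsf(tr2, unit = "nm")
  expect_equal(f_nm$rmsf, f1$rmsf / 10)
})
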