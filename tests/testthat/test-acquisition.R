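test_that("steady-state signal follows the saturation-recovery model", {
  meta <- grid_meta(c(8, 8, 8), 4)
  p <- sequence_params()
  vol <- function(v) scalar_volume(array(v, c(8, 8, 8)), meta)
  # T1 -> 0, T2* -> Inf: signal equals concentration
  s <- steady_state_signal(vol(50), vol(1e-9), vol(1e9), p)
  expect_equal(s$data, array(50, c(8, 8, 8)), tolerance = 1e-7)
  # TR = 100, T1 = 50, TE effect off: ratio 1 - e^-2
  p0 <- sequence_params(te_ms = 0)
  s2 <- steady_state_signal(vol(100), vol(50), vol(4), p0)
  expect_equal(s2$data[1], 100 * (1 - exp(-2)))
  # brain defaults: (1 - e^(-100/35)) e^(-0.1)
  s3 <- steady_state_signal(vol(1), vol(35), vol(4), p)
  expect_equal(s3$data[1], (1 - exp(-100 / 35)) * exp(-0.4 / 4))
  expect_error(steady_state_signal(vol(1), vol(-1), vol(4), p), "positive")
})

test_that("density-adapted trajectory has the stated geometry", {
  p <- sequence_params(n_spokes = 9000, n_samples = 384)
  tr <- make_trajectory(p)
  # Nyquist radius of the 4 mm nominal resolution
  expect_lte(max(tr$radii), 0.125 + 1e-12)
  expect_gt(max(tr$radii), 0.12)
  expect_equal(p$apparent_res_mm, 2)
  # constant density weights beyond the ramp
  beyond <- tr$dcf_radial[(tr$ramp_samples + 1):p$n_samples]
  expect_lt(diff(range(beyond)) / mean(beyond), 1e-6)
  # k^2 law on the ramp
  ramp <- seq_len(tr$ramp_samples)
  expect_equal(tr$dcf_radial[ramp] / tr$radii[ramp]^2,
               rep(tr$dcf_radial[1] / tr$radii[1]^2, length(ramp)))
  # quasi-uniform spokes: mean nearest-neighbour angular spacing within
  # 20% of the uniform-coverage value sqrt(4 pi / N)
  nn <- numeric(9000)
  for (b in split(seq_len(9000), ceiling(seq_len(9000) / 1500))) {
    d <- tcrossprod(tr$dirs[b, , drop = FALSE], tr$dirs)
    d[cbind(seq_along(b), b)] <- -2
    nn[b] <- acos(pmin(1, apply(d, 1, max)))
  }
  expect_lt(abs(mean(nn) / sqrt(4 * pi / 9000) - 1), 0.2)
})

test_that("fast FFT forward model agrees with the exact NUDFT oracle", {
  p <- sequence_params(n_spokes = 500, n_samples = 48, noise_sd = 0)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(24, 24, 24), 2)
  set.seed(4)
  blob <- array(0, c(24, 24, 24))
  blob[8:16, 9:15, 10:14] <- rnorm(9 * 7 * 5, 1, 0.2)
  sig <- scalar_volume(blob, meta)
  a <- simulate_acquisition(sig, tr, noise_sd = 0, method = "fft")
  b <- simulate_acquisition(sig, tr, noise_sd = 0, method = "nudft")
  rel <- sqrt(mean(Mod(a$samples - b$samples)^2)) /
    sqrt(mean(Mod(b$samples)^2))
  expect_lt(rel, 0.01)
})

test_that("forward model matches the analytic Fourier transform of a ball", {
  p <- sequence_params(n_spokes = 800, n_samples = 48, noise_sd = 0)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(32, 32, 32), 1)
  R <- 8
  d <- sqrt(na23tsc:::voxel_dist2(meta, c(0, 0, 0)))
  sig <- scalar_volume(array(pmin(1, pmax(0, 0.5 + (R - d))), c(32, 32, 32)),
                       meta)
  ks <- simulate_acquisition(sig, tr, noise_sd = 0, method = "fft")
  pts <- trajectory_points(tr)
  kr <- 2 * pi * sqrt(rowSums(pts^2)) * R
  analytic <- 4 / 3 * pi * R^3 * 3 * (sin(kr) - kr * cos(kr)) / kr^3
  vals <- as.vector(t(ks$samples))
  rel <- sqrt(mean(Mod(vals - analytic)^2)) / sqrt(mean(analytic^2))
  expect_lt(rel, 0.02)
})

test_that("acquisition noise is linear, seeded, and absent for zero signal", {
  p <- sequence_params(n_spokes = 200, n_samples = 32)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(16, 16, 16), 4)
  zero <- scalar_volume(array(0, c(16, 16, 16)), meta)
  ks0 <- simulate_acquisition(zero, tr, noise_sd = 0, seed = 1)
  expect_true(all(Mod(ks0$samples) == 0))
  ks1 <- simulate_acquisition(zero, tr, noise_sd = 0.5, seed = 9)
  ks2 <- simulate_acquisition(zero, tr, noise_sd = 0.5, seed = 9)
  expect_identical(ks1$samples, ks2$samples)
  ks3 <- simulate_acquisition(zero, tr, noise_sd = 0.5, seed = 10)
  expect_false(identical(ks1$samples, ks3$samples))
})

test_that("regridding reconstruction is quantitative on a ball phantom", {
  # full 384-point readout: radial sampling density near the k-space
  # centre is what the absolute amplitude depends on
  p <- sequence_params(n_spokes = 1500, n_samples = 384, noise_sd = 0)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(64, 64, 64), 2)       # 128 mm FOV
  R <- 16                                   # ball >> PSF so the interior
  d <- sqrt(na23tsc:::voxel_dist2(meta, c(0, 0, 0)))  # mean is meaningful
  sig <- scalar_volume(array(pmin(1, pmax(0, 0.5 + (R - d) / 2)),
                             c(64, 64, 64)), meta)
  ks <- simulate_acquisition(sig, tr, noise_sd = 0)
  rec <- reconstruct(ks)
  # output grid: zero-fill factor 2 over FOV / 4 mm cells -> 2 mm voxels
  expect_equal(rec$meta$shape, c(64L, 64L, 64L))
  expect_equal(rec$meta$spacing, c(2, 2, 2))
  inner <- na23tsc:::voxel_dist2(rec$meta, c(0, 0, 0)) < (R - 5)^2
  bg <- na23tsc:::voxel_dist2(rec$meta, c(0, 0, 0)) > (R + 10)^2
  expect_lt(abs(mean(rec$data[inner]) - 1), 0.05)
  expect_lt(mean(rec$data[bg]) / mean(rec$data[inner]), 0.05)
  expect_error(reconstruct(make_trajectory(p)), "no samples")
})

test_that("two 12 mm-separated balls are resolved at 4 mm nominal resolution", {
  p <- sequence_params(n_spokes = 1500, n_samples = 64, noise_sd = 0)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(48, 48, 48), 2)
  b <- pmin(1, pmax(0, 0.5 + (4 - sqrt(na23tsc:::voxel_dist2(meta, c(-6, 0, 0)))) / 2)) +
    pmin(1, pmax(0, 0.5 + (4 - sqrt(na23tsc:::voxel_dist2(meta, c(6, 0, 0)))) / 2))
  ks <- simulate_acquisition(scalar_volume(array(b, c(48, 48, 48)), meta), tr,
                             noise_sd = 0)
  rec <- reconstruct(ks)
  x <- rec$meta$origin[1] + (seq_len(48) - 1) * 2
  mid <- which.min(abs(rec$meta$origin[3] + (seq_len(48) - 1) * 2))
  prof <- rec$data[, mid, mid]
  trough <- prof[which.min(abs(x))]
  expect_lt(trough / max(prof), 0.8)
})

test_that("complex reconstruction is linear in k-space", {
  p <- sequence_params(n_spokes = 400, n_samples = 48, noise_sd = 0)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(24, 24, 24), 4)
  mk <- function(ctr) {
    d <- sqrt(na23tsc:::voxel_dist2(meta, ctr))
    simulate_acquisition(scalar_volume(array(pmax(0, 8 - d), c(24, 24, 24)),
                                       meta), tr, noise_sd = 0)
  }
  k1 <- mk(c(-8, 0, 0)); k2 <- mk(c(10, 4, -4))
  ksum <- k1
  ksum$samples <- 2 * k1$samples - 0.5 * k2$samples
  r1 <- reconstruct(k1, output = "complex")
  r2 <- reconstruct(k2, output = "complex")
  rs <- reconstruct(ksum, output = "complex")
  expect_equal(rs, 2 * r1 - 0.5 * r2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("compartment intensity ratios survive reconstruction within 3%", {
  p <- sequence_params(n_spokes = 1500, n_samples = 64, noise_sd = 0)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(48, 48, 48), 2)
  d1 <- sqrt(na23tsc:::voxel_dist2(meta, c(-14, 0, 0)))
  d2 <- sqrt(na23tsc:::voxel_dist2(meta, c(14, 0, 0)))
  obj <- pmin(1, pmax(0, 0.5 + (10 - d1) / 2)) +
    2 * pmin(1, pmax(0, 0.5 + (10 - d2) / 2))
  ks <- simulate_acquisition(scalar_volume(array(obj, c(48, 48, 48)), meta),
                             tr, noise_sd = 0)
  rec <- reconstruct(ks)
  m1 <- na23tsc:::voxel_dist2(rec$meta, c(-14, 0, 0)) < 36
  m2 <- na23tsc:::voxel_dist2(rec$meta, c(14, 0, 0)) < 36
  ratio <- mean(rec$data[m2]) / mean(rec$data[m1])
  expect_lt(abs(ratio - 2) / 2, 0.03)
})

test_that("image noise scales linearly with k-space noise", {
  p <- sequence_params(n_spokes = 600, n_samples = 48)
  tr <- make_trajectory(p)
  meta <- grid_meta(c(32, 32, 32), 3)
  zero <- scalar_volume(array(0, c(32, 32, 32)), meta)
  sd_img <- vapply(c(0.5, 1), function(s) {
    r <- reconstruct(simulate_acquisition(zero, tr, noise_sd = s, seed = 3))
    stats::sd(r$data)
  }, numeric(1))
  expect_lt(abs(sd_img[2] / sd_img[1] - 2), 0.2)
})
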