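test_that("rigid transforms compose, invert, and serialize exactly", {
  tf <- rigid_transform(c(10, -5, 3), c(4, -2, 7))
  expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
  expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-12)
  inv <- invert_transform(tf)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(inv, apply_transform(tf, pts)), pts,
               tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, f)
  back <- read_transform(f)
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tf$translation)
})

test_that("mask resampling preserves geometry across grids", {
  meta1 <- grid_meta(c(40, 40, 40), 1)
  meta2 <- grid_meta(c(20, 20, 20), 2)
  ball <- mask_sphere(meta1, c(0, 0, 0), 8)
  # identity, same grid: unchanged
  same <- resample_mask(ball, rigid_transform(), meta1, meta = meta1)
  expect_equal(same$data != 0L, ball, ignore_attr = TRUE)
  # 1 mm -> 2 mm: volume within 15%
  coarse <- resample_mask(ball, rigid_transform(), meta2, meta = meta1)
  expect_lt(abs(sum(coarse$data) * 8 - sum(ball)) / sum(ball), 0.15)
  # grid-commensurate shift: exactly one voxel of the target grid
  shifted <- resample_mask(ball, rigid_transform(c(0, 0, 0), c(2, 0, 0)),
                           meta2, meta = meta1)
  base <- resample_mask(ball, rigid_transform(), meta2, meta = meta1)
  expect_equal(shifted$data[2:20, , ], base$data[1:19, , ])
  expect_warning(
    resample_mask(ball, rigid_transform(c(0, 0, 0), c(500, 0, 0)),
                  meta2, meta = meta1),
    "left the target")
})

test_that("mask round trip through a transform keeps its volume", {
  meta <- grid_meta(c(40, 40, 40), 1.5)
  ball <- mask_sphere(meta, c(0, 0, 0), 9)
  tf <- rigid_transform(c(7, -4, 3), c(2.3, -1.1, 0.7))
  fwd <- resample_mask(ball, tf, meta, meta = meta)
  back <- resample_mask(fwd$data != 0L, invert_transform(tf), meta,
                        meta = meta)
  inter <- sum(back$data != 0L & ball)
  expect_gt(2 * inter / (sum(back$data != 0L) + sum(ball)), 0.9)
})

test_that("self-registration returns the identity", {
  gt <- fx_phantom()$gt
  small <- na23tsc:::downsample_volume(gt$anatomy, 2)
  tf <- suppressWarnings(register_rigid(small, small))
  expect_lt(max(abs(tf$translation)), 0.05)
  expect_lt(max(abs(tf$angles_deg)), 0.1)
})

test_that("known shift and rotation of a sodium scan are recovered", {
  gt <- fx_phantom()$gt
  meta <- gt$labels$meta
  p <- fx_params()
  sig <- steady_state_signal(gt$tsc$I, gt$t1, gt$t2star, p)
  recover <- function(ang, tvec) {
    motion <- rigid_transform(ang, tvec)
    moved <- resample_volume(sig, invert_transform(motion), meta)
    ks <- simulate_acquisition(moved, fx_traj(), noise_sd = 0, seed = 1)
    rec <- reconstruct(ks)
    tf <- suppressWarnings(register_rigid(rec, gt$anatomy))
    list(d_mm = sqrt(sum((tf$translation - tvec)^2)),
         d_deg = max(abs(tf$angles_deg - ang)),
         metric = attr(tf, "metric"),
         rec = rec, motion = motion)
  }
  shift <- recover(c(0, 0, 0), c(3, -2, 1))
  expect_lt(shift$d_mm, 0.5)
  expect_lt(shift$d_deg, 0.5)
  rot <- recover(c(5, 0, 0), c(0, 0, 0))
  expect_lt(rot$d_mm, 0.5)
  expect_lt(rot$d_deg, 0.5)
  # no spurious optimum: metric at the estimate is at least the metric at
  # the ground-truth transform minus tolerance
  mv_true <- resample_volume(
    scalar_volume(na23tsc:::box_smooth3(rot$rec$data), rot$rec$meta),
    rot$motion, gt$anatomy$meta, fill = NA_real_)
  nmi_true <- na23tsc:::nmi_metric(
    mv_true$data,
    na23tsc:::box_smooth3(gt$anatomy$data))
  expect_gte(rot$metric, nmi_true - 0.01)
})

test_that("tissue segmentation recovers the phantom classes", {
  gt <- fx_phantom()$gt
  tis <- fx_segmentation()
  lab <- gt$labels$data
  core <- lab %in% c(1L, 2L, 3L)
  pred <- ifelse(tis$p_wm$data > 0.5, 1L,
                 ifelse(tis$p_gm$data > 0.5, 2L,
                        ifelse(tis$p_csf$data > 0.5, 3L, 0L)))
  expect_gte(mean(pred[core] == lab[core]), 0.95)
  # ventricle voxels are confidently CSF
  vent <- lab == 3L &
    na23tsc:::voxel_dist2(gt$labels$meta,
                          na23tsc:::head_geometry(gt$labels$meta)$head_center) <
      40^2
  expect_gt(mean(tis$p_csf$data[vent] > 0.5), 0.95)
  s <- tis$p_wm$data + tis$p_gm$data + tis$p_csf$data
  expect_lte(max(s), 1 + 1e-9)
  expect_gte(min(s), 0)
  expect_error(segment_tissues(scalar_volume(array(1, c(8, 8, 8)),
                                             grid_meta(c(8, 8, 8), 1)),
                               array(TRUE, c(8, 8, 8))),
               "degenerate")
})

test_that("segmentation is deterministic for a fixed seed", {
  gt <- fx_phantom()$gt
  a <- segment_tissues(gt$anatomy, gt$brain_mask, seed = 5)
  b <- segment_tissues(gt$anatomy, gt$brain_mask, seed = 5)
  expect_identical(a$p_wm$data, b$p_wm$data)
})
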