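# analytic radial dose field: dose(r) = 44 * 2^(-(r - R0) / 2) outside a
# 10 mm core, so every isodose surface is a sphere with known radius
analytic_dose <- function(n = 96, h = 1) {
  meta <- grid_meta(rep(n, 3L), h)
  r <- sqrt(na23tsc:::voxel_dist2(meta, c(0, 0, 0)))
  R0 <- 10
  d <- ifelse(r <= R0, 44, 44 * 2^(-(r - R0) / 2))
  list(dose = scalar_volume(array(d, rep(n, 3L)), meta, "Gy"), meta = meta,
       R0 = R0, radius_of = function(level) R0 + 2 * log2(44 / level))
}

test_that("isodose shells partition the dose range and match analytic volumes", {
  ad <- analytic_dose()
  shells <- build_isodose_shells(ad$dose, rx_gy = 22)
  masks <- shells$masks
  # exact partition of {dose >= 2} \ {dose >= 22}
  overlap <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  expect_true(all(overlap <= 1L))
  dom <- ad$dose$data >= 2 & !(ad$dose$data >= 22)
  expect_equal(overlap == 1L, dom, ignore_attr = TRUE)
  # analytic spherical-shell volumes within one voxel shell
  for (i in seq_along(shells$levels)) {
    lo <- shells$levels[i]
    hi <- if (i < length(shells$levels)) shells$levels[i + 1] else 22
    r_out <- ad$radius_of(lo); r_in <- ad$radius_of(hi)
    v_true <- 4 / 3 * pi * (r_out^3 - r_in^3)
    v_shell <- 4 * pi * (r_out^2 + r_in^2) / 2  # one voxel (1 mm) shell
    expect_lt(abs(sum(masks[[i]]) - v_true), v_shell)
  }
  # mean dose strictly ordered across shells
  md <- vapply(masks, function(m) mean(ad$dose$data[m]), numeric(1))
  expect_true(all(diff(md) > 0))
})

test_that("degenerate dose fields yield empty flagged shells, not errors", {
  meta <- grid_meta(c(16, 16, 16), 2)
  cold <- scalar_volume(array(1, c(16, 16, 16)), meta, "Gy")
  expect_message(sh <- build_isodose_shells(cold, rx_gy = 22), "empty")
  expect_true(all(!vapply(sh$masks, any, logical(1))))
  expect_equal(length(sh$empty_levels), 8L)
})

test_that("GTV and PTV voxels are excluded from every shell", {
  fx <- fx_phantom()
  sh <- build_isodose_shells(fx$dg)
  excl <- Reduce(`|`, fx$dg$gtv_masks) | Reduce(`|`, fx$dg$ptv_masks)
  for (m in sh$masks) expect_false(any(m & excl))
  # partition of the peritumoral dose range outside the targets
  overlap <- Reduce(`+`, lapply(sh$masks, function(m) m + 0L))
  d <- fx$dg$dose$data
  dom <- d >= 2 & !(d >= 22) & !excl
  expect_equal(overlap == 1L, dom, ignore_attr = TRUE)
})

test_that("CSF subtraction removes what the segmentation calls CSF", {
  gt <- fx_phantom()$gt
  tis <- fx_segmentation()
  meta <- gt$labels$meta
  # ROI fully inside deep WM: nothing removed
  wm_roi <- erode_mask(gt$labels$data == 1L, meta, 8)
  r1 <- subtract_csf(wm_roi, tis)
  expect_equal(r1$n_removed, 0L)
  expect_equal(sum(r1$mask), sum(wm_roi))
  # ROI overlapping a ventricle: removal matches ground truth within 5%
  geo <- na23tsc:::head_geometry(meta)
  roi <- mask_sphere(meta, geo$head_center + c(9.6, 0, 0), 12)
  truth <- sum(roi & gt$labels$data == 3L)
  r2 <- subtract_csf(roi, tis)
  expect_lt(abs(r2$n_removed - truth) / truth, 0.05)
  # threshold 1 removes nothing
  expect_equal(subtract_csf(roi, tis, threshold = 1)$n_removed, 0L)
})

test_that("healthy cylinders are white-matter pure, clear of dose, reproducible", {
  fx <- fx_phantom()
  tis <- fx_segmentation()
  sh <- build_isodose_shells(fx$dg)
  hrs <- place_healthy_rois(tis, sh, fx$dg$gtv_masks, seed = 4)
  expect_length(hrs, 2L)
  shell_union <- Reduce(`|`, sh$masks) | sh$upper_bound_mask
  vol_target <- pi * 25 * 10
  for (hr in hrs) {
    expect_gte(mean(tis$p_wm$data[hr$mask] > 0.5), 0.95)
    expect_false(any(hr$mask & shell_union))
    expect_lt(abs(sum(hr$mask) * prod(fx$gt$labels$meta$spacing) -
                    vol_target) / vol_target, 0.35)
  }
  again <- place_healthy_rois(tis, sh, fx$dg$gtv_masks, seed = 4)
  expect_equal(hrs[[1]]$center, again[[1]]$center)
  expect_equal(hrs[[2]]$center, again[[2]]$center)
})

test_that("ROI statistics match hand calculations and flag empties", {
  meta <- grid_meta(c(4, 4, 4), 1)
  const <- scalar_volume(array(45, c(4, 4, 4)), meta, "mM")
  roi <- array(FALSE, c(4, 4, 4)); roi[1:2, 1, 1] <- TRUE
  s <- roi_statistics(const, roi, "r", "I")
  expect_equal(s$mean_tsc, 45)
  expect_equal(s$sd_tsc, 0)
  two <- scalar_volume(array(c(40, 50, rep(0, 62)), c(4, 4, 4)), meta)
  s2 <- roi_statistics(two, roi)
  expect_equal(s2$mean_tsc, 45)
  expect_equal(s2$sd_tsc, sqrt(50))
  s3 <- roi_statistics(const, array(FALSE, c(4, 4, 4)))
  expect_true(s3$flag_missing)
  expect_equal(s3$n_voxels, 0L)
})

test_that("healthy-ROI means recover the white-matter ground truth", {
  fx <- fx_phantom()
  tsc <- fx_tsc_ref("I")
  tis <- fx_segmentation()
  sh <- build_isodose_shells(fx$dg)
  hrs <- place_healthy_rois(tis, sh, fx$dg$gtv_masks, seed = 4)
  hr_mean <- mean(tsc$data[hrs[[1]]$mask | hrs[[2]]$mask])
  # T1-mismatch bias times tsc_wm, within the 10% recovery budget
  expect_lt(abs(hr_mean / 40 - 1), 0.15)
  expect_lt(abs(hr_mean / (40 * (1 - exp(-100 / 35))) - 1), 0.10)
})
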