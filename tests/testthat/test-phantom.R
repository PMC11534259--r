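small_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 48), voxel_size_mm = 3,
               tsc_params = tsc_evolution_params(noise_sd = 0), seed = 7, ...)
}

test_that("a lesion-free noise-free phantom is constant across scans", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), voxel_size_mm = 3,
                       lesion_centers = list(), lesion_radii_mm = numeric(0),
                       tsc_params = tsc_evolution_params(noise_sd = 0),
                       seed = 7)
  gt <- generate_phantom(spec)
  expect_identical(gt$tsc$I$data, gt$tsc$II$data)
  expect_identical(gt$tsc$I$data, gt$tsc$III$data)
  wm <- gt$labels$data == phantom_labels[["wm"]]
  expect_true(all(gt$tsc$I$data[wm] == 40))
})

test_that("phantom generation is bit-identical for a fixed seed", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), voxel_size_mm = 3, seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$tsc$I$data, b$tsc$I$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$anatomy$data, b$anatomy$data)
})

test_that("GTV label volume matches the analytic sphere volume", {
  meta0 <- grid_meta(c(96, 96, 96), 1.5)
  geo <- na23tsc:::head_geometry(meta0)
  spec <- phantom_spec(grid_shape = c(96, 96, 96), voxel_size_mm = 1.5,
                       lesion_centers = list(geo$default_lesion_center),
                       lesion_radii_mm = 5, seed = 1)
  gt <- generate_phantom(spec)
  v <- sum(gt$labels$data == 11L) * 1.5^3
  target <- 4 / 3 * pi * 125
  shell <- (sum(mask_sphere(gt$labels$meta, geo$default_lesion_center, 6.5)) -
              sum(mask_sphere(gt$labels$meta, geo$default_lesion_center, 3.5))) *
    1.5^3 / 2
  expect_lt(abs(v - target), shell)
})

test_that("phantom rejects invalid lesion placement", {
  expect_error(generate_phantom(
    phantom_spec(grid_shape = c(48, 48, 48), voxel_size_mm = 3,
                 lesion_centers = list(c(70, 70, 70)), lesion_radii_mm = 5)),
    "outside the brain")
  expect_warning(
    phantom_spec(grid_shape = c(48, 48, 48), voxel_size_mm = 3,
                 lesion_radii_mm = 2),
    "64 mm")
})

test_that("dose evolution follows the acute/late model exactly", {
  gt <- generate_phantom(small_spec())
  meta <- gt$labels$meta
  # zero dose: scan II equals scan I exactly
  zero <- scalar_volume(array(0, meta$shape), meta, "Gy")
  gt0 <- compose_evolution(gt, zero)
  expect_equal(gt0$tsc$II$data, gt0$tsc$I$data)
  # uniform 18 Gy: rise of alpha * 18 = 6.3 mM in WM, none in VH/CSF
  d18 <- scalar_volume(array(18, meta$shape), meta, "Gy")
  gt18 <- compose_evolution(gt, d18)
  wm <- gt18$labels$data == phantom_labels[["wm"]]
  vh <- gt18$labels$data == phantom_labels[["vh_left"]]
  csf <- gt18$labels$data == phantom_labels[["csf"]]
  expect_equal(gt18$tsc$II$data[wm] - gt18$tsc$I$data[wm],
               rep(0.35 * 18, sum(wm)))
  expect_true(all(gt18$tsc$II$data[vh] == 145))
  expect_true(all(gt18$tsc$III$data[vh] == 145))
  expect_equal(gt18$tsc$II$data[csf], gt18$tsc$I$data[csf])
  # late decline: -beta * (18 - floor)
  expect_equal(gt18$tsc$III$data[wm] - gt18$tsc$I$data[wm],
               rep(-0.55 * 16, sum(wm)))
  expect_error(compose_evolution(gt, scalar_volume(array(0, c(8, 8, 8)),
                                                   grid_meta(c(8, 8, 8), 3))),
               "different grids")
})

test_that("scan II - scan I difference is monotone in dose", {
  gt <- generate_phantom(small_spec())
  dg <- compute_dose(gt$labels, list(prescription_spec(22)))
  gt <- compose_evolution(gt, dg$dose)
  free <- gt$labels$data %in% c(1L, 2L, 6L)
  d <- dg$dose$data[free]
  diff2 <- gt$tsc$II$data[free] - gt$tsc$I$data[free]
  ord <- order(d)
  expect_true(all(diff(diff2[ord]) > -1e-9))
})

test_that("default WM concentrations sit in the healthy 30-56 mM range", {
  gt <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                      voxel_size_mm = 3, seed = 2))
  wm_mean <- mean(gt$tsc$I$data[gt$labels$data == phantom_labels[["wm"]]])
  expect_gt(wm_mean, 30)
  expect_lt(wm_mean, 56)
})

test_that("phantom writes a complete NIfTI set with spec sidecar", {
  gt <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                      voxel_size_mm = 6, seed = 1,
                                      lesion_centers = list(),
                                      lesion_radii_mm = numeric(0)))
  dir <- withr::local_tempdir()
  write_phantom(gt, dir)
  expect_true(all(file.exists(file.path(dir,
    c("labels.nii.gz", "tsc_scanI.nii.gz", "tsc_scanII.nii.gz",
      "tsc_scanIII.nii.gz", "t1.nii.gz", "t2star.nii.gz",
      "anatomy.nii.gz", "phantom.json")))))
  back <- read_volume(file.path(dir, "labels.nii.gz"))
  expect_equal(back$data, gt$labels$data)
})
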