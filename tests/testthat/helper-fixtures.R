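# Shared fixtures, built lazily and cached for the whole test run.
# Problem sizes are scaled down from the clinical protocol (64^3 ground
# truth, 2000 of 9000 spokes) to keep the suite fast while leaving the
# physics intact.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# noise-free single-lesion head phantom on a 64^3, 2.5 mm grid (160 mm FOV)
fx_phantom <- function() fx_get("phantom", function() {
  meta0 <- grid_meta(c(64, 64, 64), 2.5)
  geo <- na23tsc:::head_geometry(meta0)
  spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size_mm = 2.5,
                       lesion_centers = list(geo$default_lesion_center),
                       lesion_radii_mm = 8,
                       tsc_params = tsc_evolution_params(noise_sd = 0),
                       seed = 3)
  gt <- generate_phantom(spec)
  dg <- compute_dose(gt$labels, list(prescription_spec(22)))
  gt <- compose_evolution(gt, dg$dose)
  list(gt = gt, dg = dg)
})

fx_params <- function() sequence_params(n_spokes = 2000, noise_sd = 0)

fx_traj <- function() fx_get("traj", function() make_trajectory(fx_params()))

# noise-free reconstruction of scan I of the shared phantom
fx_recon <- function(scan = "I") fx_get(paste0("recon_", scan), function() {
  gt <- fx_phantom()$gt
  p <- fx_params()
  sig <- steady_state_signal(gt$tsc[[scan]], gt$t1, gt$t2star, p)
  ks <- simulate_acquisition(sig, fx_traj(), noise_sd = 0, seed = 1)
  reconstruct(ks)
})

# TSC map of a scan, quantified against the left VH, on the reference grid
fx_tsc_ref <- function(scan = "I") fx_get(paste0("tsc_", scan), function() {
  gt <- fx_phantom()$gt
  p <- fx_params()
  rec <- fx_recon(scan)
  vh <- resample_mask(gt$labels$data == phantom_labels[["vh_left"]],
                      rigid_transform(), rec$meta, meta = gt$labels$meta)
  cal <- calibrate_vh(rec, vh, p)
  tsc <- quantify_tsc(rec, cal)
  resample_volume(tsc$values, rigid_transform(), gt$labels$meta)
})

fx_segmentation <- function() fx_get("segmentation", function() {
  gt <- fx_phantom()$gt
  segment_tissues(gt$anatomy, gt$brain_mask, seed = 2)
})

# clean white matter: inside the WM label, one PSF main lobe away from any
# other tissue, and outside the peritumoral edema range
fx_clean_wm <- function() fx_get("clean_wm", function() {
  gt <- fx_phantom()$gt
  meta <- gt$labels$meta
  lesion <- gt$labels$data >= 11L
  erode_mask(gt$labels$data == phantom_labels[["wm"]], meta, 6) &
    !dilate_mask(lesion, meta, 2 * gt$spec$edema_extent_mm)
})

# fine-grid (1 mm) phantom + dose for shell/slope analyses (two-grid design)
fx_fine_study <- function() fx_get("fine_study", function() {
  cfg <- study_config(n_lesions = 1, grid_shape = c(128, 128, 128),
                      voxel_size_mm = 1, noise_sd = 0,
                      registration = "true",
                      tsc_params = tsc_evolution_params(noise_sd = 0),
                      seed = 11)
  simulate_lesion_study(cfg, 1, scans = c("I", "II"))
})

expect_rel_error <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
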