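#' Compartment label codes used by the digital head phantom
#'
#' Named integer constants for the phantom's tissue compartments. Gross
#' tumour volumes (GTVs) are numbered `GTV1 = 11`, `GTV2 = 12`, ...
#' @export
phantom_labels <- c(background = 0L, wm = 1L, gm = 2L, csf = 3L,
                    vh_left = 4L, vh_right = 5L, edema = 6L,
                    soft_tissue = 7L)

GTV_BASE <- 10L
gtv_label <- function(i) GTV_BASE + as.integer(i)

#' Tissue sodium concentration evolution parameters
#'
#' Baseline compartment concentrations and the dose-coupled longitudinal
#' effect sizes of the three-timepoint evolution (scan I two days before
#' radiosurgery, scan II five days after, scan III forty days after).
#' Baseline concentrations follow literature values for healthy brain
#' (white matter 40 mM, grey matter 45 mM, CSF 135 mM) with the vitreous
#' humor fixed at 145 mM, the standard extracellular reference. The lesion
#' baseline of 61 mM reflects the elevated sodium of untreated metastases.
#'
#' The longitudinal model is phenomenological: peritumoral tissue gains
#' `acute_alpha` mM per Gy of local dose at scan II (acute radiation injury
#' plus edema) and loses `late_beta` mM per Gy above `recovery_floor_gy`
#' relative to baseline at scan III (late recovery); the GTV follows its
#' own rise-then-fall offsets since its response is not dose-resolved.
#'
#' @param tsc_wm,tsc_gm,tsc_csf,tsc_vh baseline concentrations (mM).
#' @param tsc_gtv_baseline lesion baseline concentration (mM).
#' @param tsc_soft scalp/orbital soft-tissue concentration (mM).
#' @param baseline_slope_gamma mM/Gy elevation of the *baseline* (scan I)
#'   peritumoral TSC with eventual dose proximity (vasogenic edema tracks
#'   distance to the lesion, which the dose field parameterizes).
#' @param acute_alpha mM/Gy acute rise at scan II.
#' @param late_beta mM/Gy late decline below baseline at scan III.
#' @param recovery_floor_gy dose below which no late decline occurs (Gy).
#' @param gtv_acute_mm,gtv_late_mm GTV offsets (mM) at scans II and III
#'   relative to baseline.
#' @param noise_sd voxel-wise biological TSC jitter (mM, Gaussian).
#' @return object of class `tsc_evolution_params`.
#' @export
tsc_evolution_params <- function(tsc_wm = 40, tsc_gm = 45, tsc_csf = 135,
                                 tsc_vh = 145, tsc_gtv_baseline = 61,
                                 tsc_soft = 25,
                                 baseline_slope_gamma = 0.5,
                                 acute_alpha = 0.35, late_beta = 0.55,
                                 recovery_floor_gy = 2,
                                 gtv_acute_mm = 7, gtv_late_mm = -3,
                                 noise_sd = 2) {
  p <- as.list(environment())
  if (any(unlist(p[c("tsc_wm", "tsc_gm", "tsc_csf", "tsc_vh",
                     "tsc_gtv_baseline")]) < 0))
    stop("all concentrations must be >= 0")
  if (p$tsc_gtv_baseline <= p$tsc_wm)
    stop("tsc_gtv_baseline must exceed tsc_wm (lesions are sodium-elevated)")
  if (p$tsc_vh != 145)
    warning("vitreous humor reference overridden (", p$tsc_vh,
            " mM instead of the fixed 145 mM assumption)")
  structure(p, class = "tsc_evolution_params")
}

#' Specification of a synthetic longitudinal head phantom
#'
#' Geometry and evolution parameters for [generate_phantom()]. The default
#' is a 160 mm field of view at 1 mm isotropic ground-truth resolution —
#' deliberately much finer than the 4 mm nominal sodium acquisition, so
#' partial-volume effects in the simulated images are emergent rather than
#' modelled. The head is an ellipsoidal brain (cortical grey-matter shell
#' around white matter, ventricular and subarachnoid CSF) with two 11
#' mm-radius vitreous-humor spheres anterior to the brain; "left" follows
#' the LPS patient convention (+x).
#'
#' @param grid_shape voxels per axis (default `c(160, 160, 160)`).
#' @param voxel_size_mm isotropic spacing (default 1).
#' @param lesion_centers list of length-3 LPS points (mm) or NULL for the
#'   default single right-frontal lesion.
#' @param lesion_radii_mm per-lesion radius (default 6 mm, a 0.9 cm^3 GTV,
#'   typical of the treated metastases).
#' @param edema_extent_mm decay length of the peritumoral baseline
#'   elevation (mm).
#' @param tsc_params a [tsc_evolution_params()].
#' @param seed integer RNG seed; all phantom randomness derives from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160, 160, 160), voxel_size_mm = 1,
                         lesion_centers = NULL, lesion_radii_mm = 6,
                         edema_extent_mm = 10,
                         tsc_params = tsc_evolution_params(), seed = 1L) {
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be > 0")
  meta <- grid_meta(grid_shape, spacing = voxel_size_mm)
  geo <- head_geometry(meta)
  if (is.null(lesion_centers))
    lesion_centers <- list(geo$default_lesion_center)
  if (is.numeric(lesion_centers) && !is.list(lesion_centers))
    lesion_centers <- list(lesion_centers)
  lesion_radii_mm <- rep_len(lesion_radii_mm, length(lesion_centers))
  vols <- 4 / 3 * pi * lesion_radii_mm^3
  if (length(vols) && all(vols < 64))
    warning("no lesion reaches the 64 mm^3 evaluability threshold")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 lesion_centers = lesion_centers,
                 lesion_radii_mm = lesion_radii_mm,
                 edema_extent_mm = edema_extent_mm,
                 tsc_params = tsc_params, seed = as.integer(seed)),
            class = "phantom_spec")
}

# analytic head geometry scaled to the field of view (LPS, centred grids)
head_geometry <- function(meta) {
  fov <- grid_fov(meta)
  c0 <- meta$origin + (meta$shape - 1) * meta$spacing / 2   # FOV centre
  sc <- min(fov) / 160                                      # scale to FOV
  list(
    head_center = c0 + c(0, 0.05, 0) * min(fov),
    brain_semi = c(62, 72, 58) * sc,          # skull-stripped brain envelope
    gm_thick = 4 * sc,                        # cortical ribbon thickness
    rim_thick = 2.5 * sc,                     # subarachnoid CSF rim
    vent_semi = c(8, 22, 10) * sc,            # lateral ventricle ellipsoids
    vent_dx = 12 * sc,
    eye_radius = 11 * sc,
    eye_dx = 31 * sc,                         # eye lateral offset
    eye_dy = -72 * sc,                        # anterior (-y) of head centre
    eye_dz = -18 * sc,
    scalp_thick = 6 * sc,                     # scalp/skull soft-tissue shell
    orbit_thick = 5 * sc,                     # orbital tissue around the eyes
    default_lesion_center = c0 + c(-28, -20, 12) * sc       # right frontal
  )
}

ellipsoid_mask <- function(meta, center, semi) {
  ax <- lapply(1:3, function(a)
    ((meta$origin[a] + (seq_len(meta$shape[a]) - 1) * meta$spacing[a]) -
       center[a]) / semi[a])
  o <- outer(ax[[1]]^2, ax[[2]]^2, "+")
  outer(o, ax[[3]]^2, "+") <= 1
}

#' Generate a synthetic longitudinal head phantom
#'
#' Builds the ground truth the rest of the pipeline is evaluated against:
#' a compartment label volume, per-timepoint true TSC maps (initially the
#' common baseline; dose-dependent evolution is added by
#' [compose_evolution()]), compartment T1 and T2* maps, and an MPRAGE-like
#' anatomical reference with realistic relative contrast.
#'
#' Relaxation defaults are T1 = 35 ms for brain tissue, T1 = 50 ms for
#' vitreous humor and CSF (fluid-like), and a monoexponential T2* = 4 ms
#' everywhere.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ground_truth`: list with `labels`
#'   ([label_volume()]), `tsc` (list of three [scalar_volume()] maps, mM),
#'   `t1`, `t2star` (ms), `anatomy` (a.u.), `brain_mask`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  meta <- grid_meta(spec$grid_shape, spacing = spec$voxel_size_mm)
  geo <- head_geometry(meta)
  p <- spec$tsc_params

  brain_outer <- ellipsoid_mask(meta, geo$head_center, geo$brain_semi)
  brain_inner <- ellipsoid_mask(meta, geo$head_center,
                                geo$brain_semi - geo$rim_thick)
  gm_inner <- ellipsoid_mask(meta, geo$head_center,
                             geo$brain_semi - geo$rim_thick - geo$gm_thick)
  vent_l <- ellipsoid_mask(meta, geo$head_center + c(geo$vent_dx, 0, 0),
                           geo$vent_semi)
  vent_r <- ellipsoid_mask(meta, geo$head_center - c(geo$vent_dx, 0, 0),
                           geo$vent_semi)
  eye_c <- geo$head_center + c(0, geo$eye_dy, geo$eye_dz)
  vh_l <- mask_sphere(meta, eye_c + c(geo$eye_dx, 0, 0), geo$eye_radius)
  vh_r <- mask_sphere(meta, eye_c - c(geo$eye_dx, 0, 0), geo$eye_radius)
  if (any(vh_l & brain_outer) || any(vh_r & brain_outer))
    stop("phantom geometry error: vitreous humor overlaps the brain")

  # scalp/skull envelope and orbital soft tissue embedding brain and eyes:
  # heads are not surrounded by vacuum, and the soft-tissue step keeps
  # Gibbs ringing at organ boundaries realistic rather than maximal
  envelope <- ellipsoid_mask(meta, geo$head_center,
                             geo$brain_semi + geo$scalp_thick) |
    mask_sphere(meta, eye_c + c(geo$eye_dx, 0, 0),
                geo$eye_radius + geo$orbit_thick) |
    mask_sphere(meta, eye_c - c(geo$eye_dx, 0, 0),
                geo$eye_radius + geo$orbit_thick)

  lab <- array(phantom_labels[["background"]], meta$shape)
  lab[envelope] <- phantom_labels[["soft_tissue"]]
  lab[brain_outer] <- phantom_labels[["csf"]]          # subarachnoid rim
  lab[brain_inner] <- phantom_labels[["gm"]]
  lab[gm_inner] <- phantom_labels[["wm"]]
  lab[vent_l | vent_r] <- phantom_labels[["csf"]]
  lab[vh_l] <- phantom_labels[["vh_left"]]
  lab[vh_r] <- phantom_labels[["vh_right"]]

  # lesions: spheres, must lie inside the brain and clear of fluid spaces
  lesion_rim_dist <- NULL
  for (i in seq_along(spec$lesion_centers)) {
    ctr <- spec$lesion_centers[[i]]
    r <- spec$lesion_radii_mm[i]
    gtv <- mask_sphere(meta, ctr, r)
    if (!any(gtv)) stop("lesion ", i, " is smaller than one voxel")
    if (any(gtv & !brain_inner))
      stop("lesion ", i, " at (", paste(signif(ctr, 4), collapse = ", "),
           ") extends outside the brain mask")
    if (any(gtv & (vh_l | vh_r)))
      stop("lesion ", i, " overlaps the vitreous humor")
    lab[gtv] <- gtv_label(i)
    d2 <- voxel_dist2(meta, ctr)
    rim <- pmax(0, sqrt(d2) - r)          # distance to lesion rim
    lesion_rim_dist <- if (is.null(lesion_rim_dist)) rim
                       else pmin(lesion_rim_dist, rim)
  }

  # baseline TSC: compartment values + peritumoral edema decaying from the
  # lesion rim toward white-matter levels with length edema_extent_mm
  tsc0 <- array(0, meta$shape)
  tsc0[lab == phantom_labels[["wm"]]] <- p$tsc_wm
  tsc0[lab == phantom_labels[["gm"]]] <- p$tsc_gm
  tsc0[lab == phantom_labels[["csf"]]] <- p$tsc_csf
  tsc0[lab == phantom_labels[["vh_left"]] |
         lab == phantom_labels[["vh_right"]]] <- p$tsc_vh
  tsc0[lab == phantom_labels[["soft_tissue"]]] <- p$tsc_soft
  if (!is.null(lesion_rim_dist)) {
    for (i in seq_along(spec$lesion_centers))
      tsc0[lab == gtv_label(i)] <- p$tsc_gtv_baseline
    edema_amp <- (p$tsc_gtv_baseline - p$tsc_wm) * 0.6
    near <- lesion_rim_dist <= 2 * spec$edema_extent_mm
    peri <- near & (lab == phantom_labels[["wm"]] |
                      lab == phantom_labels[["gm"]])
    bump <- edema_amp * exp(-lesion_rim_dist[peri] / spec$edema_extent_mm)
    tsc0[peri] <- tsc0[peri] + bump
    ed_mask <- array(FALSE, meta$shape)
    ed_mask[peri] <- bump > 0.25 * edema_amp
    lab[ed_mask] <- phantom_labels[["edema"]]
  }

  # biological voxel-wise jitter (outside fluid references)
  set.seed(spec$seed)
  if (p$noise_sd > 0) {
    jit <- array(stats::rnorm(prod(meta$shape), 0, p$noise_sd), meta$shape)
    keep <- lab != phantom_labels[["vh_left"]] &
      lab != phantom_labels[["vh_right"]] &
      lab != phantom_labels[["background"]]
    tsc0[keep] <- pmax(0, tsc0[keep] + jit[keep])
  }

  # relaxation maps
  t1 <- array(35, meta$shape)
  fluid <- lab == phantom_labels[["csf"]] |
    lab == phantom_labels[["vh_left"]] | lab == phantom_labels[["vh_right"]]
  t1[fluid] <- 50
  t2s <- array(4, meta$shape)

  # MPRAGE-like anatomical contrast (a.u.), mildly noisy
  contrast <- c(background = 0.02, wm = 0.75, gm = 0.55, csf = 0.12,
                vh_left = 0.10, vh_right = 0.10, edema = 0.62,
                soft_tissue = 0.50)
  anat <- array(contrast[["background"]], meta$shape)
  for (nm in names(contrast)) anat[lab == phantom_labels[[nm]]] <- contrast[[nm]]
  for (i in seq_along(spec$lesion_centers))
    anat[lab == gtv_label(i)] <- 0.92      # contrast-enhancing lesion
  anat <- anat + array(stats::rnorm(prod(meta$shape), 0, 0.01), meta$shape)

  tsc_map <- scalar_volume(tsc0, meta, units = "mM")
  structure(list(
    labels = label_volume(lab, meta, labels = phantom_labels),
    tsc = list(I = tsc_map, II = tsc_map, III = tsc_map),
    t1 = scalar_volume(t1, meta, units = "ms"),
    t2star = scalar_volume(t2s, meta, units = "ms"),
    anatomy = scalar_volume(anat, meta, units = "a.u."),
    brain_mask = brain_outer,
    spec = spec), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth phantom:", format(x$labels$meta), "\n",
      length(x$spec$lesion_centers), "lesion(s); scans:",
      paste(names(x$tsc), collapse = ", "), "\n")
}

#' Apply the dose-dependent longitudinal TSC evolution
#'
#' Rewrites the scan I/II/III true TSC maps of a phantom given a dose
#' field: the baseline gains `baseline_slope_gamma * D` (edema tracking
#' dose proximity), scan II adds the acute response `acute_alpha * D`, and
#' scan III subtracts the late decline
#' `late_beta * max(0, D - recovery_floor_gy)` relative to baseline.
#' CSF and vitreous humor are never modified; the GTV follows its own
#' rise-then-fall offsets (`gtv_acute_mm`, `gtv_late_mm`).
#'
#' @param gt a `ground_truth` from [generate_phantom()].
#' @param dose a [scalar_volume()] of absorbed dose (Gy) on the same grid.
#' @param params a [tsc_evolution_params()]; defaults to the phantom's own.
#' @return the modified `ground_truth`.
#' @export
compose_evolution <- function(gt, dose, params = gt$spec$tsc_params) {
  stopifnot(inherits(gt, "ground_truth"))
  assert_same_grid(gt$labels, dose, "phantom labels and dose grid")
  lab <- gt$labels$data
  d <- dose$data
  p <- params
  fixedc <- lab == phantom_labels[["csf"]] |
    lab == phantom_labels[["vh_left"]] | lab == phantom_labels[["vh_right"]] |
    lab == phantom_labels[["background"]]
  in_gtv <- lab >= GTV_BASE
  free <- !fixedc & !in_gtv

  base <- gt$tsc$I$data
  base[free] <- base[free] + p$baseline_slope_gamma * d[free]

  set.seed(gt$spec$seed + 1L)
  jit <- function() {
    if (p$noise_sd <= 0) return(0)
    array(stats::rnorm(length(base), 0, p$noise_sd), dim(base))
  }
  j2 <- jit(); j3 <- jit()

  # GTV offsets are a radiation response: unirradiated lesions stay flat
  irradiated <- as.numeric(d[in_gtv] > 0)
  s2 <- base
  s2[free] <- base[free] + p$acute_alpha * d[free] +
    (if (is.array(j2)) j2[free] else 0)
  s2[in_gtv] <- base[in_gtv] + p$gtv_acute_mm * irradiated +
    (if (is.array(j2)) j2[in_gtv] else 0)

  s3 <- base
  s3[free] <- base[free] -
    p$late_beta * pmax(0, d[free] - p$recovery_floor_gy) +
    (if (is.array(j3)) j3[free] else 0)
  s3[in_gtv] <- base[in_gtv] + p$gtv_late_mm * irradiated +
    (if (is.array(j3)) j3[in_gtv] else 0)

  meta <- gt$labels$meta
  gt$tsc <- list(I = scalar_volume(base, meta, "mM"),
                 II = scalar_volume(pmax(s2, 0), meta, "mM"),
                 III = scalar_volume(pmax(s3, 0), meta, "mM"))
  gt
}

#' Write a phantom ground truth to disk as a NIfTI set
#'
#' Emits `labels.nii.gz`, `tsc_scanI/II/III.nii.gz`, `t1.nii.gz`,
#' `t2star.nii.gz`, `anatomy.nii.gz` and a `phantom.json` sidecar holding
#' the generating [phantom_spec()].
#'
#' @param gt a `ground_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(gt$labels, file.path(dir, "labels.nii.gz"))
  for (s in names(gt$tsc))
    write_volume(gt$tsc[[s]], file.path(dir, paste0("tsc_scan", s, ".nii.gz")))
  write_volume(gt$t1, file.path(dir, "t1.nii.gz"))
  write_volume(gt$t2star, file.path(dir, "t2star.nii.gz"))
  write_volume(gt$anatomy, file.path(dir, "anatomy.nii.gz"))
  sp <- gt$spec
  sp$tsc_params <- unclass(sp$tsc_params)
  jsonlite::write_json(c(unclass(sp), tool_info()),
                       file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
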