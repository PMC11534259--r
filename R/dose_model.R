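#' Single-lesion radiosurgery prescription
#'
#' One Gamma-Knife-like single-fraction prescription: the dose is
#' prescribed to the 50% isodose surface enclosing the planning target
#' volume (PTV), so the maximum dose in the lesion core is twice the
#' prescription. The PTV is the GTV expanded by `margin_mm` (0 for frame
#' fixation, 1 mm for thermoplastic mask fixation).
#'
#' @param rx_dose_gy prescription dose in Gy; 16-22 Gy is the clinically
#'   faithful range (a warning is issued outside it).
#' @param margin_mm GTV-to-PTV expansion (mm).
#' @param falloff_half_mm distance over which the dose halves outside the
#'   PTV surface (mm); 2 mm mimics the sharp radiosurgical gradient.
#' @return object of class `prescription_spec`.
#' @export
prescription_spec <- function(rx_dose_gy, margin_mm = 1, falloff_half_mm = 2) {
  stopifnot(rx_dose_gy > 0, margin_mm >= 0, falloff_half_mm > 0)
  if (rx_dose_gy < 16 || rx_dose_gy > 22)
    warning("prescription ", rx_dose_gy,
            " Gy is outside the 16-22 Gy range used clinically")
  if (!margin_mm %in% c(0, 1))
    warning("margin ", margin_mm, " mm; fixation systems use 0 or 1 mm")
  structure(list(rx_dose_gy = rx_dose_gy, margin_mm = margin_mm,
                 falloff_half_mm = falloff_half_mm),
            class = "prescription_spec")
}

#' Expand a mask by a Euclidean margin (GTV to PTV)
#'
#' Returns the set of voxels whose centre lies within `margin_mm` (exact
#' Euclidean distance, in mm) of the input mask; `margin_mm = 0` returns
#' the input unchanged.
#'
#' @param gtv_mask a [label_volume()] (non-zero = mask) or logical array
#'   with an attached meta via the `meta` argument.
#' @param margin_mm expansion margin (mm), >= 0.
#' @param meta required when `gtv_mask` is a bare array.
#' @return a [label_volume()] (0/1 mask) on the same grid.
#' @export
expand_margin <- function(gtv_mask, margin_mm, meta = NULL) {
  if (inherits(gtv_mask, "label_volume")) {
    meta <- gtv_mask$meta
    m <- gtv_mask$data != 0L
  } else {
    stopifnot(!is.null(meta))
    m <- gtv_mask != 0
  }
  if (!any(m)) stop("expand_margin: input mask is empty")
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  out <- if (margin_mm == 0) m else dilate_mask(m, meta, margin_mm)
  label_volume(array(as.integer(out), meta$shape), meta)
}

#' Compute a simplified radiosurgery dose field
#'
#' For each lesion, with `s` the signed Euclidean distance to the PTV
#' surface (negative inside), the dose is `2 * rx * g(s)` with
#' `g(s) = min(1, 0.5 * 2^(-s / falloff_half_mm))`: exactly the
#' prescription on the PTV surface (the 50% isodose), twice the
#' prescription in the core (reached one half-distance inside the
#' surface), and exponential fall-off outside. Multiple lesions combine by
#' voxel-wise sum, capped at twice the largest prescription. The
#' functional form is a geometric stand-in for a clinical planning system:
#' only the geometry of the resulting isodose shells matters downstream.
#'
#' @param labels the phantom [label_volume()] carrying GTV labels (values
#'   `>= 11`), or a list of logical GTV masks via `gtv_masks`.
#' @param specs list of [prescription_spec()], one per lesion.
#' @param gtv_masks optional list of logical arrays overriding label lookup.
#' @return object of class `dose_grid`: `dose` ([scalar_volume()], Gy),
#'   `prescriptions`, `ptv_masks`, `gtv_masks`, and default shell levels
#'   `d_levels = c(2, 3, 4, 6, 8, 10, 12, 18)`.
#' @export
compute_dose <- function(labels, specs, gtv_masks = NULL) {
  if (inherits(specs, "prescription_spec")) specs <- list(specs)
  meta <- labels$meta
  if (is.null(gtv_masks)) {
    ids <- sort(unique(as.vector(labels$data[labels$data > GTV_BASE])))
    if (length(ids) == 0L) stop("no GTV labels (values > 10) found")
    gtv_masks <- lapply(ids, function(v) labels$data == v)
  }
  if (length(specs) != length(gtv_masks))
    stop("need one prescription_spec per lesion (",
         length(gtv_masks), " lesions, ", length(specs), " specs)")
  dose <- array(0, meta$shape)
  ptvs <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ptv <- expand_margin(gtv_masks[[i]] + 0L, sp$margin_mm, meta = meta)
    ptvs[[i]] <- ptv$data != 0L
    s <- signed_distance(ptvs[[i]], meta)
    # the physical surface lies between voxel-centre layers: shift the
    # centre-to-centre distances half a voxel toward the boundary so the
    # surface dose is the prescription, not one half-layer off
    s <- s - sign(s) * pmin(abs(s), mean(meta$spacing) / 2)
    g <- pmin(1, 0.5 * 2^(-s / sp$falloff_half_mm))
    dose <- dose + 2 * sp$rx_dose_gy * g
  }
  cap <- 2 * max(vapply(specs, `[[`, numeric(1), "rx_dose_gy"))
  dose <- pmin(dose, cap)
  structure(list(dose = scalar_volume(dose, meta, units = "Gy"),
                 prescriptions = specs,
                 gtv_masks = gtv_masks, ptv_masks = ptvs,
                 d_levels = c(2, 3, 4, 6, 8, 10, 12, 18)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d lesion(s), rx %s Gy, max %.1f Gy\n",
              length(x$prescriptions),
              paste(vapply(x$prescriptions, `[[`, numeric(1), "rx_dose_gy"),
                    collapse = "/"),
              max(x$dose$data)))
}

#' Cohort summary of prescription doses
#'
#' Mean and sample (n-1) standard deviation of the prescribed doses,
#' reported to one decimal as in clinical summaries.
#'
#' @param specs list of [prescription_spec()] (or a numeric dose vector);
#'   at least two for the SD.
#' @return list with `n`, `mean_gy`, `sd_gy` (rounded to one decimal) and
#'   the unrounded `mean_raw`, `sd_raw`.
#' @export
summarize_prescriptions <- function(specs) {
  doses <- if (is.numeric(specs)) specs
           else vapply(specs, `[[`, numeric(1), "rx_dose_gy")
  if (length(doses) == 0L) stop("no prescriptions to summarize")
  if (length(doses) < 2L) stop("need >= 2 prescriptions for a sample SD")
  m <- mean(doses)
  s <- stats::sd(doses)
  list(n = length(doses), mean_gy = round(m, 1), sd_gy = round(s, 1),
       mean_raw = m, sd_raw = s)
}

#' Write a dose grid to NIfTI + JSON prescriptions
#' @param dg a `dose_grid`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dose <- function(dg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(dg$dose, file.path(dir, "dose.nii.gz"))
  jsonlite::write_json(
    list(prescriptions = lapply(dg$prescriptions, unclass),
         d_levels = dg$d_levels, provenance = tool_info()),
    file.path(dir, "prescriptions.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
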