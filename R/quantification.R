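#' Saturation-recovery T1 correction factor
#'
#' Fraction of the fully-relaxed signal recovered at repetition time
#' `tr_ms` for a tissue with longitudinal relaxation time `t1_ms`:
#' `1 - exp(-TR/T1)`. With the sequence's TR = 100 ms and the vitreous
#' humor's T1 = 50 ms this is `1 - exp(-2) ~ 0.8647`.
#'
#' @param tr_ms repetition time (ms), > 0.
#' @param t1_ms longitudinal relaxation time (ms), > 0.
#' @return scalar in (0, 1).
#' @export
t1_correction_factor <- function(tr_ms, t1_ms) {
  if (tr_ms <= 0 || t1_ms <= 0)
    stop("tr_ms and t1_ms must be positive")
  1 - exp(-tr_ms / t1_ms)
}

#' Calibrate sodium signal against the left vitreous humor
#'
#' The quantification reference: mean sodium signal within the (eroded)
#' left vitreous humor ROI, corrected for residual T1 weighting by
#' dividing by `1 - exp(-TR/T1_VH)` with T1(VH) = 50 ms. The VH sodium
#' concentration is taken as a constant 145 mM (extracellular sodium).
#' The mask is eroded by one apparent voxel to suppress partial-volume
#' contamination at the organ boundary; a single-voxel mask still yields
#' a calibration but is flagged low-confidence, as is a reference signal
#' at or below the background noise floor.
#'
#' @param sodium_img reconstructed sodium [scalar_volume()].
#' @param vh_mask left-VH mask ([label_volume()] or logical array) already
#'   transferred to the sodium grid.
#' @param params a [sequence_params()] (supplies TR).
#' @param t1_vh_ms vitreous-humor T1 (ms).
#' @param c_vh_mm reference concentration (mM).
#' @param erode_mm erosion radius (mm); defaults to one apparent voxel.
#' @param noise_floor optional background signal level for the QC flag.
#' @return object of class `quant_calibration`: `si_vh`, `si_vh_t1corr`,
#'   `correction_factor`, `n_voxels`, `flags`.
#' @export
calibrate_vh <- function(sodium_img, vh_mask, params, t1_vh_ms = 50,
                         c_vh_mm = 145, erode_mm = NULL, noise_floor = 0) {
  meta <- sodium_img$meta
  m <- if (inherits(vh_mask, "label_volume")) vh_mask$data != 0L
       else as.array(vh_mask) != 0
  if (!identical(as.integer(dim(m)), meta$shape))
    stop("vh_mask must be on the sodium image grid (transfer it first)")
  erode_mm <- erode_mm %||% params$apparent_res_mm
  flags <- character(0)
  er <- erode_mask(m, meta, erode_mm)
  if (!any(er)) {
    if (!any(m)) stop("calibrate_vh: vitreous humor mask is empty")
    er <- m
    flags <- c(flags, "erosion_emptied_mask")
  }
  if (sum(er) < 2) flags <- c(flags, "low_confidence_single_voxel")
  si <- mean(sodium_img$data[er])
  if (si <= 0) stop("non-positive vitreous humor signal; wrong mask?")
  if (si <= noise_floor) flags <- c(flags, "reference_at_noise_floor")
  cf <- t1_correction_factor(params$tr_ms, t1_vh_ms)
  structure(list(c_vh_mm = c_vh_mm, t1_vh_ms = t1_vh_ms,
                 tr_ms = params$tr_ms, correction_factor = cf,
                 si_vh = si, si_vh_t1corr = si / cf,
                 n_voxels = sum(er), flags = flags),
            class = "quant_calibration")
}

#' @export
print.quant_calibration <- function(x, ...) {
  cat(sprintf(
    "quant_calibration: SI(VH) %.4g over %d voxels, /(1-e^-TR/T1)=%.4f -> %.4g%s\n",
    x$si_vh, x$n_voxels, x$correction_factor, x$si_vh_t1corr,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
}

#' Left/right vitreous-humor calibration consistency check
#'
#' Quality control: calibrates against both eyes and warns when the two
#' reference signals differ by more than `tol` (default 5%).
#'
#' @param sodium_img reconstructed sodium [scalar_volume()].
#' @param vh_left,vh_right masks on the sodium grid.
#' @param params a [sequence_params()].
#' @param tol relative tolerance before warning.
#' @return named list with both calibrations and their `ratio`.
#' @export
check_vh_symmetry <- function(sodium_img, vh_left, vh_right, params,
                              tol = 0.05) {
  cl <- calibrate_vh(sodium_img, vh_left, params)
  cr <- calibrate_vh(sodium_img, vh_right, params)
  ratio <- cl$si_vh / cr$si_vh
  if (abs(ratio - 1) > tol)
    warning(sprintf("left/right VH calibration differs by %.1f%%",
                    100 * abs(ratio - 1)))
  list(left = cl, right = cr, ratio = ratio)
}

#' Convert a sodium image to a tissue sodium concentration map
#'
#' The central quantification step: voxel-wise
#' `TSC(x) = SI(x) * 145 mM / SI_T1corr(VH)`. Only the vitreous-humor
#' reference is T1-corrected; tissue T1 weighting is left uncorrected
#' because the long TR already minimises it. Negative values (noise) are
#' retained by default so ROI means stay unbiased; set
#' `clip_nonneg = TRUE` to clip at zero.
#'
#' @param sodium_img reconstructed sodium [scalar_volume()].
#' @param cal a `quant_calibration` from [calibrate_vh()].
#' @param clip_nonneg clip negative concentrations to zero?
#' @return object of class `tsc_map`: `values` ([scalar_volume()], mM)
#'   plus the calibration.
#' @export
quantify_tsc <- function(sodium_img, cal, clip_nonneg = FALSE) {
  if (!inherits(cal, "quant_calibration"))
    stop("cal must be a quant_calibration from calibrate_vh()")
  v <- sodium_img$data * cal$c_vh_mm / cal$si_vh_t1corr
  if (clip_nonneg) v <- pmax(v, 0)
  structure(list(values = scalar_volume(v, sodium_img$meta, units = "mM"),
                 calibration = cal, clipped = clip_nonneg),
            class = "tsc_map")
}

#' @export
print.tsc_map <- function(x, ...) {
  cat("tsc_map:", format(x$values$meta), "\n  ")
  print(x$calibration)
}
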