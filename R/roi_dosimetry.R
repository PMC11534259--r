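#' Build nested isodose shells from a dose grid
#'
#' An isodose shell for level `D_i` is the region receiving at least
#' `D_i` Gy minus the region enclosed by the next-higher listed level —
#' rings between consecutive isodose surfaces. The innermost listed shell
#' (18 Gy by default) is closed from inside by the prescription isodose
#' `{dose >= rx}`, which is excluded everywhere, as are the GTV and PTV so
#' tumour signal never contaminates the peritumoral rings. The shells
#' therefore partition `{dose >= min level} \ {dose >= rx}` minus the
#' target volumes exactly. Empty shells (small lesion, steep gradient)
#' are retained with `n = 0` and flagged, not treated as errors.
#'
#' @param dose_grid a `dose_grid` from [compute_dose()], or a
#'   [scalar_volume()] of dose (then `rx_gy` is required).
#' @param gtv,ptv logical arrays (or [label_volume()]s) to exclude;
#'   defaults to the dose grid's own masks.
#' @param levels ascending dose levels (Gy).
#' @param rx_gy prescription dose bounding the innermost shell; defaults
#'   to the smallest prescription in `dose_grid`.
#' @return object of class `isodose_shells`: `levels`, named list
#'   `masks`, `upper_bound_mask`, `empty_levels`, `meta`.
#' @export
build_isodose_shells <- function(dose_grid, gtv = NULL, ptv = NULL,
                                 levels = NULL, rx_gy = NULL) {
  if (inherits(dose_grid, "dose_grid")) {
    dvol <- dose_grid$dose
    levels <- levels %||% dose_grid$d_levels
    rx_gy <- rx_gy %||% min(vapply(dose_grid$prescriptions, `[[`,
                                   numeric(1), "rx_dose_gy"))
    gtv <- gtv %||% Reduce(`|`, dose_grid$gtv_masks)
    ptv <- ptv %||% Reduce(`|`, dose_grid$ptv_masks)
  } else {
    dvol <- dose_grid
    levels <- levels %||% c(2, 3, 4, 6, 8, 10, 12, 18)
    if (is.null(rx_gy)) stop("rx_gy is required with a bare dose volume")
  }
  as_mask <- function(x) {
    if (is.null(x)) array(FALSE, dvol$meta$shape)
    else if (inherits(x, "label_volume")) x$data != 0L
    else as.array(x) != 0
  }
  excl <- as_mask(gtv) | as_mask(ptv)
  levels <- sort(levels)
  d <- dvol$data
  upper <- d >= rx_gy
  masks <- vector("list", length(levels))
  names(masks) <- paste0(levels, "Gy")
  for (i in seq_along(levels)) {
    hi <- if (i < length(levels)) d >= levels[i + 1] else FALSE
    masks[[i]] <- d >= levels[i] & !hi & !upper & !excl
  }
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty))
    message("empty isodose shells (steep gradient / small lesion): ",
            paste(empty, collapse = ", "))
  structure(list(levels = levels, masks = masks,
                 upper_bound_mask = upper, excluded = excl,
                 empty_levels = empty, meta = dvol$meta),
            class = "isodose_shells")
}

#' @export
print.isodose_shells <- function(x, ...) {
  n <- vapply(x$masks, sum, numeric(1))
  cat("isodose_shells:",
      paste(sprintf("%s=%d", names(x$masks), n), collapse = " "), "\n")
}

#' Remove CSF voxels from an ROI
#'
#' Excludes voxels whose CSF posterior probability exceeds `threshold`
#' so fluid sodium does not inflate tissue ROI means.
#'
#' @param roi logical array or [label_volume()].
#' @param tissue a [tissue_probability_maps()] on the same grid.
#' @param threshold CSF probability above which a voxel is removed.
#' @return list with the filtered logical `mask`, `n_removed`, and
#'   `flag_empty`.
#' @export
subtract_csf <- function(roi, tissue, threshold = 0.5) {
  m <- if (inherits(roi, "label_volume")) roi$data != 0L else as.array(roi) != 0
  if (!identical(dim(m), dim(tissue$p_csf$data)))
    stop("ROI and tissue maps are on different grids")
  drop <- m & (tissue$p_csf$data > threshold)
  out <- m & !drop
  list(mask = out, n_removed = sum(drop), flag_empty = !any(out))
}

#' Place two cylindrical healthy reference ROIs in white matter
#'
#' Automates the radiation oncologist's choice of two cylindrical
#' healthy-appearing white-matter regions (radius 5 mm, height 10 mm,
#' axis superior-inferior): candidate centres are drawn reproducibly from
#' high-probability white matter, and a cylinder is accepted when at
#' least `wm_fraction` of its voxels are white matter, it lies outside
#' all isodose shells and the prescription region, and it keeps
#' `min_gtv_dist_mm` clearance from every lesion. Contralateral
#' placement (opposite left-right side to the first lesion) is preferred
#' when feasible.
#'
#' @param tissue a [tissue_probability_maps()].
#' @param shells an `isodose_shells` (optional).
#' @param gtvs list of logical GTV masks (optional).
#' @param seed RNG seed; same seed, same centres.
#' @param radius_mm,height_mm cylinder geometry.
#' @param wm_fraction minimum white-matter voxel fraction.
#' @param min_gtv_dist_mm minimum distance from any GTV voxel (mm).
#' @return list of two `healthy_roi` objects (`center`, `mask`,
#'   `radius_mm`, `height_mm`, `axis`).
#' @export
place_healthy_rois <- function(tissue, shells = NULL, gtvs = NULL, seed = 1L,
                               radius_mm = 5, height_mm = 10,
                               wm_fraction = 0.95, min_gtv_dist_mm = 20) {
  meta <- tissue$p_wm$meta
  wm <- tissue$p_wm$data > 0.5
  excl <- array(FALSE, meta$shape)
  if (!is.null(shells))
    excl <- excl | Reduce(`|`, shells$masks) | shells$upper_bound_mask
  gtv_all <- NULL
  if (!is.null(gtvs) && length(gtvs)) {
    gtv_all <- Reduce(`|`, lapply(gtvs, function(g)
      if (inherits(g, "label_volume")) g$data != 0L else as.array(g) != 0))
    excl <- excl | dilate_mask(gtv_all, meta, min_gtv_dist_mm)
  }
  # EDT prefilter: a centre can only work if the whole cylinder has room —
  # clearance from non-WM and from the exclusion zone of at least the
  # cylinder's circumscribed radius (minus tolerance for the WM fraction)
  circum <- sqrt(radius_mm^2 + (height_mm / 2)^2)
  d_nonwm <- edt3d(!wm, meta$spacing)
  ok <- wm & d_nonwm >= 0.75 * circum
  if (any(excl)) ok <- ok & edt3d(excl, meta$spacing) > circum
  cand <- which(ok)
  if (length(cand) < 10) stop("insufficient white matter clear of the ",
                              "irradiated region to place healthy ROIs")
  # contralateral preference: opposite LPS-x side to the first lesion
  side <- 0
  if (!is.null(gtv_all) && any(gtv_all)) {
    gx <- index_to_world(meta, which_indices(gtv_all))[, 1]
    side <- -sign(mean(gx) - grid_center_world(meta)[1])
  }
  set.seed(seed)
  cand <- sample(cand)
  idx <- arrayInd(cand, meta$shape)
  xyz <- index_to_world(meta, idx)
  if (side != 0) {
    pref <- sign(xyz[, 1] - grid_center_world(meta)[1]) == side
    ordn <- order(!pref)          # contralateral candidates first
    cand <- cand[ordn]; xyz <- xyz[ordn, , drop = FALSE]
  }
  rois <- list()
  centers <- NULL
  for (i in seq_along(cand)) {
    ctr <- xyz[i, ]
    if (!is.null(centers) &&
        any(sqrt(rowSums(sweep(centers, 2, ctr)^2)) < 3 * radius_mm))
      next
    cyl <- mask_cylinder(meta, ctr, radius_mm, height_mm)
    nv <- sum(cyl)
    if (nv < 0.5 * pi * radius_mm^2 * height_mm / prod(meta$spacing)) next
    if (mean(wm[cyl]) < wm_fraction) next
    if (any(cyl & excl)) next
    rois[[length(rois) + 1]] <- structure(
      list(center = ctr, radius_mm = radius_mm, height_mm = height_mm,
           axis = c(0, 0, 1), mask = cyl, n_voxels = nv),
      class = "healthy_roi")
    centers <- rbind(centers, ctr)
    if (length(rois) == 2L) return(rois)
  }
  stop("could not place two healthy cylinders satisfying the white-matter",
       " and clearance constraints (", length(rois), " found)")
}

which_indices <- function(mask) arrayInd(which(mask), dim(mask))

#' Per-ROI TSC statistics
#'
#' Mean and sample (n-1) SD of a TSC map over an ROI. An empty ROI yields
#' a flagged record with `n_voxels = 0` rather than an error so that
#' downstream group analyses can drop it explicitly.
#'
#' @param tsc a `tsc_map` (from [quantify_tsc()]) or [scalar_volume()].
#' @param roi logical array or [label_volume()] on the same grid.
#' @param roi_name,scan_id labels carried into the record.
#' @param n_csf_removed bookkeeping from [subtract_csf()].
#' @return object of class `roi_statistics` (also a one-row data.frame
#'   via [as.data.frame()]).
#' @export
roi_statistics <- function(tsc, roi, roi_name = "roi", scan_id = NA,
                           n_csf_removed = 0L) {
  vol <- if (inherits(tsc, "tsc_map")) tsc$values else tsc
  m <- if (inherits(roi, "label_volume")) roi$data != 0L else as.array(roi) != 0
  if (!identical(dim(m), dim(vol$data)))
    stop("ROI and TSC map are on different grids")
  v <- vol$data[m]
  structure(list(roi = roi_name, scan = scan_id, n_voxels = length(v),
                 mean_tsc = if (length(v)) mean(v) else NA_real_,
                 sd_tsc = if (length(v) > 1) stats::sd(v) else
                   if (length(v) == 1) 0 else NA_real_,
                 excluded_csf_voxels = n_csf_removed,
                 flag_missing = length(v) == 0L),
            class = "roi_statistics")
}

#' @export
as.data.frame.roi_statistics <- function(x, ...) {
  data.frame(roi = x$roi, scan = x$scan, n_voxels = x$n_voxels,
             mean_tsc = x$mean_tsc, sd_tsc = x$sd_tsc,
             excluded_csf_voxels = x$excluded_csf_voxels,
             flag_missing = x$flag_missing)
}

#' @export
print.roi_statistics <- function(x, ...) {
  cat(sprintf("ROI %s scan %s: %.1f +/- %.1f mM (n=%d%s)\n", x$roi,
              as.character(x$scan), x$mean_tsc, x$sd_tsc, x$n_voxels,
              if (x$flag_missing) ", MISSING" else ""))
}
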