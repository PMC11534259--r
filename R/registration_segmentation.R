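#' Rigid transform between two physical spaces
#'
#' A 6-DOF rigid transform mapping points from the *moving* image's
#' physical space into the *fixed* image's physical space (LPS mm):
#' `x_fixed = R %*% x_moving + t`. Rotations are intrinsic Z-Y-X Euler
#' angles in degrees.
#'
#' @param angles_deg rotations about the z, y, x world axes (degrees).
#' @param translation_mm length-3 translation (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
                 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]),
                 0, -sin(a[3]), cos(a[3])), 3, 3)
  structure(list(rotation = rz %*% ry %*% rx,
                 angles_deg = as.numeric(angles_deg),
                 translation = as.numeric(translation_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (%.3f, %.3f, %.3f) deg, t (%.3f, %.3f, %.3f) mm\n",
              x$angles_deg[1], x$angles_deg[2], x$angles_deg[3],
              x$translation[1], x$translation[2], x$translation[3]))
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param xyz n x 3 matrix of points (LPS mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(tf, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(xyz %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  out <- rigid_transform()
  out$rotation <- rt
  out$translation <- as.numeric(-rt %*% tf$translation)
  out$angles_deg <- rotation_to_euler(rt)
  out
}

rotation_to_euler <- function(r) {
  # inverse of the Z-Y-X convention above
  ry <- asin(-r[3, 1])
  rz <- atan2(r[2, 1], r[1, 1])
  rx <- atan2(r[3, 2], r[3, 3])
  c(rz, ry, rx) * 180 / pi
}

#' Serialize / deserialize rigid transforms as JSON
#' @param tf a [rigid_transform()].
#' @param path output/input `.json` path.
#' @return `path` invisibly / a `rigid_transform`.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(list(convention = "moving-to-fixed, LPS",
                            matrix = as.vector(tf$rotation),
                            angles_deg = tf$angles_deg,
                            translation_mm = tf$translation,
                            provenance = tool_info()),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- rigid_transform(o$angles_deg, o$translation_mm)
  tf$rotation <- matrix(o$matrix, 3, 3)
  tf
}

#' Resample a scalar volume onto a target grid under a rigid transform
#'
#' Pull-style resampling with trilinear interpolation: each target voxel
#' centre is mapped through the *inverse* of `transform` (which maps
#' moving to fixed space) and the moving image is sampled there.
#'
#' @param vol moving [scalar_volume()].
#' @param transform a [rigid_transform()] (moving -> fixed space);
#'   identity by default.
#' @param target_meta the fixed-space output [grid_meta()].
#' @param fill value for points outside the moving image.
#' @return a [scalar_volume()] on `target_meta`.
#' @export
resample_volume <- function(vol, transform = rigid_transform(), target_meta,
                            fill = 0) {
  xyz <- voxel_grid_world(target_meta)
  inv <- invert_transform(transform)
  src <- world_to_index(vol$meta, apply_transform(inv, xyz))
  vals <- interp3_real_cpp(vol$data + 0.0, src, fill)
  scalar_volume(array(vals, target_meta$shape), target_meta,
                units = vol$units)
}

#' Resample a label mask with nearest-neighbour interpolation
#'
#' A target voxel is included when its centre maps inside the source mask
#' (nearest-voxel rule). An empty result triggers a warning (the ROI has
#' left the field of view), not an error.
#'
#' @param mask a [label_volume()] or logical array (with `meta`).
#' @param transform a [rigid_transform()] (moving -> fixed).
#' @param target_meta output [grid_meta()].
#' @param meta source grid when `mask` is a bare array.
#' @return a [label_volume()] on `target_meta`.
#' @export
resample_mask <- function(mask, transform = rigid_transform(), target_meta,
                          meta = NULL) {
  if (inherits(mask, "label_volume")) {
    meta <- mask$meta
    m <- mask$data
  } else {
    stopifnot(!is.null(meta))
    m <- array(as.integer(mask), dim(mask))
  }
  xyz <- voxel_grid_world(target_meta)
  inv <- invert_transform(transform)
  src <- round(world_to_index(meta, apply_transform(inv, xyz)))
  ok <- src[, 1] >= 1 & src[, 1] <= meta$shape[1] &
    src[, 2] >= 1 & src[, 2] <= meta$shape[2] &
    src[, 3] >= 1 & src[, 3] <= meta$shape[3]
  vals <- integer(nrow(src))
  vals[ok] <- m[src[ok, , drop = FALSE]]
  out <- label_volume(array(vals, target_meta$shape), target_meta)
  if (any(m != 0L) && !any(vals != 0L))
    warning("resampled mask is empty: the ROI left the target field of view")
  out
}

# block-mean downsampling by an integer factor (multi-resolution pyramid)
downsample_volume <- function(vol, factor = 2L) {
  n <- vol$meta$shape
  nn <- n %/% factor
  crop <- vol$data[seq_len(nn[1] * factor), seq_len(nn[2] * factor),
                   seq_len(nn[3] * factor)]
  dim(crop) <- c(factor, nn[1], factor, nn[2], factor, nn[3])
  small <- apply(crop, c(2, 4, 6), mean)
  meta <- grid_meta(nn, spacing = vol$meta$spacing * factor,
                    origin = vol$meta$origin +
                      vol$meta$spacing * (factor - 1) / 2,
                    orientation = vol$meta$orientation)
  scalar_volume(small, meta, units = vol$units)
}

# 3^3 box smoothing by shift-and-add
box_smooth3 <- function(a) {
  out <- array(0, dim(a))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    out <- out + shift_array(a, c(dx, dy, dz), fill = 0)
  out / 27
}

# stride-decimated view of a volume (no smoothing; keeps intensity detail)
decimate_volume <- function(vol, stride = 2L) {
  n <- vol$meta$shape
  ix <- lapply(1:3, function(a) seq(1L, n[a], by = stride))
  meta <- grid_meta(vapply(ix, length, integer(1)),
                    spacing = vol$meta$spacing * stride,
                    origin = vol$meta$origin,
                    orientation = vol$meta$orientation)
  scalar_volume(vol$data[ix[[1]], ix[[2]], ix[[3]]], meta, units = vol$units)
}

# normalized mutual information (Studholme) from a 2-D joint histogram;
# bin ranges may be precomputed once per image pair for speed
nmi_metric <- function(a, b, bins = 32L, qa = NULL, qb = NULL) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 100) return(0)
  qa <- qa %||% stats::quantile(a, c(0.005, 0.995))
  qb <- qb %||% stats::quantile(b, c(0.005, 0.995))
  if (diff(qa) <= 0 || diff(qb) <= 0) return(0)
  ia <- pmin(bins, pmax(1L, 1L + floor((a - qa[1]) / diff(qa) * (bins - 1e-9))))
  ib <- pmin(bins, pmax(1L, 1L + floor((b - qb[1]) / diff(qb) * (bins - 1e-9))))
  h <- matrix(tabulate(ia + (ib - 1L) * bins, bins * bins), bins, bins)
  # mild smoothing regularizes the discrete histogram for the optimizer
  k <- c(0.25, 0.5, 0.25)
  h <- apply(h, 2, function(col) stats::filter(col, k, sides = 2) |>
               (\(x) ifelse(is.na(x), col, x))())
  h <- t(apply(h, 1, function(row) stats::filter(row, k, sides = 2) |>
                 (\(x) ifelse(is.na(x), row, x))()))
  p <- h / sum(h)
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (ent(px) + ent(py)) / ent(as.vector(p))
}

#' Rigid co-registration by normalized-mutual-information maximisation
#'
#' Registers a moving image to a fixed reference (the scan-I anatomical
#' MPRAGE in the pipeline) with a 6-DOF rigid transform, maximising
#' normalized mutual information over a two-level multi-resolution
#' pyramid with Nelder-Mead refinement. Deterministic for fixed inputs
#' and optimizer settings.
#'
#' @param moving,fixed [scalar_volume()]s with overlapping fields of view.
#' @param init optional initial [rigid_transform()].
#' @param bins joint-histogram bins for the metric.
#' @param maxit optimizer iteration cap per level.
#' @return a [rigid_transform()] (moving -> fixed) with attributes
#'   `metric` (final NMI) and `converged` (optimizer status); a
#'   non-converged fit carries `converged = FALSE` plus a warning rather
#'   than failing silently.
#' @export
register_rigid <- function(moving, fixed, init = NULL, bins = 32L,
                           maxit = 400L) {
  init <- init %||% rigid_transform()
  par <- c(init$angles_deg, init$translation)
  # light box smoothing of both images regularizes the histogram metric
  # without moving its optimum (the sodium image is already band-limited,
  # so its smoothing is nearly a no-op)
  fixed <- scalar_volume(box_smooth3(fixed$data), fixed$meta,
                         units = fixed$units)
  moving <- scalar_volume(box_smooth3(moving$data), moving$meta,
                          units = moving$units)
  multires <- min(fixed$meta$shape) >= 32
  # coarse level: block-mean pyramid; fine level: stride-2 decimation of the
  # fixed grid (full-resolution intensities at a quarter of the voxels) —
  # the histogram metric needs samples, not every voxel
  # per level: coarse block-mean pyramid, stride decimation, then (for
  # moderate grids) full resolution; the finest level restarts Nelder-Mead
  # once with a fresh simplex, which recovers the precision a collapsed
  # simplex loses
  large <- min(fixed$meta$shape) >= 96
  levels <- if (large)
    list(list("mean4", maxit, 1L), list("decimate3", maxit, 2L))
  else if (multires)
    list(list("mean", maxit, 1L), list("decimate", maxit, 1L),
         list("full", 250L, 2L))
  else list(list("full", maxit, 2L))
  conv <- 0L
  mmeta <- moving$meta
  fast <- max(abs(mmeta$orientation - diag(3))) < 1e-9
  movdata <- moving$data + 0.0
  qm <- stats::quantile(movdata, c(0.005, 0.995))
  for (lv in levels) {
    fx <- switch(lv[[1]],
                 mean4 = downsample_volume(fixed, 4L),
                 mean = downsample_volume(fixed, 2L),
                 decimate3 = decimate_volume(fixed, 3L),
                 decimate = decimate_volume(fixed, 2L),
                 fixed)
    xyz <- voxel_grid_world(fx$meta)       # fixed-space sample positions
    fvals <- as.vector(fx$data)
    qf <- stats::quantile(fvals, c(0.005, 0.995))
    objective <- function(p) {
      tf <- rigid_transform(p[1:3], p[4:6])
      if (fast) {
        # pull: x_moving = R^T (x_fixed - t), then to voxel indices
        src <- xyz %*% tf$rotation
        off <- as.numeric(crossprod(tf$rotation, tf$translation)) +
          mmeta$origin
        for (a in 1:3) src[, a] <- (src[, a] - off[a]) / mmeta$spacing[a] + 1
        mv <- interp3_real_cpp(movdata, src, NA_real_)
      } else {
        mv <- resample_volume(moving, tf, fx$meta, fill = NA_real_)$data
      }
      -nmi_metric(mv, fvals, bins, qa = qm, qb = qf)
    }
    for (rs in seq_len(lv[[3]])) {
      opt <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = list(maxit = lv[[2]], reltol = 1e-10,
                                         parscale = c(2, 2, 2, 2, 2, 2)))
      par <- opt$par
      conv <- opt$convergence
    }
  }
  out <- rigid_transform(par[1:3], par[4:6])
  attr(out, "metric") <- -opt$value
  attr(out, "converged") <- conv == 0L
  if (conv != 0L)
    warning("register_rigid: optimizer did not converge (code ", conv,
            "); inspect attr(, 'metric')")
  out
}

#' Tissue probability maps (white matter, grey matter, CSF)
#'
#' @param p_wm,p_gm,p_csf probability [scalar_volume()]s on a common grid,
#'   each in `[0, 1]` with voxel-wise sum at most 1 (remainder =
#'   background/other).
#' @return object of class `tissue_probability_maps`.
#' @export
tissue_probability_maps <- function(p_wm, p_gm, p_csf) {
  assert_same_grid(p_wm, p_gm); assert_same_grid(p_wm, p_csf)
  s <- p_wm$data + p_gm$data + p_csf$data
  if (min(p_wm$data, p_gm$data, p_csf$data) < -1e-9 || max(s) > 1 + 1e-6)
    stop("probabilities must lie in [0,1] and sum to at most 1 per voxel")
  structure(list(p_wm = p_wm, p_gm = p_gm, p_csf = p_csf),
            class = "tissue_probability_maps")
}

#' Intensity-based WM/GM/CSF segmentation
#'
#' Three-class Gaussian-mixture model on anatomical intensities within a
#' brain mask (an intensity-threshold mask is derived when none is
#' given), classes assigned to CSF < GM < WM by ascending mean intensity
#' as on T1-weighted contrast. Posterior probabilities outside the brain
#' mask are zero.
#'
#' @param anatomy anatomical reference [scalar_volume()].
#' @param brain_mask logical array on the same grid (optional).
#' @param seed RNG seed (the mixture fit is seeded and deterministic).
#' @return a [tissue_probability_maps()].
#' @export
segment_tissues <- function(anatomy, brain_mask = NULL, seed = 1L) {
  meta <- anatomy$meta
  if (is.null(brain_mask)) {
    thr <- 0.5 * mean(range(anatomy$data))
    brain_mask <- anatomy$data > thr
  }
  vals <- anatomy$data[brain_mask]
  if (length(unique(round(vals, 6))) < 3 || stats::sd(vals) < 1e-9)
    stop("degenerate intensity histogram: cannot separate three classes")
  set.seed(seed)
  fit_vals <- if (length(vals) > 150000)
    sample(vals, 100000) else vals      # the 1-D mixture needs a sample,
                                        # not every voxel
  # seed the EM from quantile-anchored k-means: the unimodal hierarchical
  # initialization can split the dominant WM mode instead of separating CSF
  km <- stats::kmeans(fit_vals,
                      centers = matrix(stats::quantile(fit_vals,
                                                       c(0.1, 0.5, 0.9)),
                                       3, 1))
  z0 <- matrix(0, length(fit_vals), 3L)
  z0[cbind(seq_along(fit_vals), km$cluster)] <- 1
  fit <- mclust::me(modelName = "V", data = fit_vals, z = z0)
  if (is.null(fit$parameters) || anyNA(fit$parameters$mean))
    stop("Gaussian-mixture segmentation failed to fit three classes")
  ord <- order(fit$parameters$mean)            # CSF < GM < WM intensity
  pars <- fit$parameters
  dens <- vapply(ord, function(g)
    pars$pro[g] * stats::dnorm(vals, pars$mean[g],
                               sqrt(pars$variance$sigmasq[g])),
    numeric(length(vals)))
  post <- dens / pmax(rowSums(dens), 1e-300)
  mk <- function(col) {
    arr <- array(0, meta$shape)
    arr[brain_mask] <- post[, col]
    scalar_volume(arr, meta)
  }
  tissue_probability_maps(p_wm = mk(3L), p_gm = mk(2L), p_csf = mk(1L))
}

#' Write tissue probability maps as three NIfTI files
#' @param tpm a [tissue_probability_maps()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tissue_maps <- function(tpm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(tpm$p_wm, file.path(dir, "p_wm.nii.gz"))
  write_volume(tpm$p_gm, file.path(dir, "p_gm.nii.gz"))
  write_volume(tpm$p_csf, file.path(dir, "p_csf.nii.gz"))
  invisible(dir)
}
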