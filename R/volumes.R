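#' Grid geometry of a 3-D image volume
#'
#' A `grid_meta` records everything needed to map voxel indices to physical
#' space: array shape, isotropic or anisotropic voxel spacing (mm), the world
#' coordinate of the first voxel centre (mm), and a direction matrix. All
#' physical coordinates in this package are LPS (left-posterior-superior),
#' the DICOM patient convention: +x is patient left, +y posterior, +z
#' superior. Voxel `(1,1,1)` sits at `origin`; voxel `(i,j,k)` sits at
#' `origin + orientation %*% (spacing * (c(i,j,k) - 1))`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param origin world coordinate (mm, LPS) of the centre of voxel (1,1,1).
#' @param orientation 3x3 direction cosine matrix (orthonormal, det +1).
#' @return an object of class `grid_meta`.
#' @export
grid_meta <- function(shape, spacing = 1, origin = NULL, orientation = diag(3)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0")
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal")
  if (is.null(origin)) {
    # default: grid centred on the world origin
    origin <- -as.numeric(orientation %*% (spacing * (shape - 1) / 2))
  }
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 orientation = orientation, space = "LPS"),
            class = "grid_meta")
}

#' @export
format.grid_meta <- function(x, ...) {
  sprintf("<grid %s @ %s mm, origin (%s) LPS>",
          paste(x$shape, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"),
          paste(signif(x$origin, 4), collapse = ", "))
}

#' @export
print.grid_meta <- function(x, ...) cat(format(x), "\n")

#' Field of view of a grid (mm per axis)
#' @param meta a [grid_meta()].
#' @return numeric length 3.
#' @export
grid_fov <- function(meta) meta$shape * meta$spacing

same_grid <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

assert_same_grid <- function(a, b, what = "volumes") {
  ma <- if (inherits(a, "grid_meta")) a else a$meta
  mb <- if (inherits(b, "grid_meta")) b else b$meta
  if (!same_grid(ma, mb))
    stop(sprintf("%s are on different grids: %s vs %s",
                 what, format(ma), format(mb)), call. = FALSE)
  invisible(TRUE)
}

#' Scalar image volume
#'
#' Thin container pairing a 3-D numeric array with its [grid_meta()].
#' Used for signal, dose (Gy) and concentration (mM) images.
#'
#' @param data 3-D numeric array.
#' @param meta a [grid_meta()] matching `dim(data)`.
#' @param units optional unit string ("mM", "Gy", "a.u.").
#' @return object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, meta, units = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("scalar_volume requires a 3-D array")
  if (!identical(as.integer(dim(data)), meta$shape))
    stop("array dimensions do not match grid_meta shape")
  structure(list(data = data, meta = meta, units = units),
            class = "scalar_volume")
}

#' Integer label volume (compartments, ROI masks)
#'
#' @param data 3-D integer (or logical) array.
#' @param meta a [grid_meta()].
#' @param labels optional named integer vector mapping names to label values.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, meta, labels = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("label_volume requires a 3-D array")
  if (!identical(as.integer(dim(data)), meta$shape))
    stop("array dimensions do not match grid_meta shape")
  storage.mode(data) <- "integer"
  structure(list(data = data, meta = meta, labels = labels),
            class = "label_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume %s%s, range [%.4g, %.4g]\n", format(x$meta),
              if (is.null(x$units)) "" else paste0(" [", x$units, "]"),
              min(x$data), max(x$data)))
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume %s, %d distinct labels\n", format(x$meta),
              length(unique(as.vector(x$data)))))
}

is_volume <- function(x) inherits(x, c("scalar_volume", "label_volume"))

#' Voxel-index to world-coordinate conversion
#'
#' @param meta a [grid_meta()].
#' @param ijk n x 3 matrix of 1-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of LPS world coordinates (mm).
#' @export
index_to_world <- function(meta, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(t(meta$orientation %*% (t(ijk) - 1) * meta$spacing), 2L,
        meta$origin, "+")
}

#' World-coordinate to voxel-index conversion (inverse of [index_to_world()])
#' @param meta a [grid_meta()].
#' @param xyz n x 3 matrix of LPS world coordinates (mm).
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_index <- function(meta, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  t(crossprod(meta$orientation, t(xyz) - meta$origin) / meta$spacing) |>
    sweep(2L, c(1, 1, 1), "+")
}

# n_voxels x 3 matrix of all voxel centre world coordinates, in array order
voxel_grid_world <- function(meta) {
  idx <- as.matrix(expand.grid(i = seq_len(meta$shape[1]),
                               j = seq_len(meta$shape[2]),
                               k = seq_len(meta$shape[3])))
  index_to_world(meta, idx)
}

# squared world distance of every voxel centre to a point (fast path for the
# common axis-aligned case; avoids materialising the full coordinate matrix)
voxel_dist2 <- function(meta, point) {
  stopifnot(max(abs(meta$orientation - diag(3))) < 1e-9)
  ax <- lapply(1:3, function(a)
    (meta$origin[a] + (seq_len(meta$shape[a]) - 1) * meta$spacing[a]) - point[a])
  o <- outer(ax[[1]]^2, ax[[2]]^2, "+")
  outer(o, ax[[3]]^2, "+")
}

#' Spherical mask on a grid
#' @param meta a [grid_meta()].
#' @param center world coordinate (mm, LPS) of the sphere centre.
#' @param radius_mm sphere radius.
#' @return logical 3-D array (voxel-centre containment).
#' @export
mask_sphere <- function(meta, center, radius_mm) {
  voxel_dist2(meta, center) <= radius_mm^2
}

#' Axis-aligned cylinder mask (axis along superior-inferior by default)
#' @param meta a [grid_meta()].
#' @param center world coordinate of the cylinder centre.
#' @param radius_mm,height_mm cylinder radius and full height (mm).
#' @param axis one of 1, 2, 3 (world axis index; 3 = superior-inferior).
#' @return logical 3-D array.
#' @export
mask_cylinder <- function(meta, center, radius_mm, height_mm, axis = 3L) {
  stopifnot(max(abs(meta$orientation - diag(3))) < 1e-9)
  ax <- lapply(1:3, function(a)
    (meta$origin[a] + (seq_len(meta$shape[a]) - 1) * meta$spacing[a]) - center[a])
  perp <- setdiff(1:3, axis)
  # broadcast per-axis offsets over the 3-D grid
  bc <- function(a) {
    v <- ax[[a]]
    if (a == 1L) array(v, meta$shape)
    else if (a == 2L) array(rep(v, each = meta$shape[1]), meta$shape)
    else array(rep(v, each = meta$shape[1] * meta$shape[2]), meta$shape)
  }
  r2 <- bc(perp[1])^2 + bc(perp[2])^2
  h <- abs(bc(axis))
  r2 <= radius_mm^2 & h <= height_mm / 2
}

# ---- binary morphology ----------------------------------------------------

shift_array <- function(x, off, fill = FALSE) {
  d <- dim(x)
  src <- lapply(1:3, function(a) {
    s <- seq_len(d[a]) - off[a]
    s
  })
  ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= d[a])
  out <- array(fill, d)
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    x[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

#' Binary dilation/erosion with a physical-radius ball
#'
#' Dilation marks every voxel whose centre lies within `radius_mm` of a voxel
#' centre of the input mask (exact Euclidean distance, in mm); erosion is
#' its dual (voxels farther than `radius_mm` from the mask complement).
#' Implemented via the exact distance transform, so large radii cost the
#' same as small ones.
#'
#' @param mask logical 3-D array.
#' @param meta the mask's [grid_meta()] (supplies spacing).
#' @param radius_mm structuring ball radius in mm.
#' @return logical 3-D array.
#' @export
dilate_mask <- function(mask, meta, radius_mm) {
  if (!any(mask)) return(array(FALSE, dim(mask)))
  edt3d(mask, meta$spacing) <= radius_mm + 1e-9
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, meta, radius_mm) {
  if (all(mask)) return(array(TRUE, dim(mask)))
  edt3d(!mask, meta$spacing) > radius_mm + 1e-9
}

#' Signed Euclidean distance to a mask surface
#'
#' Positive outside the mask, negative inside; computed with an exact
#' separable distance transform honouring anisotropic spacing.
#'
#' @param mask logical 3-D array (non-empty).
#' @param meta the mask's [grid_meta()].
#' @return 3-D numeric array of signed distances (mm).
#' @export
signed_distance <- function(mask, meta) {
  if (!any(mask)) stop("signed_distance: mask is empty")
  d_out <- edt3d(mask, meta$spacing)          # distance to mask, 0 inside
  d_in <- edt3d(!mask, meta$spacing)          # distance to complement
  d_out - d_in
}

# exact Euclidean distance transform (mm) to the TRUE set of `mask`
edt3d <- function(mask, spacing) {
  arr <- edt3d_cpp(array(as.integer(mask), dim(mask)), as.numeric(spacing))
  array(arr, dim(mask))
}
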