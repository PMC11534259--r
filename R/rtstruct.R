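# Minimal DICOM RT-STRUCT support: a self-contained explicit-VR
# little-endian reader/writer restricted to the structure-set elements the
# pipeline needs (ROI names and planar contour stacks). JSON structure sets
# remain the native ROI format; DICOM RT is an import convenience for
# planning-system exports.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

# ---- low-level element IO -------------------------------------------------

dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_elements <- function(con, until = Inf) {
  elems <- list()
  repeat {
    if (seek(con, where = NA) >= until) break
    grp <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = "little")
    if (length(grp) == 0) break
    el <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                  endian = "little")
    tag <- sprintf("%04x%04x", grp, el)
    if (tag == "fffee00d" || tag == "fffee0dd") {    # item/sequence delim
      readBin(con, "integer", 1, size = 4, endian = "little")
      break
    }
    if (tag == "fffee000") {                          # nested item start
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
      stop("unexpected bare item at depth 0")
    }
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% dicom_long_vrs) {
      readBin(con, "raw", 2)                          # reserved
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    if (vr == "SQ") {
      elems[[tag]] <- read_dicom_sequence(con, len)
    } else {
      if (len < 0) stop("undefined length outside a sequence")
      payload <- readBin(con, "raw", len)
      if (length(payload) < len)
        stop("truncated DICOM element ", tag)
      elems[[tag]] <- list(vr = vr, bytes = payload)
    }
  }
  elems
}

read_dicom_sequence <- function(con, len) {
  items <- list()
  end <- if (len == -1L) Inf else seek(con, where = NA) + len
  repeat {
    if (seek(con, where = NA) >= end) break
    grp <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = "little")
    if (length(grp) == 0) break
    el <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                  endian = "little")
    tag <- sprintf("%04x%04x", grp, el)
    ilen <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (tag == "fffee0dd") break                      # sequence delimiter
    if (tag != "fffee000") stop("malformed sequence item tag ", tag)
    iend <- if (ilen == -1L) Inf else seek(con, where = NA) + ilen
    items[[length(items) + 1]] <- read_dicom_item(con, iend, ilen == -1L)
  }
  list(vr = "SQ", items = items)
}

read_dicom_item <- function(con, end, undefined) {
  elems <- list()
  repeat {
    pos <- seek(con, where = NA)
    if (pos >= end) break
    grp <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = "little")
    if (length(grp) == 0) break
    el <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                  endian = "little")
    tag <- sprintf("%04x%04x", grp, el)
    if (tag == "fffee00d") {                          # item delimiter
      readBin(con, "integer", 1, size = 4, endian = "little")
      break
    }
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% dicom_long_vrs) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    if (vr == "SQ") {
      elems[[tag]] <- read_dicom_sequence(con, len)
    } else {
      elems[[tag]] <- list(vr = vr, bytes = readBin(con, "raw", len))
    }
  }
  elems
}

dicom_string <- function(elem) {
  if (is.null(elem)) return(NULL)
  trimws(rawToChar(elem$bytes))
}

# ---- writer ---------------------------------------------------------------

w16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                            endian = "little")
w32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                            endian = "little")

encode_element <- function(grp, el, vr, payload) {
  if (is.character(payload)) payload <- charToRaw(payload)
  if (length(payload) %% 2 == 1)
    payload <- c(payload, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
  hdr <- c(w16(grp), w16(el), charToRaw(vr))
  if (vr %in% dicom_long_vrs)
    c(hdr, as.raw(c(0, 0)), w32(length(payload)), payload)
  else
    c(hdr, w16(length(payload)), payload)
}

encode_sequence <- function(grp, el, items) {
  body <- unlist(lapply(items, function(it)
    c(w16(0xfffe), w16(0xe000), w32(-1L), it,
      w16(0xfffe), w16(0xe00d), w32(0L))))
  c(w16(grp), w16(el), charToRaw("SQ"), as.raw(c(0, 0)), w32(-1L),
    if (is.null(body)) raw(0) else body,
    w16(0xfffe), w16(0xe0dd), w32(0L))
}

#' Export planar contours as a minimal DICOM RT-STRUCT file
#'
#' Writes an explicit-VR little-endian RT structure set containing ROI
#' names and CLOSED_PLANAR contour stacks — the subset a planning-system
#' round trip needs. Contours are lists of n x 3 point matrices (LPS mm,
#' constant z per contour).
#'
#' @param contours named list; each entry is a list of n x 3 matrices.
#' @param path output file.
#' @param frame_of_reference_uid frame-of-reference identifier embedded in
#'   the file (must match at import).
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(contours, path,
                           frame_of_reference_uid = "2.25.4242.1") {
  stopifnot(is.list(contours), !is.null(names(contours)))
  fmt <- function(x) sprintf("%.6g", x)

  ss_items <- lapply(seq_along(contours), function(i) {
    c(encode_element(0x3006, 0x0022, "IS", as.character(i)),
      encode_element(0x3006, 0x0024, "UI", frame_of_reference_uid),
      encode_element(0x3006, 0x0026, "LO", names(contours)[i]))
  })
  rc_items <- lapply(seq_along(contours), function(i) {
    polys <- contours[[i]]
    c_items <- lapply(polys, function(p) {
      p <- matrix(as.numeric(p), ncol = 3)
      c(encode_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        encode_element(0x3006, 0x0046, "IS", as.character(nrow(p))),
        encode_element(0x3006, 0x0050, "DS",
                       paste(fmt(t(p)), collapse = "\\")))
    })
    c(encode_sequence(0x3006, 0x0040, c_items),
      encode_element(0x3006, 0x0084, "IS", as.character(i)))
  })

  dataset <- c(
    encode_element(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    encode_element(0x0008, 0x0018, "UI", paste0("2.25.", config_hash(contours))),
    encode_element(0x0020, 0x0052, "UI", frame_of_reference_uid),
    encode_element(0x3006, 0x0002, "SH", "na23tsc"),
    encode_sequence(0x3006, 0x0020, ss_items),
    encode_sequence(0x3006, 0x0039, rc_items))

  meta_body <- c(
    encode_element(0x0002, 0x0002, "UI", UID_RTSTRUCT),
    encode_element(0x0002, 0x0003, "UI", "2.25.424242"),
    encode_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE))
  meta <- c(encode_element(0x0002, 0x0000, "UL", w32(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

#' Import a DICOM RT-STRUCT as rasterized masks
#'
#' Reads an explicit-VR little-endian RT structure set and rasterizes
#' each CLOSED_PLANAR contour stack onto `target_meta` by a
#' voxel-centre-in-polygon (even-odd) rule per slice; multiple contours
#' on one slice toggle (holes supported). Structures without contours
#' yield empty masks with a warning.
#'
#' @param path RT-STRUCT file.
#' @param target_meta output [grid_meta()] (axis-aligned).
#' @param frame_of_reference_uid when given, contours referencing a
#'   different frame of reference raise an error.
#' @return named list of logical mask arrays plus attribute `meta`.
#' @export
import_rtstruct <- function(path, target_meta,
                            frame_of_reference_uid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132)
  if (length(pre) < 132 || rawToChar(pre[129:132]) != "DICM")
    stop("'", path, "' is not a DICOM file (missing DICM magic)")
  sz <- file.info(path)$size
  elems <- read_dicom_elements(con, until = sz)

  ts <- dicom_string(elems[["00020010"]])
  if (!is.null(ts) && ts != UID_EXPLICIT_VR_LE)
    stop("unsupported transfer syntax ", ts)
  for_uid <- dicom_string(elems[["00200052"]])
  if (!is.null(frame_of_reference_uid) && !is.null(for_uid) &&
      for_uid != frame_of_reference_uid)
    stop("structure set references frame of reference ", for_uid,
         " but ", frame_of_reference_uid, " was expected")

  ss <- elems[["30060020"]]
  rc <- elems[["30060039"]]
  if (is.null(ss) || is.null(rc))
    stop("file lacks StructureSetROISequence / ROIContourSequence")
  names_by_num <- list()
  for (it in ss$items) {
    num <- dicom_string(it[["30060022"]])
    names_by_num[[num]] <- dicom_string(it[["30060026"]]) %||%
      paste0("ROI", num)
  }
  out <- list()
  for (it in rc$items) {
    num <- dicom_string(it[["30060084"]])
    nm <- names_by_num[[num]] %||% paste0("ROI", num)
    cs <- it[["30060040"]]
    polys <- list()
    if (!is.null(cs)) for (ci in cs$items) {
      dat <- dicom_string(ci[["30060050"]])
      if (is.null(dat) || !nzchar(dat)) next
      v <- as.numeric(strsplit(dat, "\\\\")[[1]])
      polys[[length(polys) + 1]] <- matrix(v, ncol = 3, byrow = TRUE)
    }
    if (length(polys) == 0) {
      warning("structure '", nm, "' has no contours; empty mask returned")
      out[[nm]] <- array(FALSE, target_meta$shape)
    } else {
      out[[nm]] <- rasterize_contours(polys, target_meta)
    }
  }
  attr(out, "meta") <- target_meta
  out
}

# even-odd rasterization of planar contour stacks onto an axis-aligned grid
rasterize_contours <- function(polys, meta) {
  stopifnot(max(abs(meta$orientation - diag(3))) < 1e-9)
  mask <- array(FALSE, meta$shape)
  zc <- meta$origin[3] + (seq_len(meta$shape[3]) - 1) * meta$spacing[3]
  xs <- meta$origin[1] + (seq_len(meta$shape[1]) - 1) * meta$spacing[1]
  ys <- meta$origin[2] + (seq_len(meta$shape[2]) - 1) * meta$spacing[2]
  gx <- rep(xs, times = meta$shape[2])
  gy <- rep(ys, each = meta$shape[1])
  for (p in polys) {
    z <- mean(p[, 3])
    k <- which(abs(zc - z) <= meta$spacing[3] / 2 + 1e-9)
    if (length(k) == 0) next
    k <- k[which.min(abs(zc[k] - z))]
    inside <- point_in_polygon(gx, gy, p[, 1], p[, 2])
    mask[, , k] <- xor(mask[, , k], matrix(inside, meta$shape[1]))
  }
  mask
}

# vectorized even-odd (crossing number) point-in-polygon test
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Convert a mask to per-slice boundary contours (for RT-STRUCT export)
#'
#' Extracts an ordered boundary polygon per axial slice by sorting
#' boundary voxel centres around the slice centroid, pushed half a voxel
#' outward — adequate for the star-convex (spherical/cylindrical) ROIs
#' this pipeline produces; not a general marching-squares tracer.
#'
#' @param mask logical 3-D array.
#' @param meta the mask's [grid_meta()].
#' @return list of n x 3 contour matrices (LPS mm).
#' @export
mask_to_contours <- function(mask, meta) {
  polys <- list()
  for (k in seq_len(meta$shape[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    er <- sl
    er[-1, ] <- er[-1, ] & sl[-nrow(sl), ]
    er[-nrow(sl), ] <- er[-nrow(sl), ] & sl[-1, ]
    er[, -1] <- er[, -1] & sl[, -ncol(sl)]
    er[, -ncol(sl)] <- er[, -ncol(sl)] & sl[, -1]
    bnd <- which(sl & !er, arr.ind = TRUE)
    if (nrow(bnd) < 3) bnd <- which(sl, arr.ind = TRUE)
    if (nrow(bnd) < 3) next
    pts <- index_to_world(meta, cbind(bnd, k))
    ctr <- colMeans(pts)
    ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
    ord <- order(ang)
    pts <- pts[ord, , drop = FALSE]
    # push half a voxel outward along the radial direction
    rad <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    sc <- (rad + mean(meta$spacing[1:2]) / 2) / pmax(rad, 1e-9)
    pts[, 1] <- ctr[1] + (pts[, 1] - ctr[1]) * sc
    pts[, 2] <- ctr[2] + (pts[, 2] - ctr[2]) * sc
    polys[[length(polys) + 1]] <- pts
  }
  polys
}
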