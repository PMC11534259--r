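#' Read a 3-D volume from a NIfTI file
#'
#' Loads a NIfTI-1/2 image and converts its geometry to the package's LPS
#' [grid_meta()] convention (NIfTI affines are RAS; the first two world axes
#' are negated). Integer-typed images are returned as [label_volume()],
#' floating-point images as [scalar_volume()]. A JSON sidecar
#' (`<stem>.json`), when present, supplies units and provenance.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `scalar_volume` or `label_volume`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI '", path,
                                           "': ", conditionMessage(e)))
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("read_volume supports 3-D images only; '", path, "' is ",
         length(dm), "-D")
  aff <- RNifti::xform(img)            # voxel (0-based) -> RAS world
  meta <- affine_to_meta(aff, dm)
  data <- array(as.vector(img), dm)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  units <- NULL
  if (file.exists(sidecar) && sidecar != path)
    units <- jsonlite::read_json(sidecar)$units
  dt <- img$datatype %||% attr(img, "datatype")
  is_int <- is.integer(as.vector(img)[1]) ||
    (!is.null(dt) && dt %in% c(2L, 4L, 8L, 256L, 512L, 768L))
  if (is_int && all(data == round(data)))
    label_volume(data, meta)
  else
    scalar_volume(data, meta, units = units %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NIfTI 0-based-voxel -> RAS affine, converted to LPS grid_meta
affine_to_meta <- function(aff, shape) {
  if (any(!is.finite(aff)))
    stop("volume has a missing or non-finite affine")
  ras2lps <- diag(c(-1, -1, 1))
  m <- ras2lps %*% aff[1:3, 1:3]
  origin <- as.numeric(ras2lps %*% aff[1:3, 4])
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0)) stop("volume affine has degenerate spacing")
  orient <- sweep(m, 2L, spacing, "/")
  if (max(abs(crossprod(orient) - diag(3))) > 1e-4)
    stop("volume affine is not orthonormal (sheared grids are unsupported)")
  grid_meta(shape, spacing = spacing, origin = origin, orientation = orient)
}

meta_to_affine <- function(meta) {
  lps2ras <- diag(c(-1, -1, 1))
  aff <- diag(4)
  aff[1:3, 1:3] <- lps2ras %*% sweep(meta$orientation, 2L, meta$spacing, "*")
  aff[1:3, 4] <- as.numeric(lps2ras %*% meta$origin)
  aff
}

#' Write a volume to NIfTI with a JSON provenance sidecar
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar write a `<stem>.json` sidecar with units, tool version and
#'   any extra provenance fields?
#' @param provenance named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = TRUE, provenance = list()) {
  stopifnot(is_volume(vol))
  data <- vol$data
  if (inherits(vol, "label_volume")) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(meta_to_affine(vol$meta), code = 2L))
  RNifti::writeNifti(img, path)
  if (sidecar) {
    sc <- c(list(units = vol$units, space = "LPS"), provenance, tool_info())
    jsonlite::write_json(sc, sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

tool_info <- function() {
  list(tool = "na23tsc",
       tool_version = as.character(utils::packageVersion("na23tsc")))
}

# stable hash of a configuration list (provenance sidecars)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  # rolling polynomial hash (mod a Mersenne prime); provenance only
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# ---- JSON structure sets (run-length encoded masks) -----------------------

#' Save a named set of ROI masks as a JSON structure set
#'
#' The native on-disk ROI format: each structure is a run-length-encoded
#' flat mask plus the shared grid geometry, readable without DICOM tooling.
#'
#' @param masks named list of logical 3-D arrays on a common grid.
#' @param meta the shared [grid_meta()].
#' @param path output `.json` path.
#' @param provenance named list stored alongside (seeds, config hash).
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(masks, meta, path, provenance = list()) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  enc <- lapply(masks, function(m) {
    stopifnot(identical(as.integer(dim(m)), meta$shape))
    r <- rle(as.vector(as.logical(m)))
    list(lengths = r$lengths, first = r$values[1])
  })
  obj <- list(format = "na23tsc-structure-set", version = 1L,
              grid = list(shape = meta$shape, spacing = meta$spacing,
                          origin = meta$origin,
                          orientation = as.vector(meta$orientation),
                          space = meta$space),
              structures = enc,
              provenance = c(provenance, tool_info()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON structure set written by [write_structure_set()]
#' @param path `.json` path.
#' @return list with `masks` (named list of logical arrays), `meta`,
#'   and `provenance`.
#' @export
read_structure_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "na23tsc-structure-set"))
    stop("'", path, "' is not a na23tsc structure set")
  g <- obj$grid
  meta <- grid_meta(g$shape, spacing = g$spacing, origin = g$origin,
                    orientation = matrix(g$orientation, 3, 3))
  masks <- lapply(obj$structures, function(e) {
    vals <- rep(rep(c(e$first, !e$first), length.out = length(e$lengths)),
                e$lengths)
    array(vals, meta$shape)
  })
  list(masks = masks, meta = meta, provenance = obj$provenance)
}
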