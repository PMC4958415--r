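#' CT volume container
#'
#' A `voxel_volume` holds a 3D scalar attenuation grid (HU) together with its
#' world-space geometry: voxel spacing in mm, the world coordinate of the
#' *center* of voxel (0,0,0), and a 3x3 direction-cosine matrix. Voxel
#' indices are 0-based and continuous: index (0,0,0) is the center of the
#' corner voxel, so subvoxel positions are plain fractional indices.
#'
#' @param data 3D numeric array of attenuation values, at least 2 voxels per
#'   axis.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, world mm of the center of voxel (0,0,0).
#' @param direction 3x3 direction-cosine matrix; must be orthonormal with
#'   determinant +1.
#' @return An object of class `voxel_volume`.
#' @seealso [read_volume()], [write_volume()], [voxel_to_world()]
#' @examples
#' vol <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.6, 0.6, 0.3))
#' voxel_to_world(vol, c(1, 1, 1))
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  direction <- as.matrix(direction)
  check_direction(direction)
  structure(
    list(data = data, spacing = spacing, origin = origin,
         direction = direction),
    class = "voxel_volume"
  )
}

check_direction <- function(direction) {
  if (!all(dim(direction) == c(3L, 3L)) || any(!is.finite(direction)))
    stop("`direction` must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` matrix is not orthonormal", call. = FALSE)
  if (abs(det(direction) - 1) > 1e-6)
    stop("`direction` matrix must have determinant +1 (no reflection)",
         call. = FALSE)
  invisible(direction)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) mm, HU range [%.1f, %.1f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("points must have 3 coordinates", call. = FALSE)
    matrix(as.numeric(p), 1L, 3L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    storage.mode(p) <- "double"
    p
  }
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world()` maps continuous 0-based voxel indices to world mm via
#' `world = origin + direction %*% (index * spacing)`; `world_to_voxel()` is
#' its exact inverse. Indices may be fractional and may lie outside the grid.
#'
#' @param volume A [voxel_volume()].
#' @param index,world A length-3 vector or an n x 3 matrix.
#' @return A vector or matrix of the same shape as the input.
#' @export
voxel_to_world <- function(volume, index) {
  idx <- as_point_matrix(index)
  out <- sweep(idx, 2L, volume$spacing, "*") %*% t(volume$direction)
  out <- sweep(out, 2L, volume$origin, "+")
  if (is.null(dim(index))) drop(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, world) {
  w <- as_point_matrix(world)
  w <- sweep(w, 2L, volume$origin, "-") %*% volume$direction
  out <- sweep(w, 2L, volume$spacing, "/")
  if (is.null(dim(world))) drop(out) else out
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else if (grepl("\\.(mha|mhd)$", lower)) "metaimage"
  else stop(sprintf("unsupported volume format for '%s' (expected .nii, .nii.gz, .mha or .mhd)",
                    path), call. = FALSE)
}

#' Read a CT volume from NIfTI-1 or MetaImage
#'
#' Reads `.nii`/`.nii.gz` (via RNifti) or `.mha`/`.mhd` files into a
#' [voxel_volume()]. Geometry (spacing, origin, direction) is taken from the
#' header; for NIfTI the sform is preferred over the qform when both are
#' present, so behaviour is deterministic across writers. A non-orthonormal
#' or reflecting direction matrix is rejected.
#'
#' @param path Path to the volume file.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  fmt <- volume_format(path)
  if (fmt == "nifti") read_volume_nifti(path) else read_metaimage(path)
}

read_volume_nifti <- function(path) {
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop(sprintf("cannot read NIfTI volume '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(dim(img)) != 3L)
    stop(sprintf("volume '%s' is not 3D", path), call. = FALSE)
  # useQuaternionFirst = FALSE prefers the sform when its code is nonzero
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  mat <- xf[seq_len(3), seq_len(3), drop = FALSE]
  spacing <- sqrt(colSums(mat^2))
  if (any(spacing <= 0))
    stop(sprintf("volume '%s' has non-positive voxel spacing", path),
         call. = FALSE)
  direction <- sweep(mat, 2L, spacing, "/")
  check_direction(direction)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = spacing, origin = xf[seq_len(3), 4L],
               direction = direction)
}

#' Write a CT volume
#'
#' Writes a [voxel_volume()] to NIfTI-1 (`.nii`/`.nii.gz`) or MetaImage
#' (`.mha`, or `.mhd` with a sidecar `.raw`). The header round-trips
#' losslessly through [read_volume()]; NIfTI files carry the geometry in
#' both sform and qform.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path; the extension selects the format.
#' @param datatype Storage type: `"double"` (lossless, default) or
#'   `"float"` (half the size, for bulk simulation output).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = c("double", "float")) {
  stopifnot(inherits(volume, "voxel_volume"))
  datatype <- match.arg(datatype)
  fmt <- volume_format(path)
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write volume: directory '%s' does not exist",
                 dirname(path)), call. = FALSE)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(volume$data)
    xfm <- rbind(cbind(volume$direction %*% diag(volume$spacing),
                       volume$origin),
                 c(0, 0, 0, 1))
    RNifti::qform(img) <- structure(xfm, code = 2L)
    RNifti::sform(img) <- structure(xfm, code = 2L)
    ok <- tryCatch({
      RNifti::writeNifti(img, path, datatype = datatype)
      TRUE
    }, error = function(e) FALSE)
    if (!ok || !file.exists(path))
      stop(sprintf("failed to write NIfTI volume to '%s'", path),
           call. = FALSE)
  } else {
    write_metaimage(volume, path, datatype = datatype)
  }
  invisible(path)
}
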