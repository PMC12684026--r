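# TIFF + YAML-sidecar I/O for stacks and volumes. Data are stored as
# multi-frame TIFF (one frame per sheet position, or per z-slice for
# volumes); all geometry metadata live in the sidecar, which is
# authoritative. 16-bit files hold integer counts exactly; 32-bit float
# files are stored scaled into [0, 1] by a power-of-two factor recorded in
# the sidecar and round-trip at single precision.

.sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")

.validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("dopm_validation_error", "error")))
}

.require_fields <- function(meta, fields, where) {
  missing <- setdiff(fields, names(meta))
  if (length(missing))
    .validation_error(sprintf("sidecar '%s' is missing field(s): %s",
                              where, paste(missing, collapse = ", ")))
  invisible(TRUE)
}

.write_frames <- function(a, path, bits) {
  # a: 3D array, first index = frame
  if (bits == 16L) {
    if (any(a < 0 | a > 65535) || any(a != round(a)))
      stop("16-bit storage requires integer values in [0, 65535]",
           call. = FALSE)
    frames <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 65535)
    tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                    compression = "none")
    1
  } else {
    mx <- max(a, 0)
    scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx * (1 + 1e-7)))
    frames <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / scale)
    suppressWarnings(tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                                     compression = "none"))
    scale
  }
}

.read_frames <- function(path, bits, scale) {
  frames <- tiff::readTIFF(path, all = TRUE,
                           as.is = (bits == 16L))
  a <- array(0, dim = c(length(frames), dim(frames[[1]])[1:2]))
  for (i in seq_along(frames)) a[i, , ] <- frames[[i]]
  if (bits != 16L) a <- a * scale
  a
}

#' Write / read an oblique stack as TIFF with a metadata sidecar
#'
#' One TIFF frame per sheet position; the sidecar (`<path>.yaml`) carries
#' the acquisition geometry (`pixel_um`, `scan_step_um`, `tilt_deg`,
#' `view_id`, `scan_mode`) and the storage encoding. Reading validates the
#' sidecar and names any missing field.
#'
#' @param stack an [ObliqueStack-class].
#' @param path TIFF file path; the sidecar is written next to it.
#' @param bits 16 (exact integer counts) or 32 (scaled float).
#' @return `readStack` returns an [ObliqueStack-class]; `writeStack`
#'   returns `path` invisibly.
#' @export
writeStack <- function(stack, path, bits = 32L) {
  stopifnot(is(stack, "ObliqueStack"), bits %in% c(16L, 32L))
  scale <- .write_frames(stack@voxels, path, bits)
  meta <- list(type = "ObliqueStack",
               pixel_um = stack@pixel_um, scan_step_um = stack@scan_step_um,
               tilt_deg = stack@tilt_deg, view_id = stack@view_id,
               scan_mode = stack@scan_mode,
               dims = as.integer(dim(stack@voxels)),
               bits = as.integer(bits), scale = scale)
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

#' @rdname writeStack
#' @param meta_path optional explicit sidecar path.
#' @export
readStack <- function(path, meta_path = NULL) {
  meta_path <- if (is.null(meta_path)) .sidecar_path(path) else meta_path
  if (!file.exists(meta_path))
    .validation_error(sprintf("metadata sidecar '%s' not found", meta_path))
  meta <- yaml::read_yaml(meta_path)
  .require_fields(meta, c("pixel_um", "scan_step_um", "tilt_deg", "view_id",
                          "scan_mode", "bits", "scale"), meta_path)
  a <- .read_frames(path, meta$bits, meta$scale)
  if (!is.null(meta$dims) && !identical(as.integer(dim(a)),
                                        as.integer(meta$dims)))
    .validation_error("TIFF dimensions do not match the sidecar")
  ObliqueStack(a, pixel_um = meta$pixel_um,
               scan_step_um = meta$scan_step_um, tilt_deg = meta$tilt_deg,
               view_id = as.integer(meta$view_id), scan_mode = meta$scan_mode)
}

#' Write / read an image volume as TIFF with a metadata sidecar
#'
#' One TIFF frame per z-slice. The validity mask is written as a companion
#' 8-bit TIFF (`<path>_mask.tif`) and restored on read.
#'
#' @param vol an [ImageVolume-class].
#' @param path TIFF file path.
#' @param bits 16 or 32.
#' @return `readVolume` returns an [ImageVolume-class]; `writeVolume`
#'   returns `path` invisibly.
#' @export
writeVolume <- function(vol, path, bits = 32L) {
  stopifnot(is(vol, "ImageVolume"), bits %in% c(16L, 32L))
  scale <- .write_frames(vol@voxels, path, bits)
  mask_path <- paste0(sub("\\.tiff?$", "", path), "_mask.tif")
  frames <- lapply(seq_len(dim(vol@valid)[1]),
                   function(i) (vol@valid[i, , ]) * 1)
  tiff::writeTIFF(frames, mask_path, bits.per.sample = 8L,
                  compression = "none")
  meta <- list(type = "ImageVolume",
               voxel_um = vol@voxel_um, origin_um = vol@origin_um,
               dims = as.integer(dim(vol@voxels)),
               bits = as.integer(bits), scale = scale)
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

#' @rdname writeVolume
#' @param meta_path optional explicit sidecar path.
#' @export
readVolume <- function(path, meta_path = NULL) {
  meta_path <- if (is.null(meta_path)) .sidecar_path(path) else meta_path
  if (!file.exists(meta_path))
    .validation_error(sprintf("metadata sidecar '%s' not found", meta_path))
  meta <- yaml::read_yaml(meta_path)
  .require_fields(meta, c("voxel_um", "origin_um", "bits", "scale"),
                  meta_path)
  a <- .read_frames(path, meta$bits, meta$scale)
  mask_path <- paste0(sub("\\.tiff?$", "", path), "_mask.tif")
  valid <- if (file.exists(mask_path)) {
    frames <- tiff::readTIFF(mask_path, all = TRUE)
    v <- array(TRUE, dim = dim(a))
    for (i in seq_along(frames)) v[i, , ] <- frames[[i]] > 0.5
    v
  } else array(TRUE, dim = dim(a))
  ImageVolume(a, voxel_um = as.numeric(meta$voxel_um),
              origin_um = as.numeric(meta$origin_um), valid = valid)
}
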