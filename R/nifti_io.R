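#' Read a NIfTI image (with sidecar if present) as a scan_volume
#'
#' The affine is taken from the sform/qform; 0-based voxel indices map to
#' world mm through it. A missing sidecar on a scan yields a warning and
#' empty metadata. If the loaded array is binary and `as_roi` is TRUE the
#' result is a [roi_mask()].
#'
#' @param image_path .nii or .nii.gz file
#' @param sidecar_path path to JSON sidecar; default: image path with .json
#'   extension; NA suppresses the sidecar lookup (and the warning)
#' @param as_roi coerce to roi_mask
#' @return scan_volume (or roi_mask)
#' @export
read_scan <- function(image_path, sidecar_path = NULL, as_roi = FALSE) {
  if (!file.exists(image_path)) vox_stop("image not found: ", image_path)
  im <- tryCatch(RNifti::readNifti(image_path),
                 error = function(e) vox_stop("unreadable NIfTI '", image_path,
                                              "': ", conditionMessage(e)))
  A <- unname(unclass(RNifti::xform(im, useQuaternionFirst = FALSE)))
  attributes(A) <- list(dim = dim(A))
  hdr <- RNifti::niftiHeader(image_path)   # on-disk header, not in-memory
  dt <- switch(as.character(hdr$datatype),
               "2" = "uint8", "4" = "int16", "8" = "int32",
               "16" = "float", "64" = "double", "float")
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))
  suppress <- identical(sidecar_path, NA) || isTRUE(is.na(sidecar_path))
  scp <- if (is.character(sidecar_path)) sidecar_path else sidecar_path_for(image_path)
  sc <- empty_sidecar()
  if (!suppress) {
    if (file.exists(scp)) {
      sc <- read_sidecar(scp)
    } else if (!as_roi) {
      warning("missing sidecar for ", basename(image_path),
              "; using empty metadata", call. = FALSE)
    }
  }
  if (as_roi) {
    arr3 <- arr
    if (length(dim(arr3)) > 3L) dim(arr3) <- dim(arr3)[1:3]
    return(roi_mask(arr3, A, sc))
  }
  scan_volume(arr, A, sc, datatype = dt)
}

#' Write a scan_volume as a NIfTI (.nii or .nii.gz) plus JSON sidecar
#'
#' The affine is stored in both sform and qform (code 2); writing never
#' mutates the affine. ROI masks are written as uint8.
#'
#' @param vol scan_volume
#' @param image_path output image path (.nii or .nii.gz)
#' @param write_sidecar_file also write the JSON sidecar next to the image
#' @return invisibly, a list with `image` and `sidecar` paths
#' @export
write_scan <- function(vol, image_path, write_sidecar_file = TRUE) {
  stopifnot(inherits(vol, "scan_volume"))
  arr <- vol$array
  if (vol$datatype %in% c("uint8", "int16", "int32")) storage.mode(arr) <- "integer"
  im <- RNifti::asNifti(arr, datatype = vol$datatype)
  # sform only: quaternion storage cannot represent shears and renormalizes
  # scales, so the qform is left unset and readers use the sform
  aff <- structure(vol$affine, code = 2L)
  RNifti::sform(im) <- aff
  RNifti::writeNifti(im, image_path)
  scp <- sidecar_path_for(image_path)
  if (write_sidecar_file) write_sidecar(vol$sidecar, scp)
  invisible(list(image = image_path, sidecar = if (write_sidecar_file) scp else NULL))
}
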