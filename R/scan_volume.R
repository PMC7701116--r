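#' Scan volumes
#'
#' A `scan_volume` bundles the three things every processing module consumes
#' and produces: a numeric array (3D to 5D: x, y, z plus optional time/echo
#' dimensions), a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in mm (RAS+), and the JSON sidecar metadata as a named list.
#'
#' @param array numeric array with at least 3 dimensions (trailing singleton
#'   dimensions may be given explicitly for 4D/5D data)
#' @param affine 4x4 numeric matrix, invertible, last row (0,0,0,1)
#' @param sidecar named list of metadata (see [empty_sidecar()])
#' @param datatype on-disk storage type: one of "uint8", "int16", "int32",
#'   "float", "double"
#' @return an object of class `scan_volume`
#' @export
scan_volume <- function(array, affine = diag(4), sidecar = empty_sidecar(),
                        datatype = "float") {
  if (is.null(dim(array))) vox_stop("scan array must have dimensions")
  if (length(dim(array)) < 3L) {
    dim(array) <- c(dim(array), rep(1L, 3L - length(dim(array))))
  }
  check_affine(affine)
  datatype <- match.arg(datatype, c("uint8", "int16", "int32", "float", "double"))
  structure(list(array = array, affine = unname(affine), sidecar = sidecar,
                 datatype = datatype),
            class = "scan_volume")
}

#' Binary region-of-interest mask
#'
#' An ROI is a 3D binary mask with its own affine; it is a `scan_volume`
#' whose array contains only 0 and 1 and is stored as uint8.
#'
#' @param array array coercible to 0/1
#' @param affine 4x4 affine
#' @param sidecar optional metadata
#' @return object of class `c("roi_mask", "scan_volume")`
#' @export
roi_mask <- function(array, affine = diag(4), sidecar = empty_sidecar()) {
  arr <- array
  arr[is.na(arr)] <- 0
  if (!all(arr %in% c(0, 1))) vox_stop("an ROI mask must be binary (0/1)")
  storage.mode(arr) <- "integer"
  v <- scan_volume(arr, affine, sidecar, datatype = "uint8")
  class(v) <- c("roi_mask", class(v))
  v
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    vox_stop("affine must be a 4x4 matrix")
  if (!isTRUE(all.equal(unname(affine[4, ]), c(0, 0, 0, 1))))
    vox_stop("affine last row must be (0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    vox_stop("affine is singular")
  invisible(TRUE)
}

#' Voxel dimensions (mm) of a scan volume
#' @param vol scan_volume or 4x4 affine
#' @return length-3 numeric vector of voxel edge lengths
#' @export
voxel_sizes <- function(vol) {
  A <- if (is.matrix(vol)) vol else vol$affine
  sqrt(colSums(A[1:3, 1:3]^2))
}

#' Voxel volume in cubic millimetres
#' @param vol scan_volume or affine
#' @export
voxel_volume_mm3 <- function(vol) {
  A <- if (is.matrix(vol)) vol else vol$affine
  abs(det(A[1:3, 1:3]))
}

#' @export
print.scan_volume <- function(x, ...) {
  kind <- if (inherits(x, "roi_mask")) "roi_mask" else "scan_volume"
  cat(sprintf("<%s> %s  voxels %s mm  datatype %s\n", kind,
              paste(dim(x$array), collapse = "x"),
              paste(signif(voxel_sizes(x), 4), collapse = "x"),
              x$datatype))
  invisible(x)
}

#' @export
dim.scan_volume <- function(x) dim(x$array)

#' Is this scan's array binary?
#' @noRd
is_binary_array <- function(arr) {
  u <- unique(as.vector(arr[is.finite(arr)]))
  length(u) <= 2L && all(u %in% c(0, 1))
}
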