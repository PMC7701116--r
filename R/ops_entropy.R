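#' Local Shannon entropy map
#'
#' For every voxel, the Shannon entropy (bits) of the histogram of
#' intensities inside a square (2D, per-slice) or cubic (3D) neighbourhood
#' of side `2*radius + 1`. Histogram bins are equal-width over the global
#' finite intensity range of the input, so values are comparable across
#' the volume. Neighbours outside the image (and non-finite voxels, e.g.
#' after ROI masking with NaN) are excluded from the histogram; voxels
#' whose own value is non-finite get NaN. Values lie in [0, log2(bins)].
#'
#' Implementation: one binary indicator volume per bin, box-summed along
#' each axis with border truncation, which is exactly the per-voxel
#' histogram but runs as a handful of separable matrix products.
#'
#' @param scan scan_volume (3D; for 4D+, the first volume is used)
#' @param radius neighbourhood radius in voxels (>= 1)
#' @param bins number of histogram bins (>= 2)
#' @param window "2D" (per-slice) or "3D"
#' @return scan_volume of entropies in bits (float)
#' @export
op_entropy_map <- function(scan, radius = 3L, bins = 32L, window = c("2D", "3D")) {
  window <- match.arg(window)
  if (radius < 1L) vox_stop("radius must be >= 1")
  if (bins < 2L) vox_stop("bins must be >= 2")
  arr <- scan$array
  if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
  d <- dim(arr)
  finite <- is.finite(arr)
  if (!any(finite)) vox_stop("no finite voxels")
  lo <- min(arr[finite]); hi <- max(arr[finite])
  ib <- array(1L, dim = d)
  if (hi > lo)
    ib[finite] <- pmin(as.integer(bins),
                       as.integer(floor((arr[finite] - lo) / (hi - lo) * bins)) + 1L)
  axes <- if (window == "2D") 1:2 else 1:3
  boxes <- lapply(axes, function(ax) box_band_matrix(d[ax], radius))
  boxsum <- function(x) {
    for (t in seq_along(axes)) x <- apply_along_axis(x, boxes[[t]], axes[t])
    x
  }
  N <- boxsum(finite * 1.0)
  H <- array(0, dim = d)
  for (b in seq_len(bins)) {
    cb <- boxsum((ib == b & finite) * 1.0)
    pb <- cb / pmax(N, 1)
    nz <- pb > 0
    H[nz] <- H[nz] - pb[nz] * log2(pb[nz])
  }
  H[N == 0] <- NaN
  H[!finite] <- NaN
  # box sums are exact integers in disguise; clamp away float round-off
  H <- pmax(H, 0)
  scan_volume(array(H, dim = d), scan$affine, scan$sidecar, datatype = "float")
}
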