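#' Gaussian smoothing
#'
#' Separable Gaussian convolution with reflection at the borders, per slice
#' ("2D": x and y axes only, leaving z untouched) or volumetric ("3D").
#' The filter size is the Gaussian standard deviation, by default in mm and
#' converted per-axis through the voxel sizes; set `unit = "voxel"` to give
#' it directly in voxels. Output is float. Extra (time/echo) dimensions are
#' smoothed independently, never across.
#'
#' @param scan scan_volume
#' @param dimension "2D" or "3D"
#' @param size Gaussian standard deviation (> 0)
#' @param unit "mm" or "voxel"
#' @return smoothed scan_volume (float)
#' @export
op_smooth <- function(scan, dimension = c("3D", "2D"), size = 1, unit = c("mm", "voxel")) {
  dimension <- match.arg(dimension)
  unit <- match.arg(unit)
  if (!is.numeric(size) || size <= 0) vox_stop("filter size must be > 0")
  vs <- voxel_sizes(scan)
  sig <- if (unit == "mm") size / vs else rep(size, 3)
  axes <- if (dimension == "2D") 1:2 else 1:3
  arr <- scan$array * 1.0
  for (ax in axes) {
    K <- gaussian_band_matrix(dim(arr)[ax], sig[ax])
    arr <- apply_along_axis(arr, K, ax)
  }
  scan_volume(arr, scan$affine, scan$sidecar, datatype = "float")
}

#' Intensity thresholding
#'
#' Keeps voxels strictly above (or strictly below) the cutoff. `output =
#' "mask"` returns a binary ROI; `"clipped"` returns the scan with
#' out-of-range voxels set to 0.
#' @param scan scan_volume
#' @param cutoff intensity cutoff
#' @param direction "above" or "below" (strict comparison)
#' @param output "mask" or "clipped"
#' @return roi_mask or scan_volume
#' @export
op_threshold <- function(scan, cutoff, direction = c("above", "below"),
                         output = c("mask", "clipped")) {
  direction <- match.arg(direction)
  output <- match.arg(output)
  keep <- if (direction == "above") scan$array > cutoff else scan$array < cutoff
  keep[is.na(keep)] <- FALSE
  if (output == "mask") {
    m <- keep
    if (length(dim(m)) > 3L) m <- array(m[, , , 1], dim = dim(m)[1:3])
    return(roi_mask(m * 1L, scan$affine, empty_sidecar()))
  }
  arr <- scan$array
  arr[!keep] <- 0
  scan_volume(arr, scan$affine, scan$sidecar, datatype = scan$datatype)
}

#' Mask a scan with an ROI
#'
#' Voxels outside the ROI are replaced by `fill` (0 or NaN); voxels inside
#' are untouched. If the ROI lives on a different grid it is first resliced
#' onto the scan's grid with nearest-neighbour interpolation so the mask
#' stays binary. Masking is idempotent.
#' @param scan scan_volume
#' @param roi roi_mask
#' @param fill 0 or NaN
#' @return masked scan_volume
#' @export
op_mask_with_roi <- function(scan, roi, fill = 0) {
  if (!fill %in% c(0) && !is.na(fill)) vox_stop("fill must be 0 or NaN")
  roi_r <- align_roi_to(roi, scan)
  arr <- scan$array
  if (is.na(fill) && scan$datatype %in% c("uint8", "int16", "int32")) {
    arr <- arr * 1.0
    scan$datatype <- "float"
  }
  outside <- roi_r$array == 0L
  if (length(dim(arr)) > 3L) {
    extra <- prod(dim(arr)[-(1:3)])
    outside <- array(rep(outside, extra), dim = dim(arr))
  }
  arr[outside] <- fill
  scan_volume(arr, scan$affine, scan$sidecar, datatype = scan$datatype)
}

align_roi_to <- function(roi, scan) {
  same_grid <- all(dim(roi$array)[1:3] == dim(scan$array)[1:3]) &&
    max(abs(roi$affine - scan$affine)) < 1e-6
  if (same_grid) return(roi)
  op_reslice(roi, scan, interpolation = "nearest")
}

#' Reslice a scan onto the grid of a reference scan
#'
#' Each voxel of the reference grid is mapped through the composed affine
#' transform into the source volume and sampled there (nearest-neighbour or
#' trilinear). The output carries the reference's grid and affine exactly.
#' Out-of-field voxels get NaN (float data) or 0 (integer data and masks).
#' Extra dimensions are resliced volume by volume.
#'
#' @param scan scan_volume or roi_mask to resample
#' @param reference scan_volume providing the target grid and affine
#' @param interpolation "trilinear" or "nearest" (ROIs always nearest)
#' @return scan on the reference grid (roi_mask in, roi_mask out)
#' @export
op_reslice <- function(scan, reference, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_roi <- inherits(scan, "roi_mask")
  if (is_roi) interpolation <- "nearest"
  check_affine(scan$affine); check_affine(reference$affine)
  rd <- dim(reference$array)[1:3]
  M <- solve(scan$affine) %*% reference$affine
  g <- as.matrix(expand.grid(i = seq_len(rd[1]) - 1, j = seq_len(rd[2]) - 1,
                             k = seq_len(rd[3]) - 1))
  src <- M[1:3, 1:3] %*% t(g) + M[1:3, 4]          # 0-based source voxel coords
  sd3 <- dim(scan$array)[1:3]
  fill <- if (is_roi || scan$datatype %in% c("uint8", "int16", "int32")) 0 else NaN
  sample_vol <- function(vol3) {
    if (interpolation == "nearest") {
      idx <- round(src) + 1
      ok <- idx[1, ] >= 1 & idx[1, ] <= sd3[1] & idx[2, ] >= 1 &
        idx[2, ] <= sd3[2] & idx[3, ] >= 1 & idx[3, ] <= sd3[3]
      out <- rep(fill, ncol(src))
      lin <- idx[1, ok] + (idx[2, ok] - 1) * sd3[1] +
        (idx[3, ok] - 1) * sd3[1] * sd3[2]
      out[ok] <- vol3[lin]
      out
    } else {
      trilinear_sample(vol3, src, fill = fill)
    }
  }
  full_d <- dim(scan$array)
  extra <- if (length(full_d) > 3L) prod(full_d[-(1:3)]) else 1L
  out <- array(fill, dim = c(rd, if (length(full_d) > 3L) full_d[-(1:3)]))
  sv <- scan$array
  dim(sv) <- c(sd3, extra)
  ov <- array(0, dim = c(prod(rd), extra))
  for (e in seq_len(extra)) ov[, e] <- sample_vol(array(sv[, , , e], dim = sd3))
  dim(ov) <- dim(out)
  dtype <- if (is_roi) "uint8" else if (interpolation == "trilinear") "float" else scan$datatype
  if (is_roi) return(roi_mask(array(ov, dim = rd), reference$affine, scan$sidecar))
  scan_volume(ov, reference$affine, scan$sidecar, datatype = dtype)
}

#' Trilinear sampling of a 3D array at fractional 0-based voxel coordinates
#' @param vol3 3D array
#' @param pts 3 x N matrix of 0-based voxel coordinates
#' @param fill value outside the field of view
#' @return numeric vector of length N
#' @export
trilinear_sample <- function(vol3, pts, fill = NaN) {
  d <- dim(vol3)
  x <- pts[1, ] + 1; y <- pts[2, ] + 1; z <- pts[3, ] + 1
  # snap to the grid so resampling onto the own grid is exact
  x <- ifelse(abs(x - round(x)) < 1e-7, round(x), x)
  y <- ifelse(abs(y - round(y)) < 1e-7, round(y), y)
  z <- ifelse(abs(z - round(z)) < 1e-7, round(z), z)
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(y), d[2] - 1L); y0 <- pmax(y0, 1L)
  z0 <- pmin(floor(z), d[3] - 1L); z0 <- pmax(z0, 1L)
  if (d[1] == 1L) x0 <- rep(1L, length(x))
  if (d[2] == 1L) y0 <- rep(1L, length(y))
  if (d[3] == 1L) z0 <- rep(1L, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  n1 <- d[1]; n12 <- d[1] * d[2]
  lin <- function(i, j, k) i + (j - 1) * n1 + (k - 1) * n12
  v <- (1 - fx) * (1 - fy) * (1 - fz) * vol3[lin(x0, y0, z0)] +
       fx * (1 - fy) * (1 - fz) * vol3[lin(x1, y0, z0)] +
       (1 - fx) * fy * (1 - fz) * vol3[lin(x0, y1, z0)] +
       fx * fy * (1 - fz) * vol3[lin(x1, y1, z0)] +
       (1 - fx) * (1 - fy) * fz * vol3[lin(x0, y0, z1)] +
       fx * (1 - fy) * fz * vol3[lin(x1, y0, z1)] +
       (1 - fx) * fy * fz * vol3[lin(x0, y1, z1)] +
       fx * fy * fz * vol3[lin(x1, y1, z1)]
  out[ok] <- v
  out
}
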