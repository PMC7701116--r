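#' First-order statistics of a scan within an ROI
#'
#' Mean, standard deviation (population, divisor N), median, min, max,
#' voxel count and volume in cubic mm over the in-mask finite voxels. The
#' ROI is resampled to the scan grid (nearest neighbour) when the grids
#' differ. Non-finite in-mask voxels are excluded from the moments and
#' reported in `n_nan`.
#'
#' @param scan scan_volume (first volume used for 4D+)
#' @param roi roi_mask
#' @return data.frame with one row: mean, std, median, min, max, n_voxels,
#'   volume_mm3, n_nan
#' @export
roi_first_order_stats <- function(scan, roi) {
  roi_r <- align_roi_to(roi, scan)
  arr <- scan$array
  if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
  inmask <- roi_r$array != 0L
  if (!any(inmask)) vox_stop("empty ROI")
  v <- arr[inmask]
  n_nan <- sum(!is.finite(v))
  v <- v[is.finite(v)]
  if (!length(v)) vox_stop("empty ROI (no finite in-mask voxels)")
  n <- length(v)
  mu <- mean(v)
  data.frame(mean = mu,
             std = sqrt(sum((v - mu)^2) / n),
             median = stats::median(v),
             min = min(v), max = max(v),
             n_voxels = sum(inmask),
             volume_mm3 = sum(inmask) * voxel_volume_mm3(scan),
             n_nan = n_nan)
}

#' Time course of a single voxel of a 4D scan
#' @param scan4d scan_volume with a 4th dimension
#' @param voxel_index length-3 integer, 0-based
#' @return numeric vector along the 4th dimension
#' @export
voxel_timecourse <- function(scan4d, voxel_index) {
  d <- dim(scan4d$array)
  if (length(d) < 4L || d[4] < 2L) vox_stop("scan has no 4th dimension")
  s <- as.integer(voxel_index) + 1L
  if (any(s < 1L) || any(s > d[1:3])) vox_stop("voxel index outside volume")
  arr <- scan4d$array
  dim(arr) <- c(d[1:4], prod(d[-(1:4)], 1))
  as.vector(arr[s[1], s[2], s[3], , 1])
}

#' Histogram of in-mask intensities
#' @param scan scan_volume
#' @param roi roi_mask
#' @param bins number of bins (>= 1), equal width over the in-mask range
#' @return list(edges = length bins+1, counts = length bins); counts sum to
#'   the number of in-mask finite voxels
#' @export
roi_histogram <- function(scan, roi, bins = 32L) {
  if (bins < 1L) vox_stop("bins must be >= 1")
  roi_r <- align_roi_to(roi, scan)
  arr <- scan$array
  if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
  v <- arr[roi_r$array != 0L]
  v <- v[is.finite(v)]
  if (!length(v)) vox_stop("empty ROI")
  lo <- min(v); hi <- max(v)
  if (lo == hi) hi <- lo + 1
  edges <- seq(lo, hi, length.out = bins + 1L)
  ib <- pmin(bins, as.integer(floor((v - lo) / (hi - lo) * bins)) + 1L)
  list(edges = edges, counts = tabulate(ib, bins))
}

#' Paired in-mask voxel values of two scans
#'
#' Both scans are resampled (trilinear) onto the ROI grid; one value pair
#' per in-mask voxel in array order; pairs with a non-finite member are
#' dropped.
#' @param scan_a,scan_b scan_volumes
#' @param roi roi_mask defining the common grid and mask
#' @return data.frame with columns a, b
#' @export
joint_values <- function(scan_a, scan_b, roi) {
  ref <- scan_volume(array(0, dim = dim(roi$array)[1:3]), roi$affine)
  va <- op_reslice(scan_a, ref, "trilinear")$array
  vb <- op_reslice(scan_b, ref, "trilinear")$array
  if (length(dim(va)) > 3L) va <- array(va[, , , 1], dim = dim(va)[1:3])
  if (length(dim(vb)) > 3L) vb <- array(vb[, , , 1], dim = dim(vb)[1:3])
  inm <- roi$array != 0L
  out <- data.frame(a = va[inm], b = vb[inm])
  out[is.finite(out$a) & is.finite(out$b), , drop = FALSE]
}

#' Sample several scans at one world coordinate
#'
#' Each scan is sampled at the same world point through its own inverse
#' affine (trilinear); points outside a scan's field of view yield NaN.
#' @param scans list of scan_volumes (optionally named)
#' @param xyz_mm length-3 world coordinate (mm, RAS+)
#' @return named numeric vector, one value per scan
#' @export
sample_at_world_point <- function(scans, xyz_mm) {
  vapply(scans, function(s) {
    src <- solve(s$affine) %*% c(xyz_mm, 1)
    arr <- s$array
    if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
    trilinear_sample(arr, matrix(src[1:3], nrow = 3), fill = NaN)
  }, numeric(1))
}

#' Longitudinal comparison of one subject across timepoints
#'
#' All scans are resliced onto the first timepoint's grid; per-timepoint
#' first-order ROI statistics are computed, plus the mean absolute
#' difference between every pair of timepoints (a co-registration check
#' and volumetric summary).
#' @param scans named list (names = timepoint labels, in temporal order)
#' @param roi roi_mask on (or resampleable to) the first timepoint's grid
#' @return list(stats = data.frame with a timepoint column, pairwise =
#'   data.frame of mean absolute in-mask differences)
#' @export
longitudinal_compare <- function(scans, roi) {
  if (length(scans) < 2L) vox_stop("need >= 2 timepoints")
  tps <- names(scans) %||% as.character(seq_along(scans))
  ref <- scans[[1]]
  aligned <- c(list(ref), lapply(scans[-1], op_reslice, reference = ref,
                                 interpolation = "trilinear"))
  roi_r <- align_roi_to(roi, ref)
  stats <- do.call(rbind, lapply(seq_along(aligned), function(i)
    cbind(timepoint = tps[i], roi_first_order_stats(aligned[[i]], roi_r))))
  inm <- roi_r$array != 0L
  pairs <- utils::combn(seq_along(aligned), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    ai <- aligned[[i]]$array; aj <- aligned[[j]]$array
    if (length(dim(ai)) > 3L) ai <- array(ai[, , , 1], dim = dim(ai)[1:3])
    if (length(dim(aj)) > 3L) aj <- array(aj[, , , 1], dim = dim(aj)[1:3])
    dv <- abs(ai[inm] - aj[inm])
    data.frame(from = tps[i], to = tps[j],
               mean_abs_diff = mean(dv[is.finite(dv)]))
  }))
  list(stats = stats, pairwise = pw)
}
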