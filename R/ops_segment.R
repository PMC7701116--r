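# Binary morphology and connected components on 3D logical arrays.
# All helpers work on a zero-padded copy so neighbour index arithmetic never
# wraps around array edges.

neighbor_offsets <- function(connectivity = c(26L, 6L)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == "6") g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

pad_mask <- function(mask) {
  d <- dim(mask)
  p <- array(FALSE, dim = d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L) - 1L] <- mask
  p
}

unpad <- function(p) {
  d <- dim(p) - 2L
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

offsets_to_linear <- function(offs, pd) {
  offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
}

#' Label connected components of a 3D binary mask
#' @param mask 3D logical/0-1 array
#' @param connectivity 6 or 26
#' @return integer array of component labels (0 = background)
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- array(mask != 0, dim = dim(mask)[1:3])
  p <- pad_mask(mask)
  pd <- dim(p)
  lin_off <- offsets_to_linear(neighbor_offsets(connectivity), pd)
  labels <- array(0L, dim = pd)
  todo <- which(p)
  seen <- array(FALSE, dim = pd)
  lab <- 0L
  for (s in todo) {
    if (seen[s]) next
    lab <- lab + 1L
    frontier <- s
    seen[s] <- TRUE
    labels[s] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_off, `+`)))
      nb <- nb[p[nb] & !seen[nb]]
      seen[nb] <- TRUE
      labels[nb] <- lab
      frontier <- nb
    }
  }
  unpad(labels)
}

#' Largest connected component of a binary mask
#' @inheritParams label_components
#' @return logical 3D array
#' @export
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(lab)))
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Fill internal holes of a 3D binary mask
#'
#' A hole is background not reachable (6-connectivity) from the array
#' border.
#' @param mask 3D binary array
#' @return logical array with holes filled
#' @export
fill_holes <- function(mask) {
  mask <- array(mask != 0, dim = dim(mask)[1:3])
  p <- pad_mask(mask)
  pd <- dim(p)
  bg <- !p
  lin_off <- offsets_to_linear(neighbor_offsets(6L), pd)
  reach <- array(FALSE, dim = pd)
  border <- which(bg & !pad_mask(array(TRUE, dim = dim(mask))))
  reach[border] <- TRUE
  frontier <- border
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, lin_off, `+`)))
    nb <- nb[nb >= 1L & nb <= prod(pd)]
    nb <- nb[bg[nb] & !reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  unpad(p | (bg & !reach))
}

ball_offsets <- function(radius_mm, voxel_mm) {
  r_vox <- pmax(0L, as.integer(floor(radius_mm / voxel_mm)))
  g <- as.matrix(expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                             dz = -r_vox[3]:r_vox[3]))
  keep <- (g[, 1] * voxel_mm[1])^2 + (g[, 2] * voxel_mm[2])^2 +
    (g[, 3] * voxel_mm[3])^2 <= radius_mm^2 + 1e-9
  g[keep, , drop = FALSE]
}

shift_or <- function(mask, offs) {
  d <- dim(mask)
  rr <- max(abs(offs))
  p <- array(FALSE, dim = d + 2L * rr)
  core <- lapply(d, function(n) seq_len(n) + rr)
  p[core[[1]], core[[2]], core[[3]]] <- mask
  acc <- array(FALSE, dim = dim(p))
  lin_off <- offs[, 1] + offs[, 2] * dim(p)[1] + offs[, 3] * dim(p)[1] * dim(p)[2]
  idx <- which(p)
  for (o in lin_off) acc[idx + o] <- TRUE
  acc[core[[1]], core[[2]], core[[3]]]
}

#' Morphological dilation / erosion / closing with a metric ball
#' @param mask 3D binary array
#' @param radius_mm structuring-element radius in mm
#' @param voxel_mm voxel sizes (mm)
#' @return logical array
#' @export
dilate_ball <- function(mask, radius_mm, voxel_mm = c(1, 1, 1)) {
  offs <- ball_offsets(radius_mm, voxel_mm)
  if (nrow(offs) == 0L) return(array(mask != 0, dim = dim(mask)))
  shift_or(array(mask != 0, dim = dim(mask)), offs)
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius_mm, voxel_mm = c(1, 1, 1)) {
  !dilate_ball(!(mask != 0), radius_mm, voxel_mm)
}

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, radius_mm, voxel_mm = c(1, 1, 1)) {
  erode_ball(dilate_ball(mask, radius_mm, voxel_mm), radius_mm, voxel_mm)
}

#' Otsu's threshold
#' @param values numeric vector (non-finite values ignored)
#' @param nbins histogram resolution
#' @return threshold value maximizing between-class variance
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  v <- values[is.finite(values)]
  if (!length(v)) vox_stop("no finite values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)
  h <- tabulate(pmin(nbins, floor((v - lo) / (hi - lo) * nbins) + 1L), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Brain extraction (simplified intensity/morphology method)
#'
#' A deliberately simple stand-in with a standard contract: Otsu threshold
#' on the intensity histogram, largest 26-connected foreground component,
#' morphological closing with a metric ball, and hole filling. The result
#' is a single connected component with no internal holes. It is not a
#' published skull-stripping algorithm and is labelled "simplified" in the
#' module library.
#'
#' @param scan 3D anatomical scan_volume
#' @param closing_radius_mm ball radius for the closing step
#' @return roi_mask (brain mask, same affine as the scan)
#' @export
op_brain_extract <- function(scan, closing_radius_mm = 2) {
  arr <- scan$array
  if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
  thr <- otsu_threshold(as.vector(arr))
  fg <- arr > thr
  fg[!is.finite(arr)] <- FALSE
  if (!any(fg)) vox_stop("no foreground after thresholding")
  vs <- voxel_sizes(scan)
  m <- largest_component(fg, 26L)
  m <- close_ball(m, closing_radius_mm, vs)
  m <- fill_holes(m)
  m <- largest_component(m, 26L)  # closing can only merge; keep the guarantee
  roi_mask(m * 1L, scan$affine, empty_sidecar())
}

#' CT preprocessing: clip, filter, extract the brain
#'
#' The clipped scan clamps intensities to the Hounsfield window (default
#' 0-100 HU: air and bone collapse onto the window edges). The brain mask
#' combines a strict in-window test on the original HU (excluding bone and
#' air outright) with a strict `> lo` threshold on the Gaussian-filtered
#' original image (default sigma 1 mm): filtering before clamping lets the
#' strongly negative neighbourhood around the skull suppress boundary
#' voxels instead of smearing brain intensity into it. The largest
#' 26-connected component is kept and holes are filled. Optionally the
#' volume is first resampled to 1 mm isotropic.
#'
#' @param ct_scan scan_volume in Hounsfield units
#' @param hu_window length-2 HU window
#' @param smooth_sigma Gaussian sigma in mm
#' @param resize resample to 1 mm isotropic before processing
#' @return list(clipped = scan_volume, smoothed = scan_volume, roi = roi_mask)
#' @export
op_ct_preprocess <- function(ct_scan, hu_window = c(0, 100), smooth_sigma = 1,
                             resize = FALSE) {
  if (resize) ct_scan <- reslice_isotropic(ct_scan, 1)
  arr0 <- ct_scan$array
  if (length(dim(arr0)) > 3L) arr0 <- array(arr0[, , , 1], dim = dim(arr0)[1:3])
  clipped <- scan_volume(pmin(pmax(ct_scan$array, hu_window[1]), hu_window[2]),
                         ct_scan$affine, ct_scan$sidecar, datatype = "float")
  sm <- op_smooth(scan_volume(arr0, ct_scan$affine, ct_scan$sidecar,
                              datatype = "float"),
                  "3D", smooth_sigma, "mm")
  a3 <- sm$array
  inwin <- arr0 > hu_window[1] & arr0 < hu_window[2]
  fg <- inwin & a3 > hu_window[1]
  fg[!is.finite(a3) | !is.finite(arr0)] <- FALSE
  if (!any(fg)) vox_stop("no foreground after thresholding")
  m <- fill_holes(largest_component(fg, 26L))
  list(clipped = clipped, smoothed = sm,
       roi = roi_mask(m * 1L, ct_scan$affine, empty_sidecar()))
}

# resample onto an isotropic grid spanning the same world bounding box
reslice_isotropic <- function(scan, iso_mm = 1) {
  d <- dim(scan$array)[1:3]
  A <- scan$affine
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  w <- A[1:3, 1:3] %*% t(corners) + A[1:3, 4]
  lo <- apply(w, 1, min); hi <- apply(w, 1, max)
  nd <- pmax(1L, as.integer(floor((hi - lo) / iso_mm)) + 1L)
  Aref <- diag(4); Aref[1:3, 1:3] <- diag(rep(iso_mm, 3)); Aref[1:3, 4] <- lo
  ref <- scan_volume(array(0, dim = nd), Aref)
  op_reslice(scan, ref, "trilinear")
}

#' Seeded region growth (active-contour style ROI)
#'
#' Iterative region growth from a seed voxel: a candidate voxel on the
#' region boundary joins when its intensity is within `tolerance_k`
#' standard deviations of the current region mean and it touches at least
#' `smoothness_m` region voxels face-on (6-neighbourhood). Because a
#' single-voxel region has zero variance and no voxel has two neighbours
#' in it, growth is bootstrapped: the tolerance has a floor of
#' `tol_floor_frac` of the image intensity range, and the neighbour
#' requirement is relaxed to 1 while the region is smaller than 10 voxels.
#' The result is 26-connected and always contains the seed.
#'
#' @param scan 3D scan_volume
#' @param seed length-3 integer 0-based voxel index
#' @param tolerance_k tolerance in region standard deviations
#' @param smoothness_m minimum 6-neighbours in region for a voxel to join
#' @param max_iter growth iteration cap (0 returns the seed alone)
#' @param tol_floor_frac tolerance floor, as a fraction of intensity range
#' @return roi_mask
#' @export
op_active_contour <- function(scan, seed, tolerance_k = 2.5, smoothness_m = 2,
                              max_iter = 500, tol_floor_frac = 0.02) {
  arr <- scan$array
  if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
  d <- dim(arr)
  s <- as.integer(seed) + 1L
  if (any(s < 1L) || any(s > d)) vox_stop("seed outside volume")
  if (!is.finite(arr[s[1], s[2], s[3]])) vox_stop("seed on NaN voxel")
  rng <- diff(range(arr[is.finite(arr)]))
  floor_tol <- tol_floor_frac * rng
  region <- array(FALSE, dim = d)
  region[s[1], s[2], s[3]] <- TRUE
  if (max_iter >= 1) {
    off26 <- neighbor_offsets(26L)
    off6 <- neighbor_offsets(6L)
    p <- pad_mask(region)
    pd <- dim(p)
    parr <- array(NA_real_, dim = pd)
    parr[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
    l26 <- offsets_to_linear(off26, pd)
    l6 <- offsets_to_linear(off6, pd)
    for (it in seq_len(max_iter)) {
      inr <- parr[p]
      mu <- mean(inr)
      sd_r <- sqrt(mean((inr - mu)^2))
      tol <- max(tolerance_k * sd_r, floor_tol)
      m_eff <- if (sum(p) < 10L) 1L else as.integer(smoothness_m)
      idx <- which(p)
      cand <- unique(as.vector(outer(idx, l26, `+`)))
      cand <- cand[!p[cand] & is.finite(parr[cand])]
      if (!length(cand)) break
      # smoothness is counted over the 26-neighbourhood: a face-adjacent
      # candidate on a convex front has exactly one face neighbour, so a
      # face-only count >= 2 would freeze any smooth region
      nb_count <- rowSums(matrix(p[as.vector(outer(cand, l26, `+`))],
                                 nrow = length(cand)))
      join <- cand[abs(parr[cand] - mu) <= tol & nb_count >= m_eff]
      if (!length(join)) break
      p[join] <- TRUE
    }
    region <- unpad(p)
  }
  roi_mask(region * 1L, scan$affine, empty_sidecar())
}
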