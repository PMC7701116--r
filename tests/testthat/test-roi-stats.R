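test_that("first-order statistics match closed forms", {
  arr <- array(0, dim = c(5, 5, 2)); arr[1:10] <- 5
  mask <- array(0L, dim = c(5, 5, 2)); mask[1:10] <- 1L
  v <- scan_volume(arr, diag(4))
  st <- roi_first_order_stats(v, roi_mask(mask, diag(4)))
  expect_equal(st$mean, 5); expect_equal(st$std, 0)
  expect_equal(st$n_voxels, 10L); expect_equal(st$volume_mm3, 10)

  ramp <- array(0, dim = c(5, 5, 2)); ramp[1:10] <- 0:9
  str <- roi_first_order_stats(scan_volume(ramp, diag(4)),
                               roi_mask(mask, diag(4)))
  expect_equal(str$mean, 4.5)
  expect_equal(str$std, sqrt(8.25), tolerance = 1e-10)   # population sd
  expect_equal(str$median, 4.5); expect_equal(str$min, 0); expect_equal(str$max, 9)

  v2 <- scan_volume(arr, diag(c(2, 2, 2, 1)))
  expect_equal(roi_first_order_stats(v2, roi_mask(mask, diag(c(2, 2, 2, 1))))$volume_mm3,
               80)
  expect_error(roi_first_order_stats(v, roi_mask(array(0L, dim = c(5, 5, 2)),
                                                 diag(4))), "empty ROI")
})

test_that("statistics equal a naive voxel loop on random instances", {
  set.seed(61)
  for (i in 1:10) {
    shape <- sample(4:8, 3, TRUE)
    arr <- array(rnorm(prod(shape), 50, 20), dim = shape)
    if (i %% 3 == 0) arr[sample(length(arr), 3)] <- NaN
    mask <- array(runif(prod(shape)) < 0.4, dim = shape)
    if (!any(mask)) mask[1] <- TRUE
    vox <- runif(3, 0.5, 3)
    A <- diag(c(vox, 1))
    st <- roi_first_order_stats(scan_volume(arr, A), roi_mask(mask * 1L, A))
    vals <- c()
    for (ii in seq_len(shape[1])) for (jj in seq_len(shape[2]))
      for (kk in seq_len(shape[3]))
        if (mask[ii, jj, kk] && is.finite(arr[ii, jj, kk]))
          vals <- c(vals, arr[ii, jj, kk])
    expect_equal(st$mean, mean(vals), tolerance = 1e-10)
    expect_equal(st$std, sqrt(mean((vals - mean(vals))^2)), tolerance = 1e-10)
    expect_equal(st$median, median(vals), tolerance = 1e-10)
    expect_equal(st$n_voxels, sum(mask))
    expect_equal(st$volume_mm3, sum(mask) * prod(vox), tolerance = 1e-10)
  }
})

test_that("4D voxel time courses are recovered bit-equal", {
  mv <- make_volume("perfusion4d", shape = c(8, 8, 4), seed = 62,
                    params = list(nt = 15))
  ctr <- c(4L, 4L, 2L)
  tc <- voxel_timecourse(mv$volume, ctr - 1L)
  expect_equal(length(tc), 15L)
  expect_identical(tc, mv$volume$array[ctr[1], ctr[2], ctr[3], ])
  # generator truth: envelope is 1 at the centre, so series = 100 + bolus
  expect_equal(tc, 100 + mv$truth$bolus, tolerance = 1e-12)
  expect_error(voxel_timecourse(tiny_scan(), c(1, 1, 1)), "4th dimension")
  const4 <- scan_volume(array(3, dim = c(4, 4, 2, 6)), diag(4))
  expect_equal(voxel_timecourse(const4, c(0, 0, 0)), rep(3, 6))
})

test_that("ROI histograms partition the in-mask voxels", {
  arr <- array(c(rep(10, 50), rep(20, 50)), dim = c(10, 10, 1))
  v <- scan_volume(arr, diag(4))
  full <- roi_mask(array(1L, dim = c(10, 10, 1)), diag(4))
  h1 <- roi_histogram(v, full, bins = 1)
  expect_equal(h1$counts, 100L)
  h2 <- roi_histogram(v, full, bins = 2)
  expect_equal(h2$counts, c(50L, 50L))
  for (b in c(3, 7, 16)) expect_equal(sum(roi_histogram(v, full, b)$counts), 100L)
  expect_equal(h2$edges[1], 10); expect_equal(h2$edges[3], 20)
})

test_that("joint value pairing recovers linear relations and drops NaNs", {
  v <- tiny_scan(c(8, 8, 4), seed = 63)
  v2 <- v; v2$array <- 2 * v$array
  roi <- roi_mask(array(1L, dim = c(8, 8, 4)), v$affine)
  jv <- joint_values(v, v2, roi)
  expect_equal(nrow(jv), 256L)
  expect_equal(unname(coef(lm(b ~ a, jv))["a"]), 2, tolerance = 1e-9)
  jv2 <- joint_values(v, v, roi)
  expect_equal(jv2$a, jv2$b)
  # disjoint fields of view pair nothing
  far <- v; far$affine[1, 4] <- far$affine[1, 4] + 1000
  expect_equal(nrow(joint_values(v, far, roi)), 0L)
})

test_that("world-point sampling is affine-aware across resolutions", {
  set.seed(64)
  # linear intensity field sampled at 1 mm and 2 mm
  f <- function(x, y, z) 2 * x + 3 * y - z + 50
  mk <- function(vox, shape) {
    A <- diag(c(vox, vox, vox, 1)); A[1:3, 4] <- c(-8, -8, -8)
    g <- expand.grid(i = seq_len(shape) - 1, j = seq_len(shape) - 1,
                     k = seq_len(shape) - 1)
    w <- t(A[1:3, 1:3] %*% t(as.matrix(g)) + A[1:3, 4])
    scan_volume(array(f(w[, 1], w[, 2], w[, 3]), dim = rep(shape, 3)), A)
  }
  s1 <- mk(1, 16); s2 <- mk(2, 8)
  pt <- c(1.3, -2.2, 0.7)
  vals <- sample_at_world_point(list(a = s1, b = s2), pt)
  expect_equal(unname(vals["a"]), unname(vals["b"]), tolerance = 1e-6)
  expect_equal(unname(vals["a"]), f(pt[1], pt[2], pt[3]), tolerance = 1e-6)
  # voxel centre hits the stored value exactly
  centre <- s1$affine[1:3, 1:3] %*% c(3, 4, 5) + s1$affine[1:3, 4]
  expect_equal(unname(sample_at_world_point(list(s1), centre)[1]),
               s1$array[4, 5, 6])
  expect_true(is.nan(sample_at_world_point(list(s1), c(1e4, 0, 0))[1]))
})

test_that("longitudinal comparison tracks volumes and registration error", {
  A <- diag(4)
  base <- make_volume("ellipsoid_brain", shape = c(20, 20, 14), seed = 65,
                      params = list(noise = 0))$volume
  same <- longitudinal_compare(list(T0 = base, T1 = base, T2 = base),
                               roi_mask(array(1L, dim = c(20, 20, 14)), A))
  expect_equal(nrow(same$stats), 3L)
  expect_true(all(same$pairwise$mean_abs_diff == 0))
  # growing ellipsoid: ROI volume strictly increases over timepoints
  grow <- lapply(1:3, function(i)
    make_volume("ellipsoid_brain", shape = c(20, 20, 14), seed = 65,
                params = list(noise = 0, semiaxes = c(4, 4, 3) + i)))
  vols <- vapply(grow, function(g) {
    roi <- roi_mask(g$truth$mask * 1L, A)
    roi_first_order_stats(g$volume, roi)$volume_mm3
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_error(longitudinal_compare(list(T0 = base),
                                    roi_mask(array(1L, dim = c(20, 20, 14)), A)),
               ">= 2 timepoints")
})
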