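test_that("smoothing preserves constants, conserves impulse mass, respects 2D slices", {
  const <- scan_volume(array(7, dim = c(8, 8, 6)), diag(4))
  sm <- op_smooth(const, "3D", 2)
  expect_equal(sm$array, const$array, tolerance = 1e-12)
  expect_equal(sm$affine, const$affine)

  imp <- array(0, dim = c(16, 16, 16)); imp[8, 8, 8] <- 5
  v <- scan_volume(imp, diag(4))
  sm3 <- op_smooth(v, "3D", 2)
  expect_equal(sum(sm3$array), 5, tolerance = 1e-6 * 5)
  # direct convolution oracle at the centre voxel (separable kernel)
  r <- ceiling(4 * 2); kk <- exp(-(-r:r)^2 / (2 * 4)); kk <- kk / sum(kk)
  expect_equal(sm3$array[8, 8, 8], 5 * kk[r + 1]^3, tolerance = 1e-10)

  # 2D mode never mixes along z
  imp2 <- array(0, dim = c(8, 8, 4)); imp2[4, 4, 1] <- 1; imp2[4, 4, 3] <- 2
  sm2 <- op_smooth(scan_volume(imp2, diag(4)), "2D", 1.5)
  expect_equal(sum(sm2$array[, , 1]), 1, tolerance = 1e-9)
  expect_equal(sum(sm2$array[, , 2]), 0)
  expect_equal(sum(sm2$array[, , 3]), 2, tolerance = 1e-9)
  expect_error(op_smooth(const, "3D", -1), "size")
})

test_that("thresholding is strict and mask/clipped outputs are consistent", {
  ramp <- scan_volume(array(0:99, dim = c(10, 10, 1)), diag(4))
  m <- op_threshold(ramp, 50, "above", "mask")
  expect_s3_class(m, "roi_mask")
  expect_equal(sum(m$array), 49L)          # strict >
  cl <- op_threshold(ramp, 50, "above", "clipped")
  expect_equal(sum(cl$array != 0), sum(m$array))
  all1 <- op_threshold(ramp, -1, "above", "mask")
  expect_true(all(all1$array == 1L))
  below <- op_threshold(ramp, 50, "below", "mask")
  expect_equal(sum(below$array), 50L)      # 0..49
})

test_that("ROI masking fills outside voxels and is idempotent", {
  v <- tiny_scan(c(10, 10, 6), seed = 31)
  full <- roi_mask(array(1L, dim = c(10, 10, 6)), v$affine)
  expect_equal(op_mask_with_roi(v, full)$array, v$array)
  none <- roi_mask(array(0L, dim = c(10, 10, 6)), v$affine)
  expect_true(all(op_mask_with_roi(v, none, 0)$array == 0))
  set.seed(32)
  sphere <- roi_mask(array(stats::runif(600) > 0.5, dim = c(10, 10, 6)) * 1L,
                     v$affine)
  vpos <- v; vpos$array <- abs(vpos$array) + 1
  m1 <- op_mask_with_roi(vpos, sphere)
  expect_equal(sum(m1$array != 0), sum(sphere$array))
  expect_equal(op_mask_with_roi(m1, sphere)$array, m1$array)  # idempotent
  # NaN fill promotes to float and leaves inside untouched
  mn <- op_mask_with_roi(vpos, sphere, NaN)
  expect_equal(sum(is.finite(mn$array)), sum(sphere$array))
})

test_that("reslicing is exact on its own grid and shifts match array rolls", {
  v <- tiny_scan(c(9, 8, 7), seed = 33)
  same <- op_reslice(v, v, "trilinear")
  expect_equal(max(abs(same$array - v$array)), 0)
  expect_equal(same$affine, v$affine)

  # reference shifted by exactly one voxel along x
  ref <- v
  ref$affine[1, 4] <- ref$affine[1, 4] + 1
  sh <- op_reslice(v, ref, "trilinear")
  expect_equal(sh$array[1:8, , ], v$array[2:9, , ], tolerance = 1e-12)
  expect_true(all(is.na(sh$array[9, , ])))

  # downsampling a constant image stays constant
  const <- scan_volume(array(4.5, dim = c(8, 8, 8)), diag(4))
  ref2 <- scan_volume(array(0, dim = c(4, 4, 4)), diag(c(2, 2, 2, 1)))
  expect_true(all(abs(op_reslice(const, ref2)$array - 4.5) < 1e-12 |
                  is.na(op_reslice(const, ref2)$array)))
  expect_error(op_reslice(v, scan_volume(array(0, dim = c(2, 2, 2)),
                                         matrix(0, 4, 4))), "affine")
})

test_that("stats of a scan resliced onto its own grid equal the original's", {
  v <- tiny_scan(c(10, 10, 6), seed = 34)
  roi <- roi_mask((v$array > 100) * 1L, v$affine)
  s1 <- roi_first_order_stats(v, roi)
  s2 <- roi_first_order_stats(op_reslice(v, v, "trilinear"), roi)
  expect_equal(s1, s2)
})

test_that("brain extraction recovers the phantom ellipsoid as one filled component", {
  mv <- make_volume("ellipsoid_brain", shape = c(28, 28, 20), seed = 41)
  roi <- op_brain_extract(mv$volume)
  expect_gte(dice(roi$array == 1, mv$truth$mask), 0.95)
  lab <- label_components(roi$array, 26)
  expect_equal(max(lab), 1L)
  filled <- fill_holes(roi$array)
  expect_equal(sum(filled), sum(roi$array))
  expect_error(op_brain_extract(scan_volume(array(0, dim = c(6, 6, 6)), diag(4))),
               "no foreground")
})

test_that("CT preprocessing clamps the HU window and isolates the brain", {
  mv <- make_volume("ct_head", shape = c(32, 32, 24), seed = 42)
  res <- op_ct_preprocess(mv$volume)
  # clamp: air -1000 -> 0, bone 1000 -> 100
  expect_equal(min(res$clipped$array), 0)
  expect_equal(max(res$clipped$array), 100)
  inroi <- res$roi$array == 1
  expect_equal(sum(mv$volume$array[inroi] > 100), 0L)   # no bone in the ROI
  expect_equal(sum(mv$volume$array[inroi] < -500), 0L)  # no air either
  expect_lt(abs(sum(inroi) - sum(mv$truth$mask)) / sum(mv$truth$mask), 0.05)
})

test_that("seeded region growth segments the phantom and respects max_iter", {
  mv <- make_volume("ellipsoid_brain", shape = c(24, 24, 16), seed = 43,
                    params = list(noise = 1))
  ctr <- as.integer(round((dim(mv$volume$array) + 1) / 2)) - 1L
  roi <- op_active_contour(mv$volume, ctr)
  expect_gte(dice(roi$array == 1, mv$truth$mask), 0.9)
  # background seed stays in the background
  bg <- op_active_contour(mv$volume, c(1L, 1L, 1L))
  expect_equal(sum(bg$array & mv$truth$mask), 0L)
  # max_iter = 0 returns the seed alone
  single <- op_active_contour(mv$volume, ctr, max_iter = 0)
  expect_equal(sum(single$array), 1L)
  expect_equal(single$array[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1], 1L)
  nanvol <- mv$volume; nanvol$array[2, 2, 2] <- NaN
  expect_error(op_active_contour(nanvol, c(1L, 1L, 1L)), "NaN")
})

test_that("the stats CSV export matches the library statistics row by row", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 1,
                               shape = c(12, 12, 8), seed = 44), root)
  out <- file.path(tempdir(), "stats.csv")
  df <- export_stats_csv(p, "Seq01", "BrainROI", out)
  expect_equal(nrow(df), 6L)
  got <- utils::read.csv(out)
  expect_equal(nrow(got), 6L)
  e <- filter_database(p, subject = "S01", timepoint = "T0", type = "Scan")
  r <- filter_database(p, subject = "S01", timepoint = "T0", type = "ROI")
  st <- roi_first_order_stats(
    read_scan(file.path(root, e$path, e$filename)),
    read_scan(file.path(root, r$path, r$filename), as_roi = TRUE))
  expect_equal(got$mean[got$subject == "S01" & got$timepoint == "T0"], st$mean,
               tolerance = 1e-6)
  expect_error(export_stats_csv(p, "Nope", "BrainROI", out), "no scan/ROI")
})

test_that("the HTML report is self-contained with one image per scan", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 1,
                               shape = c(12, 12, 8), seed = 45), root)
  out <- file.path(tempdir(), "report.html")
  html_report(p, filter_database(p, type = "Scan"), "BrainROI", out)
  txt <- readLines(out)
  expect_equal(sum(lengths(regmatches(txt, gregexpr("<img ", txt)))), 6L)
  expect_equal(sum(grepl("http", txt)), 0L)        # no external assets
  expect_true(any(grepl("data:image/png;base64", txt)))
  expect_error(html_report(p, filter_database(p, subject = "nope"),
                           NULL, out), "empty selection")
  # deterministic given fixed inputs
  out2 <- file.path(tempdir(), "report2.html")
  html_report(p, filter_database(p, type = "Scan"), "BrainROI", out2)
  expect_identical(readLines(out), readLines(out2))
})
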