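#' Export first-order ROI statistics of a cohort as CSV
#'
#' One row per (subject, timepoint) session of the project that has both
#' the scan sequence and the ROI sequence, with columns subject,
#' timepoint, scan, roi, mean, std, median, min, max, n_voxels,
#' volume_mm3. Values are exactly those of [roi_first_order_stats()].
#'
#' @param project vox_project
#' @param sequence scan sequence-name tag
#' @param roi_sequence ROI sequence-name tag
#' @param out_path output CSV path
#' @return the data.frame written, invisibly
#' @export
export_stats_csv <- function(project, sequence, roi_sequence, out_path) {
  scans <- filter_database(project, sequence = sequence, type = "Scan")
  rois <- filter_database(project, sequence = roi_sequence, type = "ROI")
  if (!nrow(scans) || !nrow(rois)) vox_stop("no scan/ROI pairing resolvable")
  rows <- list()
  for (i in seq_len(nrow(scans))) {
    srow <- scans[i, ]
    rrow <- rois[rois$subject == srow$subject & rois$timepoint == srow$timepoint, ]
    if (!nrow(rrow)) next
    scan <- read_scan(entry_image_path(project, srow))
    roi <- read_scan(entry_image_path(project, rrow[1, ]), as_roi = TRUE)
    st <- roi_first_order_stats(scan, roi)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(subject = srow$subject, timepoint = srow$timepoint,
                       scan = srow$sequence, roi = rrow$sequence[1]),
            st[, c("mean", "std", "median", "min", "max", "n_voxels",
                   "volume_mm3")])
  }
  if (!length(rows)) vox_stop("no scan/ROI pairing resolvable")
  df <- do.call(rbind, rows)
  df <- df[order(df$subject, df$timepoint), , drop = FALSE]
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Static HTML report of scans and ROI
#'
#' A single self-contained HTML file (no external assets: thumbnails are
#' base64-embedded PNGs) with, per scan, the mid-axial slice, the ROI
#' contour overlaid in red when a matching ROI exists, and the first-order
#' statistics table.
#'
#' @param project vox_project
#' @param scans data.frame of Scan entries (e.g. from [filter_database()])
#' @param roi_sequence optional ROI sequence-name to overlay / tabulate
#' @param out_path output .html path
#' @param title report title
#' @return out_path, invisibly
#' @export
html_report <- function(project, scans, roi_sequence = NULL, out_path,
                        title = "Image and ROI report") {
  if (!nrow(scans)) vox_stop("empty selection")
  body <- character(0)
  for (i in seq_len(nrow(scans))) {
    srow <- scans[i, ]
    scan <- read_scan(entry_image_path(project, srow))
    roi <- NULL
    if (!is.null(roi_sequence)) {
      rrow <- filter_database(project, subject = srow$subject,
                              timepoint = srow$timepoint,
                              sequence = roi_sequence, type = "ROI")
      if (nrow(rrow)) roi <- read_scan(entry_image_path(project, rrow[1, ]),
                                       as_roi = TRUE)
    }
    body <- c(body, scan_panel_html(srow, scan, roi))
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            sprintf("<title>%s</title>", title),
            "<style>body{font-family:sans-serif} table{border-collapse:collapse}",
            "td,th{border:1px solid #999;padding:2px 6px}</style></head><body>",
            sprintf("<h1>%s</h1>", title), body, "</body></html>")
  writeLines(html, out_path)
  invisible(out_path)
}

scan_panel_html <- function(srow, scan, roi) {
  png_b64 <- mid_slice_png_base64(scan, roi)
  stats_html <- if (!is.null(roi)) {
    st <- roi_first_order_stats(scan, roi)
    paste0("<table><tr>",
           paste(sprintf("<th>%s</th>", names(st)), collapse = ""), "</tr><tr>",
           paste(sprintf("<td>%s</td>", signif(unlist(st), 6)), collapse = ""),
           "</tr></table>")
  } else ""
  paste0("<div class='panel'><h2>", srow$subject, " / ", srow$timepoint, " / ",
         srow$sequence, "</h2><img alt='", srow$filename,
         "' src='data:image/png;base64,", png_b64, "'/>", stats_html, "</div>")
}

mid_slice_png_base64 <- function(scan, roi = NULL) {
  arr <- scan$array
  if (length(dim(arr)) > 3L) arr <- array(arr[, , , 1], dim = dim(arr)[1:3])
  z <- max(1L, dim(arr)[3] %/% 2L)
  sl <- arr[, , z]
  sl[!is.finite(sl)] <- min(sl[is.finite(sl)], 0)
  rng <- range(sl)
  g <- if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0
  rgb <- array(rep(g, 3), dim = c(dim(g), 3))
  if (!is.null(roi) && all(dim(roi$array)[1:3] == dim(arr))) {
    m <- roi$array[, , z] != 0
    edge <- m & !(shift2(m, 1, 0) & shift2(m, -1, 0) &
                  shift2(m, 0, 1) & shift2(m, 0, -1))
    rgb[, , 1][edge] <- 1; rgb[, , 2][edge] <- 0; rgb[, , 3][edge] <- 0
  }
  # PNG rows are the first dimension of the array; transpose for display
  img <- aperm(rgb, c(2, 1, 3))[dim(rgb)[2]:1, , , drop = FALSE]
  raw_png <- png::writePNG(img)
  jsonlite::base64_enc(raw_png)
}

shift2 <- function(m, dx, dy) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}
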