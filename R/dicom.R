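# Minimal DICOM part-10 support: classic single-frame files, explicit VR,
# little endian. This covers exactly the dialect the converter contracts to
# read (and the fixture writer emits); enhanced multi-frame files, sequences
# and other transfer syntaxes are rejected up front.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dicom_tag <- function(group, element) sprintf("%04X%04X", group, element)

# ---- reading ---------------------------------------------------------------

#' Read one single-frame DICOM file
#'
#' Parses a part-10, explicit-VR little-endian DICOM file into a named list
#' of elements keyed by "GGGGEEEE" tag strings. Numeric VRs (US/UL/SS/SL,
#' DS/IS/FL/FD) are decoded to numbers; PixelData is returned as an integer
#' matrix (columns x rows).
#' @param path DICOM file
#' @return named list with `elements` and `pixel` (matrix or NULL)
#' @export
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    vox_stop("not a part-10 DICOM file: ", path)
  pos <- 133L
  elements <- list()
  rows <- cols <- NA_integer_
  pixel <- NULL
  bits <- 16L; signed <- TRUE
  n <- length(raw)
  while (pos <= n - 7L) {
    group <- readBin(raw[pos:(pos + 1L)], "integer", size = 2, endian = "little",
                     signed = FALSE)
    element <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2,
                       endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- readBin(raw[(pos + 8L):(pos + 11L)], "integer", size = 4,
                     endian = "little")
      hdr <- 12L
    } else {
      len <- readBin(raw[(pos + 6L):(pos + 7L)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      hdr <- 8L
    }
    if (len < 0L) vox_stop("undefined-length element unsupported in ", path)
    val_raw <- if (len > 0L) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tag <- dicom_tag(group, element)
    if (tag == "00020010") {
      ts <- trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
      if (ts != TRANSFER_SYNTAX_EXPLICIT_LE)
        vox_stop("unsupported transfer syntax ", ts, " in ", path)
    }
    if (tag == "7FE00010") {
      vals <- readBin(val_raw, "integer", n = len %/% (bits %/% 8L),
                      size = bits %/% 8L, endian = "little", signed = signed)
      pixel <- matrix(vals, nrow = cols, ncol = rows)  # column index fastest
    } else {
      v <- decode_dicom_value(vr, val_raw)
      elements[[tag]] <- v
      if (tag == "00280010") rows <- as.integer(v)
      if (tag == "00280011") cols <- as.integer(v)
      if (tag == "00280100") bits <- as.integer(v)
      if (tag == "00280103") signed <- as.integer(v) == 1L
    }
    pos <- pos + hdr + len
  }
  list(elements = elements, pixel = pixel)
}

decode_dicom_value <- function(vr, val_raw) {
  if (vr %in% c("US")) return(readBin(val_raw, "integer", n = length(val_raw) / 2,
                                      size = 2, endian = "little", signed = FALSE))
  if (vr %in% c("SS")) return(readBin(val_raw, "integer", n = length(val_raw) / 2,
                                      size = 2, endian = "little"))
  if (vr %in% c("UL", "SL")) return(readBin(val_raw, "integer",
                                            n = length(val_raw) / 4,
                                            size = 4, endian = "little"))
  if (vr == "FL") return(readBin(val_raw, "double", n = length(val_raw) / 4,
                                 size = 4, endian = "little"))
  if (vr == "FD") return(readBin(val_raw, "double", n = length(val_raw) / 8,
                                 size = 8, endian = "little"))
  s <- trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
  if (vr %in% c("DS", "IS")) {
    return(as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]]))
  }
  s
}

# ---- writing ---------------------------------------------------------------

encode_element <- function(group, element, vr, value) {
  val_raw <- if (vr %in% c("US")) {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("UL")) {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("OW")) {
    value  # already raw
  } else {
    s <- if (vr %in% c("DS", "IS")) paste(formatC(value, format = "fg",
                                                  digits = 10, width = 1),
                                          collapse = "\\")
         else as.character(value)
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    b
  }
  len <- length(val_raw)
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% LONG_VRS) {
    head <- c(head, as.raw(c(0L, 0L)),
              writeBin(as.integer(len), raw(), size = 4, endian = "little"))
  } else {
    head <- c(head, writeBin(as.integer(len), raw(), size = 2, endian = "little"))
  }
  c(head, val_raw)
}

synthetic_uid <- function(...) {
  # deterministic study/series/instance UIDs in a private test root
  paste0("1.2.826.0.1.3680043.9999.", paste(..., sep = "."))
}

write_dicom_slice <- function(path, slice_matrix, meta) {
  body <- raw(0)
  add <- function(g, e, vr, v) body <<- c(body, encode_element(g, e, vr, v))
  add(0x0008, 0x0018, "UI", meta$sop_uid)
  if (!is.null(meta$AcquisitionDateTime)) add(0x0008, 0x002A, "DT", meta$AcquisitionDateTime)
  add(0x0008, 0x0060, "CS", meta$Modality %||% "MR")
  if (!is.null(meta$SeriesDescription)) add(0x0008, 0x103E, "LO", meta$SeriesDescription)
  if (!is.null(meta$SliceThickness)) add(0x0018, 0x0050, "DS", meta$SliceThickness)
  if (!is.null(meta$RepetitionTime)) add(0x0018, 0x0080, "DS", meta$RepetitionTime)
  if (!is.null(meta$EchoTime)) add(0x0018, 0x0081, "DS", meta$EchoTime)
  if (!is.null(meta$FlipAngle)) add(0x0018, 0x1314, "DS", meta$FlipAngle)
  add(0x0020, 0x000D, "UI", meta$study_uid)
  add(0x0020, 0x000E, "UI", meta$series_uid)
  add(0x0020, 0x0013, "IS", meta$instance_number)
  add(0x0020, 0x0032, "DS", meta$ipp)
  add(0x0020, 0x0037, "DS", meta$iop)
  add(0x0028, 0x0002, "US", 1L)
  add(0x0028, 0x0004, "CS", "MONOCHROME2")
  # slice_matrix is (column index, row index), so Rows = ncol, Columns = nrow
  add(0x0028, 0x0010, "US", ncol(slice_matrix))
  add(0x0028, 0x0011, "US", nrow(slice_matrix))
  add(0x0028, 0x0030, "DS", meta$pixel_spacing)
  add(0x0028, 0x0100, "US", 16L)
  add(0x0028, 0x0101, "US", 16L)
  add(0x0028, 0x0102, "US", 15L)
  add(0x0028, 0x0103, "US", 1L)
  pix <- writeBin(as.integer(slice_matrix), raw(), size = 2, endian = "little")
  body <- c(body, encode_element(0x7FE0, 0x0010, "OW", pix))

  meta_grp <- c(
    encode_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    encode_element(0x0002, 0x0003, "UI", meta$sop_uid),
    encode_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE))
  meta_grp <- c(encode_element(0x0002, 0x0000, "UL", length(meta_grp)), meta_grp)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_grp, body), con)
  invisible(path)
}

# ---- series conversion -----------------------------------------------------

#' Convert a directory of single-frame DICOM slices into a scan volume
#'
#' Slices are sorted by the projection of ImagePositionPatient onto the
#' slice normal (the cross product of the row and column direction
#' cosines); the 4x4 affine is assembled from ImageOrientationPatient,
#' ImagePositionPatient and PixelSpacing and converted from DICOM's LPS to
#' the RAS+ world convention. Sidecar metadata are collected through the
#' mapping. Mixed series in one directory and irregular slice spacing are
#' errors.
#'
#' @param series_dir directory containing the .dcm files of one series
#' @param mapping [load_metadata_mapping()] result; default: shipped mapping
#' @param out_path optional output image path (.nii.gz); when given, the
#'   NIfTI + JSON pair is written and their paths returned
#' @param spacing_tol relative tolerance on inter-slice spacing regularity
#' @return a scan_volume, or (with `out_path`) list(image, sidecar) paths
#' @export
convert_dicom_series <- function(series_dir, mapping = load_metadata_mapping(),
                                 out_path = NULL, spacing_tol = 1e-3) {
  files <- list.files(series_dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) vox_stop("no DICOM files in ", series_dir)
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, function(s) s$elements[["0020000E"]] %||% "", character(1))
  if (length(unique(uids)) != 1L)
    vox_stop("mixed SeriesInstanceUIDs in ", series_dir, ": ",
             paste(unique(uids), collapse = ", "))
  iop <- slices[[1]]$elements[["00200037"]]
  if (length(iop) != 6L) vox_stop("missing ImageOrientationPatient")
  u <- iop[1:3]; v <- iop[4:6]
  normal <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
  ipps <- t(vapply(slices, function(s) s$elements[["00200032"]], numeric(3)))
  proj <- as.vector(ipps %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; ipps <- ipps[ord, , drop = FALSE]; proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(proj)
    if (max(gaps) - min(gaps) > spacing_tol * stats::median(gaps))
      vox_stop("inconsistent slice spacing in ", series_dir, "; gaps: ",
               paste(signif(gaps, 6), collapse = ", "))
  }
  ps <- slices[[1]]$elements[["00280030"]]  # (between rows, between cols)
  dr <- ps[1]; dc <- ps[2]
  arr <- array(0L, dim = c(nrow(slices[[1]]$pixel), ncol(slices[[1]]$pixel), nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[k]]$pixel
  step <- if (nz > 1L) (ipps[nz, ] - ipps[1, ]) / (nz - 1L)
          else normal * (slices[[1]]$elements[["00180050"]] %||% 1)
  A_lps <- rbind(cbind(u * dc, v * dr, step, ipps[1, ]), c(0, 0, 0, 1))
  A <- diag(c(-1, -1, 1, 1)) %*% A_lps

  sc <- empty_sidecar()
  for (r in unclass(mapping)) {
    if (r$source_dialect != "dicom") next
    tag <- toupper(gsub("[(),]", "", r$source_address))
    val <- slices[[1]]$elements[[tag]]
    if (is.null(val)) next
    if (is.numeric(val)) val <- val * r$unit_conversion
    sc[[r$target_key]] <- if (length(val) == 1L) val else as.list(val)
  }
  vol <- scan_volume(arr, unname(A), sc, datatype = "int16")
  if (is.null(out_path)) return(vol)
  write_scan(vol, out_path)
  list(image = out_path, sidecar = sidecar_path_for(out_path))
}

#' Normalize a NIfTI (+ optional sidecar) into the canonical .nii.gz + JSON pair
#'
#' The image is copied (or recompressed) to `.nii.gz` with the affine
#' preserved; an existing sidecar is carried over, otherwise a minimal one
#' (Modality "unknown", empty History) is synthesized.
#' @param image path to a .nii or .nii.gz file
#' @param sidecar optional path to a JSON sidecar
#' @param out_path output image path (.nii.gz)
#' @return list(image, sidecar) paths
#' @export
convert_nifti <- function(image, sidecar = NULL, out_path) {
  vol <- read_scan(image, sidecar_path = sidecar %||% NA)
  sc <- if (!is.null(sidecar)) {
    read_sidecar(sidecar)
  } else {
    auto <- sidecar_path_for(image)
    if (file.exists(auto)) read_sidecar(auto) else empty_sidecar(Modality = "unknown")
  }
  vol$sidecar <- sc
  write_scan(vol, out_path)
  list(image = out_path, sidecar = sidecar_path_for(out_path))
}
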