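#' Sidecar metadata
#'
#' Every scan is described by a NIfTI file plus a JSON sidecar holding the
#' acquisition metadata (echo time, repetition time, ...) and the processing
#' history of the file. Keys follow BIDS naming; times are in milliseconds.
#' Absent source fields are simply omitted, never stored as null.
#'
#' @param Modality modality string, e.g. "MR" or "CT"
#' @param ... further key = value metadata pairs
#' @return named list with a `History` component (list of history records)
#' @export
empty_sidecar <- function(Modality = NULL, ...) {
  sc <- list(...)
  if (!is.null(Modality)) sc$Modality <- Modality
  if (is.null(sc$History)) sc$History <- list()
  sc
}

#' Read a JSON sidecar
#' @param path path to a .json file
#' @return named list; `History` guaranteed present (possibly empty)
#' @export
read_sidecar <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc <- lapply(sc, simplify_sidecar_value)
  names(sc) <- names(jsonlite::read_json(path, simplifyVector = FALSE))
  if (is.null(sc$History)) sc$History <- list()
  sc
}

# scalars arrive as length-1 lists from read_json; unwrap them but keep
# History (list of records) and other structured values intact
simplify_sidecar_value <- function(v) {
  if (is.list(v) && length(v) > 0L && is.null(names(v)) &&
      all(vapply(v, function(e) is.atomic(e) && length(e) == 1L, logical(1)))) {
    return(unlist(v))
  }
  if (is.list(v) && length(v) == 1L && is.null(names(v)) && is.atomic(v[[1]]))
    return(v[[1]])
  v
}

#' Write a JSON sidecar
#' @param sidecar named list
#' @param path output path
#' @export
write_sidecar <- function(sidecar, path) {
  drop_null <- function(x) {
    if (is.list(x) && !is.null(names(x))) x <- x[!vapply(x, is.null, logical(1))]
    x
  }
  sidecar <- drop_null(sidecar)
  if (is.null(sidecar$History)) sidecar$History <- list()
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Sidecar path conventionally paired with an image path
#' @param image_path path ending in .nii or .nii.gz
#' @export
sidecar_path_for <- function(image_path) {
  sub("\\.nii(\\.gz)?$", ".json", image_path)
}
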