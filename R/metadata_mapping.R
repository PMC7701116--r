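#' Metadata extraction mappings
#'
#' The converter decides which acquisition metadata end up in the JSON
#' sidecar through a user-editable YAML mapping: a list of rules, each
#' binding one target sidecar key to a source address in a given dialect
#' (for DICOM, a tag like "(0018,0081)") with an optional numeric unit
#' conversion factor. Times are stored in milliseconds (DICOM's native
#' unit), so the default conversion factor is 1.
#'
#' @param yaml_path path to a YAML mapping file; default: the mapping
#'   shipped with the package
#' @return a `metadata_mapping` object (list of validated rules)
#' @export
load_metadata_mapping <- function(yaml_path = default_mapping_path()) {
  doc <- tryCatch(yaml::read_yaml(yaml_path),
                  error = function(e) vox_stop("cannot parse mapping YAML: ",
                                               conditionMessage(e)))
  rules <- doc$rules
  if (!is.list(rules) || !length(rules)) vox_stop("mapping has no rules")
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!is_scalar_character(r$target_key) || !nzchar(r$target_key))
      vox_stop("rule ", i, ": missing target_key")
    if (!is_scalar_character(r$source_dialect) ||
        !r$source_dialect %in% c("dicom", "nifti"))
      vox_stop("rule ", i, " ('", r$target_key %||% "?",
               "'): unknown dialect '", r$source_dialect %||% "", "'")
    if (r$source_dialect == "dicom" &&
        !grepl("^\\([0-9A-Fa-f]{4},[0-9A-Fa-f]{4}\\)$", r$source_address %||% ""))
      vox_stop("rule ", i, " ('", r$target_key,
               "'): bad DICOM tag syntax '", r$source_address %||% "", "'")
    rules[[i]]$unit_conversion <- as.numeric(r$unit_conversion %||% 1)
  }
  keys <- vapply(rules, `[[`, character(1), "target_key")
  if (anyDuplicated(keys))
    vox_stop("duplicate target_key in mapping: ", keys[duplicated(keys)][1])
  structure(rules, class = "metadata_mapping")
}

#' Path of the default metadata mapping shipped with the package
#' @export
default_mapping_path <- function() {
  system.file("extdata", "metadata_mapping.yaml", package = "voxpipe",
              mustWork = TRUE)
}

#' Write a metadata mapping back to YAML
#' @param mapping metadata_mapping
#' @param path output YAML path
#' @export
dump_metadata_mapping <- function(mapping, path) {
  rules <- lapply(unclass(mapping), function(r)
    list(target_key = r$target_key, source_dialect = r$source_dialect,
         source_address = r$source_address, unit_conversion = r$unit_conversion))
  yaml::write_yaml(list(rules = rules), path)
  invisible(path)
}

# registry for additional source dialects (e.g. vendor formats): a reader
# takes a directory and returns list(array, affine, metadata)
.dialects <- new.env(parent = emptyenv())

#' Register a source-dialect reader
#'
#' Extension hook for image dialects beyond DICOM and NIfTI: the reader
#' receives a directory (or file) path and must return a list with
#' `array`, `affine` (4x4 RAS+) and `metadata` (named list). Registered
#' dialects become valid values for conversion entry points.
#' @param name dialect name
#' @param reader function(path) -> list(array, affine, metadata)
#' @export
register_dialect <- function(name, reader) {
  stopifnot(is_scalar_character(name), is.function(reader))
  assign(name, reader, envir = .dialects)
  invisible(name)
}

get_dialect <- function(name) {
  if (!exists(name, envir = .dialects)) vox_stop("unknown dialect '", name, "'")
  get(name, envir = .dialects)
}
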