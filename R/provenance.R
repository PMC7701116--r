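ENGINE_VERSION <- "1"

#' Create a provenance history record
#'
#' One record per module execution, stored under the `History` key of every
#' output's JSON sidecar: module id, the full parameter map, input and
#' output filenames (relative to the project root), the execution
#' timestamp, and the engine version. Records are appended, never mutated.
#'
#' @param module_id module identifier (e.g. "Module_Smooth")
#' @param parameters named list of parameter values
#' @param inputs character vector of input filenames (relative)
#' @param outputs character vector of output filenames (relative)
#' @param timestamp character timestamp; defaults to now (UTC, ISO-8601)
#' @return a `history_record` (named list)
#' @export
history_record <- function(module_id, parameters, inputs, outputs,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                                              tz = "UTC")) {
  if (!length(inputs) || !length(outputs))
    vox_stop("history record needs at least one input and one output")
  structure(list(module_id = module_id,
                 parameters = parameters %||% list(),
                 inputs = as.list(unname(inputs)),
                 outputs = as.list(unname(outputs)),
                 timestamp = timestamp,
                 engine_version = ENGINE_VERSION),
            class = "history_record")
}

#' Append a history record to a sidecar
#' @param sidecar sidecar list
#' @param record [history_record()]
#' @return sidecar with History grown by one; prior records untouched
#' @export
append_history <- function(sidecar, record) {
  if (!inherits(record, "history_record") &&
      !all(c("module_id", "inputs", "outputs") %in% names(record)))
    vox_stop("not a history record")
  sidecar$History <- c(sidecar$History %||% list(), list(unclass(record)))
  sidecar
}

#' Trace a derived entry back to raw data
#'
#' Recursively walks the History of the entry's sidecar and of every input
#' file's sidecar until files with empty History (raw data) are reached.
#' Returns the provenance as a tree (fan-in modules have several parents)
#' plus a flat chain ordered raw-to-entry.
#'
#' @param project vox_project
#' @param entry one database row
#' @return list(tree, chain = list of records raw-first, truncated = paths
#'   whose sidecar was missing, leaves = raw filenames); for a raw entry
#'   the chain is empty
#' @export
trace_to_raw <- function(project, entry) {
  truncated <- character(0)
  leaves <- character(0)
  seen_stack <- character(0)
  walk <- function(rel_image) {
    if (rel_image %in% seen_stack)
      vox_stop("provenance cycle through ", rel_image)
    seen_stack <<- c(seen_stack, rel_image)
    on.exit(seen_stack <<- seen_stack[-length(seen_stack)])
    scp <- sidecar_path_for(file.path(project$root, rel_image))
    if (!file.exists(scp)) {
      truncated <<- c(truncated, rel_image)
      return(NULL)
    }
    hist <- read_sidecar(scp)$History
    rec <- NULL
    for (h in hist) {  # the record that produced this file (normally the last)
      if (rel_image %in% unlist(h$outputs)) rec <- h
    }
    if (is.null(rec) && length(hist)) rec <- hist[[length(hist)]]
    if (is.null(rec)) {
      leaves <<- c(leaves, rel_image)
      return(NULL)
    }
    parents <- lapply(unlist(rec$inputs), walk)
    list(record = rec, file = rel_image,
         parents = parents[!vapply(parents, is.null, logical(1))])
  }
  rel <- file.path(entry$path, entry$filename)
  tree <- walk(rel)
  chain <- list()
  flatten <- function(node) {
    if (is.null(node)) return(invisible())
    for (p in node$parents) flatten(p)
    chain[[length(chain) + 1L]] <<- node$record
  }
  flatten(tree)
  # deduplicate while keeping raw-first order
  ids <- vapply(chain, function(r) paste(r$module_id,
                                         paste(unlist(r$outputs), collapse = ","),
                                         sep = "|"), character(1))
  chain <- chain[!duplicated(ids)]
  list(tree = tree, chain = chain, truncated = unique(truncated),
       leaves = unique(leaves))
}

#' Human-readable processing history of an entry
#' @param project vox_project
#' @param entry one database row
#' @return character vector of report lines (also printed invisibly usable)
#' @export
file_history_report <- function(project, entry) {
  tr <- trace_to_raw(project, entry)
  if (!length(tr$chain))
    return(sprintf("%s: raw data, no history", entry$filename))
  lines <- sprintf("Provenance of %s (%d processing step%s):", entry$filename,
                   length(tr$chain), if (length(tr$chain) == 1) "" else "s")
  for (i in seq_along(tr$chain)) {
    r <- tr$chain[[i]]
    pars <- if (length(r$parameters))
      paste(sprintf("%s=%s", names(r$parameters),
                    vapply(r$parameters, function(p)
                      paste(format(unlist(p)), collapse = ","), character(1))),
            collapse = ", ")
    else "(no parameters)"
    lines <- c(lines,
               sprintf("  %d. %s [%s]", i, r$module_id, r$timestamp),
               sprintf("     parameters: %s", pars),
               sprintf("     inputs:  %s", paste(unlist(r$inputs), collapse = ", ")),
               sprintf("     outputs: %s", paste(unlist(r$outputs), collapse = ", ")))
  }
  if (length(tr$truncated))
    lines <- c(lines, sprintf("  [chain truncated: missing sidecar for %s]",
                              paste(tr$truncated, collapse = ", ")))
  lines
}
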