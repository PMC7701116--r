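PARAM_KINDS <- c("sequence_selector", "roi_selector", "number", "choice", "string")

#' Validate a module declaration
#'
#' A module is declared in an R file that assigns a list named `module`
#' with fields: `id` (starting with "Module_"), `category`, `description`,
#' `params` (named list of parameter specs, each `list(kind, default,
#' choices)` with kind in sequence_selector / roi_selector / number /
#' choice / string), `outputs` (list of `list(name, type = Scan|ROI|File,
#' extension | extension_param)`), `arity` ("per-session" or
#' "per-subject"), a `run` function `(inputs, params, ctx)`, and optional
#' `finalize` / `parent_action` hooks.
#'
#' @param spec the module list
#' @return the spec (classed `module_spec`); errors describe the defect
#' @export
validate_module_spec <- function(spec) {
  if (!is.list(spec)) vox_stop("module declaration is not a list")
  if (!is_scalar_character(spec$id) || !grepl("^Module_", spec$id))
    vox_stop("module id must be a string starting with 'Module_'")
  if (!is_scalar_character(spec$category)) vox_stop(spec$id, ": missing category")
  if (!is.list(spec$params)) vox_stop(spec$id, ": params must be a named list")
  for (pn in names(spec$params)) {
    p <- spec$params[[pn]]
    if (!is_scalar_character(p$kind) || !p$kind %in% PARAM_KINDS)
      vox_stop(spec$id, ": parameter '", pn, "' has unknown kind '",
               p$kind %||% "", "'")
    if (p$kind == "number" && !is.null(p$default) && !is.numeric(p$default))
      vox_stop(spec$id, ": default of number parameter '", pn, "' is not numeric")
    if (p$kind == "choice") {
      if (!is.character(p$choices) || length(p$choices) < 1L)
        vox_stop(spec$id, ": choice parameter '", pn, "' has no choices")
      if (!is.null(p$default) && !p$default %in% p$choices)
        vox_stop(spec$id, ": default of '", pn, "' not among its choices")
    }
  }
  selectors <- selector_params(spec)
  if (!is.list(spec$outputs)) vox_stop(spec$id, ": outputs must be a list")
  for (o in spec$outputs) {
    if (!is_scalar_character(o$name)) vox_stop(spec$id, ": output without a name")
    if (!is_scalar_character(o$type) || !o$type %in% c("Scan", "ROI", "File"))
      vox_stop(spec$id, ": output '", o$name, "' has invalid type")
    if (o$type != "File" && is.null(o[["extension"]]) && is.null(o[["extension_param"]]))
      vox_stop(spec$id, ": output '", o$name, "' needs extension or extension_param")
  }
  spec$arity <- spec$arity %||% "per-session"
  if (!spec$arity %in% c("per-session", "per-subject"))
    vox_stop(spec$id, ": invalid arity '", spec$arity, "'")
  if (!is.function(spec$run) && !is.function(spec$parent_action))
    vox_stop(spec$id, ": missing run function")
  if (length(selectors) < 1L)
    vox_stop(spec$id, ": needs at least one selector parameter")
  class(spec) <- "module_spec"
  spec
}

selector_params <- function(spec) {
  kinds <- vapply(spec$params, function(p) p$kind, character(1))
  names(kinds)[kinds %in% c("sequence_selector", "roi_selector")]
}

#' Directory of the module library shipped with the package
#' @export
builtin_modules_path <- function() {
  system.file("modules", package = "voxpipe", mustWork = TRUE)
}

#' Discover module declarations under one or more directories
#'
#' Reads every `Module_*.R` file below the search paths (sub-folders are
#' categories), sources each in an isolated environment and validates the
#' declared spec. Malformed files are reported as broken with the reason,
#' never fatal; adding or removing a file changes the next discovery.
#'
#' @param search_paths directories to scan; default: the builtin library
#' @return a `module_library`: list with `specs` (named list of
#'   module_spec, sorted by category then id) and `broken` (data.frame
#'   file/reason)
#' @export
discover_modules <- function(search_paths = builtin_modules_path()) {
  files <- unlist(lapply(search_paths, list.files, pattern = "^Module_.*\\.R$",
                         recursive = TRUE, full.names = TRUE))
  specs <- list()
  broken <- data.frame(file = character(0), reason = character(0))
  for (f in files) {
    env <- new.env(parent = asNamespace("voxpipe"))
    res <- tryCatch({
      sys.source(f, envir = env)
      if (!exists("module", envir = env, inherits = FALSE))
        vox_stop("file defines no 'module' object")
      validate_module_spec(get("module", envir = env))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      broken <- rbind(broken, data.frame(file = f, reason = conditionMessage(res)))
    } else {
      if (is.null(res$category)) res$category <- basename(dirname(f))
      specs[[res$id]] <- res
    }
  }
  ord <- order(vapply(specs, function(s) paste(s$category, s$id), character(1)))
  structure(list(specs = specs[ord], broken = broken), class = "module_library")
}

#' @export
print.module_library <- function(x, ...) {
  cat(sprintf("<module_library> %d modules, %d broken\n", length(x$specs),
              nrow(x$broken)))
  for (s in x$specs) cat(sprintf("  %-24s [%s]\n", s$id, s$category))
  invisible(x)
}

# merge user params with defaults and validate values against the schema
resolve_params <- function(spec, params) {
  unknown <- setdiff(names(params), names(spec$params))
  if (length(unknown))
    vox_stop(spec$id, ": unknown parameter(s) ", paste(unknown, collapse = ", "))
  out <- list()
  for (pn in names(spec$params)) {
    p <- spec$params[[pn]]
    v <- if (pn %in% names(params)) params[[pn]] else p$default
    if (is.null(v))
      vox_stop(spec$id, ": parameter '", pn, "' has no value and no default")
    if (p$kind == "number" && !is.numeric(v))
      vox_stop(spec$id, ": parameter '", pn, "' must be numeric")
    if (p$kind == "choice" && !v %in% p$choices)
      vox_stop(spec$id, ": '", v, "' is not a valid choice for '", pn, "'")
    if (p$kind %in% c("sequence_selector", "roi_selector", "string") &&
        !is_scalar_character(v))
      vox_stop(spec$id, ": parameter '", pn, "' must be a string")
    out[[pn]] <- v
  }
  out
}
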