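PIPELINE_FORMAT_VERSION <- 1L

#' Start a new pipeline over a project
#'
#' The pipeline carries its own working copy of the project database:
#' adding modules appends virtual entries to it, so later modules can
#' select the declared outputs of earlier ones before anything has been
#' executed.
#' @param project vox_project
#' @return a `vox_pipeline`
#' @export
new_pipeline <- function(project) {
  structure(list(project_root = project$root,
                 database = project$database,
                 modules = list(),
                 jobs = list()),
            class = "vox_pipeline")
}

#' @export
print.vox_pipeline <- function(x, ...) {
  cat(sprintf("<vox_pipeline> %d module(s), %d job(s)\n", length(x$modules),
              length(x$jobs)))
  for (m in x$modules)
    cat(sprintf("  %d. %-24s [%s] %d job(s)\n", m$index, m$spec$id,
                module_status_color(m), length(m$job_ids)))
  invisible(x)
}

#' Compliance/execution color of a pipeline module
#'
#' red: the module's selectors match nothing in the database (it cannot
#' generate jobs); orange: some of its jobs have already been executed;
#' green: compliant and not yet executed.
#' @param module a module instance from a pipeline
#' @return "green", "orange" or "red"
#' @export
module_status_color <- function(module) module$state

#' Add a module to a pipeline
#'
#' Generates one job per distinct (subject, timepoint) group of the
#' database rows matched by the module's selector parameters (or per
#' subject for per-subject modules), and declares one virtual database
#' entry per Scan/ROI output of each job, named after the primary input
#' sequence plus "_" plus the extension string. A module whose selectors
#' match nothing is added in red state with zero jobs. Outputs that
#' already exist in the database as derived entries (from a previous
#' execution) are reused and flag the job as already executed.
#'
#' @param pipeline vox_pipeline
#' @param spec module_spec (from [discover_modules()])
#' @param params named list of parameter values (defaults fill the rest)
#' @param filter optional [filter_criteria()] restricting the rows the
#'   module may consume
#' @return the updated pipeline
#' @export
add_module <- function(pipeline, spec, params = list(), filter = NULL) {
  stopifnot(inherits(spec, "module_spec"))
  params <- resolve_params(spec, params)
  idx <- length(pipeline$modules) + 1L
  db <- pipeline$database
  if (!is.null(filter)) db <- filter_database(db, filter)

  sel <- selector_params(spec)
  matches <- lapply(sel, function(pn) {
    want_type <- if (spec$params[[pn]]$kind == "roi_selector") "ROI" else "Scan"
    db[db$sequence == params[[pn]] & db$type == want_type, , drop = FALSE]
  })
  names(matches) <- sel

  group_of <- function(rows) {
    if (spec$arity == "per-subject") rows$subject
    else paste(rows$subject, rows$timepoint, sep = "\r")
  }
  groups <- Reduce(intersect, lapply(matches, group_of))
  groups <- groups[order(groups)]

  inst <- list(index = idx, spec = spec, params = params,
               state = if (length(groups)) "green" else "red",
               job_ids = character(0))
  new_jobs <- list()
  for (g in groups) {
    inputs <- lapply(matches, function(rows) rows[group_of(rows) == g, ][1, ])
    primary <- inputs[[1]]
    job_id <- sprintf("m%02d_%s_%s_%s", idx, spec$id, primary$subject,
                      primary$timepoint)
    out_rows <- list(); out_files <- list()
    for (o in spec$outputs) {
      if (o$type == "File") { out_files[[o$name]] <- o; next }
      ext <- o[["extension"]] %||% params[[o[["extension_param"]]]]
      new_seq <- paste0(primary$sequence, "_", ext)
      row <- data.frame(type = if (o$type == "ROI") "ROI" else "Scan",
                        subject = primary$subject, timepoint = primary$timepoint,
                        sequence = new_seq, group = primary$group,
                        path = if (o$type == "ROI") "ROI_data" else "Derived_data",
                        filename = default_filename(primary$subject,
                                                    primary$timepoint, new_seq),
                        status = "virtual", stringsAsFactors = FALSE)
      key <- entry_key(row)
      existing <- pipeline$database[entry_key(pipeline$database) == key, ]
      if (nrow(existing)) {
        if (existing$status[1] == "virtual")
          vox_stop(spec$id, ": output ", row$sequence, " for ", row$subject,
                   "/", row$timepoint, " is already declared by another module")
        row$status <- existing$status[1]   # derived/roi from a previous run
      } else {
        pipeline$database <- rbind(pipeline$database, row)
      }
      out_rows[[o$name]] <- row
    }
    new_jobs[[job_id]] <- list(id = job_id, module_index = idx,
                               module_id = spec$id, params = params,
                               inputs = inputs, outputs = out_rows,
                               file_outputs = out_files, state = "pending")
    inst$job_ids <- c(inst$job_ids, job_id)
  }
  pipeline$jobs <- c(pipeline$jobs, new_jobs)
  pipeline$modules[[idx]] <- inst
  pipeline
}

#' Dependency graph of the pipeline's jobs
#'
#' There is an edge from job A to job B iff an output entry of A is an
#' input entry of B. The graph is verified acyclic (guaranteed by
#' construction, since a module only consumes entries that existed at its
#' insertion point) and returned with a topological job order.
#' @param pipeline vox_pipeline
#' @return list(edges = data.frame(from, to), order = job ids in
#'   topological order, parents = named list of parent job ids)
#' @export
build_dependency_graph <- function(pipeline) {
  jobs <- pipeline$jobs
  producer <- list()
  for (j in jobs) for (o in j$outputs) producer[[entry_key(o)]] <- j$id
  edges_from <- character(0); edges_to <- character(0)
  for (j in jobs) {
    for (inp in j$inputs) {
      p <- producer[[entry_key(inp)]]
      if (!is.null(p) && p != j$id) {
        edges_from <- c(edges_from, p); edges_to <- c(edges_to, j$id)
      }
    }
  }
  edges <- unique(data.frame(from = edges_from, to = edges_to,
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = names(jobs)))
  if (!igraph::is_dag(g)) {
    fb <- tryCatch(names(jobs)[as.integer(igraph::feedback_arc_set(g))],
                   error = function(e) character(0))
    vox_stop("dependency cycle between jobs",
             if (length(fb)) paste0(" involving ", paste(fb, collapse = ", ")))
  }
  ord <- names(igraph::topo_sort(g, mode = "out"))
  parents <- lapply(names(jobs), function(id) edges$from[edges$to == id])
  names(parents) <- names(jobs)
  list(edges = edges, order = ord, parents = parents)
}

#' Save a pipeline definition
#'
#' Only the module sequence and parameters are serialized (a portable,
#' versioned JSON text format) - not the jobs, which are specific to a
#' database and are regenerated on load.
#' @param pipeline vox_pipeline
#' @param path output file (conventionally under Saved_Pipelines/)
#' @return path, invisibly
#' @export
save_pipeline <- function(pipeline, path) {
  doc <- list(format_version = PIPELINE_FORMAT_VERSION,
              modules = lapply(pipeline$modules, function(m)
                list(spec_id = m$spec$id, params = m$params)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a pipeline definition onto a project
#'
#' Re-runs module binding against the given project's database: modules
#' whose selector tag values are absent become red (and modules consuming
#' their declared outputs follow, by propagation); modules whose outputs
#' were produced by a previous execution are marked orange; the rest are
#' green.
#' @param path pipeline JSON file
#' @param project vox_project
#' @param library [discover_modules()] result to resolve module ids
#' @return vox_pipeline with compliance states set
#' @export
load_pipeline <- function(path, project, library = discover_modules()) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.integer(doc$format_version %||% -1L), PIPELINE_FORMAT_VERSION))
    vox_stop("incompatible pipeline file version: ",
             doc$format_version %||% "missing", " (expected ",
             PIPELINE_FORMAT_VERSION, ")")
  pipeline <- new_pipeline(project)
  for (m in doc$modules) {
    spec <- library$specs[[m$spec_id]]
    if (is.null(spec)) vox_stop("unknown module '", m$spec_id,
                                "' in pipeline file")
    pipeline <- add_module(pipeline, spec, lapply(m$params, identity))
  }
  mark_already_executed(pipeline, project)
}

# orange detection: a job counts as already executed iff every Scan/ROI
# output file exists on disk AND its sidecar History references the module
mark_already_executed <- function(pipeline, project) {
  for (jid in names(pipeline$jobs)) {
    j <- pipeline$jobs[[jid]]
    if (!length(j$outputs)) next
    done <- all(vapply(j$outputs, function(o) {
      img <- entry_image_path(project, o)
      if (!file.exists(img)) return(FALSE)
      scp <- sidecar_path_for(img)
      if (!file.exists(scp)) return(FALSE)
      any(vapply(read_sidecar(scp)$History, function(h)
        identical(h$module_id, j$module_id), logical(1)))
    }, logical(1)))
    if (done) pipeline$jobs[[jid]]$already_done <- TRUE
  }
  for (i in seq_along(pipeline$modules)) {
    m <- pipeline$modules[[i]]
    if (m$state == "red") next
    if (any(vapply(m$job_ids, function(id)
      isTRUE(pipeline$jobs[[id]]$already_done), logical(1))))
      pipeline$modules[[i]]$state <- "orange"
  }
  pipeline
}
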