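# Pipeline execution: jobs compute into Tmp/jobs/<id>/ and only on success
# are their files promoted into Derived_data / ROI_data and the database
# rows flipped from virtual to derived/roi. Failed jobs leave nothing in
# the final folders; their transitive descendants are skipped.

#' Execute a pipeline
#'
#' `mode = "single"` runs all jobs of the first module, then all jobs of
#' the second, and so on. `mode = "multi"` runs jobs as soon as their
#' parents in the dependency graph are satisfied, with at most `workers`
#' concurrent worker processes; outputs are identical between the two
#' modes (only the scheduling order differs). Jobs whose outputs already
#' exist from a previous execution are re-run only with `overwrite =
#' TRUE`, otherwise skipped with their files kept.
#'
#' @param pipeline vox_pipeline (at least one non-red module)
#' @param mode "single" or "multi"
#' @param workers maximum concurrent jobs in multi mode
#' @param overwrite re-run already-executed (orange) jobs
#' @return list(report = vox_execution_report, project = updated
#'   vox_project, pipeline = pipeline with job states)
#' @export
execute <- function(pipeline, mode = c("single", "multi"), workers = 2L,
                    overwrite = FALSE) {
  mode <- match.arg(mode)
  if (workers < 1L) vox_stop("workers must be >= 1")
  if (!length(pipeline$modules) ||
      all(vapply(pipeline$modules, function(m) m$state == "red", logical(1))))
    vox_stop("pipeline has no executable (non-red) module")
  project <- load_project(pipeline$project_root)
  dag <- build_dependency_graph(pipeline)
  jobs <- pipeline$jobs
  job_dir <- file.path(project$root, "Tmp", "jobs")
  dir.create(job_dir, recursive = TRUE, showWarnings = FALSE)
  log_dir <- file.path(project$root, "Tmp", "logs")
  dir.create(log_dir, showWarnings = FALSE)

  states <- stats::setNames(rep("pending", length(jobs)), names(jobs))
  logs <- stats::setNames(rep("", length(jobs)), names(jobs))
  t_start <- t_stop <- stats::setNames(rep(NA_real_, length(jobs)), names(jobs))
  fragments <- list()   # module_index -> list(job_id -> file paths)

  # a parent satisfies its children when done, or when skipped because its
  # outputs already exist (orange skip); failure/ancestor-skip poisons them
  satisfied <- function(id) states[[id]] == "done" || states[[id]] == "skipped_done"
  terminal <- function(id) states[[id]] %in%
    c("done", "failed", "skipped_done", "skipped")

  frag_dir <- file.path(project$root, "Tmp", "fragments")

  existing_fragments <- function(id) {
    list.files(frag_dir, pattern = paste0("^", id, "_"), full.names = TRUE)
  }

  job_outputs_done <- function(j) {
    if (!length(j$outputs))
      return(length(j$file_outputs) > 0L && length(existing_fragments(j$id)) > 0L)
    all(vapply(j$outputs, function(o) {
      img <- entry_image_path(project, o)
      scp <- sidecar_path_for(img)
      file.exists(img) && file.exists(scp) &&
        any(vapply(read_sidecar(scp)$History, function(h)
          identical(h$module_id, j$module_id), logical(1)))
    }, logical(1)))
  }

  set_state <- function(id, s) {
    states[[id]] <<- s
    if (s == "skipped_done") {
      j <- jobs[[id]]
      if (length(j$file_outputs)) {
        ef <- existing_fragments(id)
        if (length(ef)) fragments[[as.character(j$module_index)]][[id]] <<- ef
      }
    }
  }

  prepare <- function(id) {
    # returns "run", "skip_done" or "skip_ancestor"
    j <- jobs[[id]]
    parents <- dag$parents[[id]]
    if (length(parents) && !all(vapply(parents, satisfied, logical(1))))
      return("skip_ancestor")
    if (!overwrite && (isTRUE(j$already_done) || job_outputs_done(j)))
      return("skip_done")
    "run"
  }

  promote <- function(id, res) {
    j <- jobs[[id]]
    for (o in j$outputs) {
      tmp_img <- file.path(job_dir, id, o$filename)
      dst_img <- entry_image_path(project, o)
      if (!file.exists(tmp_img)) vox_stop("job ", id, " produced no ", o$filename)
      file.copy(tmp_img, dst_img, overwrite = TRUE)
      tmp_sc <- sidecar_path_for(tmp_img)
      if (file.exists(tmp_sc))
        file.copy(tmp_sc, sidecar_path_for(dst_img), overwrite = TRUE)
      final_status <- if (o$type == "ROI") "roi" else "derived"
      keys <- entry_key(project$database)
      hit <- which(keys == entry_key(o))
      if (length(hit)) {
        project$database$status[hit] <- final_status
      } else {
        row <- o; row$status <- final_status
        project$database <- rbind(project$database, row[, DB_COLUMNS])
      }
      project <<- project
    }
    if (length(res$files)) {
      dir.create(frag_dir, showWarnings = FALSE)
      kept <- vapply(res$files, function(f) {
        dst <- file.path(frag_dir, paste0(id, "_", basename(f)))
        file.copy(f, dst, overwrite = TRUE)
        dst
      }, character(1))
      fragments[[as.character(j$module_index)]][[id]] <<- unname(kept)
    }
    unlink(file.path(job_dir, id), recursive = TRUE)
    save_project(project)
  }

  finish <- function(id, res) {
    t_stop[[id]] <<- as.numeric(Sys.time())
    if (isTRUE(res$ok)) {
      ok <- tryCatch({ promote(id, res); TRUE },
                     error = function(e) { logs[[id]] <<- conditionMessage(e); FALSE })
      states[[id]] <<- if (ok) "done" else "failed"
    } else {
      states[[id]] <<- "failed"
      logs[[id]] <<- res$error %||% "unknown failure"
      writeLines(logs[[id]], file.path(log_dir, paste0(id, ".log")))
      unlink(file.path(job_dir, id), recursive = TRUE)
    }
  }

  launch_ctx <- function(id) {
    d <- file.path(job_dir, id)
    unlink(d, recursive = TRUE)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    list(project_root = project$root, tmp_dir = d, job_id = id)
  }

  run_parent_action <- function(id) {
    j <- jobs[[id]]
    spec <- pipeline$modules[[j$module_index]]$spec
    res <- tryCatch({
      project <<- spec$parent_action(project, j$inputs, j$params)
      save_project(project)
      list(ok = TRUE, files = NULL)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    res
  }

  process_job <- function(id) {
    action <- prepare(id)
    if (action != "run") {
      set_state(id, if (action == "skip_done") "skipped_done" else "skipped")
      return(invisible())
    }
    t_start[[id]] <<- as.numeric(Sys.time())
    j <- jobs[[id]]
    spec <- pipeline$modules[[j$module_index]]$spec
    res <- if (is.function(spec$parent_action)) run_parent_action(id)
           else run_job_payload(spec, j, launch_ctx(id))
    finish(id, res)
  }

  if (mode == "single") {
    for (m in pipeline$modules) for (id in m$job_ids) process_job(id)
  } else {
    execute_multi(pipeline, dag, jobs, workers, prepare, launch_ctx,
                  run_parent_action, finish, set_state = set_state,
                  get_states = function() states, terminal = terminal)
  }

  # assemble File outputs (e.g. cohort CSV) in the parent, module order
  for (m in pipeline$modules) {
    if (!is.function(m$spec$finalize)) next
    frag <- fragments[[as.character(m$index)]] %||% list()
    if (!length(frag)) next
    frag <- frag[order(names(frag))]
    done_ids <- m$job_ids[states[m$job_ids] %in% c("done", "skipped_done")]
    frag <- frag[names(frag) %in% done_ids]
    if (length(frag))
      m$spec$finalize(frag, m$params,
                      list(project_root = project$root,
                           out_dir = file.path(project$root, "Derived_data")))
  }

  report_states <- ifelse(states == "skipped_done", "skipped", states)
  report <- data.frame(job_id = names(jobs),
                       module = vapply(jobs, `[[`, character(1), "module_id"),
                       state = unname(report_states),
                       start = unname(t_start[names(jobs)]),
                       stop = unname(t_stop[names(jobs)]),
                       log = unname(logs[names(jobs)]),
                       stringsAsFactors = FALSE)
  counts <- list(done = sum(report$state == "done"),
                 failed = sum(report$state == "failed"),
                 skipped = sum(report$state == "skipped"))
  rep <- structure(list(jobs = report, counts = counts, mode = mode,
                        workers = workers), class = "vox_execution_report")
  for (id in names(jobs)) pipeline$jobs[[id]]$state <- report_states[[id]]
  list(report = rep, project = project, pipeline = pipeline)
}

#' @export
print.vox_execution_report <- function(x, ...) {
  cat(sprintf("<vox_execution_report> mode=%s workers=%d: %d done, %d failed, %d skipped\n",
              x$mode, x$workers, x$counts$done, x$counts$failed, x$counts$skipped))
  bad <- x$jobs[x$jobs$state == "failed", ]
  for (i in seq_len(nrow(bad)))
    cat(sprintf("  FAILED %s: %s\n", bad$job_id[i], bad$log[i]))
  invisible(x)
}

# the computational payload of one job; safe to run in a forked worker.
# Reads inputs from the project folders, runs the module, writes every
# declared output (image + sidecar with the new history record) into the
# job's Tmp directory, and returns file-output fragment paths.
run_job_payload <- function(spec, j, ctx) {
  tryCatch({
    inputs <- lapply(j$inputs, function(row) {
      img <- file.path(ctx$project_root, row$path, row$filename)
      read_scan(img, as_roi = identical(row$type, "ROI"))
    })
    out <- spec$run(inputs, j$params, ctx)
    rel_in <- vapply(j$inputs, function(r) file.path(r$path, r$filename),
                     character(1))
    rel_out <- c(vapply(j$outputs, function(o) file.path(o$path, o$filename),
                        character(1)),
                 vapply(names(j$file_outputs), function(n)
                   paste0("Derived_data/", n), character(1)))
    rec <- history_record(spec$id, j$params, rel_in, rel_out)
    files <- character(0)
    for (oname in names(j$outputs)) {
      o <- j$outputs[[oname]]
      vol <- out[[oname]]
      if (is.null(vol)) vox_stop("module returned no output '", oname, "'")
      primary <- inputs[[1]]
      sc <- if (inherits(vol, "roi_mask")) empty_sidecar() else primary$sidecar
      vol$sidecar <- append_history(sc, rec)
      write_scan(vol, file.path(ctx$tmp_dir, o$filename))
    }
    for (fname in names(j$file_outputs)) {
      fp <- out[[fname]]
      if (!is.character(fp) || !all(file.exists(fp)))
        vox_stop("module returned no file output '", fname, "'")
      files <- c(files, fp)
    }
    list(ok = TRUE, files = files)
  }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
}

# dependency-aware worker pool on top of parallel::mcparallel: at most
# `workers` jobs run concurrently; a job becomes eligible when all its
# parents are terminal. Promotion always happens in the parent process.
execute_multi <- function(pipeline, dag, jobs, workers, prepare, launch_ctx,
                          run_parent_action, finish, set_state, get_states,
                          terminal) {
  remaining <- dag$order
  running <- list()   # job_id -> mcparallel handle
  repeat {
    progressed <- FALSE
    # launch eligible jobs up to the worker limit
    for (id in remaining) {
      if (length(running) >= workers) break
      parents <- dag$parents[[id]]
      if (length(parents) && !all(vapply(parents, terminal, logical(1)))) next
      action <- prepare(id)
      if (action != "run") {
        set_state(id, if (action == "skip_done") "skipped_done" else "skipped")
        remaining <- setdiff(remaining, id)
        progressed <- TRUE
        next
      }
      j <- jobs[[id]]
      spec <- pipeline$modules[[j$module_index]]$spec
      if (is.function(spec$parent_action)) {
        finish(id, run_parent_action(id))
        remaining <- setdiff(remaining, id)
        progressed <- TRUE
        next
      }
      ctx <- launch_ctx(id)
      running[[id]] <- parallel::mcparallel(run_job_payload(spec, j, ctx))
      remaining <- setdiff(remaining, id)
      progressed <- TRUE
    }
    if (!length(running) && !length(remaining)) break
    if (length(running)) {
      got <- parallel::mccollect(running, wait = FALSE, timeout = 0.02)
      got <- got[!vapply(got, is.null, logical(1))]
      for (pid in names(got)) {
        id <- names(running)[vapply(running, function(h)
          as.character(h$pid) == pid, logical(1))]
        res <- got[[pid]]
        if (!is.list(res) || is.null(res$ok))
          res <- list(ok = FALSE,
                      error = paste("worker crashed:",
                                    paste(utils::capture.output(res), collapse = " ")))
        running[[id]] <- NULL
        finish(id, res)
        progressed <- TRUE
      }
    }
    if (!progressed && !length(running) && length(remaining)) {
      # every remaining job has an unsatisfiable parent; drain as skipped
      for (id in remaining) set_state(id, "skipped")
      break
    }
  }
  invisible()
}
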