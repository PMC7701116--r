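PROJECT_SUBDIRS <- c("Raw_data", "Derived_data", "ROI_data", "Tmp", "Saved_Pipelines")
DATABASE_FILE <- "project_database.tsv"
DB_COLUMNS <- c("type", "subject", "timepoint", "sequence", "group",
                "path", "filename", "status")

empty_database <- function() {
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(DB_COLUMNS)),
                                      DB_COLUMNS))
  df
}

#' Create a new image project
#'
#' A project is a directory containing five fixed sub-folders (`Raw_data`,
#' `Derived_data`, `ROI_data`, `Tmp`, `Saved_Pipelines`) and a flat TSV
#' database (`project_database.tsv`) that entirely describes the cohort:
#' one row per scan or ROI with its subject, timepoint, sequence-name and
#' group tags, its relative path and filename, and its status (raw,
#' derived, roi or virtual). All paths are stored relative to the project
#' root so a project directory can be moved between machines as a whole.
#'
#' @param root directory to create the project in (created if absent)
#' @return a `vox_project` object
#' @export
create_project <- function(root) {
  if (file.exists(file.path(root, DATABASE_FILE)))
    vox_stop("project exists: ", root, " already contains a project database")
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) vox_stop("cannot create project root ", root)
  for (d in PROJECT_SUBDIRS) dir.create(file.path(root, d), showWarnings = FALSE)
  project <- structure(list(root = normalizePath(root), database = empty_database()),
                       class = "vox_project")
  save_project(project)
  project
}

#' @export
print.vox_project <- function(x, ...) {
  cat(sprintf("<vox_project> %s\n  %d entries (%s)\n", x$root, nrow(x$database),
              paste(sprintf("%s: %d", names(table(x$database$status)),
                            as.integer(table(x$database$status))), collapse = ", ")))
  invisible(x)
}

#' Persist the project database
#'
#' Serializes the database as a tab-separated table at the project root.
#' The table alone is sufficient to reopen the project.
#' @param project vox_project
#' @return the database file path, invisibly
#' @export
save_project <- function(project) {
  path <- file.path(project$root, DATABASE_FILE)
  utils::write.table(project$database[, DB_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reopen a project from its root directory
#'
#' Validates that every non-virtual entry's image file exists on disk;
#' missing files are flagged (attribute `missing` on the database, and a
#' warning) without failing the load.
#' @param root project root directory
#' @return vox_project
#' @export
load_project <- function(root) {
  path <- file.path(root, DATABASE_FILE)
  if (!file.exists(path)) vox_stop("no project database found under ", root)
  db <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                      na.strings = NULL, quote = "", comment.char = ""),
    error = function(e) vox_stop("corrupt project database ", path, ": ",
                                 conditionMessage(e)))
  if (!identical(names(db), DB_COLUMNS))
    vox_stop("corrupt project database ", path, ": expected columns ",
             paste(DB_COLUMNS, collapse = ", "), " but found ",
             paste(names(db), collapse = ", "))
  project <- structure(list(root = normalizePath(root), database = db),
                       class = "vox_project")
  missing <- vapply(seq_len(nrow(db)), function(i) {
    db$status[i] != "virtual" && !file.exists(entry_image_path(project, db[i, ]))
  }, logical(1))
  if (any(missing))
    warning(sum(missing), " database entr", if (sum(missing) == 1) "y" else "ies",
            " with missing files", call. = FALSE)
  attr(project$database, "missing") <- missing
  project
}

entry_image_path <- function(project, entry) {
  file.path(project$root, entry$path, entry$filename)
}

entry_sidecar_path <- function(project, entry) {
  sidecar_path_for(entry_image_path(project, entry))
}

entry_key <- function(entry) {
  paste(entry$subject, entry$timepoint, entry$sequence, entry$type, sep = "\r")
}

status_dir <- function(status) {
  switch(status, raw = "Raw_data", derived = "Derived_data", roi = "ROI_data",
         virtual = vox_stop("virtual entries have no directory"),
         vox_stop("unknown status ", status))
}

default_filename <- function(subject, timepoint, sequence) {
  sprintf("%s_%s_%s.nii.gz", subject, timepoint, sequence)
}

#' Register an image into the project
#'
#' Copies (or moves) the image into the sub-folder matching its status,
#' writes the JSON sidecar next to it, and appends a row to the database.
#' The tag combination (subject, timepoint, sequence, type) must be unique
#' within the project; collisions are refused rather than auto-renamed so
#' that pipelines stay deterministic.
#'
#' @param project vox_project
#' @param image_file readable NIfTI file (.nii or .nii.gz)
#' @param subject,timepoint,sequence required tag values (non-empty)
#' @param type "Scan" or "ROI"
#' @param group optional group tag (stored verbatim)
#' @param sidecar metadata list written as the sidecar (Scan entries); if
#'   NULL an existing sidecar next to `image_file` is carried over
#' @param status "raw", "derived" or "roi"; defaults to "raw" for scans and
#'   "roi" for ROIs
#' @param move move instead of copy
#' @return the updated vox_project (database persisted)
#' @export
register_entry <- function(project, image_file, subject, timepoint, sequence,
                           type = c("Scan", "ROI"), group = "", sidecar = NULL,
                           status = NULL, move = FALSE) {
  type <- match.arg(type)
  for (v in c(subject = subject, timepoint = timepoint, sequence = sequence)) {
    if (!is_scalar_character(v) || !nzchar(v))
      vox_stop("subject, timepoint and sequence tags must be non-empty strings")
  }
  if (!grepl("\\.nii(\\.gz)?$", image_file) || !file.exists(image_file))
    vox_stop("not a readable NIfTI file: ", image_file)
  # validate payload early so a bad file never enters the database
  vol <- read_scan(image_file, sidecar_path = NA)
  status <- status %||% if (type == "ROI") "roi" else "raw"
  status <- match.arg(status, c("raw", "derived", "roi"))
  if (type == "ROI" && status != "roi") vox_stop("ROI entries must have status 'roi'")
  if (type == "ROI" && !is_binary_array(vol$array))
    vox_stop("ROI image must contain a binary mask")

  key <- format_key(subject, timepoint, sequence, type)
  new_row <- data.frame(type = type, subject = subject, timepoint = timepoint,
                        sequence = sequence, group = group,
                        path = status_dir(status),
                        filename = default_filename(subject, timepoint, sequence),
                        status = status, stringsAsFactors = FALSE)
  if (entry_key(new_row) %in% entry_key(project$database))
    vox_stop("duplicate database key ", key)

  dest <- entry_image_path(project, new_row)
  src_sidecar <- sidecar_path_for(image_file)
  if (grepl("\\.nii$", image_file)) {
    # normalize to compressed storage; payload identical voxelwise
    write_scan(scan_volume(vol$array, vol$affine, empty_sidecar(),
                           datatype = vol$datatype),
               dest, write_sidecar_file = FALSE)
    if (move) unlink(image_file)
  } else {
    file.copy(image_file, dest, overwrite = FALSE)
    if (move) unlink(image_file)
  }
  if (type == "Scan") {
    sc <- sidecar %||% (if (file.exists(src_sidecar)) read_sidecar(src_sidecar)
                        else empty_sidecar(Modality = "unknown"))
    if (is.null(sc$History)) sc$History <- list()
    write_sidecar(sc, sidecar_path_for(dest))
  } else if (!is.null(sidecar)) {
    write_sidecar(sidecar, sidecar_path_for(dest))
  }
  project$database <- rbind(project$database, new_row)
  save_project(project)
  project
}

# append a database row for a file already in place (pipeline promotion)
register_existing_file <- function(project, row) {
  if (entry_key(row) %in% entry_key(project$database))
    vox_stop("duplicate database key ",
             format_key(row$subject, row$timepoint, row$sequence, row$type))
  project$database <- rbind(project$database, row[, DB_COLUMNS])
  save_project(project)
  project
}

#' Filter criteria for the tag database
#'
#' Each argument is a character vector of admissible values for that tag
#' (membership test); NULL means "no constraint". Criteria combine by
#' conjunction. An empty criteria set selects the whole database.
#' @param subject,timepoint,sequence,type,status,group value sets
#' @return a `filter_criteria` object
#' @export
filter_criteria <- function(subject = NULL, timepoint = NULL, sequence = NULL,
                            type = NULL, status = NULL, group = NULL) {
  structure(list(subject = subject, timepoint = timepoint, sequence = sequence,
                 type = type, status = status, group = group),
            class = "filter_criteria")
}

#' Filter the database by tag values
#'
#' Returns exactly the rows matching the conjunction of per-tag membership
#' tests; the input is never modified and filtering is idempotent.
#' @param db a project database (data.frame) or vox_project
#' @param criteria [filter_criteria()]; alternatively pass tag vectors via `...`
#' @param ... shortcut tag arguments forwarded to [filter_criteria()]
#' @return data.frame subset
#' @export
filter_database <- function(db, criteria = NULL, ...) {
  if (inherits(db, "vox_project")) db <- db$database
  extra <- list(...)
  if (is.null(criteria)) {
    bad <- setdiff(names(extra), names(formals(filter_criteria)))
    if (length(bad)) vox_stop("unknown tag name(s): ", paste(bad, collapse = ", "))
    criteria <- do.call(filter_criteria, extra)
  } else if (!inherits(criteria, "filter_criteria")) {
    bad <- setdiff(names(criteria), names(formals(filter_criteria)))
    if (length(bad)) vox_stop("unknown tag name(s): ", paste(bad, collapse = ", "))
    criteria <- do.call(filter_criteria, criteria)
  }
  keep <- rep(TRUE, nrow(db))
  for (tag in names(criteria)) {
    vals <- criteria[[tag]]
    if (!is.null(vals)) keep <- keep & db[[tag]] %in% vals
  }
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rename a tag value across the database
#'
#' Updates every row whose `tag` equals `old` and regenerates the on-disk
#' filenames so they stay consistent with the tags. The rename is atomic:
#' if it would make two rows collide on the uniqueness key, nothing is
#' changed.
#' @param project vox_project
#' @param tag one of "subject", "timepoint", "sequence", "group"
#' @param old,new tag values
#' @return list with `project` (updated) and `count` of rows changed
#' @export
rename_tag_value <- function(project, tag, old, new) {
  tag <- match.arg(tag, c("subject", "timepoint", "sequence", "group"))
  db <- project$database
  hit <- which(db[[tag]] == old)
  if (!length(hit)) return(list(project = project, count = 0L))
  new_db <- db
  new_db[[tag]][hit] <- new
  if (tag != "group") {
    keys <- entry_key(new_db)
    if (anyDuplicated(keys)) {
      dup <- new_db[duplicated(keys) | duplicated(keys, fromLast = TRUE), ]
      vox_stop("rename would collide rows on key ",
               format_key(dup$subject[1], dup$timepoint[1], dup$sequence[1],
                          dup$type[1]), "; nothing renamed")
    }
  }
  for (i in hit) {
    if (new_db$status[i] == "virtual" || tag == "group") {
      if (tag != "group")
        new_db$filename[i] <- default_filename(new_db$subject[i],
                                               new_db$timepoint[i],
                                               new_db$sequence[i])
      next
    }
    old_img <- entry_image_path(project, db[i, ])
    new_name <- default_filename(new_db$subject[i], new_db$timepoint[i],
                                 new_db$sequence[i])
    new_img <- file.path(project$root, new_db$path[i], new_name)
    if (old_img != new_img) {
      if (!file.rename(old_img, new_img))
        vox_stop("failed to rename ", old_img)
      old_sc <- sidecar_path_for(old_img)
      if (file.exists(old_sc)) file.rename(old_sc, sidecar_path_for(new_img))
    }
    new_db$filename[i] <- new_name
  }
  project$database <- new_db
  save_project(project)
  list(project = project, count = length(hit))
}

#' Delete entries from the database
#'
#' @param project vox_project
#' @param selection data.frame of rows to delete (subset of the database,
#'   e.g. from [filter_database()])
#' @param remove_files also delete the image/sidecar files from disk
#' @return list with `project`, `count` of rows removed, and `failed_files`
#'   (paths whose deletion failed; their rows are kept)
#' @export
delete_entries <- function(project, selection, remove_files = FALSE) {
  if (nrow(selection) == 0L)
    return(list(project = project, count = 0L, failed_files = character(0)))
  db <- project$database
  sel_keys <- entry_key(selection)
  if (!all(sel_keys %in% entry_key(db)))
    vox_stop("selection contains rows not present in the database")
  drop <- logical(nrow(db))
  failed <- character(0)
  for (i in which(entry_key(db) %in% sel_keys)) {
    row <- db[i, ]
    if (row$status == "virtual") { drop[i] <- TRUE; next }
    if (remove_files) {
      img <- entry_image_path(project, row)
      sc <- sidecar_path_for(img)
      ok <- !file.exists(img) || unlink(img) == 0L
      if (file.exists(sc)) unlink(sc)
      if (!ok) { failed <- c(failed, img); next }
    }
    drop[i] <- TRUE
  }
  project$database <- db[!drop, , drop = FALSE]
  rownames(project$database) <- NULL
  save_project(project)
  list(project = project, count = sum(drop), failed_files = failed)
}

#' Audit referential integrity of a project
#'
#' Checks that every non-virtual row's image file exists and that every
#' image file under the data folders has exactly one database row.
#' @param project vox_project
#' @return list with `missing_rows` (data.frame) and `orphan_files`
#'   (character paths relative to root); both empty when consistent
#' @export
audit_project <- function(project) {
  db <- project$database
  nonvirtual <- db[db$status != "virtual", , drop = FALSE]
  missing <- vapply(seq_len(nrow(nonvirtual)), function(i)
    !file.exists(entry_image_path(project, nonvirtual[i, ])), logical(1))
  expected <- file.path(nonvirtual$path, nonvirtual$filename)
  on_disk <- unlist(lapply(c("Raw_data", "Derived_data", "ROI_data"), function(d) {
    f <- list.files(file.path(project$root, d), pattern = "\\.nii(\\.gz)?$",
                    recursive = TRUE)
    file.path(d, f)
  }))
  list(missing_rows = nonvirtual[missing, , drop = FALSE],
       orphan_files = setdiff(on_disk, expected))
}

#' Status color of a database entry
#'
#' The database color code: blue for raw data, green for derived data,
#' pink for ROI data and yellow for virtual files (declared outputs of a
#' pipeline that has not been executed yet).
#' @param status entry status string(s) or a database data.frame
#' @return character vector of colors
#' @export
entry_status_color <- function(status) {
  if (is.data.frame(status)) status <- status$status
  vapply(status, function(s)
    switch(s, raw = "blue", derived = "green", roi = "pink", virtual = "yellow",
           vox_stop("unknown status ", s)), character(1), USE.NAMES = FALSE)
}
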