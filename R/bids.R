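#' Import a BIDS-organized directory tree into a project
#'
#' Walks `sub-*/[ses-*/]<datatype>/*.nii[.gz]`. The `sub-` label becomes the
#' subject tag and the `ses-` label the timepoint tag (datasets without a
#' session level get a single default timepoint "ses-01"). The sequence
#' name is the filename suffix, prefixed by the `acq-` label when present.
#' Existing BIDS JSON sidecars are carried over verbatim.
#'
#' @param project vox_project
#' @param bids_root root of the BIDS dataset
#' @return list with `project` (updated) and `entries` (data.frame of the
#'   rows added)
#' @export
import_bids <- function(project, bids_root) {
  subs <- list.dirs(bids_root, recursive = FALSE, full.names = TRUE)
  subs <- subs[grepl("^sub-", basename(subs))]
  if (!length(subs)) vox_stop("not a BIDS tree: no sub-* directories under ", bids_root)
  added <- empty_database()
  for (sd in subs) {
    subject <- sub("^sub-", "", basename(sd))
    sess <- list.dirs(sd, recursive = FALSE, full.names = TRUE)
    sess <- sess[grepl("^ses-", basename(sess))]
    layers <- if (length(sess)) sess else sd
    for (ld in layers) {
      timepoint <- if (grepl("^ses-", basename(ld))) sub("^ses-", "", basename(ld))
                   else "ses-01"
      imgs <- list.files(ld, pattern = "\\.nii(\\.gz)?$", recursive = TRUE,
                         full.names = TRUE)
      for (img in imgs) {
        sequence <- bids_sequence_name(basename(img))
        project <- register_entry(project, img, subject = subject,
                                  timepoint = timepoint, sequence = sequence,
                                  type = "Scan")
        added <- rbind(added, project$database[nrow(project$database), ])
      }
    }
  }
  rownames(added) <- NULL
  list(project = project, entries = added)
}

# sub-01_ses-02_acq-highres_T1w.nii.gz -> "highres_T1w"; without acq -> "T1w"
bids_sequence_name <- function(fname) {
  stem <- sub("\\.nii(\\.gz)?$", "", fname)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  suffix <- parts[length(parts)]
  acq <- grep("^acq-", parts, value = TRUE)
  if (length(acq)) paste(sub("^acq-", "", acq[1]), suffix, sep = "_") else suffix
}
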