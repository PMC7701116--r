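# Deterministic synthetic fixtures: phantoms, cohorts and DICOM series with
# known ground truth, so every other component is testable without any
# download. Generation is a pure function of the spec (RNG state is saved
# and restored around each generator).

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

ellipsoid_mask <- function(shape, center, semiaxes) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  d <- ((g$i - center[1]) / semiaxes[1])^2 + ((g$j - center[2]) / semiaxes[2])^2 +
    ((g$k - center[3]) / semiaxes[3])^2
  array(d <= 1, dim = shape)
}

#' Generate a synthetic phantom volume with known ground truth
#'
#' Kinds:
#' \describe{
#'   \item{ramp}{values 0 .. prod(shape)-1 in array order}
#'   \item{checkerboard}{two values alternating with (x+y) parity,
#'     constant along z}
#'   \item{ellipsoid_brain}{bright ellipsoid "brain" and a thin bright
#'     shell "skull" separated by a dark gap, plus Gaussian noise; truth =
#'     the ellipsoid mask}
#'   \item{ct_head}{Hounsfield-valued head: air -1000, skull shell about
#'     +1000, brain about +40 with noise, and a sub-zero gap between brain
#'     and skull; truth = the brain mask}
#'   \item{perfusion4d}{4D gamma-variate bolus time-courses on a spatial
#'     envelope; truth = the noiseless 4D array and the bolus parameters}
#' }
#'
#' @param kind phantom kind
#' @param shape length-3 integer grid size
#' @param voxel_mm voxel sizes in mm (diagonal affine)
#' @param params kind-specific parameter overrides
#' @param seed RNG seed (local to this call)
#' @return list(volume = scan_volume, truth = kind-specific ground truth)
#' @export
make_volume <- function(kind = c("ellipsoid_brain", "ct_head", "ramp",
                                 "checkerboard", "perfusion4d"),
                        shape = c(32L, 32L, 16L), voxel_mm = c(1, 1, 1),
                        params = list(), seed = 1L) {
  kind <- match.arg(kind)
  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * shape / 2
  with_local_seed(seed, {
    if (kind == "ramp") {
      arr <- array(seq_len(prod(shape)) - 1, dim = shape)
      return(list(volume = scan_volume(arr, affine, empty_sidecar("MR"),
                                       datatype = "float"),
                  truth = list(min = 0, max = prod(shape) - 1)))
    }
    if (kind == "checkerboard") {
      vals <- params$values %||% c(0, 1)
      g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                       k = seq_len(shape[3]))
      arr <- array(vals[((g$i + g$j) %% 2) + 1L], dim = shape)
      return(list(volume = scan_volume(arr, affine, empty_sidecar("MR"),
                                       datatype = "float"),
                  truth = list(values = vals)))
    }
    if (kind == "ellipsoid_brain") {
      semi <- params$semiaxes %||% (shape / 3.2)
      ctr <- params$center %||% ((shape + 1) / 2)
      noise <- params$noise %||% 2
      brain <- ellipsoid_mask(shape, ctr, semi)
      shell_out <- ellipsoid_mask(shape, ctr, semi * 1.35)
      shell_in <- ellipsoid_mask(shape, ctr, semi * 1.25)
      arr <- array(10, dim = shape)
      arr[shell_out & !shell_in] <- 90
      arr[brain] <- 100
      arr <- arr + stats::rnorm(length(arr), 0, noise)
      return(list(volume = scan_volume(arr, affine, empty_sidecar("MR"),
                                       datatype = "float"),
                  truth = list(mask = brain, semiaxes = semi, center = ctr)))
    }
    if (kind == "ct_head") {
      semi <- params$semiaxes %||% (shape / 3.2)
      ctr <- params$center %||% ((shape + 1) / 2)
      noise <- params$noise %||% 3
      brain <- ellipsoid_mask(shape, ctr, semi)
      gap <- ellipsoid_mask(shape, ctr, semi * 1.25)
      skull <- ellipsoid_mask(shape, ctr, semi * 1.45)
      arr <- array(-1000, dim = shape)              # air
      arr[skull & !gap] <- 1000                     # bone
      arr[gap & !brain] <- -40                      # separability gap
      arr[brain] <- 40 + stats::rnorm(sum(brain), 0, noise)
      return(list(volume = scan_volume(arr, affine, empty_sidecar("CT"),
                                       datatype = "float"),
                  truth = list(mask = brain)))
    }
    # perfusion4d
    nt <- params$nt %||% 20L
    t0 <- params$t0 %||% 4; tp <- params$tp %||% 3
    alpha <- params$alpha %||% 2.5; amp <- params$amp %||% 50
    noise <- params$noise %||% 0
    tt <- seq_len(nt)
    rel <- pmax(tt - t0, 0) / tp
    bolus <- amp * rel^alpha * exp(alpha * (1 - rel))
    env <- ellipsoid_mask(shape, (shape + 1) / 2, shape / 3) * 1
    clean <- array(0, dim = c(shape, nt))
    for (t in seq_len(nt)) clean[, , , t] <- 100 + env * bolus[t]
    arr <- clean + if (noise > 0) stats::rnorm(length(clean), 0, noise) else 0
    list(volume = scan_volume(arr, affine, empty_sidecar("MR"),
                              datatype = "float"),
         truth = list(clean = clean, bolus = bolus,
                      params = list(t0 = t0, tp = tp, alpha = alpha, amp = amp)))
  })
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate a small preclinical study: 2 subjects, 3 timepoints,
#' 10 MR sequences per session, with one brain ROI per session.
#'
#' @param n_subjects number of subjects
#' @param timepoints character vector of timepoint labels (or a count)
#' @param sequences character vector of sequence names (or a count)
#' @param shape,voxel_mm grid geometry for every volume
#' @param kind phantom kind used for the scans
#' @param roi_per_session also register a ground-truth brain ROI per session
#' @param roi_name sequence-name tag of that ROI
#' @param timepoints_per_subject optional integer vector recycled over
#'   subjects, for cohorts where subjects have different visit counts
#' @param seed master seed; every file derives its own sub-seed from it
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_subjects = 2L, timepoints = c("T0", "T1", "T2"),
                        sequences = sprintf("Seq%02d", 1:10),
                        shape = c(24L, 24L, 12L), voxel_mm = c(1, 1, 1),
                        kind = "ellipsoid_brain", roi_per_session = TRUE,
                        roi_name = "BrainROI", timepoints_per_subject = NULL,
                        seed = 1L) {
  if (is.numeric(timepoints) && length(timepoints) == 1L)
    timepoints <- sprintf("T%d", seq_len(timepoints) - 1L)
  if (is.numeric(sequences) && length(sequences) == 1L)
    sequences <- sprintf("Seq%02d", seq_len(sequences))
  structure(list(n_subjects = as.integer(n_subjects), timepoints = timepoints,
                 sequences = sequences, shape = shape, voxel_mm = voxel_mm,
                 kind = kind, roi_per_session = roi_per_session,
                 roi_name = roi_name,
                 timepoints_per_subject = timepoints_per_subject,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a fully registered synthetic project
#'
#' Creates the project folder skeleton, generates every scan (and one
#' ground-truth brain ROI per session when requested), registers
#' everything in the database with sidecar metadata, and saves the
#' ground-truth masks under `root/truth/` (outside the database).
#'
#' @param spec [cohort_spec()]
#' @param root project root to create
#' @return vox_project
#' @export
make_cohort <- function(spec, root) {
  project <- create_project(root)
  truth_dir <- file.path(root, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  tmp <- file.path(root, "Tmp")
  counter <- 0L
  for (si in seq_len(spec$n_subjects)) {
    subject <- sprintf("S%02d", si)
    ntp <- if (!is.null(spec$timepoints_per_subject))
      spec$timepoints_per_subject[(si - 1L) %% length(spec$timepoints_per_subject) + 1L]
    else length(spec$timepoints)
    for (tp in spec$timepoints[seq_len(ntp)]) {
      session_seed <- spec$seed + 131L * counter
      for (qi in seq_along(spec$sequences)) {
        seqname <- spec$sequences[qi]
        mv <- make_volume(spec$kind, spec$shape, spec$voxel_mm,
                          seed = session_seed + qi)
        f <- file.path(tmp, "gen.nii.gz")
        write_scan(mv$volume, f, write_sidecar_file = FALSE)
        project <- register_entry(project, f, subject = subject, timepoint = tp,
                                  sequence = seqname, type = "Scan",
                                  sidecar = empty_sidecar(
                                    Modality = if (spec$kind == "ct_head") "CT" else "MR",
                                    SeriesDescription = seqname,
                                    RepetitionTime = 2000, EchoTime = 30),
                                  move = TRUE)
        if (qi == 1L && !is.null(mv$truth$mask)) {
          tv <- roi_mask(mv$truth$mask * 1L, mv$volume$affine)
          write_scan(tv, file.path(truth_dir,
                                   sprintf("%s_%s_truth.nii.gz", subject, tp)),
                     write_sidecar_file = FALSE)
          if (spec$roi_per_session) {
            f2 <- file.path(tmp, "roi.nii.gz")
            write_scan(tv, f2, write_sidecar_file = FALSE)
            project <- register_entry(project, f2, subject = subject,
                                      timepoint = tp, sequence = spec$roi_name,
                                      type = "ROI", move = TRUE)
          }
        }
      }
      counter <- counter + 1L
    }
  }
  project
}

#' Write a scan volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian DICOM file per slice, with geometry tags
#' (ImagePositionPatient, ImageOrientationPatient, PixelSpacing) derived
#' from the volume's RAS+ affine (converted to DICOM's LPS convention) and
#' the acquisition metadata used by the default extraction mapping.
#' [convert_dicom_series()] recovers the array and affine.
#'
#' @param volume 3D scan_volume (stored as int16)
#' @param meta named list: Modality, SeriesDescription, RepetitionTime,
#'   EchoTime, FlipAngle, AcquisitionDateTime, series_number
#' @param out_dir output directory (created)
#' @return out_dir, invisibly
#' @export
make_dicom_series <- function(volume, meta = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arr <- volume$array
  if (length(dim(arr)) != 3L) vox_stop("DICOM series writer needs a 3D volume")
  A_lps <- diag(c(-1, -1, 1, 1)) %*% volume$affine
  dc <- sqrt(sum(A_lps[1:3, 1]^2)); dr <- sqrt(sum(A_lps[1:3, 2]^2))
  u <- A_lps[1:3, 1] / dc; v <- A_lps[1:3, 2] / dr
  step <- A_lps[1:3, 3]
  origin <- A_lps[1:3, 4]
  sn <- meta$series_number %||% 1L
  study_uid <- synthetic_uid(sn, "1")
  series_uid <- synthetic_uid(sn, "2")
  fmt <- function(x) paste(formatC(x, format = "fg", digits = 10, width = 1),
                           collapse = "\\")
  for (k in seq_len(dim(arr)[3])) {
    ipp <- origin + step * (k - 1L)
    slice_meta <- list(
      sop_uid = synthetic_uid(sn, "3", k),
      study_uid = study_uid, series_uid = series_uid,
      instance_number = k,
      Modality = meta$Modality %||% "MR",
      SeriesDescription = meta$SeriesDescription,
      RepetitionTime = meta$RepetitionTime,
      EchoTime = meta$EchoTime,
      FlipAngle = meta$FlipAngle,
      AcquisitionDateTime = meta$AcquisitionDateTime,
      SliceThickness = sqrt(sum(step^2)),
      ipp = fmt(ipp),
      iop = fmt(c(u, v)),
      pixel_spacing = fmt(c(dr, dc)))
    write_dicom_slice(file.path(out_dir, sprintf("slice_%03d.dcm", k)),
                      matrix(as.integer(round(arr[, , k])), nrow = dim(arr)[1]),
                      slice_meta)
  }
  invisible(out_dir)
}
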