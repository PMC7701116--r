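# Shared fixtures and independent oracles for the suite. Everything is
# generated in code at test time; nothing binary ships with the package.

tmp_root <- function(prefix = "vox") {
  tempfile(pattern = paste0(prefix, "_"))
}

# a tiny deterministic scan on a diagonal affine
tiny_scan <- function(shape = c(8, 8, 4), voxel = c(1, 1, 1), seed = 1,
                      datatype = "float") {
  set.seed(seed)
  aff <- diag(c(voxel, 1)); aff[1:3, 4] <- c(-4, -4, -2)
  scan_volume(array(rnorm(prod(shape), 100, 10), dim = shape), aff,
              empty_sidecar("MR"), datatype = datatype)
}

# write a scan to a temp .nii.gz and return the path
tmp_nifti <- function(vol, dir = tempdir(), name = NULL) {
  path <- if (is.null(name)) tempfile(pattern = "img_", tmpdir = dir,
                                      fileext = ".nii.gz")
          else file.path(dir, name)
  write_scan(vol, path, write_sidecar_file = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force local entropy oracle: per-voxel histogram loop (2D or 3D window)
entropy_oracle <- function(arr, radius, bins, window = "2D") {
  d <- dim(arr)
  finite <- is.finite(arr)
  lo <- min(arr[finite]); hi <- max(arr[finite])
  bin_of <- function(v) if (hi > lo) pmin(bins, floor((v - lo) / (hi - lo) * bins) + 1L) else 1L
  H <- array(NaN, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!finite[i, j, k]) next
    ii <- max(1, i - radius):min(d[1], i + radius)
    jj <- max(1, j - radius):min(d[2], j + radius)
    kk <- if (window == "2D") k else max(1, k - radius):min(d[3], k + radius)
    vals <- arr[ii, jj, kk]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) next
    p <- tabulate(bin_of(vals), bins) / length(vals)
    p <- p[p > 0]
    H[i, j, k] <- -sum(p * log2(p))
  }
  H
}

# brute-force filter oracle: row-by-row predicate scan
filter_oracle <- function(db, criteria) {
  keep <- vapply(seq_len(nrow(db)), function(i) {
    all(vapply(names(criteria), function(tag) {
      is.null(criteria[[tag]]) || db[[tag]][i] %in% criteria[[tag]]
    }, logical(1)))
  }, logical(1))
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# read all image files of a project's data folders as decompressed bytes,
# keyed by relative path (execution-mode comparisons)
project_image_digest <- function(root) {
  files <- sort(unlist(lapply(c("Derived_data", "ROI_data"), function(d)
    file.path(d, list.files(file.path(root, d), pattern = "\\.nii(\\.gz)?$")))))
  stats::setNames(lapply(files, function(f)
    read_decompressed_bytes(file.path(root, f))), files)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# build the standard 4-module preclinical pipeline over a cohort project
preclinical_pipeline <- function(project, lib = discover_modules()) {
  pl <- new_pipeline(project)
  pl <- add_module(pl, lib$specs$Module_Brain_Extract, list(sequence = "Seq01"))
  pl <- add_module(pl, lib$specs$Module_Mask_ROI,
                   list(sequence = "Seq01", roi = "Seq01_brain"))
  pl <- add_module(pl, lib$specs$Module_Smooth,
                   list(sequence = "Seq01_masked", size = 1))
  add_module(pl, lib$specs$Module_Export_Stats,
             list(sequence = "Seq01_masked_smooth", roi = "Seq01_brain"))
}
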