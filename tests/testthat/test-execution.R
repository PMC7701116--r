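lib <- discover_modules()

make_twin_projects <- function(seed = 81, n_subjects = 2, timepoints = 3,
                               sequences = 1) {
  lapply(1:2, function(i)
    make_cohort(cohort_spec(n_subjects = n_subjects, timepoints = timepoints,
                            sequences = sequences, shape = c(10, 10, 6),
                            seed = seed), tmp_root()))
}

test_that("single and multi-worker execution produce identical outputs", {
  tw <- make_twin_projects(seed = 81)
  pls <- lapply(tw, preclinical_pipeline, lib = lib)
  r1 <- execute(pls[[1]], mode = "single")
  r2 <- execute(pls[[2]], mode = "multi", workers = 4)
  expect_equal(r1$report$counts, list(done = 24L, failed = 0L, skipped = 0L))
  expect_equal(r2$report$counts, list(done = 24L, failed = 0L, skipped = 0L))
  d1 <- project_image_digest(tw[[1]]$root)
  d2 <- project_image_digest(tw[[2]]$root)
  expect_identical(names(d1), names(d2))
  expect_identical(d1, d2)
  # the assembled CSVs agree too
  expect_identical(readLines(file.path(tw[[1]]$root, "Derived_data", "roi_stats.csv")),
                   readLines(file.path(tw[[2]]$root, "Derived_data", "roi_stats.csv")))
})

test_that("a failing job skips exactly its transitive descendants", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 1,
                               shape = c(10, 10, 6), seed = 82), root)
  # a module that fails for one specific session
  d <- tmp_root("mods")
  dir.create(file.path(d, "Test"), recursive = TRUE)
  writeLines(c(
    "module <- list(id = 'Module_Flaky', category = 'Test',",
    "  params = list(sequence = list(kind = 'sequence_selector'),",
    "                extension = list(kind = 'string', default = 'flaky')),",
    "  outputs = list(list(name = 'out', type = 'Scan',",
    "                      extension_param = 'extension')),",
    "  run = function(inputs, params, ctx) {",
    "    if (grepl('S01_T1$', ctx$job_id)) stop('forced failure')",
    "    list(out = inputs$sequence)",
    "  })"), file.path(d, "Test", "Module_Flaky.R"))
  lib2 <- discover_modules(c(d, builtin_modules_path()))
  pl <- new_pipeline(p)
  pl <- add_module(pl, lib2$specs$Module_Flaky, list(sequence = "Seq01"))
  pl <- add_module(pl, lib2$specs$Module_Smooth, list(sequence = "Seq01_flaky"))
  res <- execute(pl, mode = "multi", workers = 2)
  expect_equal(res$report$counts, list(done = 10L, failed = 1L, skipped = 1L))
  rj <- res$report$jobs
  expect_equal(rj$state[rj$job_id == "m01_Module_Flaky_S01_T1"], "failed")
  expect_equal(rj$state[rj$job_id == "m02_Module_Smooth_S01_T1"], "skipped")
  expect_match(rj$log[rj$job_id == "m01_Module_Flaky_S01_T1"], "forced failure")
  # no partial files: the failed session's outputs are absent from
  # Derived_data and from the database
  expect_false(file.exists(file.path(root, "Derived_data",
                                     "S01_T1_Seq01_flaky.nii.gz")))
  db <- load_project(root)$database
  expect_equal(sum(db$sequence == "Seq01_flaky" & db$status == "derived"), 5L)
  audit <- audit_project(res$project)
  expect_equal(length(audit$orphan_files), 0L)
  expect_equal(nrow(audit$missing_rows), 0L)
})

test_that("re-execution without overwrite skips and keeps files untouched", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 1,
                               shape = c(10, 10, 6), seed = 83), root)
  pl <- new_pipeline(p)
  pl <- add_module(pl, lib$specs$Module_Smooth, list(sequence = "Seq01"))
  pl <- add_module(pl, lib$specs$Module_Threshold,
                   list(sequence = "Seq01_smooth", cutoff = 50))
  r1 <- execute(pl, mode = "single")
  expect_equal(r1$report$counts$done, 12L)
  f <- file.path(root, "Derived_data", "S01_T0_Seq01_smooth.nii.gz")
  mtime_before <- file.info(f)$mtime
  Sys.sleep(1.1)
  r2 <- execute(pl, mode = "single")
  expect_equal(r2$report$counts, list(done = 0L, failed = 0L, skipped = 12L))
  expect_equal(file.info(f)$mtime, mtime_before)
  # overwrite re-runs everything
  r3 <- execute(pl, mode = "single", overwrite = TRUE)
  expect_equal(r3$report$counts$done, 12L)
  expect_gt(file.info(f)$mtime, mtime_before)
})

test_that("outputs are identical across worker counts on a random pipeline mix", {
  for (w in c(1L, 4L)) {
    tw <- make_twin_projects(seed = 84, n_subjects = 1, timepoints = 2)
    mk <- function(p) {
      pl <- new_pipeline(p)
      pl <- add_module(pl, lib$specs$Module_Smooth,
                       list(sequence = "Seq01", size = 1.5))
      pl <- add_module(pl, lib$specs$Module_Brain_Extract,
                       list(sequence = "Seq01_smooth"))
      pl <- add_module(pl, lib$specs$Module_Mask_ROI,
                       list(sequence = "Seq01", roi = "Seq01_smooth_brain"))
      add_module(pl, lib$specs$Module_Entropy_Map,
                 list(sequence = "Seq01_masked", radius = 1, bins = 8))
    }
    r1 <- execute(mk(tw[[1]]), mode = "single")
    r2 <- execute(mk(tw[[2]]), mode = "multi", workers = w)
    expect_equal(r2$report$counts$done, r1$report$counts$done)
    expect_identical(project_image_digest(tw[[1]]$root),
                     project_image_digest(tw[[2]]$root))
  }
})

test_that("the HTML report module assembles one self-contained file per pipeline", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 1, timepoints = 3, sequences = 1,
                               shape = c(10, 10, 6), seed = 87), root)
  pl <- new_pipeline(p)
  pl <- add_module(pl, lib$specs$Module_HTML_Report,
                   list(sequence = "Seq01", roi = "BrainROI"))
  res <- execute(pl, mode = "multi", workers = 2)
  expect_equal(res$report$counts$done, 3L)
  out <- file.path(root, "Derived_data", "report.html")
  expect_true(file.exists(out))
  txt <- readLines(out)
  expect_equal(sum(lengths(regmatches(txt, gregexpr("<img ", txt)))), 3L)
})

test_that("executing a red-only pipeline is refused", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 1, timepoints = 1, sequences = 1,
                               shape = c(8, 8, 4), seed = 85), root)
  pl <- add_module(new_pipeline(p), lib$specs$Module_Smooth,
                   list(sequence = "missing"))
  expect_error(execute(pl), "non-red")
})

test_that("the delete-files module prunes intermediates through the engine", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 1, timepoints = 2, sequences = 1,
                               shape = c(8, 8, 4), seed = 86), root)
  pl <- new_pipeline(p)
  pl <- add_module(pl, lib$specs$Module_Smooth, list(sequence = "Seq01"))
  pl <- add_module(pl, lib$specs$Module_Threshold,
                   list(sequence = "Seq01_smooth", cutoff = 50))
  pl <- add_module(pl, lib$specs$Module_Delete_Files,
                   list(sequence = "Seq01_smooth"))
  res <- execute(pl, mode = "single")
  expect_equal(res$report$counts$failed, 0L)
  db <- load_project(root)$database
  expect_equal(sum(db$sequence == "Seq01_smooth"), 0L)
  expect_false(file.exists(file.path(root, "Derived_data",
                                     "S01_T0_Seq01_smooth.nii.gz")))
  # the threshold outputs computed from them survive
  expect_equal(sum(db$sequence == "Seq01_smooth_mask" & db$status == "roi"), 2L)
})
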