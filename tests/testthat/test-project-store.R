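test_that("project creation builds the folder skeleton and refuses overwrites", {
  root <- tmp_root()
  p <- create_project(root)
  expect_equal(nrow(p$database), 0L)
  for (d in c("Raw_data", "Derived_data", "ROI_data", "Tmp", "Saved_Pipelines"))
    expect_true(dir.exists(file.path(root, d)))
  expect_error(create_project(root), "project exists")
})

test_that("registration copies files, enforces key uniqueness and validates payloads", {
  root <- tmp_root()
  p <- create_project(root)
  img <- tmp_nifti(tiny_scan())
  p <- register_entry(p, img, "S01", "T0", "T2w")
  expect_equal(nrow(p$database), 1L)
  expect_equal(p$database$status, "raw")
  expect_true(file.exists(file.path(root, "Raw_data", "S01_T0_T2w.nii.gz")))
  expect_true(file.exists(file.path(root, "Raw_data", "S01_T0_T2w.json")))
  expect_error(register_entry(p, img, "S01", "T0", "T2w"), "duplicate")
  bad <- file.path(tempdir(), "notanifti.nii")
  writeLines("junk", bad)
  expect_error(suppressWarnings(register_entry(p, bad, "S02", "T0", "T2w")),
               "NIfTI")
  expect_error(register_entry(p, img, "", "T0", "T2w"), "non-empty")
})

test_that("a 60-scan cohort registers and filters to the expected sizes", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 10,
                               shape = c(8, 8, 4), roi_per_session = FALSE,
                               seed = 3), root)
  expect_equal(nrow(p$database), 60L)
  expect_equal(nrow(filter_database(p, subject = "S01")), 30L)
  expect_equal(nrow(filter_database(p, subject = "S01", timepoint = "T0")), 10L)
  expect_equal(nrow(filter_database(p)), 60L)           # empty criteria
  expect_equal(nrow(filter_database(p, type = "ROI")), 0L)
  expect_error(filter_database(p$database, list(flavour = "x")), "unknown tag")
})

test_that("filtering matches a brute-force row scan on random criteria", {
  set.seed(42)
  n <- 220
  db <- data.frame(
    type = sample(c("Scan", "ROI"), n, TRUE),
    subject = sample(sprintf("S%02d", 1:8), n, TRUE),
    timepoint = sample(c("T0", "T1", "T2", "T3"), n, TRUE),
    sequence = sample(sprintf("Seq%02d", 1:6), n, TRUE),
    group = sample(c("", "ctrl", "treat"), n, TRUE),
    path = "Raw_data", filename = sprintf("f%03d.nii.gz", seq_len(n)),
    status = sample(c("raw", "derived", "roi", "virtual"), n, TRUE),
    stringsAsFactors = FALSE)
  for (rep in 1:100) {
    crit <- list()
    for (tag in c("subject", "timepoint", "sequence", "type", "status")) {
      if (runif(1) < 0.5)
        crit[[tag]] <- sample(unique(db[[tag]]), sample(1:2, 1))
    }
    got <- filter_database(db, crit)
    expect_identical(got, filter_oracle(db, crit))
    expect_identical(filter_database(got, crit), got)   # idempotence
  }
})

test_that("save/load round-trips the database and flags missing files", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 10,
                               shape = c(8, 8, 4), roi_per_session = FALSE,
                               seed = 5), root)
  p2 <- load_project(root)
  db2 <- p2$database
  attr(db2, "missing") <- NULL
  expect_equal(db2, p$database)
  # delete one file: load succeeds, entry flagged
  victim <- file.path(root, p$database$path[7], p$database$filename[7])
  unlink(victim)
  expect_warning(p3 <- load_project(root), "missing")
  expect_equal(sum(attr(p3$database, "missing")), 1L)
  expect_equal(nrow(p3$database), 60L)
  # corrupt database file is a parse error
  writeLines(c("not", "a", "table"), file.path(root, "project_database.tsv"))
  expect_error(load_project(root), "corrupt")
})

test_that("renaming a tag value updates rows and files atomically", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = c("J0", "J1"),
                               sequences = 5, shape = c(8, 8, 4),
                               roi_per_session = FALSE, seed = 6), root)
  res <- rename_tag_value(p, "timepoint", "J0", "T0")
  expect_equal(res$count, 10L)
  p <- res$project
  expect_equal(nrow(filter_database(p, timepoint = "J0")), 0L)
  expect_equal(nrow(filter_database(p, timepoint = "T0")), 10L)
  expect_true(file.exists(file.path(root, "Raw_data", "S01_T0_Seq01.nii.gz")))
  expect_false(file.exists(file.path(root, "Raw_data", "S01_J0_Seq01.nii.gz")))
  # absent value: zero rows changed
  expect_equal(rename_tag_value(p, "timepoint", "J9", "T9")$count, 0L)
  # collision rejected atomically
  before <- p$database
  expect_error(rename_tag_value(p, "timepoint", "J1", "T0"), "collide")
  expect_equal(load_project(root)$database, before, ignore_attr = TRUE)
})

test_that("deleting entries removes rows and (optionally) files", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 3, sequences = 5,
                               shape = c(8, 8, 4), roi_per_session = FALSE,
                               seed = 7), root)
  expect_equal(delete_entries(p, p$database[0, ])$count, 0L)
  keep_sel <- filter_database(p, subject = "S02", timepoint = "T0")
  res <- delete_entries(p, keep_sel, remove_files = FALSE)
  expect_equal(res$count, 5L)
  expect_true(file.exists(file.path(root, "Raw_data", "S02_T0_Seq01.nii.gz")))
  p <- res$project
  sel2 <- filter_database(p, subject = "S01", timepoint = "T0")
  res2 <- delete_entries(p, sel2, remove_files = TRUE)
  expect_equal(res2$count, 5L)
  expect_false(file.exists(file.path(root, "Raw_data", "S01_T0_Seq01.nii.gz")))
  expect_equal(nrow(res2$project$database), 20L)
})

test_that("referential integrity survives random operation sequences", {
  root <- tmp_root()
  p <- make_cohort(cohort_spec(n_subjects = 2, timepoints = 2, sequences = 4,
                               shape = c(6, 6, 3), roi_per_session = FALSE,
                               seed = 8), root)
  set.seed(9)
  for (i in 1:100) {
    op <- sample(c("register", "rename", "delete"), 1)
    if (op == "register") {
      img <- tmp_nifti(tiny_scan(c(6, 6, 3), seed = i))
      sub <- sample(sprintf("S%02d", 1:4), 1)
      tp <- sample(c("T0", "T1"), 1)
      sq <- sprintf("X%03d", i)
      p <- register_entry(p, img, sub, tp, sq)
    } else if (op == "rename" && nrow(p$database)) {
      tag <- sample(c("subject", "timepoint", "sequence"), 1)
      old <- sample(unique(p$database[[tag]]), 1)
      r <- tryCatch(rename_tag_value(p, tag, old, paste0(old, "r")),
                    error = function(e) NULL)
      if (!is.null(r)) p <- r$project
    } else if (nrow(p$database)) {
      sel <- p$database[sample(nrow(p$database), 1), ]
      p <- delete_entries(p, sel, remove_files = TRUE)$project
    }
  }
  audit <- audit_project(p)
  expect_equal(nrow(audit$missing_rows), 0L)
  expect_equal(length(audit$orphan_files), 0L)
})

test_that("compressed and uncompressed payloads register to identical arrays", {
  root <- tmp_root()
  p <- create_project(root)
  vol <- tiny_scan(seed = 11, datatype = "int16")
  vol$array <- array(as.integer(round(vol$array)), dim = dim(vol$array))
  gz <- tmp_nifti(vol)
  nii <- file.path(tempdir(), "plain_payload.nii")
  write_scan(vol, nii, write_sidecar_file = FALSE)
  p <- register_entry(p, gz, "S01", "T0", "A")
  p <- register_entry(p, nii, "S01", "T0", "B")
  a <- read_scan(file.path(root, "Raw_data", "S01_T0_A.nii.gz"))
  b <- read_scan(file.path(root, "Raw_data", "S01_T0_B.nii.gz"))
  expect_identical(a$array, b$array)
})

test_that("entry status colors follow the database color code", {
  expect_equal(entry_status_color(c("raw", "derived", "roi", "virtual")),
               c("blue", "green", "pink", "yellow"))
  expect_error(entry_status_color("nonsense"), "unknown status")
})

test_that("group tag is stored verbatim and never filtered on by default", {
  root <- tmp_root()
  p <- create_project(root)
  img <- tmp_nifti(tiny_scan())
  p <- register_entry(p, img, "S01", "T0", "T2w", group = "microbeam RT")
  expect_equal(p$database$group, "microbeam RT")
  expect_equal(nrow(filter_database(p)), 1L)
})
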