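# Export first-order ROI statistics: each job writes a one-row CSV
# fragment; the engine's finalize hook assembles the cohort CSV in
# Derived_data once all jobs of the module are done.
module <- list(
  id = "Module_Export_Stats",
  category = "Export",
  description = "export a .csv file of first-order statistics within a ROI",
  params = list(
    sequence = list(kind = "sequence_selector"),
    roi = list(kind = "roi_selector"),
    filename = list(kind = "string", default = "roi_stats.csv")
  ),
  outputs = list(list(name = "csv", type = "File")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    st <- roi_first_order_stats(inputs$sequence, inputs$roi)
    srow <- st[, c("mean", "std", "median", "min", "max", "n_voxels",
                   "volume_mm3")]
    frag <- file.path(ctx$tmp_dir, "stats_fragment.csv")
    utils::write.csv(srow, frag, row.names = FALSE, quote = FALSE)
    list(csv = frag)
  },
  finalize = function(fragments, params, ctx) {
    rows <- lapply(names(fragments), function(jid) {
      df <- utils::read.csv(fragments[[jid]][1])
      parts <- strsplit(jid, "_", fixed = TRUE)[[1]]
      n <- length(parts)
      cbind(data.frame(subject = parts[n - 1], timepoint = parts[n]), df)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$subject, out$timepoint), , drop = FALSE]
    path <- file.path(ctx$out_dir, params$filename)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    path
  }
)
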