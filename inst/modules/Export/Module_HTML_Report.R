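# Self-contained HTML report: one embedded mid-slice thumbnail per job,
# assembled by the finalize hook.
module <- list(
  id = "Module_HTML_Report",
  category = "Export",
  description = "static HTML report of images and ROI",
  params = list(
    sequence = list(kind = "sequence_selector"),
    roi = list(kind = "roi_selector"),
    filename = list(kind = "string", default = "report.html")
  ),
  outputs = list(list(name = "html", type = "File")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    row <- list(subject = "", timepoint = "", sequence = params$sequence,
                filename = ctx$job_id)
    frag <- file.path(ctx$tmp_dir, "panel.html")
    writeLines(voxpipe:::scan_panel_html(row, inputs$sequence, inputs$roi),
               frag)
    list(html = frag)
  },
  finalize = function(fragments, params, ctx) {
    panels <- unlist(lapply(fragments, function(f) readLines(f[1])))
    path <- file.path(ctx$out_dir, params$filename)
    writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                 "<title>Image and ROI report</title></head><body>",
                 panels, "</body></html>"), path)
    path
  }
)
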