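# Mask a scan with an ROI (outside voxels set to 0 or NaN).
module <- list(
  id = "Module_Mask_ROI",
  category = "ROI",
  description = "mask an image with a binary ROI",
  params = list(
    sequence = list(kind = "sequence_selector"),
    roi = list(kind = "roi_selector"),
    fill = list(kind = "choice", choices = c("0", "NaN"), default = "0"),
    extension = list(kind = "string", default = "masked")
  ),
  outputs = list(list(name = "masked", type = "Scan",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    fill <- if (params$fill == "NaN") NaN else 0
    list(masked = op_mask_with_roi(inputs$sequence, inputs$roi, fill))
  }
)
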