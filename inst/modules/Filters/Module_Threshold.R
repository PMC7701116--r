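# Strict intensity threshold producing a binary ROI mask.
module <- list(
  id = "Module_Threshold",
  category = "Filters",
  description = "keep voxels strictly above/below a cutoff as a binary mask",
  params = list(
    sequence = list(kind = "sequence_selector"),
    cutoff = list(kind = "number", default = 0),
    direction = list(kind = "choice", choices = c("above", "below"),
                     default = "above"),
    extension = list(kind = "string", default = "mask")
  ),
  outputs = list(list(name = "mask", type = "ROI",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(mask = op_threshold(inputs$sequence, params$cutoff, params$direction,
                             output = "mask"))
  }
)
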