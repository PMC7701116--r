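# Zero out voxels outside the admissible intensity range.
module <- list(
  id = "Module_Clip",
  category = "Filters",
  description = "set voxels at or below the cutoff to zero, keep the rest",
  params = list(
    sequence = list(kind = "sequence_selector"),
    cutoff = list(kind = "number", default = 0),
    direction = list(kind = "choice", choices = c("above", "below"),
                     default = "above"),
    extension = list(kind = "string", default = "clip")
  ),
  outputs = list(list(name = "clipped", type = "Scan",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(clipped = op_threshold(inputs$sequence, params$cutoff,
                                params$direction, output = "clipped"))
  }
)
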