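# Simplified brain extraction: Otsu threshold, largest component,
# morphological closing, hole fill.
module <- list(
  id = "Module_Brain_Extract",
  category = "Segmentation",
  description = "simplified intensity/morphology brain extraction",
  params = list(
    sequence = list(kind = "sequence_selector"),
    closing_radius = list(kind = "number", default = 2),
    extension = list(kind = "string", default = "brain")
  ),
  outputs = list(list(name = "brain", type = "ROI",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(brain = op_brain_extract(inputs$sequence, params$closing_radius))
  }
)
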