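# Reslice a sequence onto the grid of a reference sequence.
module <- list(
  id = "Module_Reslice",
  category = "Geometry",
  description = "reslice images to match the referential of a reference image",
  params = list(
    sequence = list(kind = "sequence_selector"),
    reference = list(kind = "sequence_selector"),
    interpolation = list(kind = "choice", choices = c("trilinear", "nearest"),
                         default = "trilinear"),
    extension = list(kind = "string", default = "reslice")
  ),
  outputs = list(list(name = "resliced", type = "Scan",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(resliced = op_reslice(inputs$sequence, inputs$reference,
                               params$interpolation))
  }
)
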