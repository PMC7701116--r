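# Gaussian smoothing of one sequence, per slice or volumetric.
module <- list(
  id = "Module_Smooth",
  category = "Filters",
  description = "2D or 3D Gaussian smoothing (filter size = Gaussian sigma)",
  params = list(
    sequence = list(kind = "sequence_selector"),
    dimension = list(kind = "choice", choices = c("3D", "2D"), default = "3D"),
    size = list(kind = "number", default = 2),
    unit = list(kind = "choice", choices = c("mm", "voxel"), default = "mm"),
    extension = list(kind = "string", default = "smooth")
  ),
  outputs = list(list(name = "smoothed", type = "Scan",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(smoothed = op_smooth(inputs$sequence, params$dimension, params$size,
                              params$unit))
  }
)
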