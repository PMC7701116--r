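# Local Shannon entropy texture map (bits).
module <- list(
  id = "Module_Entropy_Map",
  category = "Texture",
  description = "per-voxel Shannon entropy of the local intensity histogram",
  params = list(
    sequence = list(kind = "sequence_selector"),
    radius = list(kind = "number", default = 3),
    bins = list(kind = "number", default = 32),
    window = list(kind = "choice", choices = c("2D", "3D"), default = "2D"),
    extension = list(kind = "string", default = "entropy")
  ),
  outputs = list(list(name = "entropy", type = "Scan",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(entropy = op_entropy_map(inputs$sequence, params$radius, params$bins,
                                  params$window))
  }
)
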