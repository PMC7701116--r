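# Seeded region growth (active-contour style) producing an ROI.
module <- list(
  id = "Module_Active_Contour",
  category = "ROI",
  description = "grow an ROI from a seed voxel by intensity similarity",
  params = list(
    sequence = list(kind = "sequence_selector"),
    seed_x = list(kind = "number", default = 0),
    seed_y = list(kind = "number", default = 0),
    seed_z = list(kind = "number", default = 0),
    tolerance_k = list(kind = "number", default = 2.5),
    smoothness_m = list(kind = "number", default = 2),
    max_iter = list(kind = "number", default = 500),
    extension = list(kind = "string", default = "acroi")
  ),
  outputs = list(list(name = "roi", type = "ROI",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(roi = op_active_contour(inputs$sequence,
                                 c(params$seed_x, params$seed_y, params$seed_z),
                                 params$tolerance_k, params$smoothness_m,
                                 params$max_iter))
  }
)
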