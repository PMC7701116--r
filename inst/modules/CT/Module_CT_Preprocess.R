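# CT preprocessing chain: clip to an HU window, Gaussian filter, brain
# extraction by thresholding + largest component + hole fill.
module <- list(
  id = "Module_CT_Preprocess",
  category = "CT",
  description = "clip, filter and extract the brain from CT scans",
  params = list(
    sequence = list(kind = "sequence_selector"),
    hu_min = list(kind = "number", default = 0),
    hu_max = list(kind = "number", default = 100),
    sigma = list(kind = "number", default = 1),
    extension = list(kind = "string", default = "ctpre")
  ),
  outputs = list(
    list(name = "clipped", type = "Scan", extension_param = "extension"),
    list(name = "brain", type = "ROI", extension = "ctbrain")
  ),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    res <- op_ct_preprocess(inputs$sequence,
                            hu_window = c(params$hu_min, params$hu_max),
                            smooth_sigma = params$sigma)
    list(clipped = res$clipped, brain = res$roi)
  }
)
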