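# Template for writing new modules. Copy this file into a category folder
# under a Modules directory, rename the id (it must start with "Module_"),
# and fill in the pieces below. The next discovery pass picks it up.
#
# A module declares:
#  * params: named parameter specs. Kinds:
#      - sequence_selector / roi_selector: the value is a Sequence-Name tag;
#        the engine resolves it against the database and passes the matching
#        scan/ROI of each (subject, timepoint) session to run().
#      - number / string: free values with a default.
#      - choice: one of a fixed set.
#  * outputs: declared outputs. type "Scan" or "ROI" creates a virtual
#    database entry named <input sequence>_<extension> that later modules
#    can select; type "File" is an arbitrary per-job fragment assembled by
#    the optional finalize() hook.
#  * arity: "per-session" (one job per subject x timepoint, the default) or
#    "per-subject" (one job per subject, e.g. longitudinal coregistration).
#  * run(inputs, params, ctx): the computation. `inputs` is a named list of
#    scan_volume / roi_mask objects (one per selector parameter); `ctx` has
#    project_root, tmp_dir and job_id. Return a named list matching the
#    declared outputs. Everything is written to Tmp by the engine and only
#    promoted into the project on success.
module <- list(
  id = "Module_Template",
  category = "Template",
  description = "identity module: copies the selected sequence",
  params = list(
    sequence = list(kind = "sequence_selector"),
    extension = list(kind = "string", default = "copy")
  ),
  outputs = list(list(name = "copy", type = "Scan",
                      extension_param = "extension")),
  arity = "per-session",
  run = function(inputs, params, ctx) {
    list(copy = inputs$sequence)
  }
)
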