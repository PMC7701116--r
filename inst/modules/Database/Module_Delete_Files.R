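# Prune intermediate files from the project database (runs in the parent
# process, since it mutates the database).
module <- list(
  id = "Module_Delete_Files",
  category = "Database",
  description = "delete files of the project's database",
  params = list(
    sequence = list(kind = "sequence_selector"),
    remove_files = list(kind = "choice", choices = c("yes", "no"),
                        default = "yes")
  ),
  outputs = list(),
  arity = "per-session",
  parent_action = function(project, inputs, params) {
    sel <- do.call(rbind, inputs)
    sel <- project$database[entry_key(project$database) %in% entry_key(sel), ]
    delete_entries(project, sel,
                   remove_files = identical(params$remove_files, "yes"))$project
  }
)
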