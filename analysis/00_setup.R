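# Shared setup for the analysis drivers: one seeded configuration defines the
# synthetic study conditions used by every numbered script. Generators are
# deterministic, so each script regenerates what it needs instead of passing
# serialized state around.

suppressMessages(library(lncclass))

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

CFG <- synth_config(seed = 1234L)

tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
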