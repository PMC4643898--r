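# Shared settings for the numbered analysis scripts. Each script is run as
#   Rscript analysis/NN_step.R
# from the repository root and reads/writes under results/.

suppressPackageStartupMessages(library(sepsimet))

SEED <- as.integer(Sys.getenv("SEPSIMET_SEED", "1"))
RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
AXIS <- default_axis()

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

write_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.csv(df, path, row.names = FALSE)
  cat("wrote", path, "\n")
}
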