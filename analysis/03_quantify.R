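# Quantify the 8-metabolite panel (region integrals over the total
# aliphatic area) at both collections and screen each metabolite with a
# one-way ANOVA between survivors and non-survivors.

source("analysis/_common.R")

cohort <- read_cohort(file.path(DATA_DIR, "cohort.csv"))
manifest <- read.csv(file.path(DATA_DIR, "manifest.csv"),
                     stringsAsFactors = FALSE)

for (tp in c("0h", "24h")) {
  ids <- cohort$sample_id[cohort$timepoint == tp]
  files <- manifest$file[match(ids, manifest$sample_id)]
  spectra <- setNames(
    lapply(seq_along(ids), function(i)
      reference_to_tsp(read_spectrum(file.path(DATA_DIR, files[i]),
                                     sample_id = ids[i]))),
    ids)
  panel <- cohort_panel(spectra)
  write_table(panel, sprintf("panel_%s.csv", tp))
  screen <- anova_screen(panel[-1], cohort$outcome[cohort$timepoint == tp])
  write_table(screen, sprintf("anova_screen_%s.csv", tp))
  cat(sprintf("%s: %d of %d metabolites at adjusted p < 0.05\n",
              tp, sum(screen$p_adj < 0.05), nrow(screen)))
}
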