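#!/usr/bin/env Rscript
# Stage 2: rank-based DEG detection per primary origin.
#
# Reads the simulated datasets written by 01_simulate_data.R, integrates
# them on the genes detected on all platforms (no intensity normalisation
# — the method uses only within-sample orderings), finds stable gene
# pairs in the controls, scores every metastasis sample with the Fisher
# reversal test, calls subpopulation-level DEGs with the binomial test at
# 5% FDR, and screens them at the medium effect-size threshold 0.5.

suppressMessages(library(metorgan))

src <- "results/simdata"
out <- "results/degs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files(src, pattern = "^ds_.*\\.tsv$", full.names = TRUE)
files <- files[!grepl("annotations", files)]
mats <- lapply(files, read_expression_tsv)

integ <- integrate_datasets(mats)
cat("Integrated", length(mats), "datasets:", integ$universe_size,
    "genes x", ncol(integ$matrix$values), "samples\n")

controls <- samples_by_role(integ$matrix, "control")
pairs <- find_stable_pairs(controls, min_consistency = 0.99)
cat("Stable pairs in", ncol(controls$values), "controls:",
    length(pairs$low), "\n")

params <- pipeline_params()
ann <- integ$matrix$annotations
origins <- sort(unique(stats::na.omit(ann$primary_site)))
for (o in origins) {
  cases <- samples_by_role(integ$matrix, "metastasis", o)
  calls <- reversal_calls(cases, pairs, sample_fdr = params$sample_fdr)
  degs <- population_deg_test(calls, null_rate = params$null_rate,
                              fdr_threshold = params$fdr)
  group <- subset_samples(integ$matrix,
                          c(colnames(cases$values), colnames(controls$values)))
  screened <- filter_by_effect_size(degs, group,
                                    threshold = params$effect_threshold)
  cat(sprintf("%-8s %d cases: %d DEGs at 5%% FDR, %d pass |delta| >= %.1f\n",
              o, ncol(cases$values), sum(degs$is_deg), nrow(screened),
              params$effect_threshold))
  utils::write.table(degs, file.path(out, paste0("degs_", o, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screened,
                     file.path(out, paste0("degs_screened_", o, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(as.character(integ$universe_size),
           file.path(out, "universe_size.txt"))
cat("Outputs in", out, "\n")
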