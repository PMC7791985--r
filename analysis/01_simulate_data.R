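#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-dataset metastasis study.
#
# Emulates the design of the real analysis: two primary origins (breast,
# lung) metastasizing to the brain, each profiled in its own dataset on
# its own "platform" (10% of genes missing per platform), one shared
# control dataset, dataset-level additive batch shifts, and planted
# ground-truth DEGs (10% common to both origins, 5% private to each,
# shifted by 1 noise-SD). Everything downstream reads only the files
# written here.

suppressMessages(library(metorgan))

seed <- 1L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_multibatch(cfg)

for (nm in names(sim$matrices)) {
  write_expression_tsv(sim$matrices[[nm]], file.path(out, paste0(nm, ".tsv")),
                       comment = paste0("simulated dataset ", nm, ", seed ", seed))
}

universe <- Reduce(intersect, lapply(sim$matrices, genes))
coll <- simulate_gene_sets(sim$truth, universe, n_decoys = 50, set_size = 40,
                           seed = seed)
write_gmt(coll, file.path(out, "pathways.gmt"))

truth <- sim$truth
truth_df <- rbind(
  data.frame(gene = truth$common_up, role = "common_up"),
  data.frame(gene = truth$common_down, role = "common_down"),
  do.call(rbind, lapply(names(truth$private), function(o) rbind(
    data.frame(gene = truth$private[[o]]$up, role = paste0("private_up_", o)),
    data.frame(gene = truth$private[[o]]$down, role = paste0("private_down_", o))))))
utils::write.table(truth_df, file.path(out, "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", length(sim$matrices), "datasets of", cfg$n_genes,
    "genes; common universe:", length(universe), "genes\n")
cat("Planted:", length(truth$common_up), "common up,",
    length(truth$common_down), "common down,",
    length(unlist(truth$private)) , "private DEGs\n")
cat("Outputs in", out, "\n")
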