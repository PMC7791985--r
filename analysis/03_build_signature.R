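#!/usr/bin/env Rscript
# Stage 3: organ-specific metastasis signature and pathway enrichment.
#
# Intersects the screened per-origin DEG lists (direction-consistent
# intersection against the shared organ controls), reports overlap
# percentages with hypergeometric significance, summarises the up/down
# composition, and runs stratified enrichment against the pathway
# collection. Also recomputes, from the published study's printed counts
# (universe 9797; breast-origin list 1857, lung-origin list 1979, overlap
# 1612), the overlap percentages and significance those counts imply.

suppressMessages(library(metorgan))

deg_dir <- "results/degs"
sim_dir <- "results/simdata"
out <- "results/signature"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

universe_size <- as.integer(readLines(file.path(deg_dir, "universe_size.txt")))
read_deg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("deg_table", "data.frame")
  d
}
files <- list.files(deg_dir, pattern = "^degs_screened_", full.names = TRUE)
origins <- sub("^degs_screened_(.*)\\.tsv$", "\\1", basename(files))
lists <- Map(function(f, o)
  origin_deg_list(read_deg(f), "brain", o, universe_size), files, origins)

sig <- intersect_deg_lists(unname(lists))
print(sig)
dirs <- summarize_directions(sig)
pw <- sig$pairwise_overlap
for (i in seq_len(nrow(pw))) {
  cat(sprintf("overlap %s vs %s: %d genes = %.0f%% of the shorter list (p = %.3g)\n",
              pw$origin_a[i], pw$origin_b[i], pw$k[i], pw$pct_shorter[i],
              pw$p[i]))
}
if (!dirs$undefined) {
  cat(sprintf("signature composition: %.0f%% up, %.0f%% down\n",
              100 * dirs$frac_up, 100 * dirs$frac_down))
}

sig_df <- rbind(data.frame(gene = sig$shared_up, direction = "up"),
                data.frame(gene = sig$shared_down, direction = "down"))
utils::write.table(sig_df, file.path(out, "signature_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pw, file.path(out, "pairwise_overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

coll <- read_gmt(file.path(sim_dir, "pathways.gmt"))
mats <- lapply(setdiff(list.files(sim_dir, pattern = "^ds_.*\\.tsv$",
                                  full.names = TRUE),
                       list.files(sim_dir, pattern = "annotations",
                                  full.names = TRUE)),
               read_expression_tsv)
universe_genes <- Reduce(intersect, lapply(mats, genes))
if (dirs$n_up + dirs$n_down > 0) {
  enr <- run_enrichment(sig, coll, universe_genes = universe_genes)
  utils::write.table(enr, file.path(out, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- enr[which.min(enr$raw_p), ]
  cat(sprintf("top pathway: %s (%s stratum, %d/%d genes, FDR %s)\n",
              top$pathway, top$stratum, top$k, top$K, top$fdr_display))
}

# the published study's printed counts, re-expressed by the same functions
pc <- overlap_percent(1612, 1857, 1979)
ref <- overlap_significance(1612, 1857, 1979, 9797, log10_p = TRUE)
cat(sprintf("reference counts: 1612/1857 = %d%%, 1612/1979 = %d%%, log10 p = %.1f\n",
            pc$pct_a_int, pc$pct_b_int, ref$log10_p))
cat("Outputs in", out, "\n")
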