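#!/usr/bin/env Rscript
# Simulate the study cohort: a 15-tissue panel, two age groups (young < 40,
# aging > 65 emulated as group labels), 60 samples per group per tissue,
# negative-binomial counts. Ten genes are planted as simultaneous aging
# signals in every tissue — a log2 fold change of 2 AND a co-expression
# module whose connectivity collapses in the aging group — so the full
# pipeline has a known answer to recover. Writes the expression tables,
# metadata and ground truth under results/cohort/.

suppressPackageStartupMessages(library(agenet))

seed <- 1L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_genes = 300, n_tissues = 15, n_de_genes = 0,
                     module_sizes = 10L, loading_young = 0.9,
                     loading_aging = 0.0, module_de_log2fc = 2,
                     n_young = 60, n_aging = 60, seed = seed)
panel <- generate_panel(cfg)

meta_all <- do.call(rbind, lapply(panel, `[[`, "meta"))
write_metadata(meta_all, file.path(out_dir, "metadata.tsv"))
for (tname in names(panel)) {
  write_expression(panel[[tname]]$counts,
                   file.path(out_dir, paste0(tname, ".counts.tsv")))
  write_expression(panel[[tname]]$tpm,
                   file.path(out_dir, paste0(tname, ".tpm.tsv")))
}
truth <- panel[[1]]$truth
write_table_tsv(data.frame(gene_id = truth$module_de_genes,
                           planted = "de_and_connectivity"),
                file.path(out_dir, "truth.tsv"))

cat(sprintf("simulated %d tissues x %d genes x %d samples each; %d planted genes\n",
            length(panel), cfg$n_genes, cfg$n_young + cfg$n_aging,
            length(truth$module_de_genes)))
cat("planted:", paste(truth$module_de_genes, collapse = ", "), "\n")
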