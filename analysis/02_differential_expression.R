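#!/usr/bin/env Rscript
# Per-tissue differential expression between the aging and young groups:
# Welch t-test on median-centered log2(TPM + 1), BH adjustment within each
# tissue, significance at adjusted p < 0.05, direction by the sign of the
# fold change with no magnitude cut-off. Reads results/cohort/, writes one
# <tissue>.de.tsv per tissue under results/de/ and prints the DEG count and
# planted-gene recall per tissue.

suppressPackageStartupMessages(library(agenet))

cohort_dir <- "results/cohort"
out_dir <- "results/de"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta_all <- read_metadata(file.path(cohort_dir, "metadata.tsv"))
truth <- read_table_tsv(file.path(cohort_dir, "truth.tsv"))$gene_id
cfg <- run_config(seed = 1L)

for (tname in sort(unique(meta_all$tissue))) {
  tpm <- read_expression(file.path(cohort_dir, paste0(tname, ".tpm.tsv")),
                         "tpm")
  meta <- meta_all[meta_all$tissue == tname, ]
  de <- builtin_de(tpm, meta, cfg)
  write_table_tsv(de, file.path(out_dir, paste0(tname, ".de.tsv")))
  hits <- de_gene_set(de)
  cat(sprintf("%s: %4d significant DEGs (%d up, %d down); planted recall %.2f\n",
              tname, length(hits),
              sum(de$significant & de$direction == "up"),
              sum(de$significant & de$direction == "down"),
              mean(truth %in% hits)))
}
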