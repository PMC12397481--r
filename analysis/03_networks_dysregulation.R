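#!/usr/bin/env Rscript
# Condition-specific co-expression networks and dysregulated nodes. For each
# tissue: filter genes to median TPM > 5 within each age group, test all
# gene pairs with Spearman correlation, keep edges at BH q < 0.05, count
# positive-edge degree, and rank genes by the absolute change in degree
# between the young and aging networks; the top 10% are the tissue's
# dysregulated nodes (DNs). Writes edge lists and DN tables under
# results/networks/ and prints per-tissue network sizes and planted recall.

suppressPackageStartupMessages(library(agenet))

cohort_dir <- "results/cohort"
out_dir <- "results/networks"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta_all <- read_metadata(file.path(cohort_dir, "metadata.tsv"))
truth <- read_table_tsv(file.path(cohort_dir, "truth.tsv"))$gene_id
cfg <- run_config(seed = 1L)

for (tname in sort(unique(meta_all$tissue))) {
  tpm <- read_expression(file.path(cohort_dir, paste0(tname, ".tpm.tsv")),
                         "tpm")
  meta <- meta_all[meta_all$tissue == tname, ]
  nets <- lapply(c(young = "young", aging = "aging"), function(g)
    build_network(tpm, meta$sample_id[meta$group == g], cfg,
                  tissue = tname, group = g))
  for (g in names(nets))
    write_network(nets[[g]],
                  edges_path = file.path(out_dir,
                                         sprintf("%s.%s.edges.tsv", tname, g)),
                  degree_path = file.path(out_dir,
                                          sprintf("%s.%s.degree.tsv", tname, g)))
  dn <- dysregulation_table(nets$young, nets$aging, cfg)
  write_table_tsv(dn, file.path(out_dir, paste0(tname, ".dn.tsv")))
  cat(sprintf(
    "%s: young %4d edges / aging %4d edges; %d DNs; planted DN recall %.2f\n",
    tname, nrow(nets$young$edges), nrow(nets$aging$edges),
    sum(dn$is_dn), mean(truth %in% dn_gene_set(dn))))
}
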