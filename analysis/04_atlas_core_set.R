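#!/usr/bin/env Rscript
# Cross-tissue aggregation. Counts, for every gene, the tissues where it is
# a significant DEG and where it is a DN, assigns the Single (1 tissue) /
# Some (2-13) / Many (>= 14 of the 15-tissue panel) categories to each, and
# intersects "DEG in Many" with "DN in Many" to form the core biomarker set.
# Reads results/de/ and results/networks/, writes results/atlas.tsv,
# results/atlas_summary.json and results/core_set.txt.

suppressPackageStartupMessages({library(agenet); library(jsonlite)})

meta_all <- read_metadata("results/cohort/metadata.tsv")
truth <- read_table_tsv("results/cohort/truth.tsv")$gene_id
tissues <- sort(unique(meta_all$tissue))
cfg <- run_config(seed = 1L)

deg_sets <- lapply(tissues, function(t)
  de_gene_set(read_table_tsv(file.path("results/de", paste0(t, ".de.tsv")))))
dn_sets <- lapply(tissues, function(t)
  dn_gene_set(read_table_tsv(file.path("results/networks",
                                       paste0(t, ".dn.tsv")))))
names(deg_sets) <- names(dn_sets) <- tissues

atlas <- build_atlas(deg_sets, dn_sets, cfg)
write_table_tsv(atlas, "results/atlas.tsv")
write_json(atlas_summary(atlas), "results/atlas_summary.json",
           auto_unbox = TRUE, pretty = TRUE)
core <- core_biomarker_set(atlas)
writeLines(core, "results/core_set.txt")

cat("DEG categories:", paste(capture.output(
  table(atlas$deg_category))[2:3], collapse = " / "), "\n")
cat("DN categories:", paste(capture.output(
  table(atlas$dn_category))[2:3], collapse = " / "), "\n")
cat(sprintf("core biomarker set: %d genes; planted recall %.2f\n",
            length(core), mean(truth %in% core)))
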