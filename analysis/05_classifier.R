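#!/usr/bin/env Rscript
# Random-forest age-group classification on the core biomarker set.
# (1) Pooled model: samples of all 15 tissues stacked (features z-scored
#     within tissue), 1000 trees, stratified 70/30 split; held-out AUC,
#     accuracy and OOB score reported.
# (2) Per-tissue models: one refit per tissue with the shared core feature
#     list.
# (3) Composite predictor: per-tissue top-5 features pooled and refit, as
#     for a multi-tissue biomarker panel.
# Writes results/classifier_report.json, results/per_tissue_auc.tsv,
# results/importance.tsv, results/roc.tsv.

suppressPackageStartupMessages({library(agenet); library(jsonlite)})

seed <- 1L
cfg <- run_config(seed = seed)
meta_all <- read_metadata("results/cohort/metadata.tsv")
core <- readLines("results/core_set.txt")
tissues <- sort(unique(meta_all$tissue))

panel <- lapply(tissues, function(t) list(
  tpm = read_expression(file.path("results/cohort", paste0(t, ".tpm.tsv")),
                        "tpm"),
  meta = meta_all[meta_all$tissue == t, ]))
names(panel) <- tissues

core_lists <- setNames(rep(list(core), length(panel)), tissues)
pooled <- composite_predictor(core_lists, panel, cfg, seed = seed)
cat(sprintf("pooled model on %d core genes: AUC %.3f, accuracy %.3f, OOB %.3f\n",
            length(core), pooled$auc, pooled$accuracy, pooled$oob_score))

per_tissue <- per_tissue_eval(core, panel, cfg, seed = seed)
write_table_tsv(per_tissue, "results/per_tissue_auc.tsv")
cat(sprintf("per-tissue AUC: median %.3f, range %.3f-%.3f\n",
            median(per_tissue$auc), min(per_tissue$auc),
            max(per_tissue$auc)))

tops <- setNames(lapply(tissues, function(t) {
  feats <- suppressWarnings(feature_matrix(panel[[t]]$tpm, core))
  labs <- panel[[t]]$meta$group[match(rownames(feats),
                                      panel[[t]]$meta$sample_id)]
  rank_features(fit_rf(feats, labs, cfg, seed = seed), min(5, length(core)))
}), tissues)
composite <- composite_predictor(tops, panel, cfg, seed = seed)
cat(sprintf("composite predictor (%d pooled features): AUC %.3f\n",
            length(unique(unlist(tops))), composite$auc))

write_table_tsv(data.frame(gene_id = names(pooled$feature_importances),
                           importance = unname(pooled$feature_importances)),
                "results/importance.tsv")
write_table_tsv(pooled$roc, "results/roc.tsv")
write_json(list(pooled = list(auc = pooled$auc, accuracy = pooled$accuracy,
                              oob_score = pooled$oob_score,
                              split = as.list(pooled$split),
                              params = pooled$params, seed = seed),
                composite = list(auc = composite$auc,
                                 n_features = length(unique(unlist(tops))))),
           "results/classifier_report.json", auto_unbox = TRUE, pretty = TRUE)
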