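#' Samples-by-genes feature matrix from a TPM expression matrix
#'
#' Transposes to samples x genes and applies log2(TPM + 1), the same
#' transform the differential-expression stage tests on. Requested genes
#' missing from the matrix are filled with zeros, with a warning (the gene is
#' absent in that tissue).
#'
#' @param tpm A TPM [expression_matrix()].
#' @param genes Gene ids to keep, in order; NULL keeps all.
#' @return Numeric matrix, samples in rows, genes in columns.
#' @export
feature_matrix <- function(tpm, genes = NULL) {
  stopifnot(inherits(tpm, "expression_matrix"),
            identical(attr(tpm, "unit"), "tpm"))
  m <- unclass(tpm); attr(m, "unit") <- NULL
  if (is.null(genes)) genes <- rownames(m)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    warning(length(missing), " requested gene(s) absent from matrix; ",
            "filled with zeros")
    m <- rbind(m, matrix(0, length(missing), ncol(m),
                         dimnames = list(missing, colnames(m))))
  }
  t(log2(m[genes, , drop = FALSE] + 1))
}

# stratified train/test split; per-class train size round(frac * n_class)
stratified_split <- function(labels, train_fraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Fit a random-forest age-group classifier
#'
#' 1000 bootstrap trees (configurable) with out-of-bag estimation, on a
#' stratified 70/30 train/test split. Reports the held-out AUC and accuracy,
#' the OOB accuracy, normalised feature importances (mean decrease in Gini
#' impurity, summing to 1), the ranked feature list, and the ROC points of
#' the held-out predictions. Deterministic given the seed.
#'
#' @param features Samples x genes numeric matrix (log2-TPM scale; see
#'   [feature_matrix()]).
#' @param labels Character/factor vector, `"young"` / `"aging"`, one per row.
#' @param config A [run_config()] (supplies `rf_trees`,
#'   `rf_train_fraction`).
#' @param seed Integer seed for the split and the forest (defaults to
#'   `config$seed`).
#' @return List of class `"classifier_report"`.
#' @export
fit_rf <- function(features, labels, config = run_config(),
                   seed = config$seed) {
  labels <- as.character(labels)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (length(unique(labels)) < 2)
    stop("need both classes present")
  set.seed(seed)
  train <- stratified_split(labels, config$rf_train_fraction)
  for (cl in unique(labels)) {
    if (sum(train & labels == cl) < 2 || sum(!train & labels == cl) < 2)
      stop("fewer than 2 samples of class '", cl,
           "' in train or test after the stratified split")
  }
  y <- factor(labels, levels = c("young", "aging"))
  fit <- randomForest::randomForest(
    x = features[train, , drop = FALSE], y = y[train],
    ntree = config$rf_trees, importance = FALSE, keep.forest = TRUE)

  prob <- stats::predict(fit, features[!train, , drop = FALSE],
                         type = "prob")[, "aging"]
  pred <- stats::predict(fit, features[!train, , drop = FALSE])
  roc <- pROC::roc(response = y[!train], predictor = prob,
                   levels = c("young", "aging"), direction = "<",
                   quiet = TRUE)
  imp <- stats::setNames(fit$importance[, "MeanDecreaseGini"],
                         rownames(fit$importance))
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))

  structure(list(
    auc = as.numeric(pROC::auc(roc)),
    accuracy = mean(pred == y[!train]),
    oob_score = 1 - unname(fit$err.rate[config$rf_trees, "OOB"]),
    feature_importances = imp,
    top_features = names(imp)[ord],
    roc = data.frame(fpr = 1 - roc$specificities,
                     tpr = roc$sensitivities,
                     threshold = roc$thresholds),
    split = c(n_train = sum(train), n_test = sum(!train)),
    seed = seed,
    params = list(ntree = config$rf_trees,
                  mtry = fit$mtry,
                  train_fraction = config$rf_train_fraction)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "classifier_report: AUC %.3f, accuracy %.3f, OOB %.3f (train %d / test %d, %d trees, seed %d)\n",
    x$auc, x$accuracy, x$oob_score, x$split["n_train"], x$split["n_test"],
    x$params$ntree, x$seed))
  invisible(x)
}

#' Top-k features of a fitted report
#'
#' Features sorted by importance descending, ties broken lexically. Asking
#' for more features than exist returns all, with a warning.
#'
#' @param report A `"classifier_report"`.
#' @param k Number of features.
#' @return Character vector of gene ids.
#' @export
rank_features <- function(report, k) {
  feats <- report$top_features
  if (k > length(feats)) {
    warning("k exceeds the number of features; returning all ",
            length(feats))
    k <- length(feats)
  }
  feats[seq_len(k)]
}

#' Evaluate a shared feature list in each tissue separately
#'
#' Refits one stratified random forest per tissue using the shared top-gene
#' list and reports the held-out AUC. Tissues failing the group-size check
#' are skipped with a message.
#'
#' @param top_genes Shared gene list (e.g. from [rank_features()]).
#' @param panel Named list of tissues, each with elements `tpm` and `meta`
#'   (as produced by [generate_panel()]).
#' @param config A [run_config()].
#' @param seed Base seed; each tissue uses a derived substream.
#' @return data.frame (tissue, auc, n_samples).
#' @export
per_tissue_eval <- function(top_genes, panel, config = run_config(),
                            seed = config$seed) {
  rows <- lapply(seq_along(panel), function(i) {
    tis <- panel[[i]]
    chk <- check_group_sizes(tis$meta, config)
    if (!all(chk$pass)) {
      message("skipping tissue ", tis$meta$tissue[1],
              ": group-size check failed")
      return(NULL)
    }
    feats <- suppressWarnings(feature_matrix(tis$tpm, top_genes))
    rep <- fit_rf(feats, tis$meta$group[match(rownames(feats),
                                              tis$meta$sample_id)],
                  config, seed = derive_seed(seed, i))
    data.frame(tissue = tis$meta$tissue[1], auc = rep$auc,
               n_samples = nrow(feats), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(tissue = character(0), auc = numeric(0),
                                      n_samples = integer(0))
  rownames(out) <- NULL
  out
}

#' Composite multi-tissue predictor from pooled top features
#'
#' Pools the per-tissue top-gene lists into one feature union, stacks the
#' samples of every supplied tissue (z-scoring each gene within its tissue
#' by default, so tissue identity cannot leak into the pooled features), and
#' fits one classifier over the pooled cohort.
#'
#' @param per_tissue_top Named list: tissue -> top gene ids.
#' @param panel Named list of tissues with `tpm` and `meta`; names must cover
#'   `names(per_tissue_top)`.
#' @param config A [run_config()].
#' @param seed Seed for the pooled fit.
#' @param zscore Z-score features within tissue before pooling (default
#'   TRUE).
#' @return A `"classifier_report"` for the pooled model.
#' @export
composite_predictor <- function(per_tissue_top, panel,
                                config = run_config(), seed = config$seed,
                                zscore = TRUE) {
  if (length(panel) < 2) stop("composite predictor needs >= 2 tissues")
  union_genes <- sort(unique(unlist(per_tissue_top, use.names = FALSE)))
  if (length(union_genes) == 0) stop("empty feature union")
  blocks <- lapply(panel, function(tis) {
    f <- suppressWarnings(feature_matrix(tis$tpm, union_genes))
    if (zscore) {
      f <- scale(f)
      f[, attr(f, "scaled:scale") == 0] <- 0   # constant gene in this tissue
      f <- f[, , drop = FALSE]
    }
    list(f = f,
         lab = tis$meta$group[match(rownames(f), tis$meta$sample_id)])
  })
  features <- do.call(rbind, lapply(blocks, `[[`, "f"))
  labels <- unlist(lapply(blocks, `[[`, "lab"), use.names = FALSE)
  fit_rf(features, labels, config, seed = seed)
}
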