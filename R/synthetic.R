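#' Configuration for the synthetic multi-tissue cohort generator
#'
#' Describes a two-group (young / aging) expression cohort with known ground
#' truth: a set of planted differentially expressed genes and a set of
#' planted co-expression modules whose connectivity differs between the
#' groups. Counts follow a negative-binomial model with shared dispersion;
#' TPM is recomputed from the counts.
#'
#' The module signal uses a latent-factor construction: genes in module m of
#' group k have log2 signal `b_g + L_k * z_scale * f_s + eps` with
#' `f_s ~ N(0, 1)` per sample and `eps ~ N(0, z_scale * sqrt(1 - L_k^2))`, so
#' the population Pearson correlation between two same-module genes is
#' `L_k^2` and the loading is directly interpretable as a correlation
#' strength. Non-module genes receive independent noise of sd `z_scale`.
#'
#' @param n_genes Total genes.
#' @param n_tissues Number of tissues the panel will span.
#' @param n_young,n_aging Samples per group (>= 2 each).
#' @param n_de_genes Number of planted DE genes.
#' @param de_log2fc Planted log2 fold change (aging minus young).
#' @param module_sizes Integer vector, genes per planted module.
#' @param loading_young,loading_aging Per-module loadings in \[0, 1\]
#'   (recycled to `length(module_sizes)`).
#' @param module_de_log2fc Log2 fold change (aging minus young) additionally
#'   planted on every module gene (default 0). Lets a module carry both a
#'   mean shift and a connectivity change, emulating genes that are
#'   simultaneously differentially expressed and network-dysregulated; such
#'   genes are listed in the truth as `module_de_genes`, separate from the
#'   base `de_genes` set (which stays disjoint from the modules).
#' @param nb_dispersion Negative-binomial dispersion; Var = mu + disp * mu^2.
#' @param baseline_log2_tpm_mean,baseline_log2_tpm_sd Per-gene baseline
#'   log2-TPM distribution.
#' @param z_scale Biological sd of the per-sample log2 signal.
#' @param batch_effect_sd SD of per-gene batch offsets (two batches, split
#'   evenly within each group so batch is not confounded with age).
#' @param library_size_mean Expected reads per sample.
#' @param seed Integer seed; generation is deterministic given
#'   (config, tissue_index).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_genes = 500L,
                          n_tissues = 1L,
                          n_young = 40L,
                          n_aging = 40L,
                          n_de_genes = 20L,
                          de_log2fc = 2,
                          module_sizes = integer(0),
                          loading_young = numeric(0),
                          loading_aging = numeric(0),
                          module_de_log2fc = 0,
                          nb_dispersion = 0.1,
                          baseline_log2_tpm_mean = 4,
                          baseline_log2_tpm_sd = 1.5,
                          z_scale = 1,
                          batch_effect_sd = 0.1,
                          library_size_mean = 1e6,
                          seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  nm <- length(module_sizes)
  if (nm > 0) {
    loading_young <- rep_len(loading_young, nm)
    loading_aging <- rep_len(loading_aging, nm)
  } else {
    loading_young <- loading_aging <- numeric(0)
  }
  stopifnot(n_genes >= 1, n_tissues >= 1,
            n_young >= 2, n_aging >= 2,
            n_de_genes >= 0,
            all(module_sizes >= 1),
            n_de_genes + sum(module_sizes) <= n_genes,
            all(loading_young >= 0 & loading_young <= 1),
            all(loading_aging >= 0 & loading_aging <= 1),
            nb_dispersion > 0,
            baseline_log2_tpm_sd >= 0, z_scale > 0,
            batch_effect_sd >= 0, library_size_mean > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 n_young = as.integer(n_young),
                 n_aging = as.integer(n_aging),
                 n_de_genes = as.integer(n_de_genes),
                 de_log2fc = de_log2fc,
                 module_sizes = module_sizes,
                 loading_young = loading_young,
                 loading_aging = loading_aging,
                 module_de_log2fc = module_de_log2fc,
                 nb_dispersion = nb_dispersion,
                 baseline_log2_tpm_mean = baseline_log2_tpm_mean,
                 baseline_log2_tpm_sd = baseline_log2_tpm_sd,
                 z_scale = z_scale,
                 batch_effect_sd = batch_effect_sd,
                 library_size_mean = library_size_mean,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Stable per-(seed, tissue) substream: fold the tissue index into the seed on
# a large prime modulus, keeping the result inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729 + 1) %%
               2147483647)
}

#' Generate one synthetic tissue
#'
#' Draws a counts matrix, the matching TPM matrix, sample metadata and the
#' ground-truth record for one tissue of the configured panel. The generative
#' model: per-gene baseline log2 TPM ~ Normal(mean, sd); per-module latent
#' factors induce within-module correlation with group-specific strength
#' (loading^2); planted DE genes add `de_log2fc` to the aging-group mean;
#' per-gene batch offsets ~ Normal(0, batch_effect_sd); the log2 signal maps
#' to an expected TPM share, counts are negative-binomial with mean
#' proportional to share x library size, and TPM is recomputed from counts
#' under unit gene length.
#'
#' @param config A [cohort_config()].
#' @param tissue_index 1-based tissue index, <= `config$n_tissues`.
#' @return List with elements `counts`, `tpm` (both [expression_matrix()]),
#'   `meta` (sample metadata), and `truth` (list: `de_genes`, `de_sign`,
#'   `module_assignments`, `connectivity_delta_genes`, `batch_labels`).
#' @export
generate_tissue <- function(config, tissue_index = 1L) {
  stopifnot(inherits(config, "cohort_config"),
            tissue_index >= 1, tissue_index <= config$n_tissues)
  G <- config$n_genes
  n_y <- config$n_young; n_a <- config$n_aging
  n <- n_y + n_a
  tissue <- sprintf("tissue%02d", tissue_index)
  gene_ids <- sprintf("gene%05d", seq_len(G))
  sample_ids <- c(sprintf("%s_Y%03d", tissue, seq_len(n_y)),
                  sprintf("%s_A%03d", tissue, seq_len(n_a)))
  group <- rep(c("young", "aging"), c(n_y, n_a))
  # two batches split evenly within each group: batch never proxies for age
  batch <- c(rep(c("b1", "b2"), length.out = n_y),
             rep(c("b1", "b2"), length.out = n_a))

  # planted sets are disjoint by construction and placed at random positions
  # (a fixed placement would let the deterministic lexical tie-breaks further
  # down the pipeline flatter recovery); the placement is drawn from the
  # panel-level stream so every tissue plants the same genes
  set.seed(derive_seed(config$seed, 0L))
  placement <- sample.int(G)
  de_idx <- placement[seq_len(config$n_de_genes)]
  module_of <- integer(G)
  nxt <- config$n_de_genes
  for (m in seq_along(config$module_sizes)) {
    module_of[placement[nxt + seq_len(config$module_sizes[m])]] <- m
    nxt <- nxt + config$module_sizes[m]
  }
  set.seed(derive_seed(config$seed, tissue_index))

  b <- stats::rnorm(G, config$baseline_log2_tpm_mean,
                    config$baseline_log2_tpm_sd)
  z <- config$z_scale
  signal <- matrix(b, nrow = G, ncol = n)
  if (config$n_de_genes > 0)
    signal[de_idx, group == "aging"] <-
      signal[de_idx, group == "aging"] + config$de_log2fc
  if (config$module_de_log2fc != 0 && any(module_of > 0))
    signal[module_of > 0, group == "aging"] <-
      signal[module_of > 0, group == "aging"] + config$module_de_log2fc

  for (m in seq_along(config$module_sizes)) {
    idx <- which(module_of == m)
    f <- stats::rnorm(n)                       # latent factor, one per sample
    L <- ifelse(group == "young",
                config$loading_young[m], config$loading_aging[m])
    shared <- outer(rep(z, length(idx)), L * f)
    resid <- matrix(stats::rnorm(length(idx) * n), length(idx), n) *
      rep(z * sqrt(1 - L^2), each = length(idx))
    signal[idx, ] <- signal[idx, ] + shared + resid
  }
  bg <- which(module_of == 0L)
  signal[bg, ] <- signal[bg, ] +
    matrix(stats::rnorm(length(bg) * n, sd = z), length(bg), n)

  if (config$batch_effect_sd > 0) {
    batches <- unique(batch)
    off <- matrix(stats::rnorm(G * length(batches),
                               sd = config$batch_effect_sd),
                  G, length(batches))
    signal <- signal + off[, match(batch, batches)]
  }

  expected_tpm <- 2^signal
  share <- sweep(expected_tpm, 2, colSums(expected_tpm), "/")
  mu <- share * config$library_size_mean
  counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                  size = 1 / config$nb_dispersion), G, n)
  dimnames(counts) <- list(gene_ids, sample_ids)
  if (any(colSums(counts) == 0))
    stop("a sample drew zero total counts; increase library_size_mean")
  tpm <- counts_to_tpm(expression_matrix(counts, "counts"))

  meta <- sample_metadata(data.frame(sample_id = sample_ids, group = group,
                                     tissue = tissue, batch = batch,
                                     stringsAsFactors = FALSE))
  diff_modules <- which(config$loading_young != config$loading_aging)
  conn_delta <- gene_ids[module_of %in% diff_modules]
  truth <- list(
    de_genes = gene_ids[de_idx],
    de_sign = if (config$n_de_genes > 0)
      stats::setNames(rep(sign(config$de_log2fc), config$n_de_genes),
                      gene_ids[de_idx]) else stats::setNames(numeric(0),
                                                             character(0)),
    module_assignments = stats::setNames(module_of[module_of > 0],
                                         gene_ids[module_of > 0]),
    connectivity_delta_genes = conn_delta,
    module_de_genes = if (config$module_de_log2fc != 0)
      gene_ids[module_of > 0] else character(0),
    batch_labels = stats::setNames(batch, sample_ids))

  list(counts = expression_matrix(counts, "counts"), tpm = tpm, meta = meta,
       truth = truth)
}

#' Generate a full synthetic tissue panel
#'
#' @param config A [cohort_config()].
#' @return Named list of per-tissue results from [generate_tissue()], one per
#'   tissue.
#' @export
generate_panel <- function(config) {
  out <- lapply(seq_len(config$n_tissues), function(i)
    generate_tissue(config, i))
  names(out) <- vapply(out, function(x) x$meta$tissue[1], character(1))
  out
}

#' Convert counts to TPM
#'
#' Standard TPM: per-gene length-normalised rate `count / length_kb`, scaled
#' so each sample column sums to 1e6. Gene lengths default to 1 kb, in which
#' case TPM is proportional to the within-sample count share.
#'
#' @param counts A counts [expression_matrix()].
#' @param lengths_kb Named positive vector of gene lengths in kb, or NULL for
#'   unit lengths.
#' @return A TPM [expression_matrix()].
#' @export
counts_to_tpm <- function(counts, lengths_kb = NULL) {
  stopifnot(inherits(counts, "expression_matrix"),
            identical(attr(counts, "unit"), "counts"))
  m <- unclass(counts); attr(m, "unit") <- NULL
  if (is.null(lengths_kb)) {
    len <- rep(1, nrow(m))
  } else {
    len <- lengths_kb[rownames(m)]
    if (any(is.na(len)) || any(len <= 0))
      stop("lengths_kb must supply a positive length for every gene")
  }
  rate <- m / len
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample(s) with all-zero counts: TPM undefined: ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(tpm, "tpm")
}
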