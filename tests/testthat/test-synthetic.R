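test_that("truth sets are constructed as configured and disjoint", {
  cfg <- cohort_config(n_genes = 200, n_de_genes = 20, de_log2fc = 2,
                       module_sizes = integer(0), n_young = 40, n_aging = 40,
                       seed = 1)
  out <- generate_tissue(cfg, 1)
  expect_length(out$truth$de_genes, 20)
  expect_length(out$truth$module_assignments, 0)
  expect_true(all(out$truth$de_genes %in% rownames(out$counts)))

  cfg2 <- cohort_config(n_genes = 100, n_de_genes = 10, module_sizes = c(15, 5),
                        loading_young = 0.8, loading_aging = c(0.8, 0.1),
                        seed = 2)
  out2 <- generate_tissue(cfg2, 1)
  mod_genes <- names(out2$truth$module_assignments)
  expect_length(mod_genes, 20)
  expect_length(intersect(out2$truth$de_genes, mod_genes), 0)
  # only the module whose loading differs contributes connectivity-delta genes
  expect_setequal(out2$truth$connectivity_delta_genes,
                  names(out2$truth$module_assignments)[
                    out2$truth$module_assignments == 2])
  expect_error(cohort_config(n_genes = 10, n_de_genes = 8,
                             module_sizes = 5L, loading_young = 1,
                             loading_aging = 1))
  expect_error(cohort_config(n_young = 1))
})

test_that("generation is bit-identical given (config, tissue_index)", {
  cfg <- cohort_config(n_genes = 80, n_tissues = 3, n_de_genes = 5,
                       module_sizes = 10L,
                       loading_young = 0.7, loading_aging = 0.2,
                       n_young = 10, n_aging = 10, seed = 42)
  a <- generate_tissue(cfg, 2)
  b <- generate_tissue(cfg, 2)
  expect_identical(a, b)
  c <- generate_tissue(cfg, 1)
  expect_false(identical(unclass(a$counts), unclass(c$counts)))
})

test_that("counts_to_tpm implements the standard formula", {
  one <- expression_matrix(
    matrix(c(10, 90), 2, 1, dimnames = list(c("a", "b"), "s1")), "counts")
  expect_equal(unname(unclass(counts_to_tpm(one))[, 1]), c(1e5, 9e5))

  # length normalisation: counts (10, 20) at lengths (1, 2) kb -> equal rates
  two <- expression_matrix(
    matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1")), "counts")
  tpm <- counts_to_tpm(two, lengths_kb = c(a = 1, b = 2))
  expect_equal(unname(unclass(tpm)[, 1]), c(5e5, 5e5))

  set.seed(7)
  m <- matrix(rpois(50, 40), 10, 5,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  cs <- colSums(unclass(counts_to_tpm(expression_matrix(m, "counts"))))
  expect_equal(unname(cs), rep(1e6, 5), tolerance = 1e-9)

  z <- m; z[, 2] <- 0
  expect_error(counts_to_tpm(expression_matrix(z, "counts")), "all-zero")
  expect_error(counts_to_tpm(two, lengths_kb = c(a = 1)), "positive length")
})

test_that("planted DE genes show the configured empirical log2 fold change", {
  diffs <- vapply(1:5, function(s) {
    cfg <- cohort_config(n_genes = 300, n_de_genes = 20, de_log2fc = 2,
                         n_young = 40, n_aging = 40, nb_dispersion = 0.1,
                         seed = s)
    out <- generate_tissue(cfg, 1)
    x <- log2(unclass(out$tpm) + 1)
    aging <- out$meta$group == "aging"
    mean(rowMeans(x[out$truth$de_genes, aging]) -
           rowMeans(x[out$truth$de_genes, !aging]))
  }, numeric(1))
  expect_true(all(abs(diffs - 2) <= 0.5))
})

test_that("module loading controls within-module Spearman correlation", {
  gap <- vapply(1:10, function(s) {
    cfg <- cohort_config(n_genes = 120, n_de_genes = 0, module_sizes = 20L,
                         loading_young = 0.9, loading_aging = 0.0,
                         n_young = 60, n_aging = 60, seed = s)
    out <- generate_tissue(cfg, 1)
    mod <- names(out$truth$module_assignments)
    x <- unclass(out$tpm)[mod, ]
    young <- out$meta$group == "young"
    ry <- cor(t(x[, young]), method = "spearman")
    ra <- cor(t(x[, !young]), method = "spearman")
    mean(ry[upper.tri(ry)]) - mean(ra[upper.tri(ra)])
  }, numeric(1))
  expect_gte(mean(gap), 0.5)
})

test_that("module_de_log2fc plants a mean shift on module genes only", {
  cfg <- cohort_config(n_genes = 150, n_de_genes = 0, module_sizes = 10L,
                       loading_young = 0.9, loading_aging = 0.0,
                       module_de_log2fc = 2, n_young = 30, n_aging = 30,
                       seed = 3)
  out <- generate_tissue(cfg, 1)
  expect_setequal(out$truth$module_de_genes,
                  names(out$truth$module_assignments))
  x <- log2(unclass(out$tpm) + 1)
  aging <- out$meta$group == "aging"
  lfc <- rowMeans(x[, aging]) - rowMeans(x[, !aging])
  mod <- names(out$truth$module_assignments)
  expect_gt(mean(lfc[mod]), 1)
  expect_lt(abs(mean(lfc[setdiff(rownames(x), mod)])), 0.3)
})

test_that("the global-null cohort yields approximately uniform p-values", {
  # pooled per-gene Welch p-values across replicate null cohorts
  ps <- unlist(lapply(1:50, function(s) {
    cfg <- cohort_config(n_genes = 200, n_de_genes = 0, de_log2fc = 0,
                         n_young = 20, n_aging = 20, seed = 1000 + s)
    out <- generate_tissue(cfg, 1)
    builtin_de(out$tpm, out$meta)$p_value
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
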