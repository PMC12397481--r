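test_that("the expression filter is strict and uses the condition median", {
  tpm <- tiny_tpm(rbind(c(6, 6, 6), c(5, 5, 5), c(0, 0, 100)),
                  genes = c("hi", "edge", "spike"))
  keep <- filter_genes(tpm, colnames(tpm), threshold = 5)
  expect_identical(keep, "hi")
  # mean rule would rescue the spike gene; all-samples rule would not
  expect_identical(filter_genes(tpm, colnames(tpm), 5, rule = "mean"),
                   sort(c("hi", "spike")))
  expect_identical(filter_genes(tpm, colnames(tpm), 5, rule = "all"), "hi")
  expect_error(filter_genes(tpm, "s01"), ">= 2 samples")
  expect_error(filter_genes(tpm, c("s01", "nope")), "unknown sample")
})

test_that("spearman_rho matches the closed form and handles monotone maps", {
  out <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(out$rho, 1 - 6 * 4 / (5 * (5^2 - 1)))  # d^2 sum = 4
  expect_equal(out$rho, 0.8)

  x <- c(0.3, 1.7, 2.2, 5.9, 9.1)
  mono <- spearman_rho(x, exp(x))
  expect_equal(mono$rho, 1)
  expect_equal(mono$p, 0)

  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:3), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "n >= 3")
})

test_that("spearman_rho agrees with the mid-rank oracle, with and without ties", {
  set.seed(21)
  for (i in 1:300) {
    n <- sample(10:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_rho(x, y)
    d <- rank(x) - rank(y)
    expect_equal(got$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
    expect_equal(got$rho, spearman_oracle(x, y), tolerance = 1e-12)
    # tied data: closed form no longer applies, mid-rank oracle does
    xt <- sample(1:4, n, replace = TRUE); yt <- rnorm(n)
    expect_equal(spearman_rho(xt, yt)$rho, spearman_oracle(xt, yt),
                 tolerance = 1e-12)
  }
  expect_equal(spearman_rho(c(1, 1, 2), c(1, 2, 3))$rho,
               spearman_oracle(c(1, 1, 2), c(1, 2, 3)), tolerance = 1e-12)
})

test_that("three co-monotone genes form a complete positive network", {
  s <- seq(10, 48, by = 2)            # n = 20, all TPM > 5
  tpm <- tiny_tpm(rbind(s, s * 2, s + 3), genes = c("a", "b", "c"))
  net <- build_network(tpm, colnames(tpm), run_config(),
                       tissue = "t1", group = "young")
  expect_identical(nrow(net$edges), 3L)
  expect_equal(net$edges$rho, rep(1, 3))
  expect_true(all(net$edges$q == 0))
  expect_equal(unname(net$degree[c("a", "b", "c")]), c(2L, 2L, 2L))
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
})

test_that("degree counts positive edges only and satisfies the handshake identity", {
  edges <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                      rho = c(0.9, 0.8, -0.7), p = c(0, 0, 0), q = c(0, 0, 0))
  net <- fake_network(c("A", "B", "C", "D"), edges)
  expect_equal(unname(net$degree[c("A", "B", "C", "D")]), c(2L, 1L, 1L, 0L))
  expect_equal(unname(net$degree_neg[c("A", "B", "C", "D")]),
               c(0L, 1L, 1L, 0L))
  expect_equal(sum(net$degree), 2L * sum(edges$rho > 0))
  empty <- fake_network(c("A", "B"))
  expect_true(all(empty$degree == 0L))
})

test_that("network construction is invariant to gene and sample order", {
  cfg <- cohort_config(n_genes = 60, n_de_genes = 0, module_sizes = 12L,
                       loading_young = 0.9, loading_aging = 0.9,
                       n_young = 25, n_aging = 25, seed = 4)
  out <- generate_tissue(cfg, 1)
  ids <- out$meta$sample_id[out$meta$group == "young"]
  net1 <- build_network(out$tpm, ids, run_config())
  gp <- sample(nrow(out$tpm)); sp <- sample(ids)
  shuf <- expression_matrix(unclass(out$tpm)[gp, ], "tpm")
  net2 <- build_network(shuf, sp, run_config())
  expect_equal(net1$edges, net2$edges)
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$degree, net2$degree)
})

test_that("blocked pair sweep equals the naive full-matrix order", {
  cfg <- cohort_config(n_genes = 50, n_de_genes = 0, module_sizes = 10L,
                       loading_young = 0.8, loading_aging = 0.8,
                       n_young = 20, n_aging = 20, seed = 6)
  out <- generate_tissue(cfg, 1)
  ids <- out$meta$sample_id[out$meta$group == "young"]
  big <- build_network(out$tpm, ids, run_config(), block_size = 1024L)
  small <- build_network(out$tpm, ids, run_config(), block_size = 7L)
  expect_equal(big$edges, small$edges)
  expect_identical(big$n_pairs_tested, small$n_pairs_tested)
  # against cor()'s Spearman on the same node set
  S <- cor(t(unclass(out$tpm)[big$nodes, ids]), method = "spearman")
  for (i in seq_len(min(nrow(big$edges), 20)))
    expect_equal(big$edges$rho[i],
                 S[big$edges$gene_a[i], big$edges$gene_b[i]],
                 tolerance = 1e-12)
})

test_that("retained edge p-values match cor.test's Edgeworth tail", {
  cfg <- cohort_config(n_genes = 40, n_de_genes = 0, module_sizes = 8L,
                       loading_young = 0.85, loading_aging = 0.85,
                       n_young = 25, n_aging = 25, seed = 12)
  out <- generate_tissue(cfg, 1)
  ids <- out$meta$sample_id[out$meta$group == "young"]
  net <- build_network(out$tpm, ids, run_config())
  x <- unclass(out$tpm)[, ids]
  for (i in seq_len(nrow(net$edges))) {
    ref <- suppressWarnings(cor.test(x[net$edges$gene_a[i], ],
                                     x[net$edges$gene_b[i], ],
                                     method = "spearman", exact = TRUE))
    expect_equal(net$edges$p[i], ref$p.value, tolerance = 1e-10)
  }
  # the plain t approximation is available and is liberal in the far tail
  nt <- build_network(out$tpm, ids, run_config(), p_method = "t")
  deep <- which(nt$edges$p < 1e-4 & nt$edges$p > 0)
  shared <- match(paste(nt$edges$gene_a, nt$edges$gene_b)[deep],
                  paste(net$edges$gene_a, net$edges$gene_b))
  expect_true(all(nt$edges$p[deep] < net$edges$p[shared], na.rm = TRUE))
})

test_that("lowering the edge FDR threshold never adds edges", {
  cfg <- cohort_config(n_genes = 80, n_de_genes = 0, module_sizes = 15L,
                       loading_young = 0.7, loading_aging = 0.7,
                       n_young = 20, n_aging = 20, seed = 8)
  out <- generate_tissue(cfg, 1)
  ids <- out$meta$sample_id[out$meta$group == "young"]
  loose <- build_network(out$tpm, ids, run_config(edge_fdr = 0.05))
  tight <- build_network(out$tpm, ids, run_config(edge_fdr = 0.01))
  key <- function(e) paste(e$gene_a, e$gene_b)
  expect_true(all(key(tight$edges) %in% key(loose$edges)))
  expect_true(all(tight$degree[names(loose$degree)] <= loose$degree))
})

test_that("constant genes stay as isolated nodes and their pairs are tallied", {
  s <- seq(10, 29)
  tpm <- tiny_tpm(rbind(s, s + 1, rep(10, 20)), genes = c("a", "b", "const"))
  net <- build_network(tpm, colnames(tpm), run_config())
  expect_true("const" %in% net$nodes)
  expect_equal(unname(net$degree["const"]), 0L)
  expect_identical(net$n_pairs_skipped, 2L)
  expect_identical(net$n_pairs_tested, 1L)
})

test_that("strong-module genes are densely connected in the high-loading group", {
  # a loading-0.9 module of 20 genes against 500 background genes, n = 60:
  # count noise attenuates the planted correlation, so per-gene degree
  # fluctuates; the frozen expectations below were computed from the
  # generative model itself over these five seeds
  stats <- vapply(1:5, function(s) {
    cfg <- cohort_config(n_genes = 520, n_de_genes = 0, module_sizes = 20L,
                         loading_young = 0.9, loading_aging = 0.0,
                         n_young = 60, n_aging = 60, seed = s)
    out <- generate_tissue(cfg, 1)
    ids <- out$meta$sample_id[out$meta$group == "young"]
    net <- build_network(out$tpm, ids, run_config())
    mod <- names(out$truth$module_assignments)
    e <- net$edges[net$edges$gene_a %in% mod & net$edges$gene_b %in% mod &
                     net$edges$rho > 0, ]
    deg <- table(factor(c(e$gene_a, e$gene_b), levels = mod))
    c(min = min(deg), mean = mean(deg))
  }, numeric(2))
  expect_true(all(stats["min", ] >= 7))     # worst gene, worst seed
  expect_true(all(stats["mean", ] >= 13))   # dense module in every seed
  expect_gte(mean(stats["mean", ]), 16)     # of 19 possible partners
})
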