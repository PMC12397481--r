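# small in-code fixtures shared across test files

tiny_tpm <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, "tpm")
}

# TPM matrix whose log2(TPM + 1) equals the given values exactly
tpm_from_log2 <- function(log2vals, genes = NULL, samples = NULL) {
  tiny_tpm(2^as.matrix(log2vals) - 1, genes, samples)
}

two_group_meta <- function(n_young, n_aging, tissue = "t1") {
  sample_metadata(data.frame(
    sample_id = c(sprintf("y%02d", seq_len(n_young)),
                  sprintf("a%02d", seq_len(n_aging))),
    group = rep(c("young", "aging"), c(n_young, n_aging)),
    tissue = tissue,
    batch = "b1",
    stringsAsFactors = FALSE))
}

# minimal hand-built network object for degree/dysregulation tests
fake_network <- function(nodes, edges = NULL, tissue = "t1",
                         group = "young") {
  if (is.null(edges))
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        rho = numeric(0), p = numeric(0), q = numeric(0))
  net <- structure(list(condition = list(tissue = tissue, group = group),
                        nodes = sort(nodes), edges = edges,
                        degree = NULL, degree_neg = NULL,
                        n_samples = NA_integer_,
                        n_pairs_tested = nrow(edges),
                        n_pairs_skipped = 0L),
                   class = "coexpression_network")
  net$degree <- degree_centrality(net, positive_only = TRUE)
  net$degree_neg <- degree_centrality(net, positive_only = FALSE) - net$degree
  net
}

# brute-force BH step-up, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[i] <- min(p[o][js] * m / js)
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# brute-force mid-rank Pearson Spearman oracle
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
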