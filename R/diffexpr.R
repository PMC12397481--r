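#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH-adjusted p-values (q-values) in the input order: with p-values
#' sorted ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Two-group differential expression on log2(TPM + 1)
#'
#' Per-gene Welch two-sample t-test between the aging and young groups of one
#' tissue, on the log2(TPM + 1) scale. The effect is the mean difference on
#' that scale (aging minus young); p-values are BH-adjusted across all tested
#' genes of the tissue. A gene with zero variance in both groups gets p = 1
#' (its effect is still the mean difference) and is flagged. Direction is the
#' sign of the effect with no magnitude cut-off; significance is
#' `adj_p < config$de_adj_p`.
#'
#' Because TPM is compositional, genuinely up-regulated genes depress every
#' other gene's TPM share, which biases null genes away from zero. With
#' `normalize = TRUE` (the default) each sample's log2(TPM + 1) column is
#' median-centered before testing — the log-scale analogue of the size-factor
#' normalisation count-based DE engines apply — which removes that shared
#' compositional shift while leaving two-group contrasts intact.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param meta Sample metadata covering `colnames(tpm)`.
#' @param config A [run_config()].
#' @param normalize Median-center log2(TPM + 1) per sample before testing
#'   (default TRUE); set FALSE to test the raw scale.
#' @param batch_center If TRUE, mean-center log2(TPM + 1) per batch before
#'   testing (off by default; a coarse stand-in for modelling batch).
#' @return data.frame (gene_id, log2fc, p_value, adj_p, direction,
#'   significant, zero_variance), sorted by adj_p, then p, then gene id.
#' @export
builtin_de <- function(tpm, meta, config = run_config(),
                       normalize = TRUE, batch_center = FALSE) {
  stopifnot(inherits(tpm, "expression_matrix"),
            identical(attr(tpm, "unit"), "tpm"))
  meta <- sample_metadata(meta)
  meta <- meta[match(colnames(tpm), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("metadata missing for some samples in the matrix")
  y <- meta$group == "young"
  a <- meta$group == "aging"
  if (sum(y) < 2 || sum(a) < 2)
    stop("both groups need >= 2 samples for the t-test")

  x <- log2(unclass(tpm) + 1)
  if (normalize)
    x <- sweep(x, 2, apply(x, 2, stats::median))
  if (batch_center) {
    for (b in unique(meta$batch)) {
      cols <- meta$batch == b
      x[, cols] <- x[, cols] - rowMeans(x[, cols, drop = FALSE])
    }
  }

  ny <- sum(y); na_ <- sum(a)
  my <- rowMeans(x[, y, drop = FALSE])
  ma <- rowMeans(x[, a, drop = FALSE])
  vy <- apply(x[, y, drop = FALSE], 1, stats::var)
  va <- apply(x[, a, drop = FALSE], 1, stats::var)
  se2 <- vy / ny + va / na_
  tstat <- (ma - my) / sqrt(se2)
  df <- se2^2 / ((vy / ny)^2 / (ny - 1) + (va / na_)^2 / (na_ - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zerovar <- vy == 0 & va == 0
  p[zerovar] <- 1

  adj <- bh_adjust(p)
  out <- data.frame(gene_id = rownames(tpm),
                    log2fc = ma - my,
                    p_value = p,
                    adj_p = adj,
                    direction = ifelse(ma - my > 0, "up", "down"),
                    significant = adj < config$de_adj_p,
                    zero_variance = zerovar,
                    stringsAsFactors = FALSE)
  out[order(out$adj_p, out$p_value, out$gene_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Ingest an externally computed differential-expression table
#'
#' Adapter for result tables from count-based DE engines (e.g. a
#' negative-binomial GLM fit with batch in the model matrix): maps their
#' columns onto the pipeline's record and re-applies the significance and
#' direction rules. Rows with missing adjusted p are kept but marked not
#' significant, with a warning.
#'
#' @param path TSV with columns gene, log2FoldChange, pvalue, padj (names
#'   configurable via `cols`).
#' @param config A [run_config()].
#' @param cols Named character vector mapping the four roles to the file's
#'   header names.
#' @return data.frame in the same shape as [builtin_de()].
#' @export
ingest_external_de <- function(path, config = run_config(),
                               cols = c(gene = "gene",
                                        log2fc = "log2FoldChange",
                                        p = "pvalue", padj = "padj")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(cols), names(df))
  if (length(miss))
    stop("external DE table missing column(s): ", paste(miss, collapse = ", "))
  padj <- df[[cols["padj"]]]
  n_na <- sum(is.na(padj))
  if (n_na > 0)
    warning(n_na, " gene(s) with NA adjusted p treated as not significant")
  lfc <- df[[cols["log2fc"]]]
  out <- data.frame(gene_id = as.character(df[[cols["gene"]]]),
                    log2fc = lfc,
                    p_value = df[[cols["p"]]],
                    adj_p = padj,
                    direction = ifelse(lfc > 0, "up", "down"),
                    significant = !is.na(padj) & padj < config$de_adj_p,
                    zero_variance = FALSE,
                    stringsAsFactors = FALSE)
  out[order(out$adj_p, out$p_value, out$gene_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Significant gene set from a DE table
#' @param de A DE table from [builtin_de()] or [ingest_external_de()].
#' @return Character vector of significant gene ids.
#' @export
de_gene_set <- function(de) sort(de$gene_id[de$significant])
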