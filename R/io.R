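#' Construct and validate an expression matrix
#'
#' The pipeline's substrate is a genes x samples numeric matrix carrying a
#' unit tag (`"tpm"` or `"counts"`). Gene and sample identifiers must be
#' unique, all values finite and non-negative; count matrices must be
#' integer-valued.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit Either `"tpm"` or `"counts"`.
#' @return The validated matrix with a `unit` attribute and class
#'   `"expression_matrix"`.
#' @export
expression_matrix <- function(values, unit = c("tpm", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values in expression matrix")
  if (any(values < 0))
    stop("negative values in expression matrix")
  if (unit == "counts" && any(values != round(values)))
    stop("count matrix contains non-integer values")
  attr(values, "unit") <- unit
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' Accepts a plain tab-separated table (first column gene id, header row of
#' sample ids) or the GCT 1.2 dialect (a `#1.2` line, a dimensions line, then
#' the table with `Name` and `Description` columns).
#'
#' @param path Path to the file.
#' @param unit Unit tag to attach, `"tpm"` or `"counts"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("tpm", "counts")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  gct <- identical(substr(first, 1L, 4L), "#1.2")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          skip = if (gct) 2L else 0L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs at least one sample column")
  gene_ids <- as.character(df[[1L]])
  drop <- 1L
  if (gct && ncol(df) >= 3L && identical(tolower(names(df)[2L]), "description"))
    drop <- c(1L, 2L)
  vals <- df[, -drop, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric expression column(s): ",
         paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  expression_matrix(m, unit)
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"gct"` (adds the 2-line GCT preamble
#'   and a Description column).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  df <- data.frame(gene_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  if (format == "gct") {
    df <- data.frame(Name = rownames(mat), Description = rownames(mat),
                     as.data.frame(unclass(mat)), check.names = FALSE)
    con <- file(path, "w")
    writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Validate a sample metadata table
#'
#' @param meta data.frame with columns `sample_id`, `group`, `tissue`,
#'   `batch`. `group` must be exactly `"young"` or `"aging"`: the design is
#'   strictly two-group (donors between the age cut-offs never enter the
#'   pipeline).
#' @return The validated data.frame.
#' @export
sample_metadata <- function(meta) {
  need <- c("sample_id", "group", "tissue", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  meta$tissue <- as.character(meta$tissue)
  meta$batch <- as.character(meta$batch)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(meta$group), c("young", "aging"))
  if (length(bad))
    stop("group must be 'young' or 'aging'; found: ",
         paste(bad, collapse = ", "))
  meta
}

#' Read / write sample metadata TSV
#' @param path Path to a TSV with columns sample_id, group, tissue, batch.
#' @return Validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param meta Validated metadata.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Houses every printed analysis parameter in one place: the expression
#' filter (median TPM > 5), the edge and gene FDR thresholds (0.05), the
#' dysregulated-node fraction (top 10%), the Single/Some/Many tissue-count
#' boundaries (1 / 2-13 / >= 14), the minimum per-group sample size (strictly
#' more than 10), and the random-forest settings (1000 trees, 70/30
#' stratified split).
#'
#' @param tpm_filter_threshold Median-TPM filter threshold (strict `>`).
#' @param edge_fdr BH q-value cut-off for network edges.
#' @param de_adj_p Adjusted-p cut-off for differential expression.
#' @param dn_fraction Fraction of the gene universe flagged as dysregulated
#'   nodes (ranked by |delta degree|).
#' @param many_min_tissues Minimum tissue count for the "many" category.
#' @param some_min_tissues Minimum tissue count for the "some" category.
#' @param min_samples_per_group A tissue enters the analysis only if both
#'   groups have strictly more than this many samples.
#' @param rf_trees,rf_train_fraction Random-forest size and train split.
#' @param seed Master seed; stage substreams are derived from it.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tpm_filter_threshold = 5,
                       edge_fdr = 0.05,
                       de_adj_p = 0.05,
                       dn_fraction = 0.10,
                       many_min_tissues = 14L,
                       some_min_tissues = 2L,
                       min_samples_per_group = 10L,
                       rf_trees = 1000L,
                       rf_train_fraction = 0.70,
                       seed = 1L) {
  stopifnot(tpm_filter_threshold >= 0,
            edge_fdr > 0, edge_fdr < 1,
            de_adj_p > 0, de_adj_p < 1,
            dn_fraction > 0, dn_fraction <= 1,
            many_min_tissues >= 1, some_min_tissues >= 1,
            some_min_tissues <= many_min_tissues,
            min_samples_per_group >= 1,
            rf_trees >= 1,
            rf_train_fraction > 0, rf_train_fraction < 1)
  structure(list(tpm_filter_threshold = tpm_filter_threshold,
                 edge_fdr = edge_fdr,
                 de_adj_p = de_adj_p,
                 dn_fraction = dn_fraction,
                 many_min_tissues = as.integer(many_min_tissues),
                 some_min_tissues = as.integer(some_min_tissues),
                 min_samples_per_group = as.integer(min_samples_per_group),
                 rf_trees = as.integer(rf_trees),
                 rf_train_fraction = rf_train_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML / flat key-value file
#'
#' Keys mirror the arguments of [run_config()]; keys absent from the file
#' keep their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Per-tissue group-size check
#'
#' A tissue passes only if both the young and the aging group have strictly
#' more than `min_samples_per_group` samples ("more than 10" is taken
#' literally, i.e. >= 11 at the default).
#'
#' @param meta Validated sample metadata (may span several tissues).
#' @param config A [run_config()].
#' @return data.frame with columns tissue, n_young, n_aging, pass.
#' @export
check_group_sizes <- function(meta, config = run_config()) {
  meta <- sample_metadata(meta)
  tissues <- sort(unique(meta$tissue))
  n_young <- vapply(tissues, function(t)
    sum(meta$tissue == t & meta$group == "young"), integer(1))
  n_aging <- vapply(tissues, function(t)
    sum(meta$tissue == t & meta$group == "aging"), integer(1))
  data.frame(tissue = tissues,
             n_young = n_young,
             n_aging = n_aging,
             pass = n_young > config$min_samples_per_group &
                    n_aging > config$min_samples_per_group,
             row.names = NULL)
}

#' Read / write a generic result table (TSV round-trip helpers)
#' @param df data.frame to write.
#' @param path File path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
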