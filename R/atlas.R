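#' Count, per gene, the tissues in which it belongs to a set
#'
#' @param per_tissue_sets Named list: tissue -> character vector of gene ids.
#' @param universe Optional gene universe; genes in no set are reported with
#'   count 0 only when a universe is supplied.
#' @return Named integer vector, gene id -> tissue count.
#' @export
count_tissues <- function(per_tissue_sets, universe = NULL) {
  if (anyDuplicated(names(per_tissue_sets)))
    stop("tissue names must be unique")
  all_genes <- unique(unlist(per_tissue_sets, use.names = FALSE))
  if (!is.null(universe)) all_genes <- union(universe, all_genes)
  all_genes <- sort(all_genes)
  counts <- stats::setNames(integer(length(all_genes)), all_genes)
  for (s in per_tissue_sets) {
    s <- unique(s)
    counts[s] <- counts[s] + 1L
  }
  counts
}

#' Map a tissue count onto the Single / Some / Many categories
#'
#' 0 tissues -> none; exactly 1 -> single; between `some_min_tissues` and
#' `many_min_tissues - 1` -> some; at least `many_min_tissues` -> many.
#' Defaults follow the 1 / 2-13 / >= 14 partition of a ~40-tissue panel.
#'
#' @param count Non-negative integer vector of tissue counts.
#' @param config A [run_config()].
#' @return Character vector of categories.
#' @export
categorize <- function(count, config = run_config()) {
  if (any(count < 0)) stop("counts must be >= 0")
  out <- rep("none", length(count))
  out[count >= 1] <- "single"
  out[count >= config$some_min_tissues] <- "some"
  out[count >= config$many_min_tissues] <- "many"
  out
}

#' Cross-tissue atlas of DEG and DN status
#'
#' Aggregates per-tissue significant-DEG sets and DN sets into one record per
#' gene: tissue counts, Single/Some/Many categories for each analysis, and
#' the core-set flag (DEG in Many AND DN in Many). The universe is every gene
#' ever tested in any tissue (DE) or present in any network (DN).
#'
#' @param deg_sets Named list: tissue -> significant DEG gene ids.
#' @param dn_sets Named list: tissue -> DN gene ids.
#' @param config A [run_config()].
#' @param universe Optional explicit gene universe.
#' @return data.frame (gene_id, n_tissues_deg, deg_category, n_tissues_dn,
#'   dn_category, in_core_set), lexically sorted by gene id.
#' @export
build_atlas <- function(deg_sets, dn_sets, config = run_config(),
                        universe = NULL) {
  if (is.null(universe))
    universe <- sort(unique(c(unlist(deg_sets, use.names = FALSE),
                              unlist(dn_sets, use.names = FALSE))))
  cd <- count_tissues(deg_sets, universe = universe)
  cn <- count_tissues(dn_sets, universe = universe)
  g <- sort(universe)
  ndeg <- ifelse(g %in% names(cd), cd[g], 0L); ndeg[is.na(ndeg)] <- 0L
  ndn <- ifelse(g %in% names(cn), cn[g], 0L); ndn[is.na(ndn)] <- 0L
  deg_cat <- categorize(ndeg, config)
  dn_cat <- categorize(ndn, config)
  data.frame(gene_id = g,
             n_tissues_deg = as.integer(ndeg),
             deg_category = deg_cat,
             n_tissues_dn = as.integer(ndn),
             dn_category = dn_cat,
             in_core_set = deg_cat == "many" & dn_cat == "many",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core biomarker set: DEG in Many intersected with DN in Many
#'
#' @param atlas Output of [build_atlas()].
#' @return Lexically sorted character vector of core genes.
#' @export
core_biomarker_set <- function(atlas) {
  sort(atlas$gene_id[atlas$in_core_set])
}

#' Per-category summary of an atlas
#' @param atlas Output of [build_atlas()].
#' @return List with per-category DEG and DN counts, percentages over
#'   ever-detected genes (count >= 1), and the core-set size.
#' @export
atlas_summary <- function(atlas) {
  lv <- c("none", "single", "some", "many")
  tab <- function(cat, n) {
    cnt <- table(factor(cat, levels = lv))
    det <- sum(n >= 1)
    list(counts = as.list(cnt),
         pct_of_detected = as.list(round(100 * cnt[lv != "none"] /
                                           max(det, 1L), 2)))
  }
  list(n_genes = nrow(atlas),
       deg = tab(atlas$deg_category, atlas$n_tissues_deg),
       dn = tab(atlas$dn_category, atlas$n_tissues_dn),
       core_set_size = sum(atlas$in_core_set))
}
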