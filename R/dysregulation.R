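#' Change in positive-edge degree between the young and aging networks
#'
#' The gene universe is the union of the two networks' node sets; a gene
#' absent from one network contributes degree 0 there (it did not pass that
#' condition's expression filter, so it has no significant positive edges).
#' Delta is aging minus young.
#'
#' @param net_young,net_aging `"coexpression_network"` objects for the same
#'   tissue.
#' @return data.frame (gene_id, degree_young, degree_aging, delta, abs_delta)
#'   over the union universe, unranked.
#' @export
delta_degree <- function(net_young, net_aging) {
  ty <- net_young$condition$tissue; ta <- net_aging$condition$tissue
  if (!is.na(ty) && !is.na(ta) && !identical(ty, ta))
    stop("networks come from different tissues: ", ty, " vs ", ta)
  universe <- sort(union(net_young$nodes, net_aging$nodes))
  if (length(universe) == 0) stop("both networks are empty")
  if (length(intersect(net_young$nodes, net_aging$nodes)) == 0 &&
      length(net_young$nodes) > 0 && length(net_aging$nodes) > 0)
    warning("young and aging node sets are disjoint; expression filter may ",
            "be unstable for this tissue")
  dy <- ifelse(universe %in% names(net_young$degree),
               net_young$degree[universe], 0L)
  da <- ifelse(universe %in% names(net_aging$degree),
               net_aging$degree[universe], 0L)
  dy[is.na(dy)] <- 0L; da[is.na(da)] <- 0L
  data.frame(gene_id = universe,
             degree_young = as.integer(dy),
             degree_aging = as.integer(da),
             delta = as.integer(da - dy),
             abs_delta = as.integer(abs(da - dy)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the most dysregulated nodes
#'
#' Ranks genes by |delta degree| descending (ties broken by lexical gene id)
#' and flags the top `ceiling(dn_fraction * N)` as dysregulated nodes.
#' Ranking by the absolute change counts connectivity gains and losses alike;
#' the signed delta stays in the record.
#'
#' @param records Output of [delta_degree()].
#' @param dn_fraction Fraction in (0, 1\]; default 0.10 (the top 10%).
#' @return The records with `rank` (1 = most dysregulated) and `is_dn` added,
#'   sorted by rank.
#' @export
select_dns <- function(records, dn_fraction = 0.10) {
  if (!(dn_fraction > 0 && dn_fraction <= 1))
    stop("dn_fraction must lie in (0, 1]")
  n <- nrow(records)
  if (n < 1) stop("no records")
  o <- order(-records$abs_delta, records$gene_id)
  records <- records[o, , drop = FALSE]
  records$rank <- seq_len(n)
  records$is_dn <- records$rank <= ceiling(dn_fraction * n)
  rownames(records) <- NULL
  records
}

#' One-call per-tissue dysregulation table
#'
#' @param net_young,net_aging Condition networks of one tissue.
#' @param config A [run_config()] (supplies `dn_fraction`).
#' @return Ranked dysregulation table; see [delta_degree()] and
#'   [select_dns()].
#' @export
dysregulation_table <- function(net_young, net_aging, config = run_config()) {
  select_dns(delta_degree(net_young, net_aging),
             dn_fraction = config$dn_fraction)
}

#' Dysregulated-node gene set from a ranked table
#' @param dn A table from [select_dns()].
#' @return Sorted character vector of DN gene ids.
#' @export
dn_gene_set <- function(dn) sort(dn$gene_id[dn$is_dn])
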