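# DEG selection: threshold filtering, duplicate-symbol removal, and the
# split into disjoint up- and down-regulated gene sets.

#' Filter a DEG table by significance and fold-change thresholds
#'
#' Retains exactly the rows with `p <= p_threshold` and
#' `|log_fc| >= lfc_threshold` (both boundaries inclusive). By default the
#' adjusted (FDR) p value is used; set `use_adjusted_p = FALSE` to filter on
#' the raw p value instead.
#'
#' @param table a [deg_table()].
#' @param p_threshold significance threshold, default 0.005.
#' @param lfc_threshold absolute log2-fold-change threshold, default 1.5.
#' @param use_adjusted_p logical; filter on `adj_p_value` (default) or
#'   `p_value`.
#' @return The filtered `deg_table` (possibly empty).
#' @export
filter_degs <- function(table, p_threshold = 0.005, lfc_threshold = 1.5,
                        use_adjusted_p = TRUE) {
  stopifnot(p_threshold > 0, lfc_threshold > 0)
  p <- if (use_adjusted_p) table$adj_p_value else table$p_value
  keep <- p <= p_threshold & abs(table$log_fc) >= lfc_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Collapse duplicate gene symbols in a DEG table
#'
#' Keeps one record per gene symbol. Under the default `min_p` policy the
#' record with the smallest (chosen) p value survives; ties are broken by
#' larger `|log_fc|`, then by lexicographic `probe_id`. Under `max_abs_lfc`
#' the record with the largest `|log_fc|` survives, ties broken by smaller
#' p then `probe_id`.
#'
#' @param table a [deg_table()].
#' @param policy `"min_p"` (default) or `"max_abs_lfc"`.
#' @param use_adjusted_p logical; which p value the policy compares.
#' @return A `deg_table` with unique `gene_symbol`s, in original row order.
#' @export
deduplicate_degs <- function(table, policy = c("min_p", "max_abs_lfc"),
                             use_adjusted_p = TRUE) {
  policy <- match.arg(policy)
  if (nrow(table) == 0) return(table)
  p <- if (use_adjusted_p) table$adj_p_value else table$p_value
  ord <- switch(policy,
    min_p      = order(table$gene_symbol, p, -abs(table$log_fc), table$probe_id),
    max_abs_lfc = order(table$gene_symbol, -abs(table$log_fc), p, table$probe_id)
  )
  first <- !duplicated(table$gene_symbol[ord])
  out <- table[sort(ord[first]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Partition a deduplicated DEG table by regulation direction
#'
#' Genes with negative `log_fc` are down-regulated, genes with positive
#' `log_fc` up-regulated. The two sets are disjoint by construction; a
#' `log_fc` of exactly zero cannot occur after [filter_degs()] (it requires
#' `|log_fc| >= lfc_threshold > 0`) and is rejected here.
#'
#' @param table a deduplicated [deg_table()].
#' @return An object of class `gene_partition`: list with character vectors
#'   `up` and `down` in table order.
#' @export
partition_by_regulation <- function(table) {
  if (anyDuplicated(table$gene_symbol)) {
    stop("table contains duplicate gene symbols; run deduplicate_degs() first")
  }
  if (any(table$log_fc == 0)) {
    stop("log_fc of exactly 0 cannot be classified; filter the table first")
  }
  structure(
    list(up = table$gene_symbol[table$log_fc > 0],
         down = table$gene_symbol[table$log_fc < 0]),
    class = "gene_partition"
  )
}
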