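# Hypergeometric over-representation analysis with Benjamini-Hochberg and
# Bonferroni correction and deterministic ranking.

#' Upper-tail hypergeometric p value
#'
#' Probability of observing `k` or more list genes inside a pathway of
#' size `K`, for a list of size `n` drawn from a universe of size `N`
#' (the observed overlap is included in the tail, the standard
#' over-representation convention). `k = 0` returns 1.
#'
#' @param k observed overlap.
#' @param n gene-list size.
#' @param K pathway size in the universe.
#' @param N universe size.
#' @return The p value `P[X >= k]`.
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers")
  }
  if (n > N || K > N || k > min(n, K)) {
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway over-representation analysis
#'
#' Tests every pathway with at least one member in the universe for
#' over-representation of the input gene list. The universe defaults to
#' all genes annotated to any pathway; an optional `background` (e.g. the
#' genes present on the array) is intersected with that universe first.
#' Raw p values are corrected by Benjamini-Hochberg step-up (`fdr`) and
#' Bonferroni (`bonferroni`) over all tested pathways. Rows are ranked by
#' ascending p, ties broken by descending overlap then pathway id.
#'
#' @param genes character vector of gene symbols.
#' @param db a [pathway_db()].
#' @param background optional character vector restricting the universe.
#' @param min_pathway_size,max_pathway_size pathway-size bounds (in the
#'   restricted universe) for a pathway to be tested; defaults 1 and `Inf`.
#' @return A data frame of class `enrichment_table` with columns
#'   `pathway_id`, `pathway_name`, `overlap_k`, `pathway_size_K`,
#'   `list_size_n`, `universe_N`, `p_value`, `fdr`, `bonferroni`.
#' @export
enrich <- function(genes, db, background = NULL,
                   min_pathway_size = 1, max_pathway_size = Inf) {
  stopifnot(inherits(db, "pathway_db"))
  universe <- db$universe
  if (!is.null(background)) {
    universe <- intersect(unique(norm_symbol(background)), universe)
    if (length(universe) == 0) {
      stop("background shares no genes with the pathway universe")
    }
  }
  gl <- intersect(unique(norm_symbol(genes)), universe)
  if (length(gl) == 0) {
    stop("no input genes fall inside the pathway universe")
  }
  N <- length(universe)
  n <- length(gl)
  rows <- lapply(names(db$sets), function(id) {
    members <- intersect(db$sets[[id]], universe)
    K <- length(members)
    if (K < max(1, min_pathway_size) || K > max_pathway_size) return(NULL)
    k <- length(intersect(gl, members))
    data.frame(pathway_id = id,
               pathway_name = unname(db$names[[id]]),
               overlap_k = k, pathway_size_K = K,
               list_size_n = n, universe_N = N,
               p_value = hypergeom_pvalue(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no pathway has members in the restricted universe")
  }
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$bonferroni <- stats::p.adjust(out$p_value, method = "bonferroni")
  out <- out[order(out$p_value, -out$overlap_k, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
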