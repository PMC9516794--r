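# Independent oracles and tiny fixture builders shared across tests.

# Classical tie-corrected Kruskal-Wallis statistic:
# H = [12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)] / [1 - sum(t^3 - t)/(N^3 - N)].
# Independent of the package's variance-of-ranks implementation.
kw_oracle_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  n <- lengths(groups)
  idx <- rep.int(seq_along(groups), n)
  R <- vapply(split(r, idx), sum, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) 0 else H / C
}

# Exact upper-tail hypergeometric probability by enumeration of all
# C(N, n) equally likely draws.
hyper_oracle <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)      # marked elements are 1..K
  mean(overlap >= k)
}

# Small named undirected graph from a flat vector of endpoint pairs,
# with optional isolated vertices.
tiny_graph <- function(edges, isolated = character(0)) {
  g <- if (length(edges)) {
    igraph::make_graph(edges, directed = FALSE)
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# Minimal valid DEG table from parallel vectors.
make_degs <- function(symbols, lfc, adj_p = rep(1e-4, length(symbols)),
                      p = adj_p / 2, probe = NULL) {
  if (is.null(probe)) probe <- sprintf("probe%02d", seq_along(symbols))
  deg_table(probe, symbols, p, adj_p, lfc)
}

# A small enrichment-like table for compare_enrichments tests.
fake_enrichment <- function(ids, p) {
  n <- length(ids)
  structure(
    data.frame(pathway_id = ids, pathway_name = ids,
               overlap_k = rev(seq_len(n)), pathway_size_K = rep(10L, n),
               list_size_n = rep(5L, n), universe_N = rep(100L, n),
               p_value = p, fdr = pmin(1, p * 2), bonferroni = pmin(1, p * 3),
               stringsAsFactors = FALSE),
    class = c("enrichment_table", "data.frame")
  )
}
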