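# Conversion of similarity matrices to networks and extraction of the
# per-branch essential gene sets by the closeness-centrality rule.

#' Convert a similarity matrix to a gene network
#'
#' Nodes are the matrix genes (isolated ones included); an edge connects
#' two genes when their similarity cell is nonzero, i.e. the Kruskal-Wallis
#' p value reached the similarity threshold. The p value is kept as the
#' edge weight.
#'
#' @param sm a [similarity_matrix()].
#' @return An undirected [igraph::graph] with vertex names and edge weights.
#' @export
to_network <- function(sm) {
  stopifnot(inherits(sm, "similarity_matrix"))
  igraph::graph_from_adjacency_matrix(sm$cells, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Component-scaled closeness centrality
#'
#' Closeness measures how near a node is to every other node: the inverse
#' of its average shortest-path (hop) distance. Similarity networks are
#' frequently disconnected, so the Wasserman-Faust component scaling is
#' used: for node `v` in a component of size `n_v` within a graph of `n`
#' nodes,
#' \deqn{CC(v) = \frac{n_v - 1}{\sum_u d(v, u)} \cdot \frac{n_v - 1}{n - 1},}
#' which keeps scores on one comparable scale so a single global average is
#' meaningful. Isolated nodes score 0. Distances are unweighted hop counts.
#'
#' @param net an undirected [igraph::graph] with vertex names.
#' @return An object of class `centrality_scores`: list with `scores`
#'   (named numeric, every node scored) and `average` (their arithmetic
#'   mean).
#' @export
closeness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) {
    return(structure(list(scores = stats::setNames(numeric(0), character(0)),
                          average = NaN),
                     class = "centrality_scores"))
  }
  nm <- igraph::V(net)$name
  if (n == 1) {
    scores <- stats::setNames(0, nm)
  } else {
    d <- igraph::distances(net, weights = NA)
    reach <- is.finite(d)
    n_v <- rowSums(reach)               # component size (self included)
    sumd <- rowSums(ifelse(reach, d, 0))
    scores <- ifelse(n_v > 1,
                     ((n_v - 1) / sumd) * ((n_v - 1) / (n - 1)),
                     0)
    names(scores) <- nm
  }
  structure(list(scores = scores, average = mean(scores)),
            class = "centrality_scores")
}

#' Select essential genes by the closeness rule
#'
#' Keeps the nodes whose closeness centrality is less than or equal to the
#' network-average closeness. Note this retains the peripheral (low
#' closeness) side of the network; `invert_cc_rule = TRUE` flips the
#' comparison to `>=` for sensitivity analysis.
#'
#' @param net the [igraph::graph] the scores were computed on.
#' @param scores a [closeness_centrality()] result covering `net`'s nodes.
#' @param regulation optional branch label (`"up"`/`"down"`) carried along.
#' @param invert_cc_rule logical, default `FALSE`.
#' @return An object of class `essential_genes`: list with `genes`,
#'   `regulation` and `provenance`.
#' @export
select_essential <- function(net, scores, regulation = NA_character_,
                             invert_cc_rule = FALSE) {
  stopifnot(inherits(scores, "centrality_scores"))
  nm <- igraph::V(net)$name
  if (!all(nm %in% names(scores$scores))) {
    stop("scores do not cover every network node")
  }
  s <- scores$scores[nm]
  sel <- if (invert_cc_rule) s >= scores$average else s <= scores$average
  structure(
    list(genes = nm[sel],
         regulation = regulation,
         provenance = sprintf("closeness %s average (%.6g)",
                              if (invert_cc_rule) ">=" else "<=",
                              scores$average)),
    class = "essential_genes"
  )
}
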