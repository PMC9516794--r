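# Mapping essential genes onto the protein-protein interaction network,
# radius-1 community expansion, and relevant-gene selection by bottleneck
# centrality.

#' Map a gene set onto the PPI network
#'
#' Genes absent from the interaction network carry no topological
#' information and are filtered out before neighborhood expansion.
#'
#' @param genes character vector or an `essential_genes` object.
#' @param ppi an undirected [igraph::graph] with vertex names.
#' @return List with `mapped` (genes present in the PPI) and `unmapped`.
#' @export
map_to_ppi <- function(genes, ppi) {
  if (inherits(genes, "essential_genes")) genes <- genes$genes
  genes <- norm_symbol(genes)
  nodes <- igraph::V(ppi)$name
  list(mapped = genes[genes %in% nodes],
       unmapped = genes[!genes %in% nodes])
}

#' Expand seed genes to their PPI neighborhood community
#'
#' Members are all nodes within hop distance `radius` (default 1) of any
#' seed, seeds included; the community subgraph is the PPI subgraph induced
#' on the members. Similar genes tend to interact to complete biological
#' tasks, so the neighborhood surfaces additional relevant genes beyond
#' the seeds themselves.
#'
#' @param ppi an undirected [igraph::graph] with vertex names.
#' @param seeds character vector of seed genes; every seed must be a PPI
#'   node (use [map_to_ppi()] first).
#' @param radius non-negative integer, default 1.
#' @param regulation optional branch label carried along.
#' @return An object of class `gene_community`: list with `seeds`,
#'   `members` (sorted), `subgraph` and `regulation`.
#' @export
ppi_neighborhood <- function(ppi, seeds, radius = 1,
                             regulation = NA_character_) {
  stopifnot(radius >= 0)
  seeds <- norm_symbol(seeds)
  if (length(seeds) == 0) stop("no seed genes supplied")
  missing <- setdiff(seeds, igraph::V(ppi)$name)
  if (length(missing)) {
    stop("seed genes absent from the PPI network: ",
         paste(missing, collapse = ", "), "; run map_to_ppi() first")
  }
  nb <- igraph::ego(ppi, order = radius, nodes = seeds)
  members <- sort(unique(c(seeds, unlist(lapply(nb, names)))))
  structure(
    list(seeds = seeds,
         members = members,
         subgraph = igraph::induced_subgraph(ppi, members),
         regulation = regulation),
    class = "gene_community"
  )
}

#' Bottleneck centrality
#'
#' Shortest-path-tree load score in the cytoHubba "BottleNeck" style. For
#' every root `s`, a deterministic BFS shortest-path tree `T_s` is grown
#' over `s`'s connected component, expanding neighbors in lexicographic
#' symbol order so parents (and hence subtree sizes) are reproducible. A
#' node `v != s` earns one point from root `s` when the number of nodes
#' whose tree path from `s` passes through or ends at `v` (the size of
#' `v`'s subtree) exceeds a quarter of the tree's node count; the root
#' earns nothing from its own tree. The score of `v` is its total points
#' over all roots.
#'
#' @param g an undirected [igraph::graph] with vertex names.
#' @return Named integer vector of scores, one per node.
#' @export
bottleneck_centrality <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  # adjacency lists with neighbors pre-sorted by symbol
  rk <- rank(nm, ties.method = "first")
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), function(v) {
    idx <- as.integer(v)
    idx[order(rk[idx])]
  })
  bn <- integer(n)
  parent <- integer(n)
  visited <- integer(n)
  dist <- integer(n)
  for (s in seq_len(n)) {
    dist[] <- -1L
    dist[s] <- 0L
    visited[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- visited[head]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          tail <- tail + 1L
          visited[tail] <- w
        }
      }
      head <- head + 1L
    }
    nt <- tail                       # tree size, root included
    if (nt > 1L) {
      size <- integer(n)
      size[visited[seq_len(nt)]] <- 1L
      for (k in seq.int(nt, 2L)) {   # reverse BFS order: children first
        v <- visited[k]
        size[parent[v]] <- size[parent[v]] + size[v]
      }
      thr <- nt / 4
      scored <- visited[2:nt]
      scored <- scored[size[scored] > thr]
      bn[scored] <- bn[scored] + 1L
    }
  }
  stats::setNames(bn, nm)
}

#' Select relevant genes by the bottleneck rule
#'
#' Scores are computed on the community's induced subgraph and averaged
#' over all community members; the genes with a score strictly greater
#' than the average are selected. When the strict set is empty (all scores
#' equal, e.g. a union of symmetric components) the rule falls back to
#' `>=` so the pipeline never silently empties; the fallback is recorded
#' and messaged.
#'
#' @param community a [ppi_neighborhood()] result.
#' @return An object of class `relevant_genes`: list with `genes`,
#'   `regulation`, `bottleneck_scores`, `average_bottleneck` and
#'   `fallback` (logical).
#' @export
select_relevant <- function(community) {
  stopifnot(inherits(community, "gene_community"))
  if (length(community$members) == 0) stop("community is empty")
  bn <- bottleneck_centrality(community$subgraph)
  avg <- mean(bn)
  genes <- names(bn)[bn > avg]
  fallback <- FALSE
  if (length(genes) == 0) {
    fallback <- TRUE
    genes <- names(bn)[bn >= avg]
    message("bottleneck selection: all scores equal the average; ",
            "falling back to >= and keeping ", length(genes), " genes")
  }
  structure(
    list(genes = genes,
         regulation = community$regulation,
         bottleneck_scores = bn,
         average_bottleneck = avg,
         fallback = fallback),
    class = "relevant_genes"
  )
}
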