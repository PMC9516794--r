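# Deterministic synthetic study generator. Plants one up- and one
# down-regulated co-expressed gene module inside an otherwise flat
# expression matrix, a matching DEG table, a scale-free PPI containing the
# module genes, and a pathway collection whose first pathway holds the
# planted modules. Every generator is a pure function of its seed and
# parameters, so end-to-end recovery is testable offline.

#' Define the planted ground truth for a synthetic study
#'
#' @param seed integer seed driving every downstream generator.
#' @param n_genes total number of genes, default 300.
#' @param module_size genes per planted module (one up, one down),
#'   default 25.
#' @param effect_size case-vs-control shift of module genes in log2 units,
#'   default 3.
#' @param noise_sd per-observation technical noise standard deviation,
#'   default 0.2.
#' @param factor_sd standard deviation of the per-sample latent factor
#'   shared by all genes of one module, default 1. This is what makes
#'   module members co-behave: the factor dominates the technical noise,
#'   so two module genes have nearly identical value distributions and a
#'   high Kruskal-Wallis similarity p value.
#' @param baseline baseline log2 expression, default 7.
#' @param planted_pathway_id id of the pathway that will contain the
#'   module genes.
#' @return An object of class `planted_truth` holding the gene universe,
#'   the two disjoint module gene sets and all generator parameters.
#' @export
planted_truth <- function(seed, n_genes = 300, module_size = 25,
                          effect_size = 3, noise_sd = 0.2, factor_sd = 1,
                          baseline = 7, planted_pathway_id = "PW_PLANTED") {
  stopifnot(2 * module_size <= n_genes, module_size >= 1,
            noise_sd > 0, factor_sd >= 0)
  genes <- sprintf("G%04d", seq_len(n_genes))
  structure(
    list(genes = genes,
         up_module = genes[seq_len(module_size)],
         down_module = genes[module_size + seq_len(module_size)],
         planted_pathway_id = planted_pathway_id,
         seed = as.integer(seed),
         effect_size = effect_size,
         noise_sd = noise_sd,
         factor_sd = factor_sd,
         baseline = baseline),
    class = "planted_truth"
  )
}

#' Simulate an expression matrix with planted modules
#'
#' Background genes are i.i.d. Normal(baseline, noise_sd) in every sample.
#' Up-module genes additionally receive a per-sample latent factor shared
#' across the module (all samples) and a `+effect_size` shift in cases;
#' the down module receives its own latent factor and a `-effect_size`
#' shift in cases. Deterministic given `truth$seed`.
#'
#' @param truth a [planted_truth()].
#' @param n_case,n_control samples per group, defaults 10 and 10.
#' @return An [expr_set()] with samples named `case_*` and `ctrl_*`.
#' @export
simulate_expression <- function(truth, n_case = 10, n_control = 10) {
  stopifnot(inherits(truth, "planted_truth"), n_case >= 2, n_control >= 2)
  ns <- n_case + n_control
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                            samples)
  withr::with_seed(truth$seed, {
    vals <- matrix(stats::rnorm(length(truth$genes) * ns,
                                truth$baseline, truth$noise_sd),
                   nrow = length(truth$genes), ncol = ns,
                   dimnames = list(truth$genes, samples))
    f_up <- stats::rnorm(ns, 0, truth$factor_sd)
    f_down <- stats::rnorm(ns, 0, truth$factor_sd)
    vals[truth$up_module, ] <-
      vals[truth$up_module, ] + rep(f_up, each = length(truth$up_module))
    vals[truth$down_module, ] <-
      vals[truth$down_module, ] + rep(f_down, each = length(truth$down_module))
    case_cols <- seq_len(n_case)
    vals[truth$up_module, case_cols] <-
      vals[truth$up_module, case_cols] + truth$effect_size
    vals[truth$down_module, case_cols] <-
      vals[truth$down_module, case_cols] - truth$effect_size
    expr_set(vals, groups)
  })
}

# Vectorized per-gene Welch two-sample t test; returns two-sided p values.
welch_p <- function(case_mat, ctrl_mat) {
  n1 <- ncol(case_mat); n2 <- ncol(ctrl_mat)
  m1 <- rowMeans(case_mat); m2 <- rowMeans(ctrl_mat)
  v1 <- rowSums((case_mat - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl_mat - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

#' Derive a GEO2R-style DEG table from a simulated expression matrix
#'
#' Per gene: Welch two-sample t test of case vs control values (two-sided),
#' Benjamini-Hochberg adjusted p, and `log_fc` = mean(case) - mean(control)
#' (the matrix is already on the log2 scale). The result has the schema the
#' pipeline consumes, regardless of how a real study would have produced it.
#'
#' @param expr an [expr_set()] from [simulate_expression()].
#' @return A [deg_table()] with one row per gene.
#' @export
simulate_deg_table <- function(expr) {
  stopifnot(inherits(expr, "expr_set"))
  case_mat <- expr$values[, expr$groups == "case", drop = FALSE]
  ctrl_mat <- expr$values[, expr$groups == "control", drop = FALSE]
  p <- welch_p(case_mat, ctrl_mat)
  lfc <- rowMeans(case_mat) - rowMeans(ctrl_mat)
  deg_table(probe_id = paste0(rownames(expr$values), "_at"),
            gene_symbol = rownames(expr$values),
            p_value = pmax(p, .Machine$double.xmin),
            adj_p_value = pmax(stats::p.adjust(p, "BH"), .Machine$double.xmin),
            log_fc = lfc)
}

#' Simulate a scale-free PPI network containing the planted modules
#'
#' A preferential-attachment (Barabasi-Albert) graph over the whole gene
#' universe, with gene symbols assigned to vertices in a seeded random
#' permutation. Each planted module is then wired as a chain through its
#' genes (so the module is connected) and its first gene is attached to
#' the highest-degree hub of the graph.
#'
#' @param truth a [planted_truth()].
#' @param attach_m edges added per vertex during preferential attachment,
#'   default 2.
#' @param seed integer seed, default `truth$seed + 1`.
#' @return An undirected simple [igraph::graph] over all genes.
#' @export
simulate_ppi <- function(truth, attach_m = 2, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "planted_truth"),
            attach_m >= 1, length(truth$genes) > attach_m)
  withr::with_seed(seed, {
    g <- igraph::sample_pa(length(truth$genes), m = attach_m,
                           directed = FALSE)
    igraph::V(g)$name <- sample(truth$genes)
    hub <- igraph::V(g)$name[which.max(igraph::degree(g))]
    extra <- character(0)
    for (module in list(truth$up_module, truth$down_module)) {
      if (length(module) > 1) {
        extra <- c(extra, rbind(module[-length(module)], module[-1]))
      }
      extra <- c(extra, module[1], hub)
    }
    g <- igraph::add_edges(g, extra)
    igraph::simplify(g)
  })
}

#' Simulate a pathway collection with one planted pathway
#'
#' The planted pathway contains every module gene plus `n_decoy_members`
#' random non-module genes; the remaining pathways are random draws from
#' the non-module genes with sizes uniform in `size_range`.
#'
#' @param truth a [planted_truth()].
#' @param n_pathways total number of pathways, default 50.
#' @param size_range integer range of decoy-pathway sizes, default
#'   `c(10, 40)`.
#' @param n_decoy_members non-module genes added to the planted pathway,
#'   default 10.
#' @param seed integer seed, default `truth$seed + 2`.
#' @return A [pathway_db()].
#' @export
simulate_pathways <- function(truth, n_pathways = 50, size_range = c(10, 40),
                              n_decoy_members = 10, seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "planted_truth"), n_pathways >= 2)
  nonmodule <- setdiff(truth$genes, c(truth$up_module, truth$down_module))
  # clamp to what the gene universe can supply (small fixtures)
  size_range <- pmin(pmax(size_range, 1), length(nonmodule))
  n_decoy_members <- min(n_decoy_members, length(nonmodule))
  withr::with_seed(seed, {
    sets <- vector("list", n_pathways)
    nms <- character(n_pathways)
    sets[[1]] <- c(truth$up_module, truth$down_module,
                   sample(nonmodule, n_decoy_members))
    nms[1] <- truth$planted_pathway_id
    for (i in seq.int(2, n_pathways)) {
      size <- sample(seq.int(size_range[1], size_range[2]), 1)
      sets[[i]] <- sample(nonmodule, size)
      nms[i] <- sprintf("PW_%04d", i)
    }
    names(sets) <- nms
    pathway_db(sets, stats::setNames(
      c("Planted module pathway",
        sprintf("Decoy pathway %d", seq.int(2, n_pathways))), nms))
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing every pipeline input from one seed:
#' expression matrix, DEG table, PPI network and pathway collection, plus
#' the planted truth.
#'
#' @param seed integer seed.
#' @param n_case,n_control samples per group, defaults 10 and 10.
#' @param n_pathways number of pathways, default 50.
#' @param ... further arguments passed to [planted_truth()].
#' @return List with elements `truth`, `expr`, `deg`, `ppi`, `pathways`.
#' @export
simulate_study <- function(seed, n_case = 10, n_control = 10,
                           n_pathways = 50, ...) {
  truth <- planted_truth(seed, ...)
  expr <- simulate_expression(truth, n_case, n_control)
  list(truth = truth,
       expr = expr,
       deg = simulate_deg_table(expr),
       ppi = simulate_ppi(truth),
       pathways = simulate_pathways(truth, n_pathways = n_pathways))
}

#' Write a simulated study to disk
#'
#' Writes the five pipeline input files into `dir`: `expression.tsv`,
#' `groups.tsv`, `deg.tsv` (GEO2R-style column names), `ppi.tsv`,
#' `pathways.gmt`, plus `truth.json` describing the planted structure.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the written file paths.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             groups = file.path(dir, "groups.tsv"),
             deg = file.path(dir, "deg.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.json"))
  expr_df <- data.frame(gene = rownames(sim$expr$values),
                        sim$expr$values, check.names = FALSE)
  utils::write.table(expr_df, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$expr$groups),
               group = unname(sim$expr$groups)),
    paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
  deg_out <- data.frame(ID = sim$deg$probe_id,
                        "Gene.symbol" = sim$deg$gene_symbol,
                        "P.Value" = sim$deg$p_value,
                        "adj.P.Val" = sim$deg$adj_p_value,
                        logFC = sim$deg$log_fc, check.names = FALSE)
  utils::write.table(deg_out, paths["deg"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ppi_edgelist(sim$ppi, paths["ppi"])
  write_gmt(sim$pathways, paths["gmt"])
  jsonlite::write_json(
    list(seed = sim$truth$seed,
         up_module = sim$truth$up_module,
         down_module = sim$truth$down_module,
         planted_pathway_id = sim$truth$planted_pathway_id,
         effect_size = sim$truth$effect_size,
         noise_sd = sim$truth$noise_sd,
         factor_sd = sim$truth$factor_sd),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
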