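# Readers and writers for the external formats the pipeline touches:
# GEO2R-style DEG tables, expression matrices with sample groups, IID-style
# PPI edge lists, GMT pathway collections and the enrichment output TSV.
# All joins across files are on uppercase-trimmed gene symbols.

#' Construct a DEG table
#'
#' Validates and normalizes a data frame of per-gene differential-expression
#' records. Used by [read_deg_table()] and [simulate_deg_table()].
#'
#' @param probe_id character probe/row identifiers.
#' @param gene_symbol character gene symbols (uppercased and trimmed).
#' @param p_value,adj_p_value numeric p values in (0, 1].
#' @param log_fc numeric log2 fold changes, finite.
#' @return A data frame of class `deg_table` with the five columns above.
#' @export
deg_table <- function(probe_id, gene_symbol, p_value, adj_p_value, log_fc) {
  df <- data.frame(
    probe_id    = as.character(probe_id),
    gene_symbol = norm_symbol(gene_symbol),
    p_value     = as.numeric(p_value),
    adj_p_value = as.numeric(adj_p_value),
    log_fc      = as.numeric(log_fc),
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(df$gene_symbol) |
    !is.finite(df$p_value) | df$p_value <= 0 | df$p_value > 1 |
    !is.finite(df$adj_p_value) | df$adj_p_value <= 0 | df$adj_p_value > 1 |
    !is.finite(df$log_fc)
  if (any(bad)) {
    stop("invalid DEG records at rows: ", paste(which(bad), collapse = ", "))
  }
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Read a GEO2R-style differential-expression table
#'
#' Expects a tab-separated file with a header row. Default column names
#' follow the GEO2R export ("Gene.symbol", "P.Value", "adj.P.Val", "logFC",
#' plus an optional probe "ID" column); `column_map` overrides any of them.
#' Rows with a blank gene symbol or unparseable p value / adjusted p value /
#' logFC are dropped and counted in the load report attached as attribute
#' `"load_report"`.
#'
#' @param path path to the TSV file.
#' @param column_map optional named character vector remapping any of
#'   `probe_id`, `gene_symbol`, `p_value`, `adj_p_value`, `log_fc` to the
#'   column names used in the file.
#' @return A `deg_table` with attribute `load_report`, a list with elements
#'   `n_input`, `n_kept` and `n_dropped`.
#' @export
read_deg_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cm <- c(probe_id = "ID", gene_symbol = "Gene.symbol",
          p_value = "P.Value", adj_p_value = "adj.P.Val", log_fc = "logFC")
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0 && ncol(raw) <= 1) stop("DEG table format error: empty file")
  for (f in c("gene_symbol", "p_value", "adj_p_value", "log_fc")) {
    if (!cm[[f]] %in% names(raw)) {
      stop("DEG table format error: missing required column: ", cm[[f]])
    }
  }
  probe <- if (cm[["probe_id"]] %in% names(raw)) {
    as.character(raw[[cm[["probe_id"]]]])
  } else {
    as.character(seq_len(nrow(raw)))
  }
  sym <- norm_symbol(raw[[cm[["gene_symbol"]]]])
  p   <- suppressWarnings(as.numeric(raw[[cm[["p_value"]]]]))
  ap  <- suppressWarnings(as.numeric(raw[[cm[["adj_p_value"]]]]))
  lfc <- suppressWarnings(as.numeric(raw[[cm[["log_fc"]]]]))
  keep <- nzchar(sym) & !is.na(sym) &
    is.finite(p) & p > 0 & p <= 1 &
    is.finite(ap) & ap > 0 & ap <= 1 &
    is.finite(lfc)
  keep[is.na(keep)] <- FALSE
  out <- deg_table(probe[keep], sym[keep], p[keep], ap[keep], lfc[keep])
  attr(out, "load_report") <- list(
    n_input = nrow(raw), n_kept = sum(keep), n_dropped = sum(!keep)
  )
  out
}

#' Construct an expression set
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames), log2 scale.
#' @param groups named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `groups`.
#' @export
expr_set <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("expression matrix must have unique gene rownames")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("expression matrix must have unique sample colnames")
  }
  groups <- vapply(groups, as.character, character(1))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  structure(list(values = values, groups = groups), class = "expr_set")
}

#' Read an expression matrix with sample groups
#'
#' The matrix file is a TSV whose header row holds sample ids and whose
#' first column holds gene identifiers. The groups file is a two-column TSV
#' (`sample_id`, `group`) mapping every sample to `case` or `control`.
#' Duplicate gene rows are collapsed by keeping the row with maximal
#' variance across samples (deterministic, favours informative probes);
#' the number of collapsed rows is recorded in the `load_report` attribute.
#'
#' @param path path to the expression TSV.
#' @param groups_path path to the sample-group TSV.
#' @return An [expr_set()] with attribute `load_report`.
#' @export
read_expression_matrix <- function(path, groups_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- norm_symbol(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  grp <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(grp) < 2) stop("groups file must have two columns: sample_id, group")
  glab <- tolower(trimws(grp[[2]]))
  names(glab) <- as.character(grp[[1]])
  offenders <- setdiff(colnames(mat), names(glab))
  if (length(offenders)) {
    stop("samples missing from groups file: ", paste(offenders, collapse = ", "))
  }
  n_dup <- 0L
  if (anyDuplicated(genes)) {
    v <- apply(mat, 1, stats::var)
    ord <- order(genes, -v)       # within a symbol, highest variance first
    first <- !duplicated(genes[ord])
    n_dup <- sum(!first)
    keep <- sort(ord[first])      # preserve original row order
    mat <- mat[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(mat) <- genes
  out <- expr_set(mat, glab)
  attr(out, "load_report") <- list(
    n_genes = nrow(mat), n_samples = ncol(mat),
    n_duplicates_collapsed = n_dup,
    duplicate_policy = "max_variance"
  )
  out
}

#' Read a tab-delimited protein-protein interaction edge list
#'
#' Expects a header row followed by lines with at least two tab-separated
#' gene symbols and an optional third numeric confidence column. Self loops
#' and duplicate (also reversed) pairs are removed; symbols are uppercased.
#'
#' @param path path to the edge-list TSV.
#' @param min_confidence optional numeric; if given and a confidence column
#'   exists, edges with confidence below it are dropped.
#' @return An undirected simple [igraph::graph] with vertex names and, when
#'   available, an edge attribute `weight` holding the confidence.
#' @export
read_ppi_edgelist <- function(path, min_confidence = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("PPI edge list format error: empty file")
  body <- lines[-1]
  body_no <- which(nzchar(trimws(body)))
  fields <- strsplit(body[body_no], "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; restore it so isolated-node
  # lines ("SYM<TAB>") survive the round trip
  trailing <- lengths(fields) == 1 & grepl("\t", body[body_no], fixed = TRUE)
  fields[trailing] <- lapply(fields[trailing], c, "")
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    stop("malformed PPI edge list at line ", body_no[bad[1]] + 1L)
  }
  a <- norm_symbol(vapply(fields, `[`, character(1), 1L))
  b <- norm_symbol(vapply(fields, `[`, character(1), 2L))
  conf <- rep(NA_real_, length(fields))
  has3 <- lengths(fields) >= 3
  conf[has3] <- suppressWarnings(
    as.numeric(vapply(fields[has3], `[`, character(1), 3L)))
  # a line with an empty partner declares an isolated node
  iso <- a[!nzchar(b)]
  keep <- nzchar(b)
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  if (!is.null(min_confidence) && any(!is.na(conf))) {
    keep <- is.na(conf) | conf >= min_confidence
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]; conf <- conf[!dup]
  d <- data.frame(from = lo, to = hi, stringsAsFactors = FALSE)
  if (any(!is.na(conf))) d$weight <- conf
  nodes <- sort(unique(c(lo, hi, iso)))
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = nodes)
}

#' Write a gene network as a tab-delimited edge list
#'
#' Inverse of [read_ppi_edgelist()]: a header row, one canonical
#' (lexicographically ordered) gene pair per line, plus a weight column when
#' the graph carries edge weights. Isolated nodes are listed in a trailing
#' comment-free block with an empty partner so the node set round-trips.
#'
#' @param net an undirected [igraph::graph] with vertex names.
#' @param path output path.
#' @export
write_ppi_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net)
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  w <- if ("weight" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$weight
  } else NULL
  ord <- order(lo, hi)
  header <- if (is.null(w)) "symbol1\tsymbol2" else "symbol1\tsymbol2\tweight"
  rows <- if (is.null(w)) {
    paste(lo[ord], hi[ord], sep = "\t")
  } else {
    paste(lo[ord], hi[ord], format(w[ord], digits = 15, trim = TRUE), sep = "\t")
  }
  iso <- setdiff(igraph::V(net)$name, c(lo, hi))
  if (length(iso)) rows <- c(rows, paste(sort(iso), "", sep = "\t"))
  writeLines(c(header, rows), path)
}

#' Construct a pathway collection
#'
#' @param sets named list of character vectors: pathway id -> member gene
#'   symbols (uppercased, deduplicated, non-empty).
#' @param pathway_names optional named character vector of display names
#'   (defaults to the ids).
#' @return An object of class `pathway_db`: list with `sets`, `names` and
#'   `universe` (union of all member sets).
#' @export
pathway_db <- function(sets, pathway_names = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("pathway sets must have unique ids")
  }
  sets <- lapply(sets, function(g) unique(norm_symbol(g)))
  if (any(lengths(sets) == 0)) stop("pathway member sets must be non-empty")
  if (is.null(pathway_names)) {
    pathway_names <- stats::setNames(names(sets), names(sets))
  }
  pathway_names <- pathway_names[names(sets)]
  structure(
    list(sets = sets,
         names = pathway_names,
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "pathway_db"
  )
}

#' Read a GMT pathway collection
#'
#' Broad-dialect GMT: one gene set per line, `name TAB description TAB gene
#' TAB gene ...`, no header. The first field is used as the pathway id and
#' the second (when non-blank) as its display name. Gene symbols are
#' uppercase-normalized; lines with fewer than three fields are an error.
#'
#' @param path path to the GMT file.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines_no <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[lines_no], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("malformed GMT line ", lines_no[bad[1]])
  ids <- vapply(fields, `[`, character(1), 1L)
  descs <- vapply(fields, `[`, character(1), 2L)
  descs[!nzchar(descs)] <- ids[!nzchar(descs)]
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- ids
  pathway_db(sets, stats::setNames(descs, ids))
}

#' Write a pathway collection as GMT
#'
#' @param db a [pathway_db()].
#' @param path output path.
#' @export
write_gmt <- function(db, path) {
  rows <- vapply(names(db$sets), function(id) {
    paste(c(id, db$names[[id]], db$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
}

# |log2 p| presentation value, computed from the value as reported
# (3 significant digits), guarded against underflow to zero.
abs_log2_report <- function(p) {
  abs(log2(pmax(signif(p, 3), .Machine$double.xmin)))
}

#' Write an enrichment table as TSV
#'
#' Columns: `pathway_id`, `pathway_name`, `p_value`, `fdr`, `bonferroni`,
#' `overlap_k`, `pathway_size_K`, `list_size_n`, `universe_N`,
#' `abs_log2_p`, `abs_log2_fdr`, `abs_log2_bonf`. The `abs_log2_*`
#' presentation columns are |log2| of the p values rounded to 3 significant
#' digits, the precision at which they are reported.
#'
#' @param table an enrichment table from [enrich()] (already ranked).
#' @param path output path.
#' @export
write_enrichment <- function(table, path) {
  out <- data.frame(
    pathway_id = table$pathway_id,
    pathway_name = table$pathway_name,
    p_value = table$p_value,
    fdr = table$fdr,
    bonferroni = table$bonferroni,
    overlap_k = table$overlap_k,
    pathway_size_K = table$pathway_size_K,
    list_size_n = table$list_size_n,
    universe_N = table$universe_N,
    abs_log2_p = abs_log2_report(table$p_value),
    abs_log2_fdr = abs_log2_report(table$fdr),
    abs_log2_bonf = abs_log2_report(table$bonferroni),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
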