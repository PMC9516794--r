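# Kruskal-Wallis rank test and the thresholded pairwise gene-gene
# similarity matrix built from its p values. A high p value (failure to
# reject equal location) is read as similarity between two genes'
# expression-value distributions.

#' Kruskal-Wallis rank test
#'
#' Non-parametric k-sample test of equal location, computed on midranks via
#' the variance-of-ranks form
#' \deqn{K = (N-1) \frac{\sum_i n_i (\bar r_i - \bar r)^2}
#'                      {\sum_{ij} (r_{ij} - \bar r)^2},}
#' which is algebraically identical to the classical
#' \eqn{12/(N(N+1)) \sum R_i^2/n_i - 3(N+1)} statistic divided by the tie
#' correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}. When every observation is
#' identical the statistic is defined as 0 (p = 1). The p value uses the
#' chi-square approximation with `g - 1` degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors; total
#'   number of observations must be at least 3.
#' @return An object of class `kw_result`: list with `H`, `df`, `p_value`,
#'   `N` and `group_sizes`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of at least 2 samples")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be non-empty")
  x <- as.numeric(unlist(groups, use.names = FALSE))
  if (any(!is.finite(x))) stop("observations must be finite")
  N <- length(x)
  if (N < 3) stop("need at least 3 observations in total")
  g <- length(groups)
  r <- rank(x)                       # midranks handle ties
  rbar <- (N + 1) / 2
  sst <- sum((r - rbar)^2)
  if (sst == 0) {
    H <- 0
    p <- 1
  } else {
    idx <- rep.int(seq_len(g), sizes)
    group_means <- vapply(split(r, idx), mean, numeric(1))
    ssb <- sum(sizes * (group_means - rbar)^2)
    H <- (N - 1) * ssb / sst
    p <- stats::pchisq(H, df = g - 1, lower.tail = FALSE)
  }
  structure(
    list(H = H, df = as.integer(g - 1), p_value = p,
         N = as.integer(N), group_sizes = as.integer(sizes)),
    class = "kw_result"
  )
}

#' Pairwise Kruskal-Wallis similarity matrix
#'
#' For every unordered gene pair (i, j), compares the per-sample expression
#' values of gene i against those of gene j (two groups) with
#' [kruskal_wallis()] and stores the p value when it is at or above
#' `threshold`, 0 otherwise. The diagonal is fixed at 0 so the derived
#' network has no self loops.
#'
#' @param expr an [expr_set()].
#' @param genes character vector of gene symbols; silently restricted to
#'   the genes present in `expr` (the missing ones are reported in the
#'   `missing_genes` attribute).
#' @param sample_scope which samples the comparison uses: `"cases"`
#'   (default, the phenotype under study), `"controls"`, or `"all"`.
#' @param threshold similarity threshold, default 0.005.
#' @return An object of class `similarity_matrix`: list with `genes`,
#'   `cells` (symmetric numeric matrix) and `threshold`.
#' @export
similarity_matrix <- function(expr, genes,
                              sample_scope = c("cases", "controls", "all"),
                              threshold = 0.005) {
  sample_scope <- match.arg(sample_scope)
  stopifnot(inherits(expr, "expr_set"), threshold > 0, threshold < 1)
  cols <- switch(sample_scope,
    cases = which(expr$groups == "case"),
    controls = which(expr$groups == "control"),
    all = seq_along(expr$groups)
  )
  if (length(cols) < 2) {
    stop("sample scope '", sample_scope, "' has fewer than 2 samples")
  }
  genes <- unique(norm_symbol(genes))
  present <- genes[genes %in% rownames(expr$values)]
  if (length(present) < 2) {
    stop("fewer than 2 requested genes are present in the expression matrix")
  }
  vals <- expr$values[present, cols, drop = FALSE]
  k <- length(present)
  cells <- matrix(0, k, k, dimnames = list(present, present))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      p <- kruskal_wallis(list(vals[i, ], vals[j, ]))$p_value
      cells[i, j] <- cells[j, i] <- if (p >= threshold) p else 0
    }
  }
  structure(
    list(genes = present, cells = cells, threshold = threshold,
         missing_genes = setdiff(genes, present)),
    class = "similarity_matrix"
  )
}
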