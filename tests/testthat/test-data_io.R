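# Readers/writers: parsing, normalization, drop rules, and round trips.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_deg_table parses GEO2R-style tables and reports drops", {
  path <- write_tsv_lines(c(
    "ID\tadj.P.Val\tP.Value\tlogFC\tGene.symbol",
    "p1\t0.001\t0.0005\t2.1\ttp53",
    "p2\t0.02\t0.01\t-1.8\tBRCA1",
    "p3\t0.5\t0.3\t0.2\tEGFR"))
  tab <- read_deg_table(path)
  expect_s3_class(tab, "deg_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$gene_symbol, c("TP53", "BRCA1", "EGFR"))  # uppercased
  expect_equal(attr(tab, "load_report")$n_dropped, 0)

  # blank symbol and unparseable logFC are dropped and counted
  path2 <- write_tsv_lines(c(
    "ID\tadj.P.Val\tP.Value\tlogFC\tGene.symbol",
    "p1\t0.001\t0.0005\t2.1\tTP53",
    "p2\t0.001\t0.0005\t2.1\t",
    "p3\t0.001\t0.0005\tnot_a_number\tEGFR"))
  tab2 <- read_deg_table(path2)
  expect_equal(nrow(tab2), 1)
  expect_equal(attr(tab2, "load_report")$n_dropped, 2)
})

test_that("read_deg_table errors name the missing column and honour column_map", {
  path <- write_tsv_lines(c(
    "ID\tadj.P.Val\tP.Value\tGene.symbol",
    "p1\t0.001\t0.0005\tTP53"))
  expect_error(read_deg_table(path), "logFC")

  path2 <- write_tsv_lines(c(
    "probe\tfdr\tpval\tfc\tsymbol",
    "p1\t0.001\t0.0005\t2.1\tTP53"))
  tab <- read_deg_table(path2, column_map = c(
    probe_id = "probe", adj_p_value = "fdr", p_value = "pval",
    log_fc = "fc", gene_symbol = "symbol"))
  expect_equal(tab$gene_symbol, "TP53")
  expect_equal(tab$log_fc, 2.1)
})

test_that("read_expression_matrix attaches groups and collapses duplicates", {
  samples <- c("s1", "s2", "s3", "s4", "s5", "s6")
  mat_lines <- c(
    paste(c("gene", samples), collapse = "\t"),
    paste(c("GA", 1:6), collapse = "\t"),
    paste(c("GB", rep(5, 6)), collapse = "\t"),        # low-variance dup
    paste(c("GB", c(1, 9, 2, 8, 3, 7)), collapse = "\t"), # high-variance dup
    paste(c("GC", 6:1), collapse = "\t"),
    paste(c("GD", rep(2, 6)), collapse = "\t"))
  mpath <- write_tsv_lines(mat_lines)
  gpath <- write_tsv_lines(c("sample_id\tgroup",
                             paste(samples, rep(c("case", "control"), each = 3),
                                   sep = "\t")))
  es <- read_expression_matrix(mpath, gpath)
  expect_s3_class(es, "expr_set")
  expect_equal(dim(es$values), c(4, 6))
  expect_equal(unname(es$groups),
               rep(c("case", "control"), each = 3))
  # the higher-variance GB row survived
  expect_equal(unname(es$values["GB", 1]), 1)
  expect_equal(attr(es, "load_report")$n_duplicates_collapsed, 1)

  gpath_short <- write_tsv_lines(c("sample_id\tgroup",
                                   paste(samples[-6], "case", sep = "\t")))
  expect_error(read_expression_matrix(mpath, gpath_short), "s6")
})

test_that("read_ppi_edgelist canonicalizes pairs, drops self-loops, filters", {
  path <- write_tsv_lines(c("symbol1\tsymbol2",
                            "A\tB", "B\tA", "A\tA", "B\tC", "c\tD"))
  g <- read_ppi_edgelist(path)
  expect_equal(igraph::ecount(g), 3)  # A-B deduped, A-A dropped
  expect_true(igraph::is_simple(g))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))

  wpath <- write_tsv_lines(c("symbol1\tsymbol2\tconfidence",
                             "A\tB\t0.4", "C\tD\t0.9"))
  gw <- read_ppi_edgelist(wpath, min_confidence = 0.5)
  expect_equal(igraph::ecount(gw), 1)
  expect_setequal(names(igraph::neighbors(gw, "C")), "D")

  bad <- write_tsv_lines(c("symbol1\tsymbol2", "A\tB", "LONELY"))
  expect_error(read_ppi_edgelist(bad), "line 3")
})

test_that("read_gmt builds the universe and normalizes case", {
  path <- write_tsv_lines(c(
    "PW1\tFirst pathway\tA\tB\tC",
    "PW2\tSecond pathway\tC\tD\tE\tF"))
  db <- read_gmt(path)
  expect_s3_class(db, "pathway_db")
  expect_equal(length(db$universe), 6)    # shared gene counted once
  expect_equal(lengths(db$sets), c(PW1 = 3L, PW2 = 4L))

  expect_error(read_gmt(write_tsv_lines(c("PW1\tdesc\tA", "PW2\tempty"))),
               "line 2")

  mixed <- read_gmt(write_tsv_lines("PW1\tdesc\ttp53\tTP53\tEGFR"))
  expect_equal(lengths(mixed$sets), c(PW1 = 2L))
})

test_that("network and pathway round trips preserve the object", {
  g <- tiny_graph(c("A", "B", "B", "C"), isolated = "Z")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_edgelist(g, path)
  g2 <- read_ppi_edgelist(path)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  el <- function(x) {
    e <- igraph::as_edgelist(x)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(el(g2), el(g))

  db <- pathway_db(list(P1 = c("A", "B"), P2 = c("B", "C", "D")))
  gpath <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, gpath)
  db2 <- read_gmt(gpath)
  expect_equal(db2$sets, db$sets)
  expect_equal(db2$universe, db$universe)
})

test_that("parsing is insensitive to input line order", {
  lines <- c("PW1\td\tA\tB", "PW2\td\tC\tD\tE", "PW3\td\tA\tE")
  db1 <- read_gmt(write_tsv_lines(lines))
  db2 <- read_gmt(write_tsv_lines(rev(lines)))
  expect_equal(db1$sets[sort(names(db1$sets))],
               db2$sets[sort(names(db2$sets))])
  expect_equal(db1$universe, db2$universe)
})

test_that("write_enrichment reports |log2 p| presentation columns", {
  tab <- fake_enrichment(c("P1", "P2"), c(0.25, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(tab, path)
  out <- read.delim(path)
  expect_equal(out$abs_log2_p, c(2, 0))

  empty <- fake_enrichment(character(0), numeric(0))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(empty, path2)
  expect_length(readLines(path2), 1)   # header only
})
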