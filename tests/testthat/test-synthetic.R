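# The planted-structure study generator: determinism, calibration of the
# planted signals, and consistency of the four generated inputs.

test_that("generators are pure functions of seed and parameters", {
  t1 <- planted_truth(99, n_genes = 60, module_size = 8)
  e1 <- simulate_expression(t1, 6, 6)
  e2 <- simulate_expression(t1, 6, 6)
  expect_identical(e1$values, e2$values)

  p1 <- simulate_ppi(t1); p2 <- simulate_ppi(t1)
  expect_identical(igraph::as_edgelist(p1), igraph::as_edgelist(p2))

  db1 <- simulate_pathways(t1, n_pathways = 10)
  db2 <- simulate_pathways(t1, n_pathways = 10)
  expect_identical(db1$sets, db2$sets)

  t_other <- planted_truth(100, n_genes = 60, module_size = 8)
  expect_false(identical(simulate_expression(t_other, 6, 6)$values, e1$values))
})

test_that("effect_size 0 leaves case and control means equal in expectation", {
  t0 <- planted_truth(5, n_genes = 40, module_size = 5, effect_size = 0)
  e <- simulate_expression(t0, 50, 50)
  d <- simulate_deg_table(e)
  expect_lt(max(abs(d$log_fc)), 1)     # no planted shift anywhere
  expect_gt(min(d$adj_p_value), 0.005) # nothing significant after BH
})

test_that("the vectorized Welch t matches stats::t.test", {
  set.seed(30)
  t1 <- planted_truth(7, n_genes = 20, module_size = 3)
  e <- simulate_expression(t1, 6, 8)
  d <- simulate_deg_table(e)
  for (g in sample(rownames(e$values), 5)) {
    ref <- t.test(e$values[g, e$groups == "case"],
                  e$values[g, e$groups == "control"])
    expect_equal(d$p_value[d$gene_symbol == g], ref$p.value,
                 tolerance = 1e-12)
    expect_equal(d$log_fc[d$gene_symbol == g],
                 unname(diff(rev(ref$estimate))), tolerance = 1e-12)
  }
})

test_that("module gene pairs read as similar under the Kruskal-Wallis score", {
  # calibration of the shared latent factor: across 200 seeds, the KW p
  # between two up-module genes on case samples clears the 0.005
  # similarity threshold in at least 95% of studies
  hits <- 0L
  for (s in 1:200) {
    tr <- planted_truth(s, n_genes = 10, module_size = 2, noise_sd = 0.1)
    e <- simulate_expression(tr, 10, 10)
    cases <- e$values[tr$up_module, e$groups == "case"]
    p <- kruskal_wallis(list(cases[1, ], cases[2, ]))$p_value
    hits <- hits + (p > 0.005)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("planted genes pass the DEG filter and backgrounds do not", {
  module_pass <- 0L; module_n <- 0L
  bg_pass <- 0L; bg_n <- 0L
  sign_ok <- 0L; sign_n <- 0L
  for (s in 1:200) {
    tr <- planted_truth(s, n_genes = 30, module_size = 5)
    d <- simulate_deg_table(simulate_expression(tr, 10, 10))
    hit <- d$adj_p_value <= 0.005 & abs(d$log_fc) >= 1.5
    is_mod <- d$gene_symbol %in% c(tr$up_module, tr$down_module)
    module_pass <- module_pass + sum(hit[is_mod]); module_n <- module_n + sum(is_mod)
    bg_pass <- bg_pass + sum(hit[!is_mod]); bg_n <- bg_n + sum(!is_mod)
    up_rows <- d$gene_symbol %in% tr$up_module
    dn_rows <- d$gene_symbol %in% tr$down_module
    sign_ok <- sign_ok + sum(d$log_fc[up_rows] > 0) + sum(d$log_fc[dn_rows] < 0)
    sign_n <- sign_n + sum(up_rows) + sum(dn_rows)
  }
  expect_gte(module_pass / module_n, 0.95)
  expect_lte(bg_pass / bg_n, 0.005)     # at most the nominal rate
  expect_gte(sign_ok / sign_n, 0.99)    # logFC sign matches planted direction
})

test_that("the simulated PPI is connected and contains wired modules", {
  tr <- planted_truth(13, n_genes = 80, module_size = 6)
  g <- simulate_ppi(tr)
  expect_true(igraph::is_connected(g))
  expect_true(all(c(tr$up_module, tr$down_module) %in% igraph::V(g)$name))
  expect_true(igraph::is_simple(g))
  # each module induces a connected subgraph (the chain wiring)
  for (mod in list(tr$up_module, tr$down_module)) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, mod)))
  }
})

test_that("the planted pathway holds the modules and the GMT round-trips", {
  tr <- planted_truth(17, n_genes = 80, module_size = 6)
  db <- simulate_pathways(tr, n_pathways = 12)
  planted <- db$sets[[tr$planted_pathway_id]]
  expect_true(all(c(tr$up_module, tr$down_module) %in% planted))
  # decoy pathways draw from non-module genes only
  decoys <- db$sets[names(db$sets) != tr$planted_pathway_id]
  expect_length(intersect(unlist(decoys), c(tr$up_module, tr$down_module)), 0)

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  expect_equal(read_gmt(path)$sets, db$sets)
})

test_that("write_study emits files that read back into equivalent objects", {
  sim <- simulate_study(23, n_case = 5, n_control = 5, n_pathways = 8,
                        n_genes = 60, module_size = 6)
  dir <- withr::local_tempdir()
  paths <- write_study(sim, dir)
  expect_true(all(file.exists(paths)))

  deg <- read_deg_table(paths["deg"])
  expect_equal(deg$gene_symbol, sim$deg$gene_symbol)
  expect_equal(deg$log_fc, sim$deg$log_fc, tolerance = 1e-6)

  expr <- read_expression_matrix(paths["expression"], paths["groups"])
  expect_equal(dim(expr$values), dim(sim$expr$values))
  expect_equal(unname(expr$groups), unname(sim$expr$groups))

  ppi <- read_ppi_edgelist(paths["ppi"])
  expect_equal(igraph::ecount(ppi), igraph::ecount(sim$ppi))
  expect_setequal(igraph::V(ppi)$name, igraph::V(sim$ppi)$name)

  expect_equal(read_gmt(paths["gmt"])$sets, sim$pathways$sets)
})
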