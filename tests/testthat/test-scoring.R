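test_that("IALS reproduces hand-evaluated layer formulas", {
  g <- net_from_pairs(c("b", "c"))
  expect_equal(ials(g, "b", c("b", "c")), 1.0)
  g2 <- net_from_pairs(c("b", "c", "c", "d"))
  # module genes at layers 1 and 2: (1+1) / (1*1 + 1*2) = 2/3
  expect_equal(ials(g2, "b", c("b", "c", "d")), 2 / 3)
  # membership indicator: a disease gene outside the module contributes 0
  expect_equal(ials(g2, "b", c("c", "d")), 0)
  # no in-module downstream genes: contributes 0
  expect_equal(ials(g2, "d", c("b", "c", "d")), 0)
  expect_warning(out <- ials(g2, character(0), "b"), "empty")
  expect_equal(out, 0)
  expect_error(ials(g2, "zz", "b"), "zz")
})

test_that("WPS reproduces hand-evaluated reverse-layer weights", {
  g <- net_from_pairs(c("a", "b", "b", "c"))
  expect_equal(wps(g, "b", "c"), 0.5)
  # pathway gene alone in layer 0
  g2 <- net_from_pairs(c("c", "x"))
  expect_equal(wps(g2, "c", "c"), 1.0)
  # module gene with no path to the pathway: zero overlap with all layers
  expect_equal(wps(g2, "x", "c"), 0)
  expect_error(wps(g, "b", "zz"), "no pathway gene")
})

test_that("IALS and WPS match the naive layer-set oracle on random graphs", {
  for (seed in 1:40) {
    rd <- random_digraph(sample(5:12, 1), runif(1, 0.1, 0.35), seed = seed)
    set.seed(seed + 1000)
    module <- sample(rd$nodes, sample(2:4, 1))
    disease <- sample(rd$nodes, sample(1:3, 1))
    pathway <- sample(rd$nodes, sample(1:3, 1))
    expect_equal(ials(rd$graph, disease, module),
                 naive_ials(rd$nodes, rd$edges, disease, module),
                 tolerance = 1e-12)
    expect_equal(wps(rd$graph, module, pathway),
                 naive_wps(rd$nodes, rd$edges, module, pathway),
                 tolerance = 1e-12)
  }
})

test_that("kernel bounds hold: IALS caps and WPS range/monotonicity", {
  for (seed in 1:15) {
    rd <- random_digraph(10, 0.25, seed = seed + 200)
    set.seed(seed)
    module <- sample(rd$nodes, 4)
    disease <- sample(rd$nodes, 3)
    v <- ials(rd$graph, disease, module)
    expect_gte(v, 0)
    expect_lte(v, length(intersect(disease, module)))
    pathway <- sample(rd$nodes, 2)
    w1 <- wps(rd$graph, module, pathway)
    expect_gte(w1, 0)
    expect_lt(w1, 2)
    # adding genes to the module never decreases WPS
    bigger <- union(module, sample(rd$nodes, 3))
    expect_gte(wps(rd$graph, bigger, pathway) + 1e-12, w1)
  }
})

test_that("restriction to a gene universe keeps, trims and drops", {
  gs <- gene_set_collection("disease", c("d1", "d2"),
                            genes = list(c("g1", "g2"), "gX"))
  r <- restrict_gene_sets(gs, c("g1", "other"))
  expect_equal(r$table$id, "d1")
  expect_equal(r$genes[["d1"]], "g1")
  expect_equal(attr(r, "dropped"), "d2")
})

test_that("CATG-0 screening flags all-downstream diseases", {
  # b<->c core, c->d->e downstream chain, sink f
  g <- net_from_pairs(c("b", "c", "c", "b", "c", "d", "d", "e", "c", "f"))
  bt <- bow_tie(g)
  expect_setequal(bt$down_lscc, c("d", "e", "f"))
  dis <- gene_set_collection(
    "disease", c("all_down", "mixed", "sink_single"),
    genes = list(c("d", "e"), c("b", "d"), "f"))
  rep0 <- screen_catg0(dis, bt)
  expect_setequal(rep0$catg0_disease_ids, c("all_down", "sink_single"))
  expect_equal(rep0$remaining_disease_ids, "mixed")
  expect_setequal(rep0$catg0_gene_pool, c("d", "e", "f"))
})

test_that("impact scores factor exactly into IALS x WPS", {
  for (seed in c(3, 17)) {
    res <- run_synthetic_pipeline(seed)
    sc <- res$scores
    memb <- res$modules$assignment
    nm <- igraph::V(res$lcc)$name
    # spot-check a handful of factor entries against the simple kernels
    set.seed(seed)
    dsel <- sample(rownames(sc$is), 3)
    psel <- sample(colnames(sc$is), 2)
    for (d in dsel) {
      genes <- res$sets$diseases$genes[[d]]
      for (t in sample(seq_len(res$modules$n_modules), 2)) {
        expect_equal(sc$ials[d, t],
                     ials(res$lcc, genes, names(memb)[memb == t]),
                     tolerance = 1e-12)
      }
    }
    for (p in psel) {
      for (t in sample(seq_len(res$modules$n_modules), 2)) {
        expect_equal(sc$wps[t, p],
                     wps(res$lcc, names(memb)[memb == t],
                         res$sets$pathways$genes[[p]]),
                     tolerance = 1e-12)
      }
    }
    expect_equal(sc$is, sc$ials %*% sc$wps, tolerance = 1e-12)
  }
})

test_that("NIS rows are min-max normalized with constant rows at zero", {
  res <- run_synthetic_pipeline(5)
  nis <- res$scores$nis
  for (i in seq_len(nrow(nis))) {
    r <- nis[i, ]
    if (all(r == 0)) {
      expect_true(diff(range(res$scores$is[i, ])) == 0)
    } else {
      expect_equal(min(r), 0)
      expect_equal(max(r), 1)
    }
  }
  # invariance under positive scaling of the IS row
  is_row <- res$scores$is[1, ]
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(mm(2 * is_row), mm(is_row), tolerance = 1e-12)
})

test_that("scoring refuses genes that are not network nodes", {
  res <- run_synthetic_pipeline(2)
  bad <- gene_set_collection("disease", "dX", genes = list("not_a_node"))
  expect_error(
    impact_scores(res$lcc, bad, res$sets$pathways, res$modules),
    "not in network")
})
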