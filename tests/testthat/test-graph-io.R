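biogrid_fixture <- function(path, tab3 = FALSE) {
  org_a <- if (tab3) "Organism ID Interactor A" else "Organism Interactor A"
  org_b <- if (tab3) "Organism ID Interactor B" else "Organism Interactor B"
  header <- paste("#BioGRID Interaction ID", "Entrez Gene Interactor A",
                  "Entrez Gene Interactor B", org_a, org_b, sep = "\t")
  # strip the leading "#" so fread keeps the header row
  header <- sub("^#", "", header)
  rows <- c(
    "1\t101\t102\t9606\t9606",
    "2\t101\t103\t9606\t9606",
    "3\t201\t101\t10090\t9606")
  writeLines(c(header, rows), path)
  path
}

test_that("BioGRID parser echoes records and preserves organisms", {
  f <- withr::local_tempfile(fileext = ".txt")
  biogrid_fixture(f)
  rec <- read_biogrid_tab(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$bait_gene, c("101", "101", "201"))
  expect_equal(rec$prey_gene, c("102", "103", "101"))
  expect_equal(rec$bait_organism, c(9606L, 9606L, 10090L))
  expect_equal(attr(rec, "skipped"), 0L)
  # same columns resolve in the TAB3 layout
  f3 <- withr::local_tempfile(fileext = ".txt")
  biogrid_fixture(f3, tab3 = TRUE)
  expect_equal(read_biogrid_tab(f3)$prey_organism, c(9606L, 9606L, 9606L))
})

test_that("rows with missing gene identifiers are skipped and counted", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("Entrez Gene Interactor A", "Entrez Gene Interactor B",
                     "Organism Interactor A", "Organism Interactor B",
                     sep = "\t"),
               "101\t102\t9606\t9606",
               "-\t103\t9606\t9606"), f)
  rec <- read_biogrid_tab(f)
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "skipped"), 1L)
})

test_that("unknown header layout raises a format error naming columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("colA\tcolB", "1\t2"), f)
  expect_error(read_biogrid_tab(f), "bait_gene")
  expect_error(read_biogrid_tab("no/such/file.txt"), "cannot read")
})

test_that("build_network dedups, drops self-loops and filters taxa", {
  mk <- function(bait, prey, org_a = 9606L, org_b = 9606L) {
    data.frame(bait_gene = bait, prey_gene = prey,
               bait_organism = org_a, prey_organism = org_b,
               source_row = seq_along(bait), stringsAsFactors = FALSE)
  }
  # duplicate collapses, direction kept
  b <- build_network(mk(c("a", "a", "b"), c("b", "b", "a")))
  expect_equal(b$report$n_nodes, 2)
  expect_equal(b$report$n_edges, 2)
  expect_equal(b$report$duplicate, 1)
  expect_true(igraph::are_adjacent(b$network, "a", "b"))
  expect_true(igraph::are_adjacent(b$network, "b", "a"))
  # self-loop dropped but node kept
  b2 <- build_network(mk(c("a", "a"), c("a", "b")))
  expect_equal(b2$report$n_nodes, 2)
  expect_equal(b2$report$n_edges, 1)
  expect_equal(b2$report$self_loop, 1)
  # retained behind the flag
  b2l <- build_network(mk(c("a", "a"), c("a", "b")), keep_self_loops = TRUE)
  expect_equal(b2l$report$n_edges, 2)
  # cross-species rows removed
  b3 <- build_network(mk(c("a", "x"), c("b", "b"),
                         org_a = c(9606L, 10090L)))
  expect_equal(b3$report$cross_species, 1)
  expect_equal(b3$report$n_nodes, 2)
})

test_that("record categories partition the input rows", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    genes <- as.character(sample(8, 2 * n, replace = TRUE))
    orgs <- sample(c(9606L, 10090L), 2 * n, replace = TRUE, prob = c(.8, .2))
    rec <- data.frame(bait_gene = genes[1:n], prey_gene = genes[(n + 1):(2 * n)],
                      bait_organism = orgs[1:n], prey_organism = orgs[(n + 1):(2 * n)],
                      source_row = 1:n, stringsAsFactors = FALSE)
    r <- build_network(rec)$report
    expect_equal(r$kept + r$duplicate + r$self_loop + r$cross_species, n)
  }
})

test_that("building from the network's own edge dump is idempotent", {
  rd <- random_digraph(15, 0.15, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(rd$graph, f1)
  b1 <- build_network(read_edge_list(f1))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(b1$network, f2)
  b2 <- build_network(read_edge_list(f2))
  expect_setequal(igraph::V(b1$network)$name, igraph::V(b2$network)$name)
  e1 <- igraph::as_edgelist(b1$network)
  e2 <- igraph::as_edgelist(b2$network)
  expect_setequal(paste(e1[, 1], e1[, 2]), paste(e2[, 1], e2[, 2]))
})

test_that("empty record list yields an empty network with a warning", {
  rec <- read_edge_list(withr::local_tempfile(fileext = ".tsv", lines = "# nothing"))
  expect_warning(b <- build_network(rec), "no interaction records")
  expect_equal(b$report$n_nodes, 0)
})

test_that("gene-set reader parses, validates and rejects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\ttop_level_class\tgenes",
               "d1\tDisease one\tmetabolic\tg1;g2"), f)
  gs <- read_gene_sets(f, "disease")
  expect_equal(n_gene_sets(gs), 1)
  expect_setequal(gs$genes[["d1"]], c("g1", "g2"))

  fdup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\ttop_level_class\tgenes",
               "d1\tA\tx\tg1", "d1\tB\tx\tg2"), fdup)
  expect_error(read_gene_sets(fdup, "disease"), "d1")

  fempty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\ttop_level_class\tgenes",
               "d1\tA\tx\tg1", "d2\tB\tx\t"), fempty)
  expect_warning(gs2 <- read_gene_sets(fempty, "disease"), "d2")
  expect_equal(gs2$table$id, "d1")
})

test_that("gene-set collections round-trip through TSV", {
  gs <- gene_set_collection("pathway", c("p1", "p2"),
                            top_level_class = c("met", "sig"),
                            genes = list(c("a", "b"), "c"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_sets(gs, f)
  back <- read_gene_sets(f, "pathway")
  expect_equal(back$table, gs$table)
  expect_equal(back$genes, gs$genes)
})

test_that("annotated tables round-trip numeric values exactly", {
  set.seed(9)
  df <- data.frame(disease = c("d1", "d2"),
                   P1 = rnorm(2), P2 = exp(rnorm(2, sd = 10)),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lamp_table(df, f, seed = 7, inputs = c())
  back <- read_lamp_table(f)
  expect_identical(back$P1, df$P1)
  expect_identical(back$P2, df$P2)
  expect_true(any(grepl("^# seed: 7", readLines(f))))
})

test_that("writing an empty table warns but produces a header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(write_lamp_table(data.frame(a = character(0)), f), "empty")
  expect_equal(nrow(read_lamp_table(f)), 0)
})
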