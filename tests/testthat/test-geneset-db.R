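test_that("GMT parsing builds sets, dedups genes and rejects bad lines", {
  col <- read_gmt(gmt_fixture())
  expect_s3_class(col, "gene_set_collection")
  expect_length(col, 2)
  expect_equal(col$sets[["GO:1"]], c("g1", "g2", "g3"))
  expect_equal(unname(col$names["GO:1"]), "T cell activation")

  dup <- read_gmt(gmt_fixture("S:1\tdesc\tg1\tg1\tg2"))
  expect_equal(dup$sets[["S:1"]], c("g1", "g2"))

  expect_error(read_gmt(gmt_fixture("GO:1\tonly-two-fields")), "line 1")
  expect_error(read_gmt(gmt_fixture(c("GO:1\ta\tg1", "GO:1\tb\tg2"))),
               "duplicate set id")
  expect_error(read_gmt(gmt_fixture("GO:1\tdesc\t\t")), "no genes")
})

test_that("GMT round-trips through write_gmt", {
  col <- read_gmt(gmt_fixture())
  path <- tempfile(fileext = ".gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_equal(back$sets, col$sets)
  expect_equal(back$names, col$names)
})

gaf_lines <- function(rows) {
  c("!gaf-version: 2.2",
    vapply(rows, function(r)
      paste(c("DB", r[["id"]], r[["symbol"]], r[["qual"]], r[["term"]],
              "REF", "IEA", "", r[["aspect"]], rep("", 6)), collapse = "\t"),
      character(1)))
}

test_that("GAF reader aggregates associations, drops NOT rows, filters aspect", {
  rows <- list(
    list(id = "1", symbol = "TCF7", qual = "", term = "GO:A", aspect = "P"),
    list(id = "2", symbol = "LEF1", qual = "", term = "GO:A", aspect = "P"),
    list(id = "3", symbol = "GAPDH", qual = "", term = "GO:B", aspect = "C"),
    list(id = "4", symbol = "PGK1", qual = "", term = "GO:B", aspect = "C"))
  path <- write_lines_tmp(gaf_lines(rows), ".gaf")
  col <- read_gaf_minimal(path)
  expect_length(col, 2)
  expect_setequal(col$sets[["GO:A"]], c("TCF7", "LEF1"))

  aspect_p <- read_gaf_minimal(path, aspect = "P")
  expect_equal(names(aspect_p$sets), "GO:A")

  not_rows <- list(list(id = "1", symbol = "X", qual = "NOT", term = "GO:A",
                        aspect = "P"))
  expect_error(read_gaf_minimal(write_lines_tmp(gaf_lines(not_rows), ".gaf")),
               "no associations")

  mixed <- c(rows, list(list(id = "5", symbol = "Y", qual = "NOT|involved_in",
                             term = "GO:A", aspect = "P")))
  col2 <- read_gaf_minimal(write_lines_tmp(gaf_lines(mixed), ".gaf"))
  expect_false("Y" %in% col2$sets[["GO:A"]])
})

obo_fixture <- function(extra = character()) {
  write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:R", "name: root", "",
    "[Term]", "id: GO:M", "name: mid", "is_a: GO:R ! root", "",
    "[Term]", "id: GO:L", "name: leaf", "is_a: GO:M", "",
    extra), ".obo")
}

test_that("OBO reader builds the is_a graph with obsolete flags", {
  g <- read_obo_minimal(obo_fixture())
  expect_equal(nrow(g$edges), 2)
  expect_equal(ontology_roots(g), "GO:R")
  expect_equal(g$edges$parent[g$edges$child == "GO:L"], "GO:M")

  g2 <- read_obo_minimal(obo_fixture(c("[Term]", "id: GO:X", "name: gone",
                                       "is_a: GO:R", "is_obsolete: true")))
  expect_true(g2$terms$obsolete[g2$terms$id == "GO:X"])
  expect_equal(nrow(g2$edges), 3)  # edges retained until pruning

  expect_error(read_obo_minimal(obo_fixture(c("[Term]", "id: GO:Y",
                                              "is_a: GO:NOPE"))),
               "undeclared")
  expect_error(read_obo_minimal(write_lines_tmp(
    c("[Term]", "id: GO:S", "name: self", "is_a: GO:S"), ".obo")), "cycle")
})

test_that("TSV edge-list loader is equivalent to the OBO form", {
  path <- write_lines_tmp(c(
    "child_id\tparent_id\tname\tobsolete",
    "GO:R\t\troot\t0",
    "GO:M\tGO:R\tmid\t0",
    "GO:L\tGO:M\tleaf\t1"), ".tsv")
  g <- read_ontology_tsv(path)
  expect_equal(ontology_roots(g), "GO:R")
  expect_true(g$terms$obsolete[g$terms$id == "GO:L"])
})

test_that("pruning removes obsolete terms without reattachment", {
  g <- ontology_graph(
    terms = tibble::tibble(id = c("a", "b", "c"), name = c("a", "b", "c"),
                           obsolete = c(FALSE, TRUE, FALSE)),
    edges = tibble::tibble(parent = c("a", "b"), child = c("b", "c")))
  p <- prune_ontology(g)
  expect_setequal(p$terms$id, c("a", "c"))
  expect_equal(nrow(p$edges), 0)            # no edge survives, no reattachment
  expect_setequal(ontology_roots(p), c("a", "c"))  # orphaned child becomes a root

  all_obs <- ontology_graph(
    terms = tibble::tibble(id = "a", name = "a", obsolete = TRUE),
    edges = tibble::tibble(parent = character(), child = character()))
  expect_error(prune_ontology(all_obs), "every term")
})

test_that("no obsolete term or incident edge survives pruning on any fixture", {
  for (seed in 1:5) {
    g <- random_dag(60, seed = seed)
    g$terms$obsolete <- runif(60) < 0.2
    if (all(g$terms$obsolete)) next
    p <- prune_ontology(g)
    expect_false(any(p$terms$obsolete))
    expect_true(all(p$edges$parent %in% p$terms$id))
    expect_true(all(p$edges$child %in% p$terms$id))
    obs_ids <- g$terms$id[g$terms$obsolete]
    expect_false(any(p$edges$parent %in% obs_ids | p$edges$child %in% obs_ids))
  }
})

test_that("indexed closures equal brute-force DFS on DAGs up to 200 terms", {
  p7 <- prune_ontology(fixture_dag())
  expect_setequal(descendants(p7, "root"), dfs_descendants(p7, "root"))
  expect_setequal(descendants(p7, "root"), c("i1", "i2", "i3", "m1", "m2"))

  for (n in c(30, 200)) {
    g <- prune_ontology(random_dag(n, seed = n))
    for (id in sample(g$terms$id, 12)) {
      expect_setequal(descendants(g, id), dfs_descendants(g, id))
      expect_setequal(ancestors(g, id), dfs_ancestors(g, id))
    }
  }
})

test_that("filter_collection composes size, subtree and end-level filters", {
  graph <- prune_ontology(fixture_dag())
  sets <- list(root = paste0("g", 1:5), i1 = paste0("g", 1:50),
               i2 = paste0("g", 1:20), i3 = paste0("g", 1:800),
               m1 = paste0("g", 1:30), m2 = paste0("g", 1:40))
  col <- gene_set_collection(sets)

  expect_equal(names(filter_collection(col, min_genes = 10, max_genes = 500)$sets),
               c("i1", "i2", "m1", "m2"))

  sub <- filter_collection(col, graph, root_terms = "i1")
  expect_setequal(names(sub$sets), c("i1", "i2", "i3"))  # DFS-oracle subtree
  expect_setequal(names(sub$sets), c("i1", dfs_descendants(graph, "i1")))

  leaves <- filter_collection(col, graph, end_level_only = TRUE)
  expect_setequal(names(leaves$sets), c("i2", "i3", "m2"))

  expect_error(filter_collection(col, graph, root_terms = "nope"), "unknown root")
  expect_warning(filter_collection(col, min_genes = 5000), "no gene sets")
  expect_error(filter_collection(col, root_terms = "i1"), "require")
})

test_that("filtering is idempotent and order-independent for independent criteria", {
  graph <- prune_ontology(fixture_dag())
  col <- gene_set_collection(list(i1 = paste0("g", 1:50), i2 = paste0("g", 1:5),
                                  m1 = paste0("g", 1:30), m2 = paste0("g", 1:40)))
  once <- filter_collection(col, graph, min_genes = 10, root_terms = "i1")
  twice <- filter_collection(once, graph, min_genes = 10, root_terms = "i1")
  expect_equal(names(twice$sets), names(once$sets))

  size_then_tree <- filter_collection(
    filter_collection(col, min_genes = 10), graph, root_terms = "i1")
  tree_then_size <- filter_collection(
    filter_collection(col, graph, root_terms = "i1"), min_genes = 10)
  expect_equal(names(size_then_tree$sets), names(tree_then_size$sets))
})

test_that("resolve_names is total, order-preserving and counts unknowns", {
  g <- fixture_dag()
  res <- resolve_names(c("i2", "root"), g)
  expect_equal(res$names, c("t cell", "process"))
  expect_equal(res$warnings, 0)

  expect_warning(res2 <- resolve_names(c("i2", "GO:???"), g), "unknown")
  expect_equal(res2$names, c("t cell", "GO:???"))
  expect_equal(res2$warnings, 1)

  expect_equal(resolve_names(character(), g)$names, character())

  col <- read_gmt(gmt_fixture())
  expect_equal(resolve_names("GO:1", col)$names, "T cell activation")
})
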