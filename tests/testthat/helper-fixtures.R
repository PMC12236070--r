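# in-code fixtures shared across the suite; everything is generated, nothing
# is read from disk except through files the helpers write to tempdirs

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

gmt_fixture <- function(lines = c(
  "GO:1\tT cell activation\tg1\tg2\tg3",
  "GO:2\tB cell activation\tg2\tg3\tg4\tg5\tg6")) {
  write_lines_tmp(lines, ".gmt")
}

# 7-term DAG: root with an immune branch (i1 -> i2, i3) and a metabolic
# branch (m1 -> m2), plus one obsolete term hanging off the root
fixture_dag <- function() {
  ontology_graph(
    terms = tibble::tibble(
      id = c("root", "i1", "i2", "i3", "m1", "m2", "obs"),
      name = c("process", "immune", "t cell", "b cell",
               "metabolism", "glycolysis", "deprecated"),
      obsolete = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    edges = tibble::tibble(
      parent = c("root", "i1", "i1", "root", "m1", "root"),
      child = c("i1", "i2", "i3", "m1", "m2", "obs")))
}

# independent brute-force closure oracle: iterative DFS with an explicit
# stack and visited set, straight off the edge list
dfs_walk <- function(graph, id, direction) {
  from <- if (direction == "down") graph$edges$parent else graph$edges$child
  to <- if (direction == "down") graph$edges$child else graph$edges$parent
  visited <- character()
  stack <- to[from == id]
  while (length(stack)) {
    node <- stack[[1]]
    stack <- stack[-1]
    if (node %in% visited) next
    visited <- c(visited, node)
    stack <- c(stack, to[from == node])
  }
  visited
}

dfs_descendants <- function(graph, id) dfs_walk(graph, id, "down")

dfs_ancestors <- function(graph, id) dfs_walk(graph, id, "up")

# random DAG on n terms: edges only from lower to higher index, so acyclic by
# construction
random_dag <- function(n, p = 0.08, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T:%03d", seq_len(n))
  from <- integer(); to <- integer()
  for (j in 2:n) {
    parents <- which(runif(j - 1) < p)
    if (length(parents) == 0L && runif(1) < 0.7) parents <- sample.int(j - 1, 1)
    from <- c(from, parents)
    to <- c(to, rep(j, length(parents)))
  }
  ontology_graph(
    terms = tibble::tibble(id = ids, name = ids, obsolete = FALSE),
    edges = tibble::tibble(parent = ids[from], child = ids[to]))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

small_expr <- function(G = 10, C = 4, seed = 1) {
  set.seed(seed)
  matrix(rpois(G * C, 5), G, C,
         dimnames = list(paste0("g", seq_len(G)), paste0("c", seq_len(C))))
}
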