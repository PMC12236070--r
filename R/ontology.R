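#' Ontology term graphs
#'
#' An `ontology_graph` holds a DAG of terms linked by `is_a` relations: a
#' `terms` tibble (`id`, `name`, `obsolete`) and an `edges` tibble
#' (`parent`, `child`). After [prune_ontology()] the object additionally
#' carries indexed descendant/ancestor closures for fast subtree queries.
#'
#' @param terms tibble/data.frame with columns `id`, `name`, `obsolete`.
#' @param edges tibble/data.frame with columns `parent`, `child`.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  if (!all(c("id", "name", "obsolete") %in% names(terms)))
    abort("`terms` needs columns id, name, obsolete")
  if (!all(c("parent", "child") %in% names(edges)))
    abort("`edges` needs columns parent, child")
  if (anyDuplicated(terms$id)) abort("duplicate term ids")
  dangling <- setdiff(c(edges$parent, edges$child), terms$id)
  if (length(dangling))
    abort(sprintf("edge endpoints not declared as terms: %s",
                  paste(unique(dangling), collapse = ", ")))
  g <- structure(list(terms = terms, edges = edges, index = NULL),
                 class = "ontology_graph")
  if (has_cycle(g)) abort("ontology graph contains a cycle")
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms (%d obsolete), %d is_a edges, %d roots%s\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges),
              length(ontology_roots(x)),
              if (is.null(x$index)) "" else ", indexed"))
  invisible(x)
}

#' @describeIn ontology_graph the term table with a per-term child count.
#' @param x an `ontology_graph`.
#' @param ... unused.
#' @export
tidy.ontology_graph <- function(x, ...) {
  nchild <- table(factor(x$edges$parent, levels = x$terms$id))
  dplyr::mutate(x$terms, n_children = as.integer(nchild[.data$id]))
}

#' Roots of an ontology graph
#' @param graph an [ontology_graph()].
#' @return Character vector of term ids with no parent.
#' @export
ontology_roots <- function(graph) {
  setdiff(graph$terms$id, graph$edges$child)
}

has_cycle <- function(graph) {
  if (nrow(graph$edges) == 0L) return(FALSE)
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("parent", "child")], directed = TRUE,
    vertices = graph$terms["id"])
  !igraph::is_dag(ig)
}

adjacency_list <- function(graph, direction = c("down", "up")) {
  direction <- match.arg(direction)
  from <- if (direction == "down") graph$edges$parent else graph$edges$child
  to <- if (direction == "down") graph$edges$child else graph$edges$parent
  split(to, factor(from, levels = graph$terms$id))
}

#' Read a minimal OBO 1.2 ontology file
#'
#' Recognises `[Term]` stanzas with `id:`, `name:`, `is_a:` and
#' `is_obsolete: true` lines; everything else (including `relationship:`
#' lines such as part_of) is ignored. `is_a` targets must be declared terms;
#' trailing `! comment` text after an is_a target is stripped. Obsolete flags
#' are preserved — pruning is a separate step ([prune_ontology()]).
#'
#' @param path path to an OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo_minimal <- function(path) {
  if (!file.exists(path)) abort(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list(); edges_parent <- character(); edges_child <- character()
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(obsolete = FALSE, parents = character()); in_term <- TRUE; next }
    if (startsWith(ln, "[")) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- trimws(sub("^is_obsolete:", "", ln)) == "true"
    }
  }
  flush()
  if (length(terms) == 0L) abort("OBO file declares no [Term] stanzas")
  ids <- names(terms)
  for (t in terms) {
    if (length(t$parents)) {
      edges_parent <- c(edges_parent, t$parents)
      edges_child <- c(edges_child, rep(t$id, length(t$parents)))
    }
  }
  dangling <- setdiff(edges_parent, ids)
  if (length(dangling))
    abort(sprintf("is_a references undeclared term(s): %s",
                  paste(unique(dangling), collapse = ", ")))
  ontology_graph(
    terms = tibble(id = ids,
                   name = vapply(terms, function(t) t$name %||% t$id, character(1)),
                   obsolete = vapply(terms, `[[`, logical(1), "obsolete")),
    edges = tibble(parent = edges_parent, child = edges_child)
  )
}

#' Read an ontology from a TSV edge list
#'
#' Neutral alternative to OBO: a header plus rows
#' `child_id<TAB>parent_id<TAB>name<TAB>obsolete{0,1}`. A row with an empty
#' `parent_id` declares a root term.
#'
#' @param path path to the TSV file.
#' @return An [ontology_graph()].
#' @export
read_ontology_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("edge-list file not found: %s", path))
  df <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("child_id", "parent_id", "name", "obsolete")
  if (!all(need %in% names(df)))
    abort(sprintf("edge list needs columns: %s", paste(need, collapse = ", ")))
  terms <- tibble(id = df$child_id, name = df$name,
                  obsolete = df$obsolete == "1")
  if (anyDuplicated(terms$id)) abort("duplicate child_id rows")
  has_parent <- nzchar(df$parent_id)
  ontology_graph(terms,
                 tibble(parent = df$parent_id[has_parent],
                        child = df$child_id[has_parent]))
}

#' Prune obsolete terms and index closures
#'
#' Removes obsolete terms together with every edge touching them — children of
#' a pruned term become roots; grandchildren are *not* reattached to
#' grandparents — then computes transitive descendant and ancestor closures so
#' [descendants()] and [ancestors()] are O(1) lookups.
#'
#' @param graph an [ontology_graph()].
#' @return The pruned, indexed [ontology_graph()].
#' @export
prune_ontology <- function(graph) {
  keep <- !graph$terms$obsolete
  if (!any(keep)) abort("pruning removed every term")
  terms <- graph$terms[keep, ]
  edges <- graph$edges[graph$edges$parent %in% terms$id &
                         graph$edges$child %in% terms$id, ]
  g <- ontology_graph(terms, edges)
  down <- adjacency_list(g, "down")
  up <- adjacency_list(g, "up")
  closure <- function(adj) {
    # reverse topological accumulation over the DAG
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("parent", "child")], directed = TRUE, vertices = g$terms["id"])
    order <- rev(names(igraph::topo_sort(ig, mode = "out")))
    out <- setNames(vector("list", nrow(g$terms)), g$terms$id)
    for (id in order) {
      kids <- adj[[id]]
      out[[id]] <- unique(c(kids, unlist(out[kids], use.names = FALSE)))
    }
    out
  }
  desc <- closure(down)
  # ancestors: same accumulation on the reversed relation, ordered root-first
  anc <- setNames(vector("list", nrow(g$terms)), g$terms$id)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("parent", "child")], directed = TRUE, vertices = g$terms["id"])
  for (id in names(igraph::topo_sort(ig, mode = "out"))) {
    parents <- up[[id]]
    anc[[id]] <- unique(c(parents, unlist(anc[parents], use.names = FALSE)))
  }
  g$index <- list(descendants = desc, ancestors = anc)
  g
}

#' Descendant / ancestor closure queries
#'
#' Require a pruned, indexed graph (see [prune_ontology()]).
#'
#' @param graph a pruned [ontology_graph()].
#' @param id a single term id.
#' @return Character vector of term ids (excluding `id` itself).
#' @export
descendants <- function(graph, id) {
  if (is.null(graph$index)) abort("graph is not indexed; call prune_ontology() first")
  if (!id %in% graph$terms$id) abort(sprintf("unknown term id '%s'", id))
  graph$index$descendants[[id]]
}

#' @rdname descendants
#' @export
ancestors <- function(graph, id) {
  if (is.null(graph$index)) abort("graph is not indexed; call prune_ontology() first")
  if (!id %in% graph$terms$id) abort(sprintf("unknown term id '%s'", id))
  graph$index$ancestors[[id]]
}
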