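#' Gene-set collections
#'
#' A `gene_set_collection` is a named list of character vectors (one per gene
#' set) together with per-set display names and provenance metadata. It is the
#' container consumed by the AUCell scoring engine and the ontology-aware
#' filters.
#'
#' @param sets named list of character vectors of gene symbols; names are set
#'   ids and must be unique.
#' @param names_ display names, one per set; defaults to the ids.
#' @param source free-text provenance label.
#' @param species `"human"`, `"mouse"` or `"synthetic"`.
#'
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names_ = NULL, source = "custom",
                                species = c("synthetic", "human", "mouse")) {
  species <- match.arg(species)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    abort("set ids must be present and unique")
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g <- g[!duplicated(g)]
    if (length(g) == 0L) abort("gene sets must be non-empty")
    g
  })
  if (is.null(names_)) names_ <- names(sets)
  if (length(names_) != length(sets)) abort("one display name per set required")
  structure(
    list(sets = sets, names = setNames(as.character(names_), names(sets)),
         source = source, species = species),
    class = "gene_set_collection"
  )
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<gene_set_collection> %d sets (%s, %s); sizes %s..%s\n",
              length(sizes), x$source, x$species,
              if (length(sizes)) min(sizes) else NA,
              if (length(sizes)) max(sizes) else NA))
  invisible(x)
}

#' @describeIn gene_set_collection one row per (set, gene) pair.
#' @param x a `gene_set_collection`.
#' @param ... unused.
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble(
    set_id = rep(names(x$sets), lengths(x$sets)),
    set_name = rep(unname(x$names), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated as
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a line
#' are removed keeping first occurrence; the description field becomes the
#' display name when non-empty.
#'
#' @param path path to a GMT file.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source = basename(path), species = "synthetic") {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("GMT file is empty")
  sets <- list(); nms <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      abort(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", i))
    id <- fields[[1]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L)
      abort(sprintf("malformed GMT line %d: no genes", i))
    if (id %in% names(sets))
      abort(sprintf("duplicate set id '%s' at line %d", id, i))
    sets[[id]] <- genes
    nms[[id]] <- if (nzchar(fields[[2]])) fields[[2]] else id
  }
  gene_set_collection(sets, names_ = nms, source = source, species = species)
}

#' Write a collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$names[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal GAF 2.x association file
#'
#' Reads gene-association (GAF) rows and aggregates them into term-wise gene
#' sets. Only the symbol (column 3), qualifier (column 4), term id (column 5)
#' and aspect (column 9) are used. Rows whose qualifier contains `NOT` are
#' dropped. Comment lines start with `!`.
#'
#' @param path path to a GAF file.
#' @param aspect optional single aspect (`"P"`, `"F"` or `"C"`) to retain.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()] with one set per term.
#' @export
read_gaf_minimal <- function(path, aspect = NULL, source = basename(path),
                             species = "synthetic") {
  if (!file.exists(path)) abort(sprintf("GAF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) abort("GAF file has no association rows")
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 9L)
  if (length(bad))
    abort(sprintf("malformed GAF row %d: fewer than 9 columns", bad[[1]]))
  symbol <- vapply(rows, `[[`, character(1), 3L)
  qualifier <- vapply(rows, `[[`, character(1), 4L)
  term <- vapply(rows, `[[`, character(1), 5L)
  asp <- vapply(rows, `[[`, character(1), 9L)
  if (any(!nzchar(symbol)) || any(!nzchar(term)))
    abort("GAF rows must carry a symbol (col 3) and a term id (col 5)")
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (!is.null(aspect)) {
    aspect <- match.arg(aspect, c("P", "F", "C"))
    keep <- keep & asp == aspect
  }
  if (!any(keep)) abort("no associations remain after filtering")
  sets <- split(symbol[keep], term[keep])
  gene_set_collection(sets, source = source, species = species)
}

#' Filter a gene-set collection by size and ontology position
#'
#' Filters compose conjunctively: size bounds always apply; `root_terms`
#' restricts to the union of the given roots' descendant closures (roots
#' included); `end_level_only` keeps only terms with no children in the pruned
#' graph. Sets whose ids are absent from the graph fail the graph-based
#' filters.
#'
#' @param collection a [gene_set_collection()].
#' @param graph optional pruned [ontology_graph()] (required for `root_terms`
#'   and `end_level_only`).
#' @param min_genes,max_genes inclusive size bounds.
#' @param root_terms optional character vector of subtree roots.
#' @param end_level_only keep only leaf (end-level) terms.
#' @return A filtered [gene_set_collection()]; empty results warn rather than
#'   error.
#' @export
filter_collection <- function(collection, graph = NULL, min_genes = 1L,
                              max_genes = Inf, root_terms = NULL,
                              end_level_only = FALSE) {
  stopifnot_scalar_number(min_genes, "min_genes", lower = 1)
  if (max_genes < min_genes) abort("`max_genes` must be >= `min_genes`")
  if ((length(root_terms) || end_level_only) && is.null(graph))
    abort("`root_terms` and `end_level_only` require an ontology graph")
  keep <- names(collection$sets)
  sizes <- lengths(collection$sets)
  keep <- keep[sizes >= min_genes & sizes <= max_genes]
  if (length(root_terms)) {
    unknown <- setdiff(root_terms, graph$terms$id)
    if (length(unknown))
      abort(sprintf("unknown root term(s): %s", paste(unknown, collapse = ", ")))
    closure <- unique(c(root_terms,
                        unlist(lapply(root_terms, descendants, graph = graph))))
    keep <- intersect(keep, closure)
  }
  if (isTRUE(end_level_only)) {
    leaves <- graph$terms$id[!(graph$terms$id %in% graph$edges$parent)]
    keep <- intersect(keep, leaves)
  }
  if (length(keep) == 0L)
    warn("filter_collection: no gene sets satisfy the filters")
  gene_set_collection(collection$sets[keep],
                      names_ = collection$names[keep],
                      source = collection$source, species = collection$species)
}

#' Resolve term ids to display names
#'
#' Total function: unknown ids are echoed back unchanged and counted.
#'
#' @param ids character vector of term/set ids.
#' @param source an [ontology_graph()] or [gene_set_collection()].
#' @return A list with `names` (same length and order as `ids`) and `warnings`
#'   (count of unknown ids).
#' @export
resolve_names <- function(ids, source) {
  ids <- as.character(ids)
  lookup <- if (inherits(source, "ontology_graph")) {
    setNames(source$terms$name, source$terms$id)
  } else if (inherits(source, "gene_set_collection")) {
    source$names
  } else abort("`source` must be an ontology_graph or gene_set_collection")
  out <- unname(lookup[ids])
  missing <- is.na(out)
  out[missing] <- ids[missing]
  if (any(missing))
    warn(sprintf("resolve_names: %d unknown id(s) echoed back", sum(missing)))
  list(names = out, warnings = sum(missing))
}
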