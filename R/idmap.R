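#' Identifier mapping tables
#'
#' An `id_map` is a two-column tibble of `(source_id, target_id)` pairs with
#' direction metadata, loaded from a local TSV so conversions work offline.
#'
#' @param pairs tibble/data.frame with columns `source_id`, `target_id`.
#' @param direction free-text direction label, e.g. `"human_symbol->mouse_symbol"`.
#' @return A tibble of class `id_map` (duplicate pairs removed) with
#'   attributes `direction` and `multiplicity` (`"one_to_one"` or
#'   `"many_to_many"`).
#' @export
id_map <- function(pairs, direction = "source->target") {
  pairs <- as_tibble(pairs)
  if (!all(c("source_id", "target_id") %in% names(pairs)))
    abort("`pairs` needs columns source_id, target_id")
  pairs <- dplyr::distinct(pairs, .data$source_id, .data$target_id)
  if (nrow(pairs) == 0L) abort("empty mapping table")
  multiplicity <- if (anyDuplicated(pairs$source_id) ||
                      anyDuplicated(pairs$target_id)) "many_to_many" else "one_to_one"
  structure(pairs, direction = direction, multiplicity = multiplicity,
            class = c("id_map", class(pairs)))
}

#' @rdname id_map
#' @param path TSV with a header and two columns (source, target).
#' @export
read_id_map <- function(path, direction = basename(path)) {
  if (!file.exists(path)) abort(sprintf("mapping table not found: %s", path))
  df <- read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) abort("mapping table needs two columns")
  id_map(tibble(source_id = df[[1]], target_id = df[[2]]), direction)
}

#' Map identifiers through a table
#'
#' Order-preserving identifier conversion with an explicit ambiguity policy:
#' `"first"` takes the lexicographically first target of each source,
#' `"all"` expands every match (with provenance), `"drop_ambiguous"` removes
#' sources with more than one target. Unmapped ids are omitted and counted.
#'
#' @param ids character vector of source identifiers.
#' @param map an [id_map()].
#' @param policy `"first"`, `"all"` or `"drop_ambiguous"`.
#' @return A list: `mapped` (tibble `source_id`, `target_id`, input order
#'   preserved), `unmapped` (count), `ambiguous` (count of ambiguous input
#'   ids).
#' @export
map_ids <- function(ids, map, policy = c("first", "all", "drop_ambiguous")) {
  policy <- match.arg(policy)
  if (!inherits(map, "id_map")) abort("`map` must be an id_map")
  ids <- as.character(ids)
  tab <- split(map$target_id, map$source_id)
  tab <- lapply(tab, sort)
  hits <- tab[ids]
  unmapped <- sum(vapply(hits, is.null, logical(1)))
  n_targets <- vapply(hits, length, integer(1))
  ambiguous <- sum(n_targets > 1L)
  keep <- switch(policy,
    first = n_targets >= 1L,
    all = n_targets >= 1L,
    drop_ambiguous = n_targets == 1L)
  src <- ids[keep]
  tgt <- hits[keep]
  if (policy == "first") tgt <- lapply(tgt, `[`, 1L)
  mapped <- tibble(source_id = rep(src, lengths(tgt)),
                   target_id = unlist(tgt, use.names = FALSE) %||% character())
  list(mapped = mapped, unmapped = unmapped, ambiguous = ambiguous)
}

#' Convert an expression matrix across species
#'
#' Renames gene rows through an ortholog table; rows mapping to the same
#' target are combined by `sum` (count semantics, the default) or `mean`
#' (suits normalised data); unmapped rows are dropped with a message. Cell
#' order is unchanged. With a total, onto, sum-aggregated map, per-cell
#' column sums are conserved exactly.
#'
#' @param expr genes x cells matrix with gene rownames.
#' @param ortholog an [id_map()] (source = current rownames).
#' @param aggregate `"sum"` or `"mean"`.
#' @return A genes x cells matrix on target identifiers.
#' @export
convert_matrix_species <- function(expr, ortholog, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  expr <- as_expression_matrix(expr)
  res <- map_ids(rownames(expr), ortholog, policy = "first")
  if (nrow(res$mapped) == 0L) abort("no gene of the matrix maps through the table")
  if (res$unmapped > 0L)
    inform(sprintf("convert_matrix_species: dropping %d unmapped gene row(s)",
                   res$unmapped))
  m <- as.matrix(expr)[res$mapped$source_id, , drop = FALSE]
  grouped <- rowsum(m, group = res$mapped$target_id)
  if (aggregate == "mean") {
    counts <- as.vector(table(res$mapped$target_id)[rownames(grouped)])
    grouped <- grouped / counts
  }
  as_expression_matrix(grouped)
}
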