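#' AUCell scoring parameters
#'
#' AUCell scores a gene set in a single cell as the (normalised) area under
#' the recovery curve of set genes within the top fraction `q` of the cell's
#' expression ranking. With `G` genes the rank cutoff is
#' `T = max(1, floor(q * G))`; the recovery curve `R(k)` counts set members at
#' rank `<= k`; the raw area is `sum(R(k), k = 1..T)` and is normalised by the
#' maximal achievable area `sum(min(k, m), k = 1..T)` for a set of `m` present
#' genes, so a score of 1 means the set occupies the very top of the ranking.
#'
#' @param q top fraction of the ranking considered, in (0, 1]. Default 0.05
#'   (top 5%), the usual AUCell convention.
#' @param tie_rule how ties in expression are broken: `"seeded_shuffle"`
#'   (a seeded random gene permutation applied before a stable sort; unbiased
#'   for zero-inflated data yet reproducible) or `"stable_index"` (input gene
#'   order; exactly hand-checkable).
#' @param seed integer seed consumed by `"seeded_shuffle"`.
#' @param min_set_genes minimum number of set genes present in the matrix for
#'   a set to be scored.
#' @return An object of class `aucell_params`.
#' @export
aucell_params <- function(q = 0.05, tie_rule = c("seeded_shuffle", "stable_index"),
                          seed = 0L, min_set_genes = 1L) {
  stopifnot_scalar_number(q, "q", lower = 1e-12, upper = 1)
  stopifnot_scalar_number(min_set_genes, "min_set_genes", lower = 1)
  structure(list(q = q, tie_rule = match.arg(tie_rule), seed = as.integer(seed),
                 min_set_genes = as.integer(min_set_genes)),
            class = "aucell_params")
}

#' Rank genes within each cell
#'
#' Produces the genes x cells integer rank matrix that AUCell scoring
#' consumes: rank 1 is the highest-expressed gene within a cell, and every
#' column is a permutation of `1..G`. Rankings are invariant under any
#' strictly monotone per-cell transform of expression.
#'
#' @param expr genes x cells numeric matrix (base or `Matrix`), with rownames.
#' @param params an [aucell_params()].
#' @return An object of class `cell_ranking` with elements `ranks`,
#'   `gene_ids`, `cell_ids`.
#' @export
rank_cells <- function(expr, params = aucell_params()) {
  expr <- as_expression_matrix(expr)
  x <- as.matrix(expr)
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite expression value at gene '%s', cell '%s'",
                  rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  G <- nrow(x)
  perm <- if (params$tie_rule == "seeded_shuffle") {
    with_stage_seed(params$seed, "rank_ties", sample.int(G))
  } else seq_len(G)
  ranks <- matrix(0L, G, ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    # stable sort of the (possibly permuted) gene order by decreasing value
    o <- order(-x[perm, j])          # base::order is stable
    ranks[perm[o], j] <- seq_len(G)
  }
  structure(list(ranks = ranks, gene_ids = rownames(x), cell_ids = colnames(x),
                 params = params),
            class = "cell_ranking")
}

aucell_cutoff <- function(q, G) max(1L, floor(q * G))

#' Score one gene set across cells
#'
#' Strict single-set variant: an empty intersection with the gene universe is
#' an error. See [score_collection()] for the lenient batch form.
#'
#' @param ranking a [rank_cells()] result.
#' @param genes character vector of gene symbols (a gene set).
#' @param params an [aucell_params()].
#' @return Named numeric vector of per-cell scores in \[0, 1\].
#' @export
score_set <- function(ranking, genes, params = aucell_params()) {
  if (!inherits(ranking, "cell_ranking")) abort("`ranking` must come from rank_cells()")
  idx <- match(unique(as.character(genes)), ranking$gene_ids)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) abort("gene set does not intersect the expression matrix")
  if (length(idx) < params$min_set_genes)
    abort(sprintf("only %d set gene(s) present; min_set_genes = %d",
                  length(idx), params$min_set_genes))
  score_idx(ranking$ranks, idx, params$q)
}

# vectorised core: A = sum over member ranks r <= T of (T - r + 1)
score_idx <- function(ranks, idx, q) {
  G <- nrow(ranks)
  T_ <- aucell_cutoff(q, G)
  m <- length(idx)
  k <- seq_len(T_)
  a_max <- sum(pmin(k, m))
  r <- ranks[idx, , drop = FALSE]
  contrib <- pmax(T_ - r + 1L, 0L)
  setNames(colSums(contrib) / a_max, colnames(ranks))
}

#' Score a whole collection into a score matrix
#'
#' Lenient batch form of [score_set()]: sets whose intersection with the gene
#' universe falls below `min_set_genes` are dropped with a warning; zero
#' surviving sets is an error. Accepts either a raw expression matrix (ranked
#' internally) or a precomputed [rank_cells()] ranking.
#'
#' @param x genes x cells expression matrix or a `cell_ranking`.
#' @param collection a [gene_set_collection()].
#' @param params an [aucell_params()].
#' @return A sets x cells numeric matrix of class `aucell_scores` with the
#'   parameter snapshot in `attr(, "params")`.
#' @export
score_collection <- function(x, collection, params = aucell_params()) {
  ranking <- if (inherits(x, "cell_ranking")) x else rank_cells(x, params)
  present <- lapply(collection$sets, function(g) {
    i <- match(g, ranking$gene_ids)
    i[!is.na(i)]
  })
  ok <- lengths(present) >= params$min_set_genes
  if (!any(ok)) abort("no gene set has enough genes in the expression matrix")
  if (any(!ok))
    warn(sprintf("dropping %d set(s) with < %d genes in the matrix: %s",
                 sum(!ok), params$min_set_genes,
                 paste(head(names(present)[!ok], 5), collapse = ", ")))
  scores <- do.call(rbind, lapply(present[ok], function(i)
    score_idx(ranking$ranks, i, params$q)))
  rownames(scores) <- names(present)[ok]
  colnames(scores) <- ranking$cell_ids
  structure(scores, params = params, class = c("aucell_scores", "matrix", "array"))
}

#' @export
print.aucell_scores <- function(x, ...) {
  cat(sprintf("<aucell_scores> %d sets x %d cells, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @describeIn score_collection long tibble of (set_id, cell_id, score).
#' @export
tidy.aucell_scores <- function(x, ...) {
  tibble(set_id = rep(rownames(x), times = ncol(x)),
         cell_id = rep(colnames(x), each = nrow(x)),
         score = as.vector(unclass(x)))
}

#' Brute-force AUCell oracle for one cell
#'
#' Independent reference implementation used to validate [score_set()]: sorts
#' a single cell's expression explicitly and accumulates the recovery curve
#' value by value in an explicit `k` loop. Shares no code with the vectorised
#' engine.
#'
#' @param values named numeric vector: one cell's expression over the gene
#'   universe.
#' @param genes gene set (character).
#' @param params an [aucell_params()]; tie handling follows `tie_rule`.
#' @return A single score in \[0, 1\].
#' @export
oracle_score_set <- function(values, genes, params = aucell_params()) {
  G <- length(values)
  ids <- names(values)
  ord_ids <- if (params$tie_rule == "seeded_shuffle") {
    perm <- with_stage_seed(params$seed, "rank_ties", sample.int(G))
    shuffled <- values[perm]
    names(shuffled)[order(-shuffled)]
  } else {
    ids[order(-values)]
  }
  members <- unique(as.character(genes))
  members <- members[members %in% ids]
  m <- length(members)
  if (m == 0L) abort("gene set does not intersect the expression universe")
  T_ <- max(1L, floor(params$q * G))
  area <- 0
  a_max <- 0
  hits <- 0
  for (k in seq_len(T_)) {
    if (ord_ids[k] %in% members) hits <- hits + 1
    area <- area + hits
    a_max <- a_max + min(k, m)
  }
  area / a_max
}
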