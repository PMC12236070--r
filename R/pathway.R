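#' Pathway-space pipeline configuration
#'
#' Configuration for [run_pathway_pipeline()], which clusters and embeds
#' cells from a pathway-score matrix (AUCell scores per gene set) instead of
#' gene expression.
#'
#' @param normalize `"libsize_log1p"` (per-cell scaling to 10,000 counts then
#'   `log1p`; the conventional choice) or `"none"`. AUCell is rank-based, so
#'   this mainly matters for the gene-space comparison arm.
#' @param score_standardize `"zscore_per_set"` (default) or `"none"`.
#' @param zclip absolute cap applied to z-scores before PCA.
#' @param n_pcs number of principal components (lowered with a warning when
#'   fewer features are available).
#' @param k_neighbors neighbourhood size of the k-NN graph (and UMAP).
#' @param cluster_method `"leiden"` (k-NN graph + Leiden partition; the
#'   default, matching current single-cell practice) or `"kmeans"` (the
#'   exactly-testable path).
#' @param resolution Leiden resolution (modularity objective).
#' @param k number of clusters for `"kmeans"`.
#' @param embed `"umap"` or `"none"`.
#' @param seed run-level seed; every stochastic stage draws from a named
#'   substream of it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(normalize = c("libsize_log1p", "none"),
                            score_standardize = c("zscore_per_set", "none"),
                            zclip = 10, n_pcs = 50L, k_neighbors = 20L,
                            cluster_method = c("leiden", "kmeans"),
                            resolution = 0.8, k = NULL,
                            embed = c("umap", "none"), seed = 0L) {
  cluster_method <- match.arg(cluster_method)
  stopifnot_scalar_number(n_pcs, "n_pcs", lower = 2)
  stopifnot_scalar_number(k_neighbors, "k_neighbors", lower = 2)
  stopifnot_scalar_number(zclip, "zclip", lower = 0)
  if (cluster_method == "kmeans" && is.null(k))
    abort("cluster_method = 'kmeans' requires `k`")
  structure(list(normalize = match.arg(normalize),
                 score_standardize = match.arg(score_standardize),
                 zclip = zclip, n_pcs = as.integer(n_pcs),
                 k_neighbors = as.integer(k_neighbors),
                 cluster_method = cluster_method, resolution = resolution,
                 k = if (is.null(k)) NULL else as.integer(k),
                 embed = match.arg(embed), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Standardise a score matrix per set
#'
#' `zscore_per_set` centres and scales each set row by its sample standard
#' deviation (ddof 1), maps zero-variance rows to all zeros, and clips the
#' result to `[-zclip, zclip]`. `none` passes through.
#'
#' @param scores sets x cells numeric matrix.
#' @param method `"zscore_per_set"` or `"none"`.
#' @param zclip absolute cap on the standardised values.
#' @return A matrix of the same shape.
#' @export
standardize_scores <- function(scores, method = c("zscore_per_set", "none"),
                               zclip = 10) {
  method <- match.arg(method)
  m <- as.matrix(scores)
  if (method == "none") return(m)
  if (ncol(m) < 2L) abort("z-scoring requires >= 2 cells")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  pmin(pmax(z, -zclip), zclip)
}

#' Cluster cells in a reduced space
#'
#' Leiden: builds a symmetrised k-nearest-neighbour graph (Euclidean in PC
#' space) and partitions it with the Leiden algorithm at the configured
#' resolution (modularity objective), seeded. K-means: seeded
#' [stats::kmeans()] with `k` centres.
#'
#' @param pcs cells x dims numeric matrix.
#' @param config a [pipeline_config()].
#' @return Integer cluster labels (1-based), named by cell.
#' @export
cluster_cells <- function(pcs, config) {
  pcs <- as.matrix(pcs)
  if (any(!is.finite(pcs))) abort("non-finite values in the reduced space")
  n <- nrow(pcs)
  if (all(apply(pcs, 2L, function(col) length(unique(col)) == 1L))) {
    warn("all cells identical in the reduced space; returning one cluster")
    return(setNames(rep(1L, n), rownames(pcs)))
  }
  labels <- if (config$cluster_method == "kmeans") {
    km <- with_stage_seed(config$seed, "kmeans",
                          kmeans(pcs, centers = config$k, nstart = 10L,
                                 iter.max = 100L))
    km$cluster
  } else {
    if (n <= config$k_neighbors) abort("need more cells than k_neighbors")
    g <- knn_graph(pcs, config$k_neighbors)
    part <- with_stage_seed(config$seed, "leiden",
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = config$resolution, n_iterations = 5L))
    igraph::membership(part)
  }
  setNames(as.integer(labels), rownames(pcs))
}

knn_graph <- function(pcs, k) {
  d <- as.matrix(dist(pcs))
  n <- nrow(d)
  nbrs <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbrs)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Run the pathway-space pipeline
#'
#' The core workflow: normalise expression, score a gene-set collection with
#' AUCell, standardise the score matrix, then PCA, k-NN/Leiden (or k-means)
#' clustering, and optionally a seeded UMAP embedding — all computed in
#' pathway space rather than gene space. Each stage records a content hash of
#' its inputs; passing a previous result as `cache` re-executes only stages
#' whose input hashes changed.
#'
#' Setting `feature_space = "gene"` skips scoring and runs the identical
#' downstream stages on the (normalised, per-gene standardised) expression
#' matrix, which is the comparison arm for batch-robustness checks.
#'
#' @param expr genes x cells expression matrix (counts or normalised).
#' @param collection a [gene_set_collection()] (ignored for
#'   `feature_space = "gene"`).
#' @param config a [pipeline_config()].
#' @param aucell an [aucell_params()].
#' @param feature_space `"pathway"` (default) or `"gene"`.
#' @param cache optional previous `pathway_space` result for conditional
#'   re-execution.
#' @return An object of class `pathway_space` with elements `scores`, `pcs`,
#'   `labels`, `embedding` (or `NULL`), `stage_hashes`, `stages_run`.
#' @export
run_pathway_pipeline <- function(expr, collection = NULL,
                                 config = pipeline_config(),
                                 aucell = aucell_params(),
                                 feature_space = c("pathway", "gene"),
                                 cache = NULL) {
  feature_space <- match.arg(feature_space)
  expr <- as_expression_matrix(expr)
  if (ncol(expr) <= config$k_neighbors)
    abort("fewer cells than k_neighbors")
  hashes <- list()
  ran <- character()
  cached <- function(stage, input_hash, compute) {
    hashes[[stage]] <<- input_hash
    if (!is.null(cache) && identical(cache$stage_hashes[[stage]], input_hash) &&
        !is.null(cache$stage_values[[stage]])) {
      inform(sprintf("stage '%s': inputs unchanged, skipped", stage))
      return(cache$stage_values[[stage]])
    }
    ran <<- c(ran, stage)
    compute()
  }
  h_expr <- hash(list(as.matrix(expr), config$normalize))
  norm <- cached("normalize", h_expr, function() {
    if (config$normalize == "libsize_log1p") normalize_libsize_log1p(expr)
    else as.matrix(expr)
  })
  if (feature_space == "pathway") {
    if (is.null(collection)) abort("a gene-set collection is required")
    h_score <- hash(list(hashes$normalize, lapply(collection$sets, identity),
                         unclass(aucell)))
    scores <- cached("score", h_score, function()
      score_collection(norm, collection, aucell))
  } else {
    h_score <- hash(list(hashes$normalize, "gene_space"))
    scores <- cached("score", h_score, function() {
      structure(norm, class = c("aucell_scores", "matrix", "array"))
    })
  }
  h_std <- hash(list(hashes$score, config$score_standardize, config$zclip))
  std <- cached("standardize", h_std, function()
    standardize_scores(scores, config$score_standardize, config$zclip))
  n_pcs <- config$n_pcs
  if (nrow(std) < n_pcs + 1L) {
    n_pcs <- max(2L, nrow(std) - 1L)
    warn(sprintf("only %d feature(s): lowering n_pcs to %d", nrow(std), n_pcs))
  }
  h_pca <- hash(list(hashes$standardize, n_pcs))
  pcs <- cached("pca", h_pca, function() {
    p <- prcomp(t(std), center = TRUE, scale. = FALSE, rank. = n_pcs)
    p$x
  })
  h_clust <- hash(list(hashes$pca, config$cluster_method, config$resolution,
                       config$k, config$k_neighbors, config$seed))
  labels <- cached("cluster", h_clust, function() cluster_cells(pcs, config))
  embedding <- NULL
  if (config$embed == "umap") {
    h_emb <- hash(list(hashes$pca, config$k_neighbors, config$seed))
    embedding <- cached("embed", h_emb, function() {
      e <- with_stage_seed(config$seed, "umap",
        uwot::umap(pcs, n_neighbors = config$k_neighbors, n_threads = 1L,
                   n_sgd_threads = 0L))
      dimnames(e) <- list(rownames(pcs), c("UMAP1", "UMAP2"))
      e
    })
  }
  structure(list(scores = scores, pcs = pcs, labels = labels,
                 embedding = embedding, stage_hashes = hashes,
                 stages_run = ran,
                 stage_values = list(normalize = norm, score = scores,
                                     standardize = std, pca = pcs,
                                     cluster = labels, embed = embedding),
                 config = config),
            class = "pathway_space")
}

#' @export
print.pathway_space <- function(x, ...) {
  cat(sprintf("<pathway_space> %d cells, %d features, %d PCs, %d clusters%s\n",
              length(x$labels), nrow(x$scores), ncol(x$pcs),
              length(unique(x$labels)),
              if (is.null(x$embedding)) "" else ", 2-D embedding"))
  invisible(x)
}

#' @describeIn run_pathway_pipeline one row per cell: label, PCs, embedding.
#' @param x a `pathway_space` result.
#' @param ... unused.
#' @export
tidy.pathway_space <- function(x, ...) {
  out <- tibble(cell_id = names(x$labels), cluster = x$labels)
  out <- dplyr::bind_cols(out, as_tibble(x$pcs[, 1:min(2L, ncol(x$pcs)), drop = FALSE]))
  if (!is.null(x$embedding)) out <- dplyr::bind_cols(out, as_tibble(x$embedding))
  out
}

#' @describeIn run_pathway_pipeline one-row summary of the fitted space.
#' @export
glance.pathway_space <- function(x, ...) {
  tibble(n_cells = length(x$labels), n_features = nrow(x$scores),
         n_pcs = ncol(x$pcs), n_clusters = length(unique(x$labels)),
         embedded = !is.null(x$embedding))
}

#' @describeIn run_pathway_pipeline embedding (or first two PCs) coloured by
#'   cluster.
#' @param object a `pathway_space` result.
#' @export
autoplot.pathway_space <- function(object, ...) {
  df <- tidy(object)
  xy <- if (!is.null(object$embedding)) c("UMAP1", "UMAP2") else c("PC1", "PC2")
  ggplot2::ggplot(df, ggplot2::aes(.data[[xy[1]]], .data[[xy[2]]],
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_minimal()
}
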