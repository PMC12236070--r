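#' Cluster-by-signature enrichment matrix
#'
#' Summarises a marker-signature AUCell score matrix per cluster: for each
#' signature, the mean score within each cluster, z-scored across clusters
#' (sample sd; constant signatures map to 0). This is the matrix behind the
#' cluster-annotation heatmap.
#'
#' @param scores signatures x cells matrix (e.g. from [score_collection()]
#'   over a marker collection).
#' @param labels per-cell cluster ids (vector, same length as `ncol(scores)`).
#' @return A `group_stats` object (metric `"zscore"`) carrying the raw
#'   cluster means in `attr(, "means")`.
#' @export
cluster_signature_matrix <- function(scores, labels) {
  m <- as.matrix(scores)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) abort("one label per cell required")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) abort("need >= 2 clusters")
  if (any(table(factor(labels, levels = groups)) == 0L))
    abort("empty cluster")
  means <- vapply(groups, function(g)
    rowMeans(m[, labels == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) means <- matrix(means, 1L, dimnames = list(rownames(m), groups))
  z <- row_zscore(means)
  new_group_stats(z, metric = "zscore",
                  params = list(summary = "cluster_mean"), means = means)
}

# z across columns per row; sample sd, zero-sd rows -> 0
row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Rank signatures per cluster and assign labels
#'
#' For each cluster, orders signatures by z-score (descending; ties broken by
#' signature id) and assigns the top signature as the cluster label when its
#' z clears `min_z` (always, when `min_z` is `NULL`).
#'
#' @param stats a z-scored signature x cluster `group_stats`, from
#'   [cluster_signature_matrix()].
#' @param top_k how many signatures to report per cluster.
#' @param min_z optional minimum z for assignment; below it the cluster is
#'   left unassigned (`NA`).
#' @return An `annotation_result`: a tibble with columns `cluster`, `rank`,
#'   `signature`, `z`, `mean`, `assigned`.
#' @export
annotate_clusters <- function(stats, top_k = 5L, min_z = NULL) {
  if (!inherits(stats, "group_stats") || stats$metric != "zscore")
    abort("`stats` must be a z-scored group_stats (see cluster_signature_matrix)")
  stopifnot_scalar_number(top_k, "top_k", lower = 1)
  z <- stats$values
  means <- attr(stats, "means")
  rows <- lapply(colnames(z), function(cl) {
    ord <- order(-z[, cl], rownames(z))
    take <- ord[seq_len(min(top_k, length(ord)))]
    top_z <- z[take[1], cl]
    tibble(cluster = cl, rank = seq_along(take),
           signature = rownames(z)[take], z = unname(z[take, cl]),
           mean = if (is.null(means)) NA_real_ else unname(means[take, cl]),
           assigned = seq_along(take) == 1L &
             (is.null(min_z) || top_z >= min_z))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("annotation_result", class(out))
  attr(out, "top_k") <- as.integer(top_k)
  out
}

#' Assigned label per cluster
#'
#' @param annotation an [annotate_clusters()] result.
#' @return Named character vector cluster -> signature (`NA` when
#'   unassigned).
#' @export
assigned_labels <- function(annotation) {
  top <- dplyr::filter(annotation, .data$rank == 1L)
  setNames(ifelse(top$assigned, top$signature, NA_character_), top$cluster)
}

#' @describeIn annotate_clusters heatmap of the per-cluster top signatures.
#' @param object an `annotation_result`.
#' @param ... unused.
#' @export
autoplot.annotation_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cluster, .data$signature,
                                       fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "cluster", y = "signature", fill = "z")
}
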