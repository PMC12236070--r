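#' Group-level statistics container
#'
#' `group_stats` wraps a features x groups matrix of one named metric, with
#' the parameter snapshot used to compute it. Created by [group_metric()],
#' [proportion_positive()] and [cluster_signature_matrix()].
#'
#' @name group_stats
NULL

new_group_stats <- function(values, metric, params = list(), means = NULL) {
  structure(list(values = values, metric = metric,
                 feature_ids = rownames(values), group_ids = colnames(values),
                 params = params),
            means = means, class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> metric '%s': %d features x %d groups\n",
              x$metric, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname group_stats
#' @param x a `group_stats` object.
#' @param ... unused.
#' @return `tidy()`: a long tibble (feature, group, value, metric).
#' @export
tidy.group_stats <- function(x, ...) {
  tibble(feature = rep(x$feature_ids, times = ncol(x$values)),
         group = rep(x$group_ids, each = nrow(x$values)),
         value = as.vector(x$values), metric = x$metric)
}

#' @rdname group_stats
#' @param object a `group_stats` object.
#' @export
autoplot.group_stats <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$group, .data$feature, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = object$metric)
}

group_split_means <- function(m, labels, groups) {
  res <- vapply(groups, function(g) rowMeans(m[, labels == g, drop = FALSE]),
                numeric(nrow(m)))
  if (!is.matrix(res))    # single-feature matrices simplify to a vector
    res <- matrix(res, 1L, dimnames = list(rownames(m), groups))
  res
}

#' Per-group feature metrics
#'
#' Computes one metric per feature x group: `mean` and `median` are plain
#' group summaries; `zscore` standardises group means across groups per
#' feature (sample sd, zero-sd rows map to 0); `logfc` is
#' `log2((m_in + p) / (m_out + p))` one-vs-rest with pseudocount `p`;
#' `tscore` is the Welch t statistic one-vs-rest.
#'
#' @param m features x cells numeric matrix with dimnames.
#' @param labels per-cell group ids.
#' @param metric one of `"mean"`, `"median"`, `"zscore"`, `"logfc"`,
#'   `"tscore"`.
#' @param pseudocount stabilising pseudocount for `logfc` (must be > 0).
#' @return A [group_stats] object.
#' @export
group_metric <- function(m, labels,
                         metric = c("mean", "median", "zscore", "logfc", "tscore"),
                         pseudocount = 1) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) abort("one label per cell required")
  groups <- sort(unique(labels))
  if (any(table(factor(labels, levels = groups)) == 0L)) abort("empty group")
  values <- switch(metric,
    mean = group_split_means(m, labels, groups),
    median = vapply(groups, function(g)
      apply(m[, labels == g, drop = FALSE], 1L, median), numeric(nrow(m))),
    zscore = row_zscore(group_split_means(m, labels, groups)),
    logfc = {
      if (pseudocount <= 0) abort("`pseudocount` must be > 0")
      vapply(groups, function(g) {
        m_in <- rowMeans(m[, labels == g, drop = FALSE])
        m_out <- rowMeans(m[, labels != g, drop = FALSE])
        log2((m_in + pseudocount) / (m_out + pseudocount))
      }, numeric(nrow(m)))
    },
    tscore = vapply(groups, function(g)
      welch_t_rows(m[, labels == g, drop = FALSE],
                   m[, labels != g, drop = FALSE]), numeric(nrow(m)))
  )
  if (nrow(m) == 1L)
    values <- matrix(values, 1L, dimnames = list(rownames(m), groups))
  dimnames(values) <- list(rownames(m), groups)
  new_group_stats(values, metric,
                  params = list(pseudocount = pseudocount, reference = "rest"))
}

welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se <- sqrt(va / na + vb / nb)
  t <- (rowMeans(a) - rowMeans(b)) / se
  t[se == 0] <- 0
  t
}

#' Proportion of positive cells per group
#'
#' Fraction of cells per feature x group with value strictly greater than
#' `threshold`.
#'
#' @inheritParams group_metric
#' @param threshold positivity cutoff (default 0).
#' @return A [group_stats] object (metric `"prop_positive"`).
#' @export
proportion_positive <- function(m, labels, threshold = 0) {
  m <- as.matrix(m)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) abort("one label per cell required")
  groups <- sort(unique(labels))
  if (any(table(factor(labels, levels = groups)) == 0L)) abort("empty group")
  values <- vapply(groups, function(g)
    rowMeans(m[, labels == g, drop = FALSE] > threshold), numeric(nrow(m)))
  if (nrow(m) == 1L)
    values <- matrix(values, 1L, dimnames = list(rownames(m), groups))
  dimnames(values) <- list(rownames(m), groups)
  new_group_stats(values, "prop_positive", params = list(threshold = threshold))
}

#' Waterfall ranking of two-group differences
#'
#' Ranks features by a two-group contrast and marks the `top_n` features by
#' absolute value for labelling in a waterfall plot (ties broken by feature
#' id; fewer than `top_n` features clamps to all of them).
#'
#' @param m features x cells matrix.
#' @param labels per-cell group ids.
#' @param group_a,group_b the two groups to contrast (a minus b).
#' @param metric `"mean_diff"`, `"logfc"` or `"tscore"`.
#' @param top_n how many features to flag for labelling (default 20).
#' @param pseudocount for `"logfc"`.
#' @return A tibble of class `waterfall_rank` sorted by metric descending:
#'   columns `feature`, `value`, `labeled`.
#' @export
waterfall_rank <- function(m, labels, group_a, group_b,
                           metric = c("mean_diff", "logfc", "tscore"),
                           top_n = 20L, pseudocount = 1) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  labels <- as.character(labels)
  if (!group_a %in% labels) abort(sprintf("unknown group id '%s'", group_a))
  if (!group_b %in% labels) abort(sprintf("unknown group id '%s'", group_b))
  a <- m[, labels == group_a, drop = FALSE]
  b <- m[, labels == group_b, drop = FALSE]
  value <- switch(metric,
    mean_diff = rowMeans(a) - rowMeans(b),
    logfc = log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount)),
    tscore = welch_t_rows(a, b))
  out <- tibble(feature = rownames(m), value = unname(value))
  out <- dplyr::arrange(out, dplyr::desc(.data$value), .data$feature)
  lab_order <- order(-abs(out$value), out$feature)
  flag <- rep(FALSE, nrow(out))
  flag[lab_order[seq_len(min(top_n, nrow(out)))]] <- TRUE
  out$labeled <- flag
  class(out) <- c("waterfall_rank", class(out))
  out
}

#' @describeIn waterfall_rank waterfall bar plot with the flagged features
#'   named.
#' @param object a `waterfall_rank` tibble.
#' @param ... unused.
#' @export
autoplot.waterfall_rank <- function(object, ...) {
  df <- dplyr::mutate(object, feature = factor(.data$feature,
                                               levels = .data$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$value,
                                   fill = .data$value > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(data = dplyr::filter(df, .data$labeled),
                       ggplot2::aes(label = .data$feature),
                       angle = 90, hjust = -0.1, size = 2.5) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "difference")
}

#' Broad-style running enrichment score
#'
#' Walks a descending-ordered gene-level statistic: set hits add
#' `|stat|^p / sum(|stat_hits|^p)`, misses subtract `1/(G - m)`. The
#' enrichment score (ES) is the maximal signed deviation of the running sum;
#' the leading edge contains the hits at or before the extremum. Significance
#' is the two-sample Kolmogorov-Smirnov test comparing the rank positions of
#' set genes against non-set genes (asymptotic p).
#'
#' @param ranked_metric named numeric vector, ordered descending (names are
#'   gene ids).
#' @param genes gene set (character).
#' @param weight_p hit-weighting exponent (default 1; `0` gives the classic
#'   unweighted Kolmogorov-Smirnov walk).
#' @return A `gsea_result` list: `es`, `running_curve` (tibble `rank`,
#'   `gene`, `running`, `hit`), `leading_edge`, `ks_stat`, `p_value`.
#' @export
gsea_running_score <- function(ranked_metric, genes, weight_p = 1) {
  stat <- ranked_metric
  if (is.null(names(stat))) abort("`ranked_metric` must be named by gene")
  if (is.unsorted(rev(stat))) {
    if (is.unsorted(-stat)) abort("`ranked_metric` must be ordered descending")
  }
  G <- length(stat)
  hit <- names(stat) %in% unique(as.character(genes))
  m <- sum(hit)
  if (m == 0L) abort("gene set does not intersect the ranked list")
  if (m == G) abort("gene set covers the whole ranked list")
  w <- abs(stat)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  if (sum(w[hit]) == 0) inc[hit] <- 1 / m   # degenerate all-zero stats
  dec <- ifelse(hit, 0, 1 / (G - m))
  running <- cumsum(inc - dec)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) names(stat)[seq_len(i_max)][hit[seq_len(i_max)]]
  else names(stat)[i_max:G][hit[i_max:G]]
  ks <- suppressWarnings(
    ks.test(which(hit), which(!hit), exact = FALSE))
  structure(list(es = unname(es),
                 running_curve = tibble(rank = seq_len(G), gene = names(stat),
                                        running = unname(running), hit = hit),
                 leading_edge = leading,
                 ks_stat = unname(ks$statistic),
                 p_value = unname(ks$p.value)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.4f, KS D = %.4f, p = %.3g, leading edge %d genes\n",
              x$es, x$ks_stat, x$p_value, length(x$leading_edge)))
  invisible(x)
}

#' @describeIn gsea_running_score one-row summary (es, ks_stat, p_value,
#'   leading-edge size).
#' @param x a `gsea_result`.
#' @param ... unused.
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(es = x$es, ks_stat = x$ks_stat, p_value = x$p_value,
         leading_edge_size = length(x$leading_edge))
}

#' @describeIn gsea_running_score the running-score curve with hit rug.
#' @export
tidy.gsea_result <- function(x, ...) x$running_curve

#' @describeIn gsea_running_score Broad-style enrichment plot.
#' @param object a `gsea_result`.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- object$running_curve
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2E7D32") +
    ggplot2::geom_rug(data = dplyr::filter(df, .data$hit), sides = "b",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "rank in ordered list", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f, KS p = %.2g",
                                     object$es, object$p_value))
}

#' Per-feature two-group tests with significance stars
#'
#' Wilcoxon rank-sum (normal approximation with continuity correction, the
#' single-cell convention) or Welch t test per feature, with the usual star
#' codes: `ns`, `*` (p < 0.05), `**` (< 0.01), `***` (< 0.001),
#' `****` (< 0.0001). Features constant across both groups get p = 1 with a
#' warning under Wilcoxon. Benjamini-Hochberg adjusted p-values are included
#' when `adjust = TRUE`.
#'
#' @param m features x cells matrix.
#' @param labels per-cell group ids (exactly two groups).
#' @param test `"wilcoxon"` or `"welch_t"`.
#' @param adjust add a BH-adjusted p column.
#' @return A tibble: `feature`, `p_value`, `stars` (and `p_adj`).
#' @export
two_group_feature_test <- function(m, labels, test = c("wilcoxon", "welch_t"),
                                   adjust = FALSE) {
  test <- match.arg(test)
  m <- as.matrix(m)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) abort("exactly two groups required")
  ia <- labels == groups[1]; ib <- labels == groups[2]
  if (sum(ia) < 2L || sum(ib) < 2L) abort("both groups need >= 2 cells")
  constant <- 0L
  p <- vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ia]; b <- m[i, ib]
    if (test == "wilcoxon") {
      if (length(unique(c(a, b))) == 1L) { constant <<- constant + 1L; return(1) }
      suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    } else {
      if (sd(a) == 0 && sd(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
      t.test(a, b)$p.value
    }
  }, numeric(1))
  if (constant > 0L)
    warn(sprintf("%d constant feature(s) set to p = 1 under wilcoxon", constant))
  out <- tibble(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
                p_value = p, stars = p_stars(p))
  if (adjust) out$p_adj <- p.adjust(p, "BH")
  out
}

#' Star codes for p-values
#'
#' Four-tier convention: `****` below 1e-4, `***` below 1e-3, `**` below
#' 0.01, `*` below 0.05, else `ns`.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of codes.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
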