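lbl_expr <- function() {
  m <- rbind(f1 = c(4, 4, 1, 1), f2 = c(2, 2, 2, 2), f3 = c(1, 2, 3, 6))
  colnames(m) <- paste0("c", 1:4)
  list(m = m, labels = c("in", "in", "out", "out"))
}

test_that("group_metric computes the closed-form mean, logfc and zscore", {
  fx <- lbl_expr()
  means <- group_metric(fx$m, fx$labels, "mean")
  expect_equal(unname(means$values["f1", c("in", "out")]), c(4, 1))

  lfc <- group_metric(fx$m, fx$labels, "logfc", pseudocount = 1)
  expect_equal(unname(lfc$values["f1", "in"]), log2(5 / 2))  # 1.3219
  expect_equal(unname(lfc$values["f2", "in"]), 0)            # equal means

  z3 <- group_metric(rbind(f = c(1, 2, 3)), c("a", "b", "c"), "zscore")
  expect_equal(unname(z3$values[1, ]), c(-1, 0, 1))

  med <- group_metric(fx$m, fx$labels, "median")
  expect_equal(unname(med$values["f3", "out"]), 4.5)

  expect_error(group_metric(fx$m, fx$labels, "logfc", pseudocount = 0),
               "pseudocount")
  expect_error(group_metric(fx$m, c("a", "a", "a", "a"), "mean"), NA)
})

test_that("zscore rows sum to zero and prop_positive stays within [0,1]", {
  set.seed(3)
  m <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(paste0("f", 1:50), paste0("c", 1:30)))
  labels <- rep(c("a", "b", "c"), each = 10)
  z <- group_metric(m, labels, "zscore")
  expect_true(all(abs(rowSums(z$values)) < 1e-9))
  pp <- proportion_positive(m, labels)
  expect_true(all(pp$values >= 0 & pp$values <= 1))
})

test_that("proportion_positive counts strictly-above-threshold cells", {
  m <- rbind(f1 = c(0, 1, 2, 0), zero = c(0, 0, 0, 0))
  colnames(m) <- paste0("c", 1:4)
  labels <- rep("g", 4)
  expect_equal(unname(proportion_positive(m, labels)$values["f1", "g"]), 0.5)
  expect_equal(unname(proportion_positive(m, labels)$values["zero", "g"]), 0)
  expect_equal(unname(proportion_positive(m, labels, threshold = 2)$values["f1", ]), 0)
})

test_that("waterfall flags exactly min(top_n, n_features) features", {
  set.seed(5)
  n <- 100
  m <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("tf%03d", 1:n), paste0("c", 1:20)))
  labels <- rep(c("A", "B"), each = 10)
  wf <- waterfall_rank(m, labels, "A", "B")
  expect_equal(sum(wf$labeled), 20)
  expect_false(is.unsorted(rev(wf$value)))   # sorted descending
  # flagged features are the top 20 by |value|
  expect_setequal(wf$feature[wf$labeled],
                  wf$feature[order(-abs(wf$value))][1:20])

  small <- waterfall_rank(m[1:5, ], labels, "A", "B")
  expect_equal(sum(small$labeled), 5)

  # identical groups: all zeros, stable id order among ties
  m0 <- matrix(1, 6, 4, dimnames = list(paste0("f", 6:1), paste0("c", 1:4)))
  wf0 <- waterfall_rank(m0, rep(c("A", "B"), each = 2), "A", "B")
  expect_true(all(wf0$value == 0))
  expect_equal(wf0$feature, sort(rownames(m0)))

  expect_error(waterfall_rank(m, labels, "A", "nope"), "unknown group")
  expect_s3_class(autoplot(wf), "ggplot")
})

test_that("the running enrichment score follows the Broad walk", {
  # single-gene set at the top: curve hits 1 at rank 1, decays by 1/(G-1)
  G <- 10
  stat <- setNames(seq(G, 1), paste0("g", 1:G))
  res <- gsea_running_score(stat, "g1", weight_p = 0)
  expect_equal(res$running_curve$running[1], 1)
  expect_equal(res$es, 1)
  expect_equal(diff(res$running_curve$running), rep(-1 / (G - 1), G - 1))
  expect_equal(res$running_curve$running[G], 0, tolerance = 1e-12)
  expect_equal(res$leading_edge, "g1")

  # front-loaded set: strong positive enrichment
  G <- 100
  stat <- setNames(seq(G, 1) / 10, sprintf("g%03d", 1:G))
  front <- gsea_running_score(stat, sprintf("g%03d", 1:5), weight_p = 0)
  expect_gt(front$es, 0.9)
  expect_lt(front$p_value, 0.01)

  expect_error(gsea_running_score(stat, "absent"), "does not intersect")
})

test_that("curve ends at zero and |ES| equals the maximal deviation", {
  set.seed(8)
  for (i in 1:10) {
    G <- 80
    stat <- sort(rnorm(G, sd = 2), decreasing = TRUE)
    names(stat) <- sprintf("g%03d", 1:G)
    genes <- sample(names(stat), sample(3:30, 1))
    res <- gsea_running_score(stat, genes)
    expect_equal(res$running_curve$running[G], 0, tolerance = 1e-12)
    expect_equal(abs(res$es), max(abs(res$running_curve$running)))
  }
})

test_that("running ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  stat <- sort(rnorm(60), decreasing = TRUE)
  names(stat) <- sprintf("g%02d", 1:60)
  genes <- sample(names(stat), 12)
  ours <- gsea_running_score(stat, genes, weight_p = 1)
  ref <- fgsea::calcGseaStat(stat, selectedStats = which(names(stat) %in% genes),
                             gseaParam = 1)
  expect_equal(ours$es, ref, tolerance = 1e-6)
})

test_that("interleaved set positions give a null KS statistic", {
  G <- 100
  stat <- setNames(seq(G, 1), sprintf("g%03d", 1:G))
  alternating <- sprintf("g%03d", seq(1, G, 2))
  res <- gsea_running_score(stat, alternating, weight_p = 0)
  expect_lte(res$ks_stat, 2 / G * 2)
  expect_gt(res$p_value, 0.5)
})

test_that("two-group tests separate signal, handle ties, and star correctly", {
  # identical groups of constant values: p = 1 under wilcoxon, with warning
  m <- rbind(flat = rep(1, 20))
  colnames(m) <- paste0("c", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  expect_warning(res <- two_group_feature_test(m, labels), "constant")
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "ns")

  # strong separation: N(0,1) vs N(5,1)
  set.seed(3)
  strong <- rbind(f = c(rnorm(50), rnorm(50, 5)))
  colnames(strong) <- paste0("c", 1:100)
  lab2 <- rep(c("a", "b"), each = 50)
  res2 <- two_group_feature_test(strong, lab2)
  expect_lt(res2$p_value, 1e-10)
  expect_equal(res2$stars, "****")
  res2t <- two_group_feature_test(strong, lab2, test = "welch_t")
  expect_lt(res2t$p_value, 1e-10)

  expect_error(two_group_feature_test(strong, rep("a", 100)), "two groups")
})

test_that("star codes follow the four-tier convention", {
  expect_equal(p_stars(c(0.2, 0.05, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "ns", "*", "**", "***", "****"))
})

test_that("the wilcoxon null is calibrated at the 5% level", {
  set.seed(17)
  n_features <- 2000
  m <- matrix(rnorm(n_features * 60), n_features, 60)
  rownames(m) <- sprintf("f%04d", seq_len(n_features))
  colnames(m) <- paste0("c", 1:60)
  labels <- rep(c("a", "b"), each = 30)
  res <- two_group_feature_test(m, labels)
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
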