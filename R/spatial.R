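#' @title Spatial clustering of regional accident profiles
#' @description
#' Regions (provinces) are characterised by socio-economic features
#' (population, GDP, road freight volume, road-network length) alongside
#' their accident counts. Features correlated with accident counts are
#' screened, the least mutually correlated pair is retained, regions are
#' clustered by k-means on the standardized pair with the elbow (SSE vs
#' k) rule guiding k, and the clustering is validated by one-way ANOVA
#' and Tukey's HSD on per-region scores: a k is accepted only when every
#' pair of clusters differs significantly.
#' @name spatial
NULL

#' Screen features by correlation with accident counts
#'
#' Retains features whose Pearson correlation with the accident counts
#' exceeds `threshold`, then selects among them the pair with the
#' smallest mutual absolute correlation (redundancy-minimizing choice of
#' cluster features).
#'
#' @param features A data frame or matrix of numeric feature columns.
#' @param accident_counts Per-region accident counts.
#' @param threshold Minimum correlation with counts (default 0.6).
#' @return A list with `selected` (the chosen pair of feature names),
#'   `cor_with_counts`, `retained`, and `cor_matrix` (correlations among
#'   retained features).
#' @export
correlation_screen <- function(features, accident_counts, threshold = 0.6) {
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  if (ncol(features) < 2) stop("need at least 2 numeric features")
  r <- vapply(features, function(f) stats::cor(f, accident_counts), numeric(1))
  retained <- names(r)[r > threshold]
  if (length(retained) == 0) stop("no feature passes the correlation threshold")
  if (length(retained) == 1)
    stop("only one feature passes the threshold; cannot select a pair")
  cm <- abs(stats::cor(features[retained]))
  diag(cm) <- Inf
  idx <- which(cm == min(cm), arr.ind = TRUE)[1, ]
  list(selected = sort(retained[idx]), cor_with_counts = r,
       retained = retained, cor_matrix = stats::cor(features[retained]))
}

#' Within-cluster SSE over a range of k (elbow method)
#'
#' Runs k-means for each k with multiple restarts and records the total
#' within-cluster sum of squared errors. Candidate elbows are reported
#' where the curvature (second difference of SSE) is largest.
#'
#' @param data Numeric matrix/data frame of observations (standardize
#'   beforehand when features are on incommensurate scales; see
#'   [kmeans_cluster()]).
#' @param k_range Integer vector of cluster counts, within `[1, n - 1]`.
#' @param seed Random seed for the restarts.
#' @param nstart Restarts per k (default 10).
#' @return A data frame with `k` and `sse`; attribute `"elbow_candidates"`
#'   holds the k values of maximal curvature (advisory only).
#' @export
elbow_sse <- function(data, k_range, seed = 1, nstart = 10) {
  data <- as.matrix(data)
  if (any(k_range < 1) || any(k_range > nrow(data) - 1))
    stop("k_range must lie within [1, n - 1]")
  set.seed(seed)
  sse <- vapply(k_range, function(k) {
    if (k == 1) sum(scale(data, scale = FALSE)^2)
    else stats::kmeans(data, centers = k, nstart = nstart,
                       iter.max = 100)$tot.withinss
  }, numeric(1))
  out <- data.frame(k = k_range, sse = sse)
  if (length(k_range) >= 3) {
    curv <- diff(diff(sse))  # positive where the drop flattens
    cand <- k_range[-c(1, length(k_range))][order(curv, decreasing = TRUE)]
    attr(out, "elbow_candidates") <- utils::head(cand, 2)
  }
  out
}

#' k-means clustering of regional features
#'
#' Lloyd's algorithm with multiple restarts, keeping the best solution by
#' SSE. Features are z-scored by default since regional indicators are on
#' incommensurate scales.
#'
#' @param data Numeric matrix/data frame (rows = regions).
#' @param k Number of clusters.
#' @param seed Random seed.
#' @param nstart Restarts (default 10).
#' @param standardize z-score columns before clustering (default TRUE).
#' @return The `stats::kmeans` fit, with the (possibly standardized) data
#'   matrix in attribute `"data"`.
#' @export
kmeans_cluster <- function(data, k, seed = 1, nstart = 10, standardize = TRUE) {
  data <- as.matrix(data)
  if (k > nrow(data)) stop("k exceeds the number of observations")
  if (standardize) {
    sds <- apply(data, 2, stats::sd)
    data <- scale(data, scale = ifelse(sds > 0, sds, 1))
  }
  set.seed(seed)
  fit <- stats::kmeans(data, centers = k, nstart = nstart, iter.max = 100)
  attr(fit, "data") <- data
  fit
}

#' Comprehensive factor score of each region
#'
#' The first principal-component score of the standardized selected
#' features, oriented so that larger feature values give larger scores.
#' This is the default per-region score aggregated per cluster during
#' validation; any other scoring function may be substituted.
#'
#' @param features Numeric matrix/data frame of the selected features.
#' @return A numeric score per region.
#' @export
factor_scores <- function(features) {
  x <- scale(as.matrix(features))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  if (sum(pc$rotation[, 1]) < 0) s <- -s  # orient with the features
  as.numeric(s)
}

#' Validate a clustering by ANOVA and Tukey's HSD
#'
#' Tests whether the per-region scores differ across clusters (one-way
#' ANOVA) and whether every pair of clusters differs (Tukey's honestly
#' significant difference at `alpha`). The verdict is `TRUE` only when
#' the ANOVA is significant and all pairwise comparisons are; a cluster
#' pair with an HSD p-value above `alpha` (the "two clusters are really
#' one group" pattern) makes it `FALSE`. Singleton clusters are excluded
#' from the test with a warning.
#'
#' @param assignments Cluster labels per region.
#' @param scores Per-region scores (e.g. [factor_scores()]).
#' @param alpha Significance level (default 0.05).
#' @return A `cluster_validation`: list with `k`, `cluster_means`,
#'   `anova_p`, `tukey` (data frame of pairwise comparisons), `verdict`,
#'   and `offending_pairs` (pairs with p > alpha).
#' @export
validate_clusters <- function(assignments, scores, alpha = 0.05) {
  if (length(assignments) != length(scores)) stop("length mismatch")
  g <- factor(assignments)
  sizes <- table(g)
  if (any(sizes < 2)) {
    warning("singleton cluster(s) excluded from validation: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- g %in% names(sizes)[sizes >= 2]
    g <- droplevels(g[keep]); scores <- scores[keep]
  }
  if (nlevels(g) < 2) stop("need at least 2 clusters with at least 2 members")
  fit <- stats::aov(scores ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                      p = hsd[, "p adj"], row.names = NULL)
  offending <- tukey$pair[tukey$p > alpha]
  structure(list(
    k = nlevels(g),
    cluster_means = tapply(scores, g, mean),
    anova_p = anova_p,
    tukey = tukey,
    verdict = (anova_p <= alpha) && all(tukey$p <= alpha),
    offending_pairs = offending
  ), class = "cluster_validation")
}

#' @export
print.cluster_validation <- function(x, ...) {
  cat(sprintf("<cluster_validation> k = %d, ANOVA p = %.4g\n", x$k, x$anova_p))
  cat("  cluster mean scores:\n")
  print(round(x$cluster_means, 4))
  cat("  Tukey HSD pairwise p-values:\n")
  print(transform(x$tukey, diff = round(diff, 4), p = round(p, 4)),
        row.names = FALSE)
  cat(sprintf("  all pairs distinct: %s\n", x$verdict))
  if (length(x$offending_pairs))
    cat("  offending pair(s): ", paste(x$offending_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end spatial clustering pipeline
#'
#' Screens features, clusters the standardized selected pair for each
#' candidate k, and validates each clustering, mirroring the adjudication
#' between competing elbow candidates.
#'
#' @param regions A data frame with a region label column, numeric feature
#'   columns and an `accidents` count column.
#' @param k_candidates Cluster counts to adjudicate (default 4:5).
#' @param seed Random seed.
#' @param threshold Correlation-screen threshold.
#' @return A list with `screen`, per-k `fits` and `validations`, and
#'   `chosen_k` (smallest candidate with a TRUE verdict, NA if none).
#' @export
cluster_regions <- function(regions, k_candidates = 4:5, seed = 1,
                            threshold = 0.6) {
  feat_cols <- setdiff(names(regions)[vapply(regions, is.numeric, logical(1))],
                       "accidents")
  screen <- correlation_screen(regions[feat_cols], regions$accidents, threshold)
  sel <- regions[screen$selected]
  scores <- factor_scores(sel)
  fits <- list(); validations <- list()
  for (k in k_candidates) {
    fit <- kmeans_cluster(sel, k, seed = seed)
    fits[[as.character(k)]] <- fit
    validations[[as.character(k)]] <-
      tryCatch(validate_clusters(fit$cluster, scores),
               error = function(e) NULL)
  }
  ok <- vapply(validations, function(v) !is.null(v) && isTRUE(v$verdict),
               logical(1))
  list(screen = screen, scores = scores, fits = fits,
       validations = validations,
       chosen_k = if (any(ok)) k_candidates[which(ok)[1]] else NA_integer_)
}
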