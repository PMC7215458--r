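#' @title CHAID cause-consequence decision tree
#' @description
#' CHAID (chi-squared automatic interaction detection) grows a
#' classification tree by, at each node, (i) merging predictor categories
#' whose target distributions do not differ significantly (adjacent
#' categories only for ordinal predictors), (ii) testing each candidate
#' predictor's merged contingency table against the target with a Pearson
#' chi-square test whose p-value is Bonferroni-adjusted for the number of
#' ways the original categories can be reduced to the merged groups
#' (Kass's correction), and (iii) splitting on the most significant
#' predictor if it passes the significance and node-size constraints.
#' Used here with the accident severity level as target and hazmat class,
#' accident type, specific type, time period, cause factor and road level
#' as predictors.
#' @name chaid
NULL

#' CHAID hyperparameters
#'
#' @param alpha_merge Significance level above which a category pair is
#'   merged (default 0.05).
#' @param alpha_split Maximum Bonferroni-adjusted p-value for a split
#'   (default 0.05).
#' @param bonferroni Apply Kass's Bonferroni adjustment (default TRUE).
#' @param min_parent Minimum node size to attempt a split (default 20).
#' @param min_child Minimum size of every child (default 10); a best
#'   predictor whose split would violate it makes the node a leaf.
#' @param max_depth Maximum tree depth; the root has depth 0 (default 3).
#' @return A `chaid_params` list.
#' @export
chaid_params <- function(alpha_merge = 0.05, alpha_split = 0.05,
                         bonferroni = TRUE, min_parent = 20, min_child = 10,
                         max_depth = 3) {
  stopifnot(alpha_merge > 0, alpha_merge <= 1, alpha_split > 0,
            alpha_split <= 1, min_child <= min_parent, max_depth >= 0)
  structure(list(alpha_merge = alpha_merge, alpha_split = alpha_split,
                 bonferroni = bonferroni, min_parent = min_parent,
                 min_child = min_child, max_depth = max_depth),
            class = "chaid_params")
}

#' Pearson chi-square test of a contingency table
#'
#' Drops empty rows and columns, then computes the Pearson statistic
#' `sum((O - E)^2 / E)`, its degrees of freedom `(R-1)(C-1)`, and the
#' upper-tail p-value. No continuity correction is applied.
#'
#' @param tab A matrix (or table) of non-negative counts.
#' @return A list with `statistic`, `dof`, `p`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table: fewer than 2 non-empty rows or columns")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p = unname(res$p.value))
}

# p-value for merging two category groups; 1 when the 2 x C subtable is
# degenerate (identical support), i.e. trivially mergeable
merge_p <- function(tab2) {
  tab2 <- tab2[, colSums(tab2) > 0, drop = FALSE]
  if (nrow(tab2) < 2 || ncol(tab2) < 2) return(1)
  suppressWarnings(stats::chisq.test(tab2, correct = FALSE))$p.value
}

#' Kass's Bonferroni multiplier
#'
#' Number of ways `c` original categories can be reduced to `r` merged
#' groups: for a nominal predictor
#' `sum_{i=0}^{r-1} (-1)^i (r - i)^c / (i! (r - i)!)` (Stirling-type
#' count); for an ordinal predictor, only contiguous merges are possible,
#' giving `choose(c - 1, r - 1)`.
#'
#' @param c_cats Number of original categories present.
#' @param r_groups Number of merged groups.
#' @param ordinal Is the predictor ordinal?
#' @return The multiplier (>= 1).
#' @export
bonferroni_multiplier <- function(c_cats, r_groups, ordinal = FALSE) {
  if (ordinal) return(choose(c_cats - 1, r_groups - 1))
  i <- 0:(r_groups - 1)
  sum((-1)^i * (r_groups - i)^c_cats / (factorial(i) * factorial(r_groups - i)))
}

#' Merge the categories of a predictor against a target
#'
#' Iteratively merges the pair of category groups (adjacent groups only
#' for ordinal predictors) whose 2 x C chi-square p-value against the
#' target is largest, while that p-value exceeds `alpha_merge`. May merge
#' down to a single group, in which case the predictor is unusable for
#' splitting.
#'
#' @param x Predictor values (coerced to character; ordinal predictors are
#'   ordered by their sorted unique values).
#' @param y Target values.
#' @param ordinal Merge only adjacent categories.
#' @param params A [chaid_params()] list.
#' @return A list with `groups` (list of character vectors of original
#'   categories), `table` (merged groups x target counts), `statistic`,
#'   `dof`, `p` (Pearson test of the merged table; NA when fewer than two
#'   groups remain) and `adj_p` (Bonferroni-adjusted).
#' @export
merge_categories <- function(x, y, ordinal = FALSE, params = chaid_params()) {
  x <- as.character(x)
  y <- factor(y)
  cats <- sort(unique(x))
  groups <- as.list(cats)
  group_tab <- function(groups) {
    t(vapply(groups, function(g) {
      as.numeric(table(y[x %in% g]))
    }, numeric(nlevels(y))))
  }
  tab <- group_tab(groups)
  while (length(groups) > 1) {
    pairs <- if (ordinal) {
      cbind(seq_len(length(groups) - 1), 2:length(groups))
    } else t(utils::combn(length(groups), 2))
    ps <- apply(pairs, 1, function(pr) merge_p(tab[pr, , drop = FALSE]))
    best <- which.max(ps)
    if (ps[best] <= params$alpha_merge) break
    pr <- pairs[best, ]
    groups[[pr[1]]] <- c(groups[[pr[1]]], groups[[pr[2]]])
    groups[[pr[2]]] <- NULL
    tab <- group_tab(groups)
  }
  rownames(tab) <- vapply(groups, paste, "", collapse = ",")
  colnames(tab) <- levels(y)
  if (length(groups) >= 2 && sum(colSums(tab) > 0) >= 2) {
    ts <- chi_square(tab)
    mult <- if (params$bonferroni)
      bonferroni_multiplier(length(cats), length(groups), ordinal) else 1
    adj_p <- min(1, ts$p * mult)
    list(groups = groups, table = tab, statistic = ts$statistic,
         dof = ts$dof, p = ts$p, adj_p = adj_p)
  } else {
    list(groups = groups, table = tab, statistic = NA_real_, dof = NA_integer_,
         p = NA_real_, adj_p = NA_real_)
  }
}

level_dist <- function(y, levels) {
  tab <- table(factor(as.character(y), levels = levels))
  as.integer(tab)
}

modal_severe <- function(counts, levels) {
  m <- which(counts == max(counts))
  levels[m[length(m)]]  # ties broken toward the more severe (later) level
}

#' Build a CHAID decision tree
#'
#' @param data An [hta_records] object (typically after
#'   [expand_multiclass()]) or a data frame.
#' @param target Name of the target column (default `"severity_level"`).
#' @param predictors Character vector of predictor columns. The special
#'   name `"period"` is derived from `hour` if absent (the four day
#'   periods) and is treated as ordinal; all other predictors are nominal.
#' @param params A [chaid_params()] list.
#' @param ordinal_predictors Predictors whose categories are ordered (only
#'   adjacent categories merge). Defaults to `"period"`.
#' @return A `chaid_tree` object. Rows with missing values in the target
#'   or any predictor are excluded listwise, with the count recorded in
#'   the `n_dropped` field.
#' @export
build_tree <- function(data, target = "severity_level",
                       predictors = c("hazmat_classes", "accident_type",
                                      "specific_type", "period",
                                      "cause_factor", "road_level"),
                       params = chaid_params(),
                       ordinal_predictors = "period") {
  df <- as.data.frame(data)
  if (length(predictors) == 0) stop("empty predictor list")
  if ("period" %in% predictors && !"period" %in% names(df)) {
    if (!"hour" %in% names(df)) stop("cannot derive 'period': no hour column")
    df$period <- as.integer(day_period(df$hour))
  }
  missing_cols <- setdiff(c(target, predictors), names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(df[c(target, predictors)])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  y <- factor(as.character(df[[target]]))
  levels_y <- levels(y)

  nodes <- list()
  next_id <- 1L

  grow <- function(idx, depth, parent) {
    id <- next_id; next_id <<- next_id + 1L
    counts <- level_dist(y[idx], levels_y)
    node <- list(id = id, parent = parent, depth = depth, n = length(idx),
                 counts = stats::setNames(counts, levels_y),
                 class = modal_severe(counts, levels_y),
                 split_var = NA_character_, groups = NULL,
                 statistic = NA_real_, p = NA_real_, adj_p = NA_real_,
                 children = integer(0))
    nodes[[id]] <<- node
    can_split <- length(idx) >= params$min_parent &&
      depth < params$max_depth && sum(counts > 0) > 1
    if (can_split) {
      cand <- lapply(predictors, function(v) {
        xv <- df[[v]][idx]
        if (length(unique(xv[!is.na(xv)])) < 2) return(NULL)
        m <- merge_categories(xv, y[idx], ordinal = v %in% ordinal_predictors,
                              params = params)
        if (is.na(m$adj_p)) NULL else c(list(var = v), m)
      })
      cand <- Filter(Negate(is.null), cand)
      if (length(cand)) {
        adj_ps <- vapply(cand, function(m) m$adj_p, numeric(1))
        best <- cand[[which.min(adj_ps)]]
        sizes <- rowSums(best$table)
        if (best$adj_p <= params$alpha_split && all(sizes >= params$min_child)) {
          xv <- as.character(df[[best$var]][idx])
          kids <- vapply(best$groups, function(g) {
            grow(idx[xv %in% g], depth + 1L, id)
          }, integer(1))
          nodes[[id]]$split_var <<- best$var
          nodes[[id]]$groups <<- best$groups
          nodes[[id]]$statistic <<- best$statistic
          nodes[[id]]$p <<- best$p
          nodes[[id]]$adj_p <<- best$adj_p
          nodes[[id]]$children <<- kids
        }
      }
    }
    id
  }
  grow(seq_len(nrow(df)), 0L, NA_integer_)
  structure(list(nodes = nodes, target = target, levels = levels_y,
                 predictors = predictors, params = params,
                 ordinal_predictors = ordinal_predictors,
                 n_cases = nrow(df), n_dropped = n_dropped),
            class = "chaid_tree")
}

#' @export
print.chaid_tree <- function(x, ...) {
  cat(sprintf("<chaid_tree> %d cases, %d nodes, target '%s'\n",
              x$n_cases, length(x$nodes), x$target))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d incomplete case(s) excluded)\n", x$n_dropped))
  recurse <- function(id, indent) {
    nd <- x$nodes[[id]]
    dist <- paste(sprintf("%s:%d", names(nd$counts), nd$counts), collapse = " ")
    cat(sprintf("%snode %d  n=%d  [%s]  -> %s\n", indent, nd$id, nd$n, dist,
                nd$class))
    if (length(nd$children)) {
      cat(sprintf("%s  split on %s (chi2=%.2f, adj p=%.3g)\n", indent,
                  nd$split_var, nd$statistic, nd$adj_p))
      for (i in seq_along(nd$children)) {
        cat(sprintf("%s  group {%s}:\n", indent,
                    paste(nd$groups[[i]], collapse = ",")))
        recurse(nd$children[i], paste0(indent, "    "))
      }
    }
  }
  recurse(1L, "")
  invisible(x)
}

#' Predict severity levels with a CHAID tree
#'
#' Routes each record down the tree by merged-category membership and
#' returns the leaf's modal class, with ties broken toward the more
#' severe level. A category unseen at a split is routed to the largest
#' child; the number of such routings is reported in the
#' `"unseen_routed"` attribute.
#'
#' @param object A `chaid_tree`.
#' @param newdata A data frame (or [hta_records]) with the split columns.
#' @param ... Unused.
#' @return A factor of predicted levels.
#' @export
predict.chaid_tree <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  if ("period" %in% object$predictors && !"period" %in% names(df) &&
      "hour" %in% names(df))
    df$period <- as.integer(day_period(df$hour))
  unseen <- 0L
  route <- function(i) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (!length(nd$children)) return(nd$class)
      val <- as.character(df[[nd$split_var]][i])
      hit <- which(vapply(nd$groups, function(g) val %in% g, logical(1)))
      if (!length(hit)) {
        unseen <<- unseen + 1L
        sizes <- vapply(nd$children, function(cid) object$nodes[[cid]]$n,
                        numeric(1))
        hit <- which.max(sizes)
      }
      id <- nd$children[hit[1]]
    }
  }
  out <- vapply(seq_len(nrow(df)), route, "")
  structure(factor(out, levels = object$levels), unseen_routed = unseen)
}

#' Confusion matrix of actual vs predicted levels
#'
#' @param actual,predicted Equal-length label vectors.
#' @param levels Optional common level set; labels outside it are an
#'   error. Defaults to the union of observed labels.
#' @return A `confusion_matrix`: list with `counts` (rows = actual,
#'   columns = predicted), `row_pct` (per-actual-level correct prediction
#'   percentage), `col_pct` (per-predicted-level share of the total) and
#'   `overall` (trace / total, as a percentage).
#' @export
confusion_matrix <- function(actual, predicted, levels = NULL) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (is.null(levels)) levels <- sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), levels)
  if (length(bad)) stop("labels outside level set: ", paste(bad, collapse = ", "))
  counts <- table(factor(actual, levels), factor(predicted, levels))
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(actual = levels, predicted = levels))
  total <- sum(counts)
  row_tot <- rowSums(counts)
  row_pct <- ifelse(row_tot > 0, 100 * diag(counts) / row_tot, NA_real_)
  structure(list(counts = counts, row_pct = row_pct,
                 col_pct = 100 * colSums(counts) / total,
                 overall = 100 * sum(diag(counts)) / total),
            class = "confusion_matrix")
}

#' Read a confusion matrix from a delimited file
#'
#' Expects a header row naming the predicted levels and a first column
#' `actual` naming the actual levels.
#' @param path CSV path.
#' @return A `confusion_matrix`.
#' @export
read_confusion_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  levels <- as.character(df$actual)
  counts <- as.matrix(df[, levels, drop = FALSE])
  actual <- rep(levels, times = rowSums(counts))
  predicted <- unlist(lapply(seq_len(nrow(counts)), function(i) {
    rep(colnames(counts), times = counts[i, ])
  }))
  confusion_matrix(actual, predicted, levels = levels)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = actual, columns = predicted\n")
  m <- cbind(x$counts, `correct %` = round(x$row_pct, 1))
  print(m)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall))
  invisible(x)
}

#' Composition report of a tree node
#'
#' @param tree A `chaid_tree`.
#' @param id Node id.
#' @param total_cases Denominator for the node share (defaults to the
#'   tree's case count).
#' @return A list with `node_share_pct` (node cases / total, 1 d.p.) and
#'   `class_pct` (per-level percentages within the node, 1 d.p.).
#' @export
node_report <- function(tree, id, total_cases = tree$n_cases) {
  nd <- tree$nodes[[id]]
  if (is.null(nd)) stop("no such node: ", id)
  list(id = nd$id, n = nd$n,
       node_share_pct = round(100 * nd$n / total_cases, 1),
       class_pct = round(100 * nd$counts / nd$n, 1))
}
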