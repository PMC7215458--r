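# a data frame where one predictor perfectly determines the level
planted_cases <- function(n_per = 60) {
  data.frame(
    severity_level = rep(c("II", "III", "IV"), each = n_per),
    cause_factor = rep(c(1L, 3L, 4L), each = n_per),
    road_level = rep_len(1:3, 3 * n_per),
    period = rep_len(1:4, 3 * n_per),
    stringsAsFactors = FALSE
  )
}

test_that("the Pearson chi-square matches the textbook formula", {
  even <- chi_square(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  diag2 <- chi_square(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag2$statistic, 40)
  expect_equal(diag2$dof, 1)
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(12, 8) + 1, 3, 4)
    res <- chi_square(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(res$dof, 6)
    expect_equal(res$p, pchisq(res$statistic, 6, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chi_square(matrix(c(3, 4), 1)), "degenerate")
  expect_error(chi_square(matrix(c(3, 0, 4, 0), 2)), "degenerate")
})

test_that("Kass's multiplier counts reachable category reductions", {
  expect_equal(bonferroni_multiplier(3, 2, ordinal = FALSE), 3)
  expect_equal(bonferroni_multiplier(3, 2, ordinal = TRUE), 2)
  expect_equal(bonferroni_multiplier(4, 4, ordinal = FALSE), 1)
  expect_equal(bonferroni_multiplier(5, 1, ordinal = FALSE), 1)
  # nominal count is the Stirling number of the second kind S(c, r)
  expect_equal(bonferroni_multiplier(4, 2, ordinal = FALSE), 7)
  expect_equal(bonferroni_multiplier(4, 2, ordinal = TRUE), 3)
})

test_that("category merging joins indistinguishable categories", {
  set.seed(8)
  y <- rep(c("II", "III"), times = c(120, 60))
  # categories a and b share a target distribution; c differs sharply
  x <- c(sample(c("a", "b"), 120, replace = TRUE), rep("c", 60))
  m <- merge_categories(x, y)
  expect_length(m$groups, 2)
  merged_ab <- vapply(m$groups, function(g) setequal(g, c("a", "b")), logical(1))
  expect_true(any(merged_ab))
  expect_lt(m$adj_p, 0.001)

  # already-binary, strongly associated: unchanged
  mb <- merge_categories(rep(c("u", "v"), times = c(90, 90)), y)
  expect_length(mb$groups, 2)

  # all categories with identical distributions collapse to one group
  y2 <- rep(c("II", "III"), 90)
  x2 <- rep(c("a", "b", "c"), each = 60)
  m2 <- merge_categories(x2, y2)
  expect_length(m2$groups, 1)
  expect_true(is.na(m2$adj_p))
})

test_that("ordinal predictors merge adjacent categories only", {
  # categories 1 and 3 share a distribution but are not adjacent
  y <- rep(rep(c("II", "III"), times = c(3, 1)), 30)
  x <- rep_len(c(1, 3), length(y))
  x[seq(2, length(y), by = 4)] <- 2
  m <- merge_categories(as.character(x), y, ordinal = TRUE)
  for (g in m$groups) {
    v <- sort(as.integer(g))
    expect_true(all(diff(v) == 1))  # contiguous blocks
  }
})

test_that("a perfectly predictive cause is chosen at the root with pure children", {
  tree <- build_tree(planted_cases(), predictors = c("cause_factor",
                                                     "road_level", "period"))
  root <- tree$nodes[[1]]
  expect_equal(root$split_var, "cause_factor")
  expect_equal(sum(root$counts), 180)
  for (cid in root$children) {
    nd <- tree$nodes[[cid]]
    expect_equal(sum(nd$counts > 0), 1)  # pure
  }
  # children partition the parent
  expect_equal(sum(vapply(root$children, function(i) tree$nodes[[i]]$n, 0)),
               root$n)
})

test_that("the root distribution equals the input distribution", {
  counts <- c(II = 408, III = 104, IV = 32, V = 25)
  df <- data.frame(
    severity_level = rep(names(counts), times = counts),
    cause_factor = rep_len(1:4, sum(counts)),
    stringsAsFactors = FALSE)
  tree <- build_tree(df, predictors = "cause_factor")
  expect_equal(tree$n_cases, 569)
  expect_equal(as.integer(tree$nodes[[1]]$counts), unname(counts))
})

test_that("prediction routes by merged groups with severe-side tie-breaks", {
  tree <- build_tree(planted_cases(), predictors = "cause_factor")
  newdata <- data.frame(cause_factor = c(1L, 3L, 4L))
  expect_equal(as.character(predict(tree, newdata)), c("II", "III", "IV"))

  # unseen category routed to the largest child and flagged
  p <- predict(tree, data.frame(cause_factor = 2L))
  expect_equal(attr(p, "unseen_routed"), 1L)
  expect_true(as.character(p) %in% c("II", "III", "IV"))

  # root-only tree predicts the modal class
  ind <- data.frame(severity_level = rep(c("II", "III"), times = c(50, 10)),
                    cause_factor = rep_len(1:2, 60))
  tr0 <- build_tree(ind, predictors = "cause_factor",
                    params = chaid_params(alpha_split = 1e-12))
  expect_length(tr0$nodes, 1)
  expect_equal(as.character(predict(tr0, data.frame(cause_factor = 9L))), "II")

  # ties go to the more severe level
  expect_equal(hazfn:::modal_severe(c(5, 5, 1), c("II", "III", "IV")), "III")
  expect_equal(hazfn:::modal_severe(c(3, 3, 3), c("II", "III", "IV")), "IV")
})

test_that("the confusion matrix reproduces published-style arithmetic", {
  path <- system.file("extdata", "china_hta_confusion.csv", package = "hazfn")
  cm <- read_confusion_matrix(path)
  expect_equal(sum(cm$counts), 569)
  expect_equal(round(cm$row_pct[["II"]], 1), 97.8)
  expect_equal(round(cm$row_pct[["III"]], 1), 8.7)
  expect_equal(round(cm$row_pct[["IV"]], 1), 0)
  expect_equal(round(cm$row_pct[["V"]], 1), 80.0)
  expect_equal(round(cm$overall, 1), 75.2)

  x <- sample(c("II", "III", "V"), 40, replace = TRUE)
  perfect <- confusion_matrix(x, x)
  expect_equal(perfect$overall, 100)
  expect_equal(sum(perfect$counts) - sum(diag(perfect$counts)), 0)
  expect_error(confusion_matrix(c("II", "VI"), c("II", "II"), levels = c("II", "III")),
               "outside")
})

test_that("node reports give shares and class percentages to 1 d.p.", {
  df <- planted_cases()  # root n = 180
  tree <- build_tree(df, predictors = "cause_factor")
  rep1 <- node_report(tree, 1, total_cases = 569)
  expect_equal(rep1$node_share_pct, round(100 * 180 / 569, 1))
  counts <- c(28, 3, 1)
  df2 <- data.frame(severity_level = rep(c("II", "III", "IV"), times = counts),
                    cause_factor = 1L)
  tr2 <- build_tree(df2, predictors = "cause_factor")
  r2 <- node_report(tr2, 1)
  expect_equal(unname(r2$class_pct), c(87.5, 9.4, 3.1))
  expect_equal(node_report(tree, 1, total_cases = 569 * 100)$node_share_pct,
               round(100 * 180 / 56900, 1))
})

test_that("trees are deterministic and conserve cases at every split", {
  rs <- generate_records(generator_config(
    n_accidents = 300, seed = 21,
    planted_rules = list(`3` = c(II = 0.1, IV = 0.9))))
  cases <- expand_multiclass(rs)
  t1 <- build_tree(cases)
  t2 <- build_tree(cases)
  expect_identical(t1$nodes, t2$nodes)
  for (nd in t1$nodes) {
    if (length(nd$children)) {
      expect_equal(sum(vapply(nd$children, function(i) t1$nodes[[i]]$n, 0)),
                   nd$n)
    }
  }
})

test_that("stricter stopping parameters never grow the tree", {
  for (seed in c(31, 32, 33)) {
    rs <- generate_records(generator_config(
      n_accidents = 250, seed = seed,
      planted_rules = list(`4` = c(II = 0.55, III = 0.25, IV = 0.2))))
    cases <- expand_multiclass(rs)
    n_base <- length(build_tree(cases)$nodes)
    n_strict_child <- length(build_tree(cases,
      params = chaid_params(min_child = 40, min_parent = 40))$nodes)
    n_strict_alpha <- length(build_tree(cases,
      params = chaid_params(alpha_split = 0.001))$nodes)
    expect_lte(n_strict_child, n_base)
    expect_lte(n_strict_alpha, n_base)
  }
})
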