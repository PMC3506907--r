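score_matrix_from_vector <- function(v, genes) {
  s <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  s[row(s) != col(s)] <- v
  grn_scores(s, directed = TRUE, method = "test")
}

test_that("AUC reproduces hand-counted pair concordance", {
  # 2 positives scored (0.9, 0.7), 2 negatives (0.8, 0.1): 3 of 4 pairs
  # concordant, AUC 0.75
  genes <- c("t", "a", "b", "c")
  gold <- grn_network(genes, c(TRUE, FALSE, FALSE, FALSE),
                      data.frame(regulator = "t", target = c("a", "b"),
                                 sign = "activate", weight = 1))
  s <- matrix(0, 4, 4, dimnames = list(genes, genes))
  s["t", "a"] <- 0.9; s["t", "b"] <- 0.7   # positives
  s["t", "c"] <- 0.8; s["a", "b"] <- 0.1   # negatives (rest tie at 0)
  sc <- grn_scores(s, directed = TRUE, method = "test")
  all_pairs <- expand.grid(regulator = genes, target = genes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$regulator != all_pairs$target, ]
  keep <- paste(all_pairs$regulator, all_pairs$target) %in%
    c("t a", "t b", "t c", "a b")
  ev <- roc_auc(sc, gold, mode = "directed", exclude_pairs = all_pairs[!keep, ])
  expect_equal(ev$auc, 0.75)
  expect_equal(ev$n_pos, 2)
  expect_equal(ev$n_neg, 2)
})

test_that("perfect ranking gives AUC 1 and reversal gives 1 - AUC", {
  net <- generate_source_network(15, "scale_free", mean_degree = 2, seed = 3)
  s <- matrix(0, 15, 15, dimnames = list(net$nodes, net$nodes))
  s[cbind(net$edges$regulator, net$edges$target)] <- 1
  sc <- grn_scores(s, directed = TRUE, method = "test")
  expect_equal(roc_auc(sc, net, mode = "directed")$auc, 1.0)

  set.seed(4)
  v <- runif(15 * 14)
  sc1 <- score_matrix_from_vector(v, net$nodes)
  sc2 <- score_matrix_from_vector(max(v) - v, net$nodes)
  a1 <- roc_auc(sc1, net, mode = "directed")$auc
  a2 <- roc_auc(sc2, net, mode = "directed")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  net <- generate_source_network(12, "erdos_renyi", mean_degree = 2, seed = 5)
  set.seed(6)
  v <- runif(12 * 11)
  a1 <- roc_auc(score_matrix_from_vector(v, net$nodes), net, mode = "directed")$auc
  a2 <- roc_auc(score_matrix_from_vector(exp(3 * v), net$nodes), net,
                mode = "directed")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("midrank AUC matches the brute-force oracle on tied instances", {
  set.seed(7)
  genes <- paste0("g", 1:8)
  for (rep in 1:50) {
    tf <- sample(genes, 3)
    n_e <- sample(3:10, 1)
    pool <- expand.grid(regulator = tf, target = genes, stringsAsFactors = FALSE)
    pool <- pool[pool$regulator != pool$target, ]
    e <- pool[sample(nrow(pool), n_e), ]
    gold <- grn_network(genes, genes %in% tf,
                        cbind(e, sign = "activate", weight = 1))
    # coarse scores force plenty of ties
    v <- sample(seq(0, 1, 0.25), 8 * 7, replace = TRUE)
    sc <- score_matrix_from_vector(v, genes)
    ev <- roc_auc(sc, gold, mode = "directed")
    grid <- expand.grid(regulator = genes, target = genes, stringsAsFactors = FALSE)
    grid <- grid[grid$regulator != grid$target, ]
    lab <- paste(grid$regulator, grid$target) %in% paste(e$regulator, e$target)
    expect_equal(ev$auc, oracle_auc(sc$scores[cbind(grid$regulator, grid$target)], lab),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  net <- generate_source_network(10, "scale_free", mean_degree = 2, seed = 8)
  set.seed(9)
  sc <- score_matrix_from_vector(sample(seq(0, 1, 0.2), 90, TRUE), net$nodes)
  roc <- roc_auc(sc, net, mode = "directed")$roc
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("undirected mode collapses the gold standard by OR", {
  genes <- c("t1", "t2", "a")
  gold <- grn_network(genes, c(TRUE, TRUE, FALSE),
                      data.frame(regulator = c("t1", "t2"), target = c("a", "t1"),
                                 sign = "activate", weight = 1))
  s <- matrix(0, 3, 3, dimnames = list(genes, genes))
  s["t1", "a"] <- s["a", "t1"] <- 0.9
  s["t1", "t2"] <- s["t2", "t1"] <- 0.8
  s["t2", "a"] <- s["a", "t2"] <- 0.1
  sc <- grn_scores(s, directed = FALSE, method = "test")
  ev <- roc_auc(sc, gold, mode = "undirected")
  # positives: {t1,a} and {t1,t2}; negative: {t2,a}; perfect ranking
  expect_equal(ev$n_pos, 2)
  expect_equal(ev$n_neg, 1)
  expect_equal(ev$auc, 1.0)
})

test_that("evaluation errors without both classes present", {
  genes <- c("t", "a")
  gold <- grn_network(genes, c(TRUE, FALSE),
                      data.frame(regulator = "t", target = "a",
                                 sign = "activate", weight = 1))
  s <- matrix(0.5, 2, 2, dimnames = list(genes, genes))
  sc <- grn_scores(s, directed = TRUE, method = "test")
  # universe = {t->a, a->t}: one positive, one negative works ...
  expect_silent(roc_auc(sc, gold, mode = "directed"))
  # ... but collapsing to one unordered pair leaves no negative
  expect_error(roc_auc(sc, gold, mode = "undirected"), "positive")
})

test_that("parameter grids have the documented cardinalities", {
  expect_equal(nrow(mi_grid()), 312)       # 4 x 3 x 26
  expect_equal(nrow(wgcna_grid()), 33)     # 3 x 11
  expect_equal(length(unique(mi_grid()$bins)), 26)
})

test_that("sweeps enumerate every configuration and select the best row", {
  d <- random_expression(6, 20, seed = 10)
  net <- generate_source_network(6, "erdos_renyi", tf_fraction = 0.4,
                                 mean_degree = 2, seed = 10)
  rownames(d$values) <- net$nodes
  d <- grn_expression(d$values)
  grid <- expand.grid(estimator = c("empirical", "mm"),
                      discretization = "equalfreq", bins = c(3, 25),
                      stringsAsFactors = FALSE)
  sw <- parameter_sweep("rn", grid, d, net, mode = "undirected")
  expect_equal(nrow(sw$results), 4)
  # bins 25 > 20 samples: equalfreq error rows recorded, sweep continues
  expect_true(all(is.na(sw$results$auc[sw$results$bins == 25])))
  expect_false(anyNA(sw$results$auc[sw$results$bins == 3]))
  expect_equal(sw$best, which.max(sw$results$auc))

  single <- parameter_sweep("correlations", data.frame(kind = "pearson"),
                            d, net, mode = "undirected")
  expect_equal(nrow(single$results), 1)
  expect_equal(single$best, 1L)
})

test_that("the joint MI sweep equals per-method sweeps", {
  d <- random_expression(6, 25, seed = 11)
  net <- generate_source_network(6, "erdos_renyi", tf_fraction = 0.4,
                                 mean_degree = 2, seed = 11)
  rownames(d$values) <- net$nodes
  d <- grn_expression(d$values)
  grid <- expand.grid(estimator = "empirical", discretization = "equalfreq",
                      bins = c(3, 4), stringsAsFactors = FALSE)
  joint <- sweep_mi_methods(d, net, methods = c("rn", "clr"), grid = grid,
                            mode = "undirected")
  expect_equal(nrow(joint), 4)  # 2 configs x 2 methods
  solo <- parameter_sweep("clr", grid, d, net, mode = "undirected")
  expect_equal(joint$auc[joint$method == "clr"], solo$results$auc)
})

test_that("pairwise comparisons apply the Bonferroni correction", {
  g <- list(a = c(0.9, 0.91, 0.9, 0.89), b = c(0.9, 0.91, 0.9, 0.89),
            c = c(0.5, 0.52, 0.49, 0.51))
  res <- compare_methods(g, alpha = 0.01)
  expect_equal(nrow(res), 3)
  self_like <- res[res$group_a == "a" & res$group_b == "b", ]
  expect_false(self_like$significant)    # identical groups
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3))

  set.seed(12)
  g2 <- list(hi = 0.9 + rnorm(12, 0, 0.01), lo = 0.5 + rnorm(12, 0, 0.01))
  res2 <- compare_methods(g2, alpha = 0.01)
  expect_true(res2$significant)
  expect_error(compare_methods(list(a = 1:5)), "two groups")
  expect_error(compare_methods(list(a = 1:2, b = 1:5)), ">= 3")
})
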