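#' ROC / AUC evaluation against a gold standard
#'
#' Scores every candidate gene pair and computes the area under the ROC
#' curve with the midrank (tie-aware) rank-sum formula — equivalent to the
#' fraction of positive-negative pairs ordered correctly, ties counted 1/2.
#' An AUC of 0.5 corresponds to a random prediction and 1 to a perfect one.
#'
#' The candidate universe is closed-world: in directed mode, all ordered
#' non-self (row, column) pairs of the score matrix (a symmetric scorer
#' contributes each pair's score in both directions); in undirected mode,
#' all unordered pairs, with the gold standard collapsed by logical OR and a
#' directed scorer contributing the larger of its two directional scores.
#'
#' @param scores A `grn_scores` (square, or directed with regulator rows).
#' @param gold A `grn_network` gold standard; its genes must be covered by
#'   the score matrix.
#' @param mode `"directed"` or `"undirected"`; default follows the scorer's
#'   directed flag.
#' @param regulators Optional character vector restricting candidate
#'   regulators (rows).
#' @param exclude_tf_tf Logical: drop pairs where both genes are gold TFs
#'   (candidate-universe variant, default `FALSE`).
#' @param exclude_pairs Optional data frame (`regulator`, `target`) of pairs
#'   to drop from the universe, e.g. interactions already used for training.
#' @return A `grn_evaluation`: list with `auc`, `roc` (data frame of fpr/tpr
#'   points), `n_pos`, `n_neg`, `mode`.
#' @export
roc_auc <- function(scores, gold, mode = NULL, regulators = NULL,
                    exclude_tf_tf = FALSE, exclude_pairs = NULL) {
  s <- scores$scores
  if (is.null(mode)) mode <- if (scores$directed) "directed" else "undirected"
  mode <- match.arg(mode, c("directed", "undirected"))
  if (!all(gold$nodes %in% union(rownames(s), colnames(s)))) {
    stop("gold-standard genes missing from the score matrix")
  }
  if (!is.null(regulators)) {
    regulators <- intersect(regulators, rownames(s))
    s <- s[regulators, , drop = FALSE]
  }
  rows <- intersect(rownames(s), gold$nodes)
  cols <- intersect(colnames(s), gold$nodes)
  pos_keys <- edge_keys(gold)
  if (mode == "directed") {
    grid <- expand.grid(regulator = rows, target = cols,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$regulator != grid$target, , drop = FALSE]
    key <- paste(grid$regulator, grid$target, sep = "\r")
    sc <- s[cbind(grid$regulator, grid$target)]
    lab <- key %in% pos_keys
  } else {
    if (!identical(rows, cols)) {
      ## directed scorer in undirected mode: use union square view
      common <- intersect(rows, cols)
      rows <- cols <- common
    }
    grid <- t(utils::combn(rows, 2))
    grid <- data.frame(regulator = grid[, 1], target = grid[, 2],
                       stringsAsFactors = FALSE)
    a <- s[cbind(grid$regulator, grid$target)]
    b <- s[cbind(grid$target, grid$regulator)]
    sc <- pmax(a, b)
    key <- paste(grid$regulator, grid$target, sep = "\r")
    key_rev <- paste(grid$target, grid$regulator, sep = "\r")
    lab <- key %in% pos_keys | key_rev %in% pos_keys
  }
  if (exclude_tf_tf) {
    both_tf <- gold$tf[grid$regulator] & gold$tf[grid$target]
    sc <- sc[!both_tf]; lab <- lab[!both_tf]; key <- key[!both_tf]
    grid <- grid[!both_tf, , drop = FALSE]
  }
  if (!is.null(exclude_pairs)) {
    drop_keys <- paste(exclude_pairs$regulator, exclude_pairs$target, sep = "\r")
    if (mode == "undirected") {
      drop_keys <- c(drop_keys,
                     paste(exclude_pairs$target, exclude_pairs$regulator, sep = "\r"))
      key2 <- paste(grid$target, grid$regulator, sep = "\r")
      keep <- !(key %in% drop_keys | key2 %in% drop_keys)
    } else keep <- !(key %in% drop_keys)
    sc <- sc[keep]; lab <- lab[keep]
  }
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) {
    stop("candidate universe needs at least one positive and one negative")
  }
  r <- rank(sc)  # midranks for ties
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, roc = roc_points(sc, lab),
                 n_pos = n_pos, n_neg = n_neg, mode = mode),
            class = "grn_evaluation")
}

## ROC polyline with tied scores collapsed into single segments
roc_points <- function(sc, lab) {
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; lab <- lab[o]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!lab)),
             tpr = c(0, tp[last] / sum(lab)))
}

#' @export
print.grn_evaluation <- function(x, ...) {
  cat(sprintf("grn_evaluation (%s): AUC %.4f (%d positives, %d negatives)\n",
              x$mode, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' The full MI-method parameter grid
#'
#' The Cartesian grid swept for each MI-based method: 4 estimators x 3
#' discretization methods x the canonical 26-value bin list = 312
#' configurations.
#' @return Data frame of 312 rows with columns `estimator`,
#'   `discretization`, `bins`.
#' @export
mi_grid <- function() {
  expand.grid(estimator = c("empirical", "mm", "shrink", "sg"),
              discretization = c("equalfreq", "equalwidth", "globalequalwidth"),
              bins = canonical_bins(),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' The soft-threshold correlation parameter grid
#'
#' 3 correlation kinds x softpower 7..17 = 33 configurations.
#' @return Data frame of 33 rows with columns `kind`, `softpower`.
#' @export
wgcna_grid <- function() {
  expand.grid(kind = c("pearson", "spearman", "kendall"),
              softpower = 7:17,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Sweep a method over a parameter grid
#'
#' Runs one inference method once per row of the grid, evaluates each
#' configuration by [roc_auc()], and selects the best row (maximum AUC; ties
#' broken by enumeration order). A configuration that fails records an error
#' row (AUC `NA`) and the sweep continues.
#'
#' @param method Method name, see [infer_scores()].
#' @param grid Data frame: one column per parameter, one row per
#'   configuration (e.g. [mi_grid()], [wgcna_grid()]).
#' @param data A `grn_expression`.
#' @param gold A `grn_network` gold standard.
#' @param mode Evaluation mode passed to [roc_auc()].
#' @param fixed Named list of parameters shared by all configurations.
#' @return A `grn_sweep`: list with `results` (the grid plus `auc` and
#'   `error` columns), `best` (index of the best row) and `method`.
#' @export
parameter_sweep <- function(method, grid, data, gold, mode = NULL, fixed = list()) {
  if (!nrow(grid)) stop("empty parameter grid")
  auc <- rep(NA_real_, nrow(grid))
  err <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- c(as.list(grid[i, , drop = FALSE]), fixed)
    res <- tryCatch({
      sc <- infer_scores(method, data, params)
      roc_auc(sc, gold, mode = mode)$auc
    }, error = function(e) e)
    if (inherits(res, "error")) err[i] <- conditionMessage(res) else auc[i] <- res
  }
  results <- cbind(grid, auc = auc, error = err, stringsAsFactors = FALSE)
  best <- if (all(is.na(auc))) NA_integer_ else which.max(auc)
  structure(list(results = results, best = best, method = method),
            class = "grn_sweep")
}

#' @export
print.grn_sweep <- function(x, ...) {
  cat(sprintf("grn_sweep (%s): %d configurations", x$method, nrow(x$results)))
  if (!is.na(x$best)) {
    cat(sprintf(", best AUC %.4f at row %d", x$results$auc[x$best], x$best))
  }
  cat("\n")
  invisible(x)
}

#' Sweep all MI-based methods sharing each MI matrix
#'
#' The four relevance-network-family methods read the data only through the
#' MI matrix, so a joint sweep computes each (estimator, discretization,
#' bins) matrix once and scores every method on it.
#'
#' @param data A `grn_expression`.
#' @param gold A `grn_network`.
#' @param methods Subset of `c("rn","clr","aracne","mrnet")`.
#' @param grid MI parameter grid, default [mi_grid()].
#' @param mode Evaluation mode passed to [roc_auc()].
#' @param eps ARACNE tolerance.
#' @return Tidy data frame: grid columns plus `method` and `auc` (NA on
#'   failed configurations).
#' @export
sweep_mi_methods <- function(data, gold, methods = c("rn", "clr", "aracne", "mrnet"),
                             grid = mi_grid(), mode = NULL, eps = 0) {
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, , drop = FALSE]
    auc <- setNames(rep(NA_real_, length(methods)), methods)
    mi <- tryCatch(mi_matrix(data, row$estimator, row$discretization, row$bins),
                   error = function(e) NULL)
    if (!is.null(mi)) {
      for (mth in methods) {
        sc <- switch(mth, rn = rn(mi), clr = clr(mi),
                     aracne = aracne(mi, eps), mrnet = mrnet(mi))
        auc[mth] <- roc_auc(sc, gold, mode = mode)$auc
      }
    }
    out[[i]] <- cbind(row[rep(1, length(methods)), , drop = FALSE],
                      method = methods, auc = auc,
                      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise method comparison by rank-sum tests
#'
#' Two-sided Mann-Whitney U tests for every pair of AUC groups with
#' Bonferroni adjustment, as used to compare inference accuracy across
#' network families.
#'
#' @param auc_groups Named list of numeric AUC vectors (each >= 3 values).
#' @param alpha Significance level applied to the Bonferroni-adjusted p
#'   values, default 0.01.
#' @return Data frame with one row per group pair: `group_a`, `group_b`,
#'   `p_raw`, `p_adj` (`min(1, p_raw * n_comparisons)`), `significant`.
#' @export
compare_methods <- function(auc_groups, alpha = 0.01) {
  if (length(auc_groups) < 2) stop("need at least two groups")
  if (any(lengths(auc_groups) < 3)) stop("each group needs >= 3 values")
  nm <- names(auc_groups)
  pairs <- utils::combn(seq_along(auc_groups), 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- if (isTRUE(all.equal(auc_groups[[i]], auc_groups[[j]]))) 1 else {
      suppressWarnings(stats::wilcox.test(auc_groups[[i]], auc_groups[[j]]))$p.value
    }
    if (!is.finite(p)) p <- 1
    data.frame(group_a = nm[i], group_b = nm[j], p_raw = p,
               p_adj = min(1, p * n_comp), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p_adj < alpha
  res
}
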