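#' Construct a score matrix
#'
#' The common output container of all inference methods: a real-valued score
#' for every candidate regulator/target pair. Symmetric methods produce a
#' square symmetric matrix; directed methods (tree ensembles, the supervised
#' method) may score only regulator rows.
#'
#' @param scores Numeric matrix with dimnames (rows = candidate regulators,
#'   columns = targets). Square matrices get a zero diagonal.
#' @param directed Logical: do row -> column scores carry direction?
#' @param method Method tag.
#' @param params List of the parameters used.
#' @return An object of class `grn_scores`.
#' @export
grn_scores <- function(scores, directed, method, params = list()) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("score matrix must carry dimnames")
  }
  if (!all(is.finite(scores))) stop("score matrix must be finite")
  if (nrow(scores) == ncol(scores) && identical(rownames(scores), colnames(scores))) {
    diag(scores) <- 0
    if (!directed && !isTRUE(all.equal(scores, t(scores)))) {
      stop("undirected score matrix must be symmetric")
    }
  } else if (!directed) {
    stop("non-square score matrices must be directed")
  }
  structure(list(scores = scores, directed = directed,
                 method = method, params = params),
            class = "grn_scores")
}

#' @export
print.grn_scores <- function(x, ...) {
  cat(sprintf("grn_scores (%s, %s): %d x %d\n", x$method,
              if (x$directed) "directed" else "undirected",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

## positive entries of a score matrix as an edge list, sorted by weight
score_edge_list <- function(scores) {
  s <- scores$scores
  if (!scores$directed) s[lower.tri(s)] <- 0
  idx <- which(s > 0, arr.ind = TRUE)
  el <- data.frame(regulator = rownames(s)[idx[, 1]],
                   target = colnames(s)[idx[, 2]],
                   weight = s[idx], stringsAsFactors = FALSE)
  el[order(-el$weight, el$regulator, el$target), , drop = FALSE]
}

#' Relevance networks
#'
#' The simplest MI-based method: the score of a gene pair is its mutual
#' information, unchanged.
#'
#' @param mi A `grn_mi` from [mi_matrix()] (or a symmetric MI matrix).
#' @return An undirected `grn_scores`.
#' @export
rn <- function(mi) {
  grn_scores(as_mi_matrix(mi), directed = FALSE, method = "rn",
             params = mi_params(mi))
}

mi_params <- function(mi) {
  if (inherits(mi, "grn_mi")) {
    list(estimator = mi$estimator, discretization = mi$discretization, bins = mi$bins)
  } else list()
}

#' Context likelihood of relatedness
#'
#' Converts each MI value into a background-corrected z-score against the
#' MI distribution of each gene's row (diagonal excluded):
#' `z_i(j) = max(0, (MI_ij - mean_i) / sd_i)`, combined as
#' `sqrt(z_i(j)^2 + z_j(i)^2)`. A zero-variance row contributes z = 0.
#'
#' @inheritParams rn
#' @return An undirected `grn_scores`.
#' @export
clr <- function(mi) {
  m <- as_mi_matrix(mi)
  n <- nrow(m)
  if (n < 3) stop("clr needs at least 3 genes")
  z <- matrix(0, n, n, dimnames = dimnames(m))
  for (i in seq_len(n)) {
    row <- m[i, -i]
    mu <- mean(row)
    sdev <- stats::sd(row)
    if (sdev > 0) z[i, -i] <- pmax(0, (row - mu) / sdev)
  }
  grn_scores(sqrt(z^2 + t(z)^2), directed = FALSE, method = "clr",
             params = mi_params(mi))
}

#' ARACNE data-processing-inequality pruning
#'
#' For every triangle of three positive MI values, the weakest edge violates
#' the data-processing inequality and is marked for removal when
#' `MI_ij < min(MI_ik, MI_jk) - eps` (strict, so exact ties survive). All
#' marks are computed against the original matrix and applied afterwards —
#' no cascading. Surviving edges keep their MI score; removed edges score 0.
#'
#' @inheritParams rn
#' @param eps Non-negative DPI tolerance, default 0.
#' @return An undirected `grn_scores`; its positive-score edge set is always
#'   a subset of the relevance-network edge set.
#' @export
aracne <- function(mi, eps = 0) {
  if (eps < 0) stop("eps must be >= 0")
  m <- as_mi_matrix(mi)
  n <- nrow(m)
  marked <- matrix(FALSE, n, n)
  for (k in seq_len(n)) {
    ## for each pair (i,j), the triangle through k prunes (i,j) when both
    ## other sides are positive and exceed MI_ij + eps
    mink <- outer(m[, k], m[k, ], pmin)
    pos <- outer(m[, k] > 0, m[k, ] > 0, `&`)
    marked <- marked | (pos & m > 0 & m < mink - eps)
  }
  out <- m
  out[marked] <- 0
  grn_scores(out, directed = FALSE, method = "aracne",
             params = c(mi_params(mi), list(eps = eps)))
}

#' MRNET maximum-relevance minimum-redundancy forward selection
#'
#' For each target gene Y, candidate regulators are ranked by forward
#' selection: the first pick maximizes `MI(X;Y)`; each further pick maximizes
#' the relevance-minus-redundancy score
#' `u_j = MI(X_j;Y) - mean_{k in selected} MI(X_j;X_k)`, stopping when the
#' best `u_j` is <= 0. A pair's score is `u_j` at selection time (so never
#' exceeds the MI value); the symmetric result takes the larger of the two
#' directions and unselected pairs score 0. Ties break by gene order.
#'
#' @inheritParams rn
#' @return An undirected `grn_scores`.
#' @export
mrnet <- function(mi) {
  m <- as_mi_matrix(mi)
  n <- nrow(m)
  s <- matrix(0, n, n, dimnames = dimnames(m))
  for (y in seq_len(n)) {
    cand <- setdiff(seq_len(n), y)
    sel <- integer()
    while (length(cand)) {
      u <- if (length(sel)) {
        m[cand, y] - rowMeans(m[cand, sel, drop = FALSE])
      } else m[cand, y]
      best <- which.max(u)  # first maximum = lowest gene index
      if (u[best] <= 0) break
      s[cand[best], y] <- u[best]
      sel <- c(sel, cand[best])
      cand <- cand[-best]
    }
  }
  grn_scores(pmax(s, t(s)), directed = FALSE, method = "mrnet",
             params = mi_params(mi))
}

## correlation matrix with constant genes mapped to 0 instead of NA
safe_cor <- function(m, kind) {
  const <- apply(m, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    grn_log("constant gene(s) get correlation 0: ",
            paste(rownames(m)[const], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(t(m), method = kind))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  r
}

#' Absolute-correlation scoring
#'
#' Scores each gene pair by the absolute value of its Pearson, Spearman or
#' Kendall correlation across samples. Constant genes get score 0.
#'
#' @param data A `grn_expression` or numeric genes x samples matrix.
#' @param kind `"pearson"`, `"spearman"` or `"kendall"`.
#' @return An undirected `grn_scores`.
#' @export
correlations <- function(data, kind = c("pearson", "spearman", "kendall")) {
  kind <- match.arg(kind)
  m <- if (inherits(data, "grn_expression")) data$values else as.matrix(data)
  if (ncol(m) < 3) stop("need at least 3 samples")
  grn_scores(abs(safe_cor(m, kind)), directed = FALSE, method = "correlations",
             params = list(kind = kind))
}

#' Soft-thresholded correlation adjacency
#'
#' Weighted-coexpression-style scoring: the adjacency
#' `a_ij = |cor(i,j)|^softpower` suppresses weak correlations while
#' preserving the ranking within each power. `softpower = 1` reduces to
#' [correlations()]. An optional topological-overlap transform replaces each
#' adjacency with its neighbourhood-overlap value.
#'
#' @inheritParams correlations
#' @param softpower Integer soft-thresholding power >= 1.
#' @param tom Logical: apply the topological-overlap transform?
#' @return An undirected `grn_scores`.
#' @export
wgcna <- function(data, kind = c("pearson", "spearman", "kendall"),
                  softpower = 7, tom = FALSE) {
  kind <- match.arg(kind)
  if (softpower < 1) stop("softpower must be >= 1")
  m <- if (inherits(data, "grn_expression")) data$values else as.matrix(data)
  if (ncol(m) < 3) stop("need at least 3 samples")
  a <- abs(safe_cor(m, kind))^softpower
  diag(a) <- 0
  if (tom) {
    k <- colSums(a)
    l <- a %*% a
    denom <- outer(k, k, pmin) + 1 - a
    a <- (l + a) / denom
    diag(a) <- 0
  }
  grn_scores(a, directed = FALSE, method = "wgcna",
             params = list(kind = kind, softpower = softpower, tom = tom))
}

#' PCIT partial-correlation filtering
#'
#' For every trio of genes (x, y, z) the three first-order partial
#' correlations, e.g. `r_xy.z = (r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 -
#' r_zy^2))`, are compared to the direct correlations. The trio tolerance is
#' the mean of the three |partial / direct| ratios; the (x, y) association is
#' flagged non-significant if for some z both `|r_xy| <= eps * |r_xz|` and
#' `|r_xy| <= eps * |r_yz|`. Surviving edges score `|r_xy|`, flagged edges 0.
#' Trios with a unit correlation in a denominator are skipped.
#'
#' @inheritParams correlations
#' @return An undirected `grn_scores`.
#' @export
pcit <- function(data, kind = c("pearson", "spearman", "kendall")) {
  kind <- match.arg(kind)
  m <- if (inherits(data, "grn_expression")) data$values else as.matrix(data)
  if (nrow(m) < 3) stop("pcit needs at least 3 genes")
  if (ncol(m) < 4) stop("pcit needs at least 4 samples")
  r <- safe_cor(m, kind)
  n <- nrow(r)
  flagged <- matrix(FALSE, n, n)
  for (x in seq_len(n - 2L)) {
    for (y in (x + 1L):(n - 1L)) {
      for (z in (y + 1L):n) {
        rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
        d_xy <- (1 - rxz^2) * (1 - ryz^2)
        d_xz <- (1 - rxy^2) * (1 - ryz^2)
        d_yz <- (1 - rxy^2) * (1 - rxz^2)
        if (d_xy <= 0 || d_xz <= 0 || d_yz <= 0) {
          grn_log(sprintf("pcit: trio (%d,%d,%d) skipped (unit correlation)", x, y, z))
          next
        }
        p_xy <- (rxy - rxz * ryz) / sqrt(d_xy)
        p_xz <- (rxz - rxy * ryz) / sqrt(d_xz)
        p_yz <- (ryz - rxy * rxz) / sqrt(d_yz)
        ratios <- c(if (rxy != 0) abs(p_xy / rxy),
                    if (rxz != 0) abs(p_xz / rxz),
                    if (ryz != 0) abs(p_yz / ryz))
        if (!length(ratios)) next
        eps <- mean(ratios)
        if (abs(rxy) <= eps * abs(rxz) && abs(rxy) <= eps * abs(ryz)) {
          flagged[x, y] <- flagged[y, x] <- TRUE
        }
        if (abs(rxz) <= eps * abs(rxy) && abs(rxz) <= eps * abs(ryz)) {
          flagged[x, z] <- flagged[z, x] <- TRUE
        }
        if (abs(ryz) <= eps * abs(rxy) && abs(ryz) <= eps * abs(rxz)) {
          flagged[y, z] <- flagged[z, y] <- TRUE
        }
      }
    }
  }
  out <- abs(r)
  out[flagged] <- 0
  grn_scores(out, directed = FALSE, method = "pcit", params = list(kind = kind))
}

#' Tree-ensemble regression scoring (GENIE3-style)
#'
#' Each target gene's profile is regressed on the candidate regulators
#' (itself excluded) with a random forest; the score of regulator j for a
#' target is j's total impurity-reduction importance, normalized so each
#' target's incoming importances sum to 1. The only directed unsupervised
#' method here.
#'
#' @param data A `grn_expression` or numeric genes x samples matrix.
#' @param candidate_regulators Optional character vector of regulator genes;
#'   default all genes.
#' @param n_trees Trees per forest, default 1000.
#' @param k_features `"sqrt"` (default) or `"all"`: candidate features tried
#'   at each split.
#' @param seed Integer seed; results are deterministic given it.
#' @return A directed `grn_scores` with regulator rows and target columns.
#' @export
genie <- function(data, candidate_regulators = NULL, n_trees = 1000,
                  k_features = c("sqrt", "all"), seed = 1) {
  k_features <- match.arg(k_features)
  if (n_trees < 1) stop("n_trees must be >= 1")
  m <- if (inherits(data, "grn_expression")) data$values else as.matrix(data)
  if (nrow(m) < 2) stop("need at least 2 genes")
  genes <- rownames(m)
  regs <- if (is.null(candidate_regulators)) genes else {
    stopifnot(all(candidate_regulators %in% genes))
    candidate_regulators
  }
  set.seed(seed)
  s <- matrix(0, length(regs), length(genes), dimnames = list(regs, genes))
  for (g in genes) {
    y <- m[g, ]
    preds <- setdiff(regs, g)
    if (length(preds) == 0) next
    if (stats::sd(y) == 0) {
      grn_log("constant target gene ", g, ": zero importances")
      next
    }
    x <- t(m[preds, , drop = FALSE])
    mtry <- if (k_features == "sqrt") max(1L, floor(sqrt(length(preds)))) else length(preds)
    fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                                      importance = FALSE)
    imp <- fit$importance[, "IncNodePurity"]
    tot <- sum(imp)
    if (tot > 0) s[preds, g] <- imp / tot
  }
  if (identical(regs, genes)) diag(s) <- 0
  grn_scores(s, directed = TRUE, method = "genie",
             params = list(n_trees = n_trees, k_features = k_features, seed = seed))
}

#' Run an inference method by name
#'
#' Uniform registry over the eight unsupervised methods (the supervised
#' method, needing a training set, lives in [sirene()]). MI-based methods
#' accept `estimator`, `discretization` and `bins`; correlation-based
#' methods accept `kind` (plus `softpower`/`tom` for `"wgcna"`, `eps` for
#' `"aracne"`); `"genie"` accepts its own parameters.
#'
#' @param method One of `"rn"`, `"clr"`, `"aracne"`, `"mrnet"`,
#'   `"correlations"`, `"wgcna"`, `"pcit"`, `"genie"`.
#' @param data A `grn_expression`.
#' @param params Named list of method parameters.
#' @param mi Optional precomputed `grn_mi`, reused by the MI-based methods.
#' @return A `grn_scores`.
#' @export
infer_scores <- function(method, data, params = list(), mi = NULL) {
  method <- match.arg(method, c("rn", "clr", "aracne", "mrnet",
                                "correlations", "wgcna", "pcit", "genie"))
  get_par <- function(nm, default) if (is.null(params[[nm]])) default else params[[nm]]
  if (method %in% c("rn", "clr", "aracne", "mrnet")) {
    if (is.null(mi)) {
      mi <- mi_matrix(data,
                      estimator = get_par("estimator", "empirical"),
                      discretization = get_par("discretization", "equalfreq"),
                      bins = get_par("bins", 3))
    }
    switch(method,
           rn = rn(mi),
           clr = clr(mi),
           aracne = aracne(mi, eps = get_par("eps", 0)),
           mrnet = mrnet(mi))
  } else {
    switch(method,
           correlations = correlations(data, kind = get_par("kind", "pearson")),
           wgcna = wgcna(data, kind = get_par("kind", "pearson"),
                         softpower = get_par("softpower", 7),
                         tom = get_par("tom", FALSE)),
           pcit = pcit(data, kind = get_par("kind", "pearson")),
           genie = genie(data,
                         candidate_regulators = params$candidate_regulators,
                         n_trees = get_par("n_trees", 1000),
                         k_features = get_par("k_features", "sqrt"),
                         seed = get_par("seed", 1)))
  }
}
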