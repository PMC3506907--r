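#' Construct a supervised training set
#'
#' Known regulator -> target interactions used to train the per-TF
#' classifiers of [sirene()].
#'
#' @param positives Data frame with columns `tf` and `target`: known
#'   interactions.
#' @param tfs Character vector of all TFs to consider; defaults to the TFs
#'   appearing in `positives`.
#' @param negatives Optional data frame of known non-interactions, same
#'   columns.
#' @return An object of class `grn_training`.
#' @export
grn_training <- function(positives, tfs = unique(positives$tf), negatives = NULL) {
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(positives))) {
    stop("positives needs columns tf, target")
  }
  positives <- positives[c("tf", "target")]
  if (any(positives$tf == positives$target)) stop("self-pairs are not allowed")
  if (!all(positives$tf %in% tfs)) stop("positive pair references TF outside tf list")
  if (!is.null(negatives)) {
    negatives <- as.data.frame(negatives, stringsAsFactors = FALSE)[c("tf", "target")]
    if (any(negatives$tf == negatives$target)) stop("self-pairs are not allowed")
    both <- merge(positives, negatives)
    if (nrow(both)) stop("pair(s) listed as both positive and negative")
  }
  structure(list(positives = positives, negatives = negatives, tfs = tfs),
            class = "grn_training")
}

#' Read a 2-column TF/target training file
#' @param path Tab-separated file with columns TF, target (no header).
#' @return A [grn_training()].
#' @export
read_training <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("tf", "target"))
  grn_training(df)
}

## stratified fold assignment: positives and negatives round-robin separately,
## so every training split keeps at least one positive when n_pos >= 2
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Supervised per-TF edge scoring (SIRENE-style)
#'
#' Trains one binary support-vector machine per transcription factor: genes
#' are instances (feature vector = expression profile across samples), the
#' TF's known targets are positives and all other genes are treated as
#' negatives (a known optimistic-labeling bias). Scores come from k-fold
#' cross-validation over genes, so each gene is scored by a classifier that
#' never saw its label; the edge weight TF -> gene is the cross-validated
#' SVM decision value — positive weights indicate interactions, negative
#' weights their absence, and the magnitude reflects confidence.
#'
#' @param data A `grn_expression` containing every TF and candidate target.
#' @param training A [grn_training()].
#' @param folds Cross-validation folds over genes, >= 2 (default 3).
#' @param min_positives TFs with fewer known targets are skipped (default 2).
#' @param cost SVM regularization constant C, default 10 (with balanced
#'   class weights and expression in \[0,1\], C around 10 avoids the
#'   underfitting seen at C = 1).
#' @param gamma RBF kernel width; default `NULL` uses the heuristic
#'   `1 / median squared pairwise distance` between gene profiles.
#' @param seed Integer seed for fold assignment.
#' @return A directed `grn_scores` with one row per trained TF; skipped TFs
#'   are listed in `params$skipped`.
#' @export
sirene <- function(data, training, folds = 3, min_positives = 2,
                   cost = 10, gamma = NULL, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  m <- data$values
  genes <- rownames(m)
  missing_tfs <- setdiff(training$tfs, genes)
  if (length(missing_tfs)) {
    stop("TF(s) without expression data: ", paste(missing_tfs, collapse = ", "))
  }
  x_all <- m  # gene instances as rows, samples as features
  if (is.null(gamma)) {
    d2 <- stats::dist(m)^2
    med <- stats::median(d2[d2 > 0])
    gamma <- if (is.finite(med) && med > 0) 1 / med else 1 / ncol(x_all)
  }
  skipped <- character()
  rows <- list()
  for (tf in training$tfs) {
    pos_targets <- unique(training$positives$target[training$positives$tf == tf])
    pos_targets <- intersect(pos_targets, genes)
    if (length(pos_targets) < min_positives) {
      skipped <- c(skipped, tf)
      next
    }
    inst <- setdiff(genes, tf)
    labels <- factor(ifelse(inst %in% pos_targets, "pos", "neg"),
                     levels = c("neg", "pos"))
    n_pos <- sum(labels == "pos"); n_neg <- sum(labels == "neg")
    if (n_neg == 0) { skipped <- c(skipped, tf); next }
    k <- min(folds, n_pos)  # never a fold layout that strands all positives
    if (k < 2) { skipped <- c(skipped, tf); next }
    fold <- stratified_folds(labels, k, seed)
    cw <- c(neg = length(inst) / (2 * n_neg), pos = length(inst) / (2 * n_pos))
    dv <- setNames(numeric(length(inst)), inst)
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2) { ok <- FALSE; break }
      fit <- e1071::svm(x = x_all[inst[tr], , drop = FALSE], y = labels[tr],
                        kernel = "radial", gamma = gamma, cost = cost,
                        class.weights = cw, scale = FALSE)
      pr <- stats::predict(fit, x_all[inst[!tr], , drop = FALSE],
                           decision.values = TRUE)
      d <- attr(pr, "decision.values")
      ## e1071 orients the decision value toward the first label it met
      if (colnames(d)[1] == "neg/pos") d <- -d
      dv[inst[!tr]] <- d[, 1]
    }
    if (!ok) {
      grn_log("TF ", tf, " skipped: could not stratify folds")
      skipped <- c(skipped, tf)
      next
    }
    row <- setNames(numeric(length(genes)), genes)
    row[inst] <- dv
    rows[[tf]] <- row
  }
  if (!length(rows)) stop("no TF had enough known targets to train on")
  s <- do.call(rbind, rows)
  colnames(s) <- genes
  grn_scores(s, directed = TRUE, method = "sirene",
             params = list(folds = folds, min_positives = min_positives,
                           cost = cost, gamma = gamma, seed = seed,
                           skipped = skipped))
}

#' High-confidence predicted interactions
#'
#' Thresholds a score matrix at a minimum weight and returns the surviving
#' edges sorted by descending confidence.
#'
#' @param scores A `grn_scores`.
#' @param threshold Minimum edge weight (e.g. 0 keeps all predicted
#'   interactions of a decision-value scorer; 0.5 keeps only the most
#'   confident).
#' @return Data frame with columns `regulator`, `target`, `weight`.
#' @export
high_confidence <- function(scores, threshold) {
  s <- scores$scores
  if (!scores$directed) s[lower.tri(s)] <- -Inf
  if (nrow(s) == ncol(s) && identical(rownames(s), colnames(s))) diag(s) <- -Inf
  idx <- which(s >= threshold, arr.ind = TRUE)
  el <- data.frame(regulator = rownames(s)[idx[, 1]],
                   target = colnames(s)[idx[, 2]],
                   weight = s[idx], stringsAsFactors = FALSE)
  el <- el[order(-el$weight, el$regulator, el$target), , drop = FALSE]
  rownames(el) <- NULL
  el
}

#' Convert thresholded scores into a network
#'
#' @param scores A `grn_scores`.
#' @param threshold Minimum weight for an edge, default strictly positive.
#' @param tfs Optional TF designation for the resulting network; defaults to
#'   the score matrix's rows (directed) or genes with outgoing edges.
#' @return A `grn_network` over the union of row and column genes.
#' @export
scores_to_network <- function(scores, threshold = 0, tfs = NULL) {
  el <- high_confidence(scores, threshold)
  el <- el[el$weight > 0, , drop = FALSE]
  nodes <- union(rownames(scores$scores), colnames(scores$scores))
  if (is.null(tfs)) {
    tfs <- if (scores$directed) rownames(scores$scores) else unique(el$regulator)
  }
  edges <- data.frame(regulator = el$regulator, target = el$target,
                      sign = NA_character_, weight = el$weight,
                      stringsAsFactors = FALSE)
  grn_network(nodes, setNames(nodes %in% tfs, nodes), edges)
}
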