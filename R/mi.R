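#' Discretize an expression matrix
#'
#' Converts continuous expression to integer bin indices, the prerequisite of
#' the histogram-based mutual-information estimators. Three schemes:
#' `"equalwidth"` splits each gene's own \[min, max\] into bins of equal
#' width; `"equalfreq"` uses per-gene quantile cut points (ties go to the
#' lower bin); `"globalequalwidth"` uses equal-width bins over the whole
#' matrix's global range, so all genes share one scale.
#'
#' @param data A `grn_expression`, or a numeric genes x samples matrix.
#' @param method One of `"equalfreq"`, `"equalwidth"`, `"globalequalwidth"`.
#' @param bins Number of bins, >= 2; for `"equalfreq"` at most the sample
#'   count.
#' @return A `grn_discretized`: list with `indices` (integer matrix, values
#'   in `0 .. bins-1`), `bins` and `method`.
#' @details A constant gene under the equal-width schemes maps to bin 0 for
#'   all samples (not an error). The last bin is right-closed, so the maximum
#'   lands in bin `bins - 1`.
#' @export
discretize <- function(data, method = c("equalfreq", "equalwidth", "globalequalwidth"),
                       bins = 3) {
  method <- match.arg(method)
  m <- if (inherits(data, "grn_expression")) data$values else as.matrix(data)
  if (bins < 2) stop("bins must be >= 2")
  if (method == "equalfreq" && bins > ncol(m)) {
    stop("equalfreq requires bins <= number of samples")
  }
  idx <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  bin_width <- function(x, lo, hi) {
    if (hi <= lo) return(rep(0L, length(x)))
    pmin(as.integer(floor((x - lo) / (hi - lo) * bins)), bins - 1L)
  }
  if (method == "globalequalwidth") {
    lo <- min(m); hi <- max(m)
    idx[] <- bin_width(m, lo, hi)
  } else if (method == "equalwidth") {
    for (i in seq_len(nrow(m))) {
      idx[i, ] <- bin_width(m[i, ], min(m[i, ]), max(m[i, ]))
    }
  } else {
    probs <- seq(0, 1, length.out = bins + 1L)
    for (i in seq_len(nrow(m))) {
      cuts <- stats::quantile(m[i, ], probs = probs[-c(1, bins + 1L)],
                              names = FALSE, type = 7)
      ## a value equal to a cut point stays in the lower bin
      idx[i, ] <- as.integer(vapply(m[i, ], function(v) sum(v > cuts), numeric(1)))
    }
  }
  structure(list(indices = idx, bins = as.integer(bins), method = method),
            class = "grn_discretized")
}

#' Entropy of a histogram in nats
#'
#' Four estimators over a histogram of counts: `"empirical"` is the plug-in
#' estimate `-sum(p * log(p))`; `"mm"` adds the Miller-Madow bias correction
#' `(occupied bins - 1) / (2n)`; `"shrink"` applies the plug-in formula to
#' James-Stein-shrunk probabilities pulled toward the uniform distribution
#' `1/m` with closed-form intensity clipped to \[0,1\]; `"sg"` applies it to
#' pseudocount probabilities `(n_i + 1/m) / (n + 1)` (a symmetric Dirichlet
#' prior with concentration `1/m`).
#'
#' @param counts Non-negative integer histogram; its length is the number of
#'   bins `m` (empty bins matter for `"shrink"` and `"sg"`).
#' @param estimator One of `"empirical"`, `"mm"`, `"shrink"`, `"sg"`.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(counts, estimator = c("empirical", "mm", "shrink", "sg")) {
  estimator <- match.arg(estimator)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("all-zero histogram")
  m <- length(counts)
  plugin <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  p_hat <- counts / n
  switch(estimator,
    empirical = plugin(p_hat),
    mm = plugin(p_hat) + (sum(counts > 0) - 1) / (2 * n),
    shrink = {
      if (n == 1) return(plugin(rep(1 / m, m)))
      denom <- (n - 1) * sum((1 / m - p_hat)^2)
      lambda <- if (denom == 0) 1 else min(1, max(0, (1 - sum(p_hat^2)) / denom))
      plugin(lambda / m + (1 - lambda) * p_hat)
    },
    sg = plugin((counts + 1 / m) / (n + 1))
  )
}

#' Mutual information of two discretized vectors
#'
#' `MI = H(X) + H(Y) - H(X,Y)` with the chosen entropy estimator applied to
#' the marginal and joint histograms. The joint histogram spans the full
#' `m_x * m_y` grid (structural zeros included, which matters for the
#' `"shrink"` and `"sg"` estimators). Negative results from bias-corrected
#' estimators are clipped to 0.
#'
#' @param x,y Equal-length integer vectors of bin indices (0-based).
#' @param estimator Entropy estimator, see [shannon_entropy()].
#' @param m_x,m_y Number of bins for each variable; defaults to
#'   `max(.) + 1`.
#' @return Mutual information in nats, >= 0.
#' @export
mutual_information <- function(x, y, estimator = "empirical",
                               m_x = max(x) + 1L, m_y = max(y) + 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  hx <- tabulate(x + 1L, nbins = m_x)
  hy <- tabulate(y + 1L, nbins = m_y)
  hxy <- tabulate(x * m_y + y + 1L, nbins = m_x * m_y)
  mi <- shannon_entropy(hx, estimator) + shannon_entropy(hy, estimator) -
    shannon_entropy(hxy, estimator)
  max(mi, 0)
}

#' Pairwise mutual-information matrix
#'
#' Discretizes the data and computes MI for every unordered gene pair; the
#' shared substrate of the relevance-network family of inference methods.
#'
#' @param data A `grn_expression` (or numeric matrix), or a
#'   `grn_discretized` produced by [discretize()].
#' @param estimator Entropy estimator, see [shannon_entropy()].
#' @param discretization Discretization method, see [discretize()]; ignored
#'   when `data` is already discretized.
#' @param bins Number of bins; ignored when `data` is already discretized.
#' @return A `grn_mi`: list with symmetric non-negative `mi` matrix
#'   (zero diagonal) and the estimator/discretization/bins tags.
#' @export
mi_matrix <- function(data, estimator = "empirical",
                      discretization = "equalfreq", bins = 3) {
  estimator <- match.arg(estimator, c("empirical", "mm", "shrink", "sg"))
  disc <- if (inherits(data, "grn_discretized")) data
          else discretize(data, discretization, bins)
  d <- disc$indices
  b <- disc$bins
  n_g <- nrow(d)
  n <- ncol(d)
  ## unchecked fast path of shannon_entropy, used once per pair
  ent <- switch(estimator,
    empirical = function(counts, m) {
      p <- counts[counts > 0] / n
      -sum(p * log(p))
    },
    mm = function(counts, m) {
      p <- counts[counts > 0] / n
      -sum(p * log(p)) + (length(p) - 1) / (2 * n)
    },
    shrink = function(counts, m) {
      p_hat <- counts / n
      if (n == 1) return(log(m))
      denom <- (n - 1) * sum((1 / m - p_hat)^2)
      lambda <- if (denom == 0) 1 else min(1, max(0, (1 - sum(p_hat^2)) / denom))
      p <- lambda / m + (1 - lambda) * p_hat
      p <- p[p > 0]
      -sum(p * log(p))
    },
    sg = function(counts, m) {
      p <- (counts + 1 / m) / (n + 1)
      -sum(p * log(p))
    })
  h <- vapply(seq_len(n_g), function(i) {
    ent(tabulate(d[i, ] + 1L, nbins = b), b)
  }, numeric(1))
  mi <- matrix(0, n_g, n_g, dimnames = list(rownames(d), rownames(d)))
  b2 <- b * b
  for (i in seq_len(n_g - 1L)) {
    xi <- d[i, ] * b + 1L
    for (j in (i + 1L):n_g) {
      hxy <- ent(tabulate(xi + d[j, ], nbins = b2), b2)
      mi[i, j] <- mi[j, i] <- max(h[i] + h[j] - hxy, 0)
    }
  }
  structure(list(mi = mi, estimator = estimator,
                 discretization = disc$method, bins = b),
            class = "grn_mi")
}

#' @export
print.grn_mi <- function(x, ...) {
  cat(sprintf("grn_mi: %d genes, estimator %s, %s with %d bins\n",
              nrow(x$mi), x$estimator, x$discretization, x$bins))
  invisible(x)
}

## accept either a grn_mi or a bare symmetric matrix
as_mi_matrix <- function(mi) {
  if (inherits(mi, "grn_mi")) return(mi$mi)
  m <- as.matrix(mi)
  if (nrow(m) != ncol(m)) stop("MI matrix must be square")
  m
}

#' The canonical bin-size list of the benchmark parameter sweep
#'
#' Bin counts 2 to 10 in steps of 1, then 15 to 95 in steps of 5 — the
#' 26-value list that, crossed with 4 estimators and 3 discretization
#' methods, gives the 312-configuration grid of the MI-based methods.
#'
#' @return Integer vector of length 26.
#' @export
canonical_bins <- function() c(2:10, seq(15L, 95L, by = 5L))
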