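# Independent naive re-implementations used as oracles. Deliberately written
# as plain loops over the definitions, sharing no code with the package.

options(grnibench.verbose = FALSE)

# AUC as the fraction of positive-negative pairs ordered correctly (ties 1/2)
oracle_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# empirical MI by direct double summation over the joint histogram
oracle_mi_empirical <- function(x, y) {
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- mean(x == a & y == b)
      if (pxy > 0) mi <- mi + pxy * log(pxy / (mean(x == a) * mean(y == b)))
    }
  }
  mi
}

oracle_clr <- function(m) {
  n <- nrow(m)
  z <- matrix(0, n, n)
  for (i in 1:n) {
    row <- m[i, -i]
    if (sd(row) > 0) {
      for (j in setdiff(1:n, i)) {
        z[i, j] <- max(0, (m[i, j] - mean(row)) / sd(row))
      }
    }
  }
  out <- matrix(0, n, n, dimnames = dimnames(m))
  for (i in 1:n) for (j in 1:n) out[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
  diag(out) <- 0
  out
}

oracle_aracne <- function(m, eps = 0) {
  n <- nrow(m)
  marked <- matrix(FALSE, n, n)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        tri <- c(m[i, j], m[i, k], m[j, k])
        if (all(tri > 0)) {
          if (m[i, j] < min(m[i, k], m[j, k]) - eps) marked[i, j] <- marked[j, i] <- TRUE
          if (m[i, k] < min(m[i, j], m[j, k]) - eps) marked[i, k] <- marked[k, i] <- TRUE
          if (m[j, k] < min(m[i, j], m[i, k]) - eps) marked[j, k] <- marked[k, j] <- TRUE
        }
      }
    }
  }
  out <- m
  out[marked] <- 0
  diag(out) <- 0
  out
}

oracle_mrnet <- function(m) {
  n <- nrow(m)
  s <- matrix(0, n, n, dimnames = dimnames(m))
  for (y in 1:n) {
    cand <- setdiff(1:n, y)
    sel <- c()
    repeat {
      if (!length(cand)) break
      u <- sapply(cand, function(x) {
        red <- if (length(sel)) mean(m[x, sel]) else 0
        m[x, y] - red
      })
      b <- which.max(u)
      if (u[b] <= 0) break
      s[cand[b], y] <- u[b]
      sel <- c(sel, cand[b])
      cand <- cand[-b]
    }
  }
  pmax(s, t(s))
}

oracle_pcit <- function(data, kind = "pearson") {
  m <- if (inherits(data, "grn_expression")) data$values else data
  r <- suppressWarnings(cor(t(m), method = kind))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  n <- nrow(r)
  keep <- matrix(TRUE, n, n)
  pc <- function(a, b, c) (r[a, b] - r[a, c] * r[c, b]) /
    sqrt((1 - r[a, c]^2) * (1 - r[c, b]^2))
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    if (abs(r[x, y]) == 1 || abs(r[x, z]) == 1 || abs(r[y, z]) == 1) next
    ratios <- c()
    for (pr in list(c(x, y, z), c(x, z, y), c(y, z, x))) {
      d <- r[pr[1], pr[2]]
      if (d != 0) ratios <- c(ratios, abs(pc(pr[1], pr[2], pr[3]) / d))
    }
    if (!length(ratios)) next
    eps <- mean(ratios)
    for (pr in list(c(x, y, z), c(x, z, y), c(y, z, x))) {
      a <- pr[1]; b <- pr[2]; c <- pr[3]
      if (abs(r[a, b]) <= eps * abs(r[a, c]) && abs(r[a, b]) <= eps * abs(r[b, c])) {
        keep[a, b] <- keep[b, a] <- FALSE
      }
    }
  }
  out <- abs(r)
  out[!keep] <- 0
  diag(out) <- 0
  out
}

# random symmetric MI-like matrix with zero diagonal
random_mi <- function(n, seed, sparsity = 0) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  if (sparsity > 0) m[m < sparsity] <- 0
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
  m
}

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  grn_expression(m)
}

# small toy network: 2 TFs, 4 targets
toy_network <- function() {
  nodes <- c("tf1", "tf2", "a", "b", "c", "d")
  edges <- data.frame(
    regulator = c("tf1", "tf1", "tf2", "tf2"),
    target = c("a", "b", "c", "d"),
    sign = "activate", weight = 1, stringsAsFactors = FALSE)
  grn_network(nodes, nodes %in% c("tf1", "tf2"), edges)
}
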