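#' Construct a directed gene regulatory network
#'
#' A `grn_network` is the central graph container of the package: a set of
#' gene identifiers, a per-gene regulator (transcription factor) flag, and a
#' directed weighted edge table. The same container serves as simulation
#' ground truth, gold standard, and thresholded prediction.
#'
#' @param nodes Character vector of unique gene identifiers.
#' @param tf Logical vector (same length as `nodes`, or named by node) marking
#'   which genes are transcription factors.
#' @param edges Data frame with columns `regulator`, `target`, `sign`
#'   (`"activate"` or `"repress"`; `NA` allowed when unknown) and `weight`
#'   (positive real). Zero-row data frames are accepted.
#' @return An object of class `grn_network`.
#' @details Invariants enforced: node identifiers unique, no self-loops, every
#'   edge regulator flagged as a TF, no duplicated regulator/target pairs.
#' @export
grn_network <- function(nodes, tf, edges = empty_edges()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (!is.null(names(tf))) tf <- tf[nodes]
  tf <- as.logical(tf)
  if (length(tf) != length(nodes) || anyNA(tf)) {
    stop("'tf' must be a complete logical flag per node")
  }
  names(tf) <- nodes
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("regulator", "target", "sign", "weight")
  if (!all(required %in% names(edges))) {
    stop("edges need columns: ", paste(required, collapse = ", "))
  }
  edges <- edges[required]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges)) {
    bad <- setdiff(c(edges$regulator, edges$target), nodes)
    if (length(bad)) stop("edge references unknown gene(s): ",
                          paste(unique(bad), collapse = ", "))
    if (any(edges$regulator == edges$target)) stop("self-loops are not allowed")
    if (!all(tf[edges$regulator])) {
      stop("edge regulator(s) not flagged as TF: ",
           paste(unique(edges$regulator[!tf[edges$regulator]]), collapse = ", "))
    }
    ok_sign <- is.na(edges$sign) | edges$sign %in% c("activate", "repress")
    if (!all(ok_sign)) stop("edge sign must be 'activate', 'repress' or NA")
    if (anyDuplicated(edges[c("regulator", "target")])) {
      stop("duplicated regulator/target pair(s)")
    }
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, tf = tf, edges = edges),
            class = "grn_network")
}

empty_edges <- function() {
  data.frame(regulator = character(), target = character(),
             sign = character(), weight = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("grn_network: %d genes (%d TFs), %d edges\n",
              length(x$nodes), sum(x$tf), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character())
  paste(net$edges$regulator, net$edges$target, sep = "\r")
}

#' Number of regulators (TFs) in a network
#' @param net A `grn_network`.
#' @return Character vector of TF identifiers.
#' @export
network_tfs <- function(net) net$nodes[net$tf]

## Weak-connectivity check by breadth-first search on the undirected skeleton.
is_weakly_connected <- function(net) {
  n <- length(net$nodes)
  if (n <= 1) return(TRUE)
  idx <- seq_len(n)
  names(idx) <- net$nodes
  adj <- vector("list", n)
  for (k in seq_len(nrow(net$edges))) {
    i <- idx[[net$edges$regulator[k]]]
    j <- idx[[net$edges$target[k]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Generate a random TF-rooted source network
#'
#' Builds a weakly connected directed network in which every edge originates
#' at a transcription factor, as a parametric stand-in for curated source
#' networks used by benchmark-data simulators. Two topology models are
#' available: `"scale_free"` grows hubs by preferential attachment on TF
#' out-degree, `"erdos_renyi"` places edges uniformly at random.
#'
#' @param n_nodes Number of genes (>= 5).
#' @param topology `"scale_free"` or `"erdos_renyi"`.
#' @param tf_fraction Fraction of genes flagged as TFs (strictly in (0,1));
#'   the TF count is `ceiling(tf_fraction * n_nodes)`.
#' @param mean_degree Target average total degree (in + out), >= 1. The edge
#'   count is `max(n_nodes - 1, round(mean_degree * n_nodes / 2))`; the floor
#'   guarantees weak connectivity through an initial spanning tree.
#' @param p_activate Probability that an edge is activating (default 0.7).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `grn_network`.
#' @export
generate_source_network <- function(n_nodes, topology = c("scale_free", "erdos_renyi"),
                                    tf_fraction = 0.2, mean_degree = 2,
                                    p_activate = 0.7, seed = 1) {
  topology <- match.arg(topology)
  if (n_nodes < 5) stop("n_nodes must be >= 5")
  if (tf_fraction <= 0 || tf_fraction >= 1) stop("tf_fraction must be in (0,1)")
  if (mean_degree < 1) stop("mean_degree must be >= 1")
  n_tf <- as.integer(ceiling(tf_fraction * n_nodes))
  n_edges <- max(n_nodes - 1L, as.integer(round(mean_degree * n_nodes / 2)))
  max_edges <- n_tf * (n_nodes - 1L)
  if (n_edges > max_edges) {
    stop(sprintf("infeasible parameters: %d edges requested but only %d TF->target pairs exist",
                 n_edges, max_edges))
  }
  set.seed(seed)
  nodes <- sprintf("G%03d", seq_len(n_nodes))
  tf <- c(rep(TRUE, n_tf), rep(FALSE, n_nodes - n_tf))
  names(tf) <- nodes
  tfs <- nodes[tf]

  ## spanning tree: attach each non-root node to a TF already placed
  order_nodes <- c(sample(tfs, 1L), sample(setdiff(nodes, character(0)), n_nodes))
  order_nodes <- unique(order_nodes)[seq_len(n_nodes)]
  reg <- character(n_nodes - 1L)
  tgt <- character(n_nodes - 1L)
  placed_tfs <- order_nodes[1L]
  out_deg <- setNames(numeric(n_tf), tfs)
  for (i in 2:n_nodes) {
    v <- order_nodes[i]
    if (topology == "scale_free") {
      w <- out_deg[placed_tfs] + 1
      r <- sample(placed_tfs, 1L, prob = w)
    } else {
      r <- sample(placed_tfs, 1L)
    }
    reg[i - 1L] <- r
    tgt[i - 1L] <- v
    out_deg[r] <- out_deg[r] + 1
    if (tf[v]) placed_tfs <- unique(c(placed_tfs, v))
  }
  ## extra edges up to the target count
  key <- paste(reg, tgt, sep = "\r")
  n_extra <- n_edges - length(reg)
  while (n_extra > 0) {
    if (topology == "scale_free") {
      w <- out_deg + 1
      r <- sample(tfs, 1L, prob = w)
    } else {
      r <- if (length(tfs) == 1L) tfs else sample(tfs, 1L)
    }
    v <- sample(setdiff(nodes, r), 1L)
    k <- paste(r, v, sep = "\r")
    if (k %in% key) next
    key <- c(key, k)
    reg <- c(reg, r); tgt <- c(tgt, v)
    out_deg[r] <- out_deg[r] + 1
    n_extra <- n_extra - 1L
  }

  edges <- data.frame(
    regulator = reg, target = tgt,
    sign = ifelse(stats::runif(length(reg)) < p_activate, "activate", "repress"),
    weight = 1, stringsAsFactors = FALSE)
  net <- grn_network(nodes, tf, edges)
  stopifnot(is_weakly_connected(net))
  net
}

#' Sample an induced sub-network by seeded neighbour growth
#'
#' Grows a node set from a random start node by repeatedly adding a uniformly
#' chosen neighbour (in either edge direction) of the current set, then takes
#' the induced subgraph, emulating how benchmark generators extract
#' sub-networks from large curated source networks. Denser sources therefore
#' yield sub-networks with more edges at equal node count.
#'
#' @param source A `grn_network`.
#' @param size Number of nodes to sample, `2 <= size <= |source|`.
#' @param seed Integer seed.
#' @return A `grn_network` on the sampled nodes.
#' @export
sample_subnetwork <- function(source, size, seed = 1) {
  n <- length(source$nodes)
  if (size < 2 || size > n) stop("size must be in [2, number of source nodes]")
  set.seed(seed)
  if (size == n) return(source)
  und_nbrs <- split(c(source$edges$target, source$edges$regulator),
                    c(source$edges$regulator, source$edges$target))
  chosen <- sample(source$nodes, 1L)
  while (length(chosen) < size) {
    frontier <- setdiff(unique(unlist(und_nbrs[chosen], use.names = FALSE)), chosen)
    if (!length(frontier)) {
      ## disconnected remainder: restart growth from a fresh unvisited node
      rest <- setdiff(source$nodes, chosen)
      grn_log("subnetwork growth stalled; restarting from a new seed node")
      frontier <- if (length(rest) == 1L) rest else sample(rest, 1L)
    }
    add <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    chosen <- c(chosen, add)
  }
  keep <- source$edges$regulator %in% chosen & source$edges$target %in% chosen
  grn_network(chosen, source$tf[chosen], source$edges[keep, , drop = FALSE])
}
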