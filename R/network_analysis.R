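#' Differential edges between two condition networks
#'
#' Set comparison of the positive-weight edge sets of two networks over the
#' same gene universe: edges specific to A, specific to B, and shared, plus
#' the per-edge weight pairs used for weight-versus-weight comparison plots.
#'
#' @param net_a,net_b `grn_network`s over the same genes (e.g. thresholded
#'   inferences for two conditions).
#' @return A `grn_condition_pair`: list with `specific_a`, `specific_b`,
#'   `shared` (edge data frames), `counts`, and `weights` (one row per union
#'   edge with the weight in each condition, 0 when absent).
#' @export
differential_edges <- function(net_a, net_b) {
  if (!setequal(net_a$nodes, net_b$nodes)) {
    stop("networks must share the same gene universe")
  }
  ea <- net_a$edges[net_a$edges$weight > 0, , drop = FALSE]
  eb <- net_b$edges[net_b$edges$weight > 0, , drop = FALSE]
  ka <- paste(ea$regulator, ea$target, sep = "\r")
  kb <- paste(eb$regulator, eb$target, sep = "\r")
  specific_a <- ea[!ka %in% kb, , drop = FALSE]
  specific_b <- eb[!kb %in% ka, , drop = FALSE]
  shared <- ea[ka %in% kb, , drop = FALSE]
  union_keys <- union(ka, kb)
  wa <- setNames(rep(0, length(union_keys)), union_keys)
  wb <- wa
  wa[ka] <- ea$weight
  wb[kb] <- eb$weight
  parts <- strsplit(union_keys, "\r", fixed = TRUE)
  weights <- data.frame(regulator = vapply(parts, `[[`, character(1), 1),
                        target = vapply(parts, `[[`, character(1), 2),
                        weight_a = unname(wa), weight_b = unname(wb),
                        stringsAsFactors = FALSE)
  structure(list(specific_a = specific_a, specific_b = specific_b,
                 shared = shared,
                 counts = c(a_total = nrow(ea), b_total = nrow(eb),
                            specific_a = nrow(specific_a),
                            specific_b = nrow(specific_b),
                            shared = nrow(shared)),
                 weights = weights),
            class = "grn_condition_pair")
}

#' @export
print.grn_condition_pair <- function(x, ...) {
  cat(sprintf("grn_condition_pair: %d edges A, %d edges B; %d specific to A, %d to B, %d shared\n",
              x$counts["a_total"], x$counts["b_total"], x$counts["specific_a"],
              x$counts["specific_b"], x$counts["shared"]))
  invisible(x)
}

## per-target regulator sets over positive-weight edges
regulator_sets <- function(net) {
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  split(e$regulator, e$target)
}

#' Detect regulator switches between two condition networks
#'
#' For every target, compares its regulator set in the two networks.
#' Targets regulated by a single TF in each condition whose regulator
#' changes from TF_x (condition A) to TF_y (condition B) are grouped by the
#' ordered pair (TF_x, TF_y); groups reaching `min_group` targets are
#' reported, largest first. Targets with multi-regulator changes are listed
#' separately in the `multi` component rather than forced into pairs.
#'
#' @param net_a,net_b `grn_network`s over the same gene universe.
#' @param min_group Minimum targets per reported switch group, default 2.
#' @return List with `groups` (data frame `old_tf`, `new_tf`, `n_targets`,
#'   `targets` comma-separated), `assignments` (one row per switched
#'   target), and `multi` (targets whose regulator sets changed but are not
#'   single-to-single).
#' @export
regulator_switches <- function(net_a, net_b, min_group = 2) {
  if (!setequal(net_a$nodes, net_b$nodes)) {
    stop("networks must share the same gene universe")
  }
  ra <- regulator_sets(net_a)
  rb <- regulator_sets(net_b)
  targets <- union(names(ra), names(rb))
  assign_rows <- list()
  multi <- character()
  for (tg in targets) {
    sa <- sort(unique(ra[[tg]]))
    sb <- sort(unique(rb[[tg]]))
    if (identical(sa, sb)) next
    if (length(sa) == 1L && length(sb) == 1L) {
      assign_rows[[tg]] <- data.frame(target = tg, old_tf = sa, new_tf = sb,
                                      stringsAsFactors = FALSE)
    } else {
      multi <- c(multi, tg)
    }
  }
  assignments <- if (length(assign_rows)) do.call(rbind, assign_rows) else {
    data.frame(target = character(), old_tf = character(),
               new_tf = character(), stringsAsFactors = FALSE)
  }
  rownames(assignments) <- NULL
  if (nrow(assignments)) {
    key <- paste(assignments$old_tf, assignments$new_tf, sep = "\r")
    grp <- split(assignments$target, key)
    grp <- grp[lengths(grp) >= min_group]
    if (length(grp)) {
      parts <- strsplit(names(grp), "\r", fixed = TRUE)
      groups <- data.frame(old_tf = vapply(parts, `[[`, character(1), 1),
                           new_tf = vapply(parts, `[[`, character(1), 2),
                           n_targets = lengths(grp),
                           targets = vapply(grp, paste, character(1), collapse = ","),
                           stringsAsFactors = FALSE)
      groups <- groups[order(-groups$n_targets, groups$old_tf, groups$new_tf), ,
                       drop = FALSE]
      rownames(groups) <- NULL
    } else groups <- empty_switch_groups()
  } else groups <- empty_switch_groups()
  list(groups = groups, assignments = assignments, multi = multi)
}

empty_switch_groups <- function() {
  data.frame(old_tf = character(), new_tf = character(),
             n_targets = integer(), targets = character(),
             stringsAsFactors = FALSE)
}

#' Assign each target its best-scoring regulator
#'
#' Reduces a score matrix to a single-regulator network: every non-TF gene
#' gets one incoming edge from the TF with the highest score for it
#' (positive scores only). This is the per-target reduction used to compare
#' condition-specific networks for regulator switching, where the question
#' is "who regulates this gene in each condition".
#'
#' @param scores A `grn_scores` (directed or symmetric).
#' @param universe Character vector of all genes of the network to build.
#' @param tfs Character vector of candidate regulators (must be score rows).
#' @return A `grn_network` over `universe` in which every edge is the argmax
#'   TF for its target; ties break by TF order.
#' @export
best_regulator_network <- function(scores, universe, tfs) {
  s <- scores$scores
  if (!all(tfs %in% rownames(s))) stop("all tfs must be score-matrix rows")
  s <- s[tfs, , drop = FALSE]
  targets <- setdiff(intersect(colnames(s), universe), tfs)
  rows <- lapply(targets, function(tg) {
    v <- s[, tg]
    best <- which.max(v)
    if (v[best] <= 0) return(NULL)
    data.frame(regulator = tfs[best], target = tg, sign = NA_character_,
               weight = v[best], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges)) edges <- empty_edges()
  grn_network(universe, setNames(universe %in% tfs, universe), edges)
}

#' Out-degree table of a network's regulators
#'
#' @param net A `grn_network`.
#' @return Data frame (`tf`, `out_degree`) over positive-weight edges,
#'   sorted by descending degree; TFs without outgoing edges get degree 0.
#' @export
hub_degrees <- function(net) {
  tfs <- network_tfs(net)
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  deg <- table(factor(e$regulator, levels = tfs))
  out <- data.frame(tf = names(deg), out_degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$out_degree, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge overlap between two inferred networks
#'
#' Fraction (as a percentage) of the reference network's edges that are also
#' present in the second network: `|E_A intersect E_B| / |E_A| * 100`. With
#' `top_k` set, the reference edge set is first restricted to its k
#' highest-weight edges — the "overlap of the most confident predictions"
#' variant. A Jaccard mode (`|A intersect B| / |A union B|`) is available
#' behind a flag.
#'
#' @param net_a Reference `grn_network` (the denominator).
#' @param net_b Comparison `grn_network`.
#' @param top_k Optional integer: restrict `net_a` to its k highest-weight
#'   edges first.
#' @param directed Logical: match edges as ordered pairs (default) or as
#'   unordered pairs.
#' @param jaccard Logical: report the Jaccard index (x100) instead of the
#'   reference-based overlap.
#' @return Overlap percentage in \[0, 100\].
#' @export
edge_overlap <- function(net_a, net_b, top_k = NULL, directed = TRUE,
                         jaccard = FALSE) {
  if (!setequal(net_a$nodes, net_b$nodes)) {
    stop("networks must share the same gene universe")
  }
  ea <- net_a$edges[net_a$edges$weight > 0, , drop = FALSE]
  eb <- net_b$edges[net_b$edges$weight > 0, , drop = FALSE]
  if (!is.null(top_k)) {
    ea <- ea[order(-ea$weight), , drop = FALSE]
    ea <- ea[seq_len(min(top_k, nrow(ea))), , drop = FALSE]
  }
  if (!nrow(ea)) stop("reference network has no edges")
  mk <- function(e) {
    if (directed) paste(e$regulator, e$target, sep = "\r")
    else paste(pmin(e$regulator, e$target), pmax(e$regulator, e$target), sep = "\r")
  }
  ka <- unique(mk(ea)); kb <- unique(mk(eb))
  if (jaccard) {
    100 * length(intersect(ka, kb)) / length(union(ka, kb))
  } else {
    100 * sum(ka %in% kb) / length(ka)
  }
}
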