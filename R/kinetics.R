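#' Attach Hill-kinetic parameters to a network
#'
#' Turns a `grn_network` into a generative steady-state model. Each gene gets
#' a basal transcription level and each edge a Hill coefficient and
#' half-saturation constant; activating edges contribute
#' `A(x) = x^n / (K^n + x^n)` and repressing edges
#' `R(x) = K^n / (K^n + x^n)` to the target's regulation function.
#'
#' @param network A `grn_network`.
#' @param ranges Named list of sampling ranges, each a length-2 numeric
#'   `c(lo, hi)`: `basal` in (0,1], `hill_n` in [1,10], `hill_K` in (0,1).
#'   Point ranges (`lo == hi`) give deterministic parameters.
#' @param leak Basal leak fraction of regulation in [0,1): a fully repressed
#'   input still transmits `leak` of its multiplier.
#' @param noise_sigma Standard deviation (log scale) of multiplicative
#'   lognormal measurement noise applied by [simulate_experiment()].
#' @param seed Integer seed; sampling is deterministic given it.
#' @return An object of class `grn_kinetic_model`.
#' @export
assign_kinetics <- function(network,
                            ranges = list(basal = c(0.3, 1),
                                          hill_n = c(1, 4),
                                          hill_K = c(0.2, 0.8)),
                            leak = 0.1, noise_sigma = 0.05, seed = 1) {
  if (!inherits(network, "grn_network")) stop("network must be a grn_network")
  if (!length(network$nodes)) stop("empty network")
  chk <- function(nm, lo, hi, lo_open = FALSE) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2]) stop("bad range for ", nm)
    if (r[1] < lo || r[2] > hi || (lo_open && r[1] <= lo)) {
      stop(nm, " range must lie within ", if (lo_open) "(" else "[", lo, ",", hi, "]")
    }
  }
  chk("basal", 0, 1, lo_open = TRUE)
  chk("hill_n", 1, 10)
  chk("hill_K", 0, 1, lo_open = TRUE)
  if (ranges$hill_K[2] >= 1) stop("hill_K range must lie within (0,1)")
  if (leak < 0 || leak >= 1) stop("leak must be in [0,1)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  set.seed(seed)
  n_g <- length(network$nodes)
  n_e <- nrow(network$edges)
  runifr <- function(k, r) if (r[1] == r[2]) rep(r[1], k) else stats::runif(k, r[1], r[2])
  structure(list(
    network = network,
    basal = setNames(runifr(n_g, ranges$basal), network$nodes),
    hill_n = runifr(n_e, ranges$hill_n),
    hill_K = runifr(n_e, ranges$hill_K),
    leak = leak,
    noise_sigma = noise_sigma
  ), class = "grn_kinetic_model")
}

#' @export
print.grn_kinetic_model <- function(x, ...) {
  cat(sprintf("grn_kinetic_model: %d genes, %d edges, leak %.2f, noise_sigma %.3f\n",
              length(x$network$nodes), nrow(x$network$edges), x$leak, x$noise_sigma))
  invisible(x)
}

#' Hill activation and repression response
#'
#' `hill_activation(x, n, K)` is `x^n / (K^n + x^n)`; `hill_repression` is its
#' complement `K^n / (K^n + x^n)`. Both equal 0.5 at `x = K`.
#' @param x Regulator level(s) in [0,1].
#' @param n Hill coefficient.
#' @param K Half-saturation constant.
#' @return Numeric response in [0,1].
#' @export
hill_activation <- function(x, n, K) x^n / (K^n + x^n)

#' @rdname hill_activation
#' @export
hill_repression <- function(x, n, K) K^n / (K^n + x^n)

## One application of the regulation map; x and multipliers named by gene.
regulation_map <- function(model, x, multipliers) {
  net <- model$network
  out <- model$basal * multipliers
  if (nrow(net$edges)) {
    xs <- x[net$edges$regulator]
    resp <- ifelse(net$edges$sign == "repress",
                   hill_repression(xs, model$hill_n, model$hill_K),
                   hill_activation(xs, model$hill_n, model$hill_K))
    fac <- model$leak + (1 - model$leak) * resp
    prod_fac <- vapply(split(fac, net$edges$target), prod, numeric(1))
    out[names(prod_fac)] <- out[names(prod_fac)] * prod_fac
  }
  pmin(out, 1)
}

#' Solve the model's steady state
#'
#' Finds a fixed point of the regulation map by damped synchronous iteration:
#' `x <- damping * f(x) + (1 - damping) * x`. Genes without regulators settle
#' at `multiplier * basal`; clamped genes are held fixed throughout (the
#' mechanism behind knockdown samples).
#'
#' @param model A `grn_kinetic_model`.
#' @param clamped Named numeric vector of genes to hold fixed, levels in [0,1].
#' @param basal_multipliers Named numeric vector of positive per-gene basal
#'   multipliers (multifactorial perturbations); genes not named get 1.
#' @param damping Damping factor in (0,1], default 0.5.
#' @param tol Convergence tolerance on the max absolute update, default 1e-8.
#' @param max_iter Iteration cap, default 5000; non-convergence is an error
#'   naming the genes that are still moving.
#' @return Named numeric vector of steady-state expression levels in [0,1].
#' @export
steady_state <- function(model, clamped = numeric(), basal_multipliers = numeric(),
                         damping = 0.5, tol = 1e-8, max_iter = 5000) {
  nodes <- model$network$nodes
  if (length(clamped)) {
    if (is.null(names(clamped)) || !all(names(clamped) %in% nodes)) {
      stop("clamped must be named by genes of the model")
    }
    if (any(clamped < 0 | clamped > 1)) stop("clamped levels must be in [0,1]")
  }
  mult <- setNames(rep(1, length(nodes)), nodes)
  if (length(basal_multipliers)) {
    if (any(basal_multipliers <= 0)) stop("basal multipliers must be > 0")
    mult[names(basal_multipliers)] <- basal_multipliers
  }
  x <- pmin(model$basal * mult, 1)
  x[names(clamped)] <- clamped
  for (it in seq_len(max_iter)) {
    fx <- regulation_map(model, x, mult)
    fx[names(clamped)] <- clamped
    delta <- abs(fx - x)
    x <- damping * fx + (1 - damping) * x
    x[names(clamped)] <- clamped
    if (max(delta) < tol) return(x)
  }
  moving <- names(sort(delta, decreasing = TRUE))
  moving <- moving[seq_len(min(5, length(moving)))]
  stop("steady_state did not converge within ", max_iter,
       " iterations; genes still moving: ", paste(moving, collapse = ", "))
}

#' Construct an expression dataset container
#'
#' @param values Numeric genes x samples matrix in [0,1] with dimnames.
#' @param design One of `"wildtype"`, `"knockdown"`, `"multifactorial"`.
#' @param condition Per-sample condition labels (recycled if length 1).
#' @param perturbation_log Per-sample list recording what was perturbed.
#' @return An object of class `grn_expression`.
#' @export
grn_expression <- function(values, design = "wildtype", condition = design,
                           perturbation_log = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyNA(values)) stop("expression matrix contains missing values")
  design <- match.arg(design, c("wildtype", "knockdown", "multifactorial"))
  condition <- rep_len(as.character(condition), ncol(values))
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 design = design,
                 condition = condition,
                 perturbation_log = perturbation_log),
            class = "grn_expression")
}

#' @export
print.grn_expression <- function(x, ...) {
  cat(sprintf("grn_expression: %d genes x %d samples (%s design)\n",
              nrow(x$values), ncol(x$values), x$design))
  invisible(x)
}

#' Simulate a steady-state expression experiment
#'
#' Three designs mirror standard benchmark layouts. `"knockdown"` produces
#' one wild-type sample plus one sample per gene with that gene clamped to
#' `kd_level` (so a g-gene model always yields g + 1 samples).
#' `"multifactorial"` draws, for every sample, per-gene basal multipliers
#' `exp(N(0, tau^2))`, resembling a cohort where each sample is a genome-wide
#' profile from a different individual. `"wildtype"` repeats the unperturbed
#' steady state. After solving, multiplicative lognormal measurement noise
#' with the model's `noise_sigma` is applied and values are clipped to [0,1].
#'
#' @param model A `grn_kinetic_model`.
#' @param design `"wildtype"`, `"knockdown"` or `"multifactorial"`.
#' @param n_samples Sample count for wildtype/multifactorial designs
#'   (ignored for knockdown).
#' @param tau Standard deviation (log scale) of the multifactorial basal
#'   multipliers, >= 0; default 0.5.
#' @param kd_level Clamp level for knocked-down genes, default 0.01 (kept
#'   slightly above zero so multiplicative noise stays well defined).
#' @param seed Integer seed.
#' @return A `grn_expression`; `perturbation_log` records, per sample, the
#'   clamped gene or the basal multipliers used.
#' @export
simulate_experiment <- function(model, design = c("multifactorial", "knockdown", "wildtype"),
                                n_samples = 100, tau = 0.5, kd_level = 0.01, seed = 1) {
  design <- match.arg(design)
  if (tau < 0) stop("tau must be >= 0")
  if (design != "knockdown" && n_samples < 1) stop("n_samples must be >= 1")
  set.seed(seed)
  nodes <- model$network$nodes
  n_g <- length(nodes)
  solve_sample <- function(clamped = numeric(), mult = numeric()) {
    tryCatch(steady_state(model, clamped, mult),
             error = function(e) {
               grn_log("retrying non-convergent sample with lighter damping")
               steady_state(model, clamped, mult, damping = 0.2, max_iter = 20000)
             })
  }
  if (design == "knockdown") {
    cols <- c("WT", paste0("KD_", nodes))
    mat <- matrix(NA_real_, n_g, n_g + 1L, dimnames = list(nodes, cols))
    mat[, 1L] <- solve_sample()
    for (i in seq_len(n_g)) {
      mat[, i + 1L] <- solve_sample(clamped = setNames(kd_level, nodes[i]))
    }
    log <- c(list(list(type = "wildtype")),
             lapply(nodes, function(g) list(type = "knockdown", gene = g, level = kd_level)))
  } else if (design == "multifactorial") {
    cols <- paste0("S", seq_len(n_samples))
    mat <- matrix(NA_real_, n_g, n_samples, dimnames = list(nodes, cols))
    log <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      m <- setNames(exp(stats::rnorm(n_g, 0, tau)), nodes)
      mat[, s] <- solve_sample(mult = m)
      log[[s]] <- list(type = "multifactorial", multipliers = m)
    }
  } else {
    cols <- paste0("S", seq_len(n_samples))
    wt <- solve_sample()
    mat <- matrix(rep(wt, n_samples), n_g, n_samples, dimnames = list(nodes, cols))
    log <- rep(list(list(type = "wildtype")), n_samples)
  }
  if (model$noise_sigma > 0) {
    mat <- mat * exp(matrix(stats::rnorm(length(mat), 0, model$noise_sigma),
                            nrow(mat), ncol(mat)))
  }
  mat <- pmin(pmax(mat, 0), 1)
  grn_expression(mat, design = design, perturbation_log = log)
}

#' Plant regulator switches between two conditions
#'
#' Creates a pair of kinetic models identical except for `n_switches`
#' disjoint groups of `switch_size` targets whose regulating TF is reassigned
#' from one TF (condition A) to another (condition B) — a plantable ground
#' truth for condition-network comparison. Targets whose only regulator is
#' the outgoing TF are preferred so the switch is recoverable from per-target
#' regulator sets; the reassigned edges keep their sign and Hill parameters.
#'
#' @param model A `grn_kinetic_model` whose network has at least two TFs.
#' @param n_switches Number of switch groups to plant.
#' @param switch_size Number of targets per group.
#' @param seed Integer seed.
#' @return A list with elements `model_a` (the input), `model_b` (rewired
#'   copy) and `manifest`, a data frame of planted (target, old_tf, new_tf)
#'   rows grouped by switch.
#' @export
make_condition_pair <- function(model, n_switches = 1, switch_size = 5, seed = 1) {
  net <- model$network
  tfs <- network_tfs(net)
  if (length(tfs) < 2) stop("need at least two TFs to plant a switch")
  if (n_switches == 0) {
    return(list(model_a = model, model_b = model,
                manifest = data.frame(switch = integer(), target = character(),
                                      old_tf = character(), new_tf = character(),
                                      stringsAsFactors = FALSE)))
  }
  set.seed(seed)
  reg_sets <- split(net$edges$regulator, net$edges$target)
  single_reg <- names(reg_sets)[lengths(reg_sets) == 1L]
  manifest <- NULL
  used_targets <- character()
  edges_b <- net$edges
  for (s in seq_len(n_switches)) {
    ## prefer TFs with enough single-regulator, TF-free targets left
    cand <- lapply(tfs, function(tf) {
      tg <- edges_b$target[edges_b$regulator == tf]
      setdiff(intersect(tg, single_reg), c(used_targets, tfs))
    })
    names(cand) <- tfs
    ok <- tfs[lengths(cand) >= switch_size]
    if (!length(ok)) {
      stop(sprintf("infeasible switch request: no TF has %d unused single-regulator targets",
                   switch_size))
    }
    old_tf <- if (length(ok) == 1L) ok else sample(ok, 1L)
    targets <- sample(cand[[old_tf]], switch_size)
    others <- setdiff(tfs, old_tf)
    new_tf <- if (length(others) == 1L) others else sample(others, 1L)
    idx <- which(edges_b$regulator == old_tf & edges_b$target %in% targets)
    edges_b$regulator[idx] <- new_tf
    used_targets <- c(used_targets, targets)
    manifest <- rbind(manifest, data.frame(switch = s, target = targets,
                                           old_tf = old_tf, new_tf = new_tf,
                                           stringsAsFactors = FALSE))
  }
  ## a reassignment may collide with an existing new_tf -> target edge
  if (anyDuplicated(edges_b[c("regulator", "target")])) {
    stop("infeasible switch request: reassignment collides with an existing edge")
  }
  model_b <- model
  model_b$network <- grn_network(net$nodes, net$tf, edges_b)
  list(model_a = model, model_b = model_b, manifest = manifest)
}
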