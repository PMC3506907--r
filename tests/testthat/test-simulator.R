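test_that("source-network generation honours TF count, determinism and feasibility", {
  net <- generate_source_network(10, "scale_free", tf_fraction = 0.3, seed = 1)
  expect_equal(sum(net$tf), 3)  # ceiling(0.3 * 10)
  expect_true(all(net$edges$regulator %in% network_tfs(net)))
  expect_false(any(net$edges$regulator == net$edges$target))

  a <- generate_source_network(40, "erdos_renyi", mean_degree = 3, seed = 7)
  b <- generate_source_network(40, "erdos_renyi", mean_degree = 3, seed = 7)
  expect_identical(a$edges, b$edges)

  expect_error(generate_source_network(4), "n_nodes")
  expect_error(generate_source_network(10, tf_fraction = 1), "tf_fraction")
  # 1 TF cannot emit 100 edges among 10 nodes
  expect_error(generate_source_network(10, tf_fraction = 0.05, mean_degree = 20),
               "infeasible")
})

test_that("scale-free topology produces heavier out-degree tails than Erdos-Renyi", {
  max_out <- function(topology, seed) {
    net <- generate_source_network(300, topology, tf_fraction = 0.2,
                                   mean_degree = 3, seed = seed)
    max(table(net$edges$regulator))
  }
  sf <- sapply(1:20, function(s) max_out("scale_free", s))
  er <- sapply(1:20, function(s) max_out("erdos_renyi", s))
  expect_gt(median(sf), median(er))
})

test_that("subnetwork sampling is deterministic, size-exact and density-sensitive", {
  src <- generate_source_network(100, "scale_free", mean_degree = 4, seed = 2)
  expect_identical(sample_subnetwork(src, 100, seed = 1), src)  # identity case
  s1 <- sample_subnetwork(src, 30, seed = 5)
  s2 <- sample_subnetwork(src, 30, seed = 5)
  expect_identical(s1$edges, s2$edges)
  expect_length(s1$nodes, 30)
  expect_error(sample_subnetwork(src, 101), "size")

  dense <- generate_source_network(150, "scale_free", mean_degree = 6, seed = 11)
  sparse <- generate_source_network(150, "scale_free", mean_degree = 2, seed = 11)
  n_edges <- function(src) {
    mean(sapply(1:20, function(s) nrow(sample_subnetwork(src, 50, seed = s)$edges)))
  }
  expect_gt(n_edges(dense), n_edges(sparse))
})

test_that("kinetic parameter assignment samples within ranges and respects point ranges", {
  net <- generate_source_network(300, "scale_free", mean_degree = 8, seed = 3)
  ranges <- list(basal = c(0.4, 0.9), hill_n = c(2, 6), hill_K = c(0.1, 0.5))
  mod <- assign_kinetics(net, ranges, seed = 4)
  expect_true(all(mod$basal >= 0.4 & mod$basal <= 0.9))
  expect_true(all(mod$hill_n >= 2 & mod$hill_n <= 6))
  expect_true(all(mod$hill_K >= 0.1 & mod$hill_K <= 0.5))
  expect_identical(mod, assign_kinetics(net, ranges, seed = 4))

  pt <- assign_kinetics(net, list(basal = c(0.5, 0.5), hill_n = c(2, 2),
                                  hill_K = c(0.3, 0.3)), seed = 1)
  expect_true(all(pt$basal == 0.5) && all(pt$hill_n == 2) && all(pt$hill_K == 0.3))
  expect_error(assign_kinetics(grn_network(character(0), logical(0))), "empty")
})

test_that("Hill responses hit the half-saturation point exactly", {
  for (n in c(1, 2.5, 7)) {
    expect_identical(hill_activation(0.37, n, 0.37), 0.5)
    expect_identical(hill_repression(0.37, n, 0.37), 0.5)
  }
  expect_lt(hill_activation(0.1, 2, 0.5), 0.5)
  expect_gt(hill_activation(0.9, 2, 0.5), 0.5)
})

test_that("steady state matches closed-form evaluation on a two-gene chain", {
  nodes <- c("A", "B")
  net <- grn_network(nodes, c(TRUE, FALSE),
                     data.frame(regulator = "A", target = "B",
                                sign = "activate", weight = 1))
  mod <- assign_kinetics(net, list(basal = c(0.6, 0.6), hill_n = c(3, 3),
                                   hill_K = c(0.4, 0.4)), leak = 0.1,
                         noise_sigma = 0, seed = 1)
  ss <- steady_state(mod)
  # A has no regulators: level = basal; substitute into the Hill formula by hand
  expect_equal(unname(ss["A"]), 0.6, tolerance = 1e-10)
  act <- 0.6^3 / (0.4^3 + 0.6^3)
  expect_equal(unname(ss["B"]), min(1, 0.6 * (0.1 + 0.9 * act)), tolerance = 1e-8)
})

test_that("converged steady states are genuine fixed points and respect clamps", {
  net <- generate_source_network(40, "scale_free", mean_degree = 3, seed = 9)
  mod <- assign_kinetics(net, seed = 10)
  ss <- steady_state(mod)
  again <- steady_state(mod)  # deterministic
  expect_identical(ss, again)
  expect_true(all(ss >= 0 & ss <= 1))
  # reapplying the regulation map moves the solution by < 1e-6
  fx <- grnibench:::regulation_map(mod, ss, setNames(rep(1, 40), net$nodes))
  expect_lt(max(abs(fx - ss)), 1e-6)

  cl <- steady_state(mod, clamped = setNames(0.3, net$nodes[5]))
  expect_identical(unname(cl[net$nodes[5]]), 0.3)
})

test_that("raising an activator's clamped level never decreases its target", {
  net <- generate_source_network(25, "scale_free", mean_degree = 2.5, seed = 21)
  mod <- assign_kinetics(net, seed = 22)
  act_edges <- mod$network$edges[mod$network$edges$sign == "activate", ]
  skip_if(nrow(act_edges) == 0)
  e <- act_edges[1, ]
  lv <- sapply(c(0.1, 0.4, 0.8), function(l) {
    steady_state(mod, clamped = setNames(l, e$regulator))[e$target]
  })
  expect_true(all(diff(lv) >= -1e-9))
})

test_that("knockdown design yields gene-count + 1 samples with the clamp visible", {
  net <- generate_source_network(30, "scale_free", mean_degree = 2, seed = 31)
  mod <- assign_kinetics(net, noise_sigma = 0, seed = 32)
  kd <- simulate_experiment(mod, "knockdown", seed = 33)
  expect_equal(ncol(kd$values), 31)
  expect_equal(kd$design, "knockdown")
  for (i in c(1, 15, 30)) {
    expect_equal(unname(kd$values[net$nodes[i], i + 1]), 0.01)
  }
})

test_that("multifactorial design has requested sample counts and collapses at tau 0", {
  net <- generate_source_network(15, "erdos_renyi", mean_degree = 2, seed = 41)
  mod <- assign_kinetics(net, noise_sigma = 0, seed = 42)
  for (ns in c(10, 50, 100, 200)) {
    d <- simulate_experiment(mod, "multifactorial", n_samples = ns, tau = 0.5,
                             seed = 43)
    expect_equal(ncol(d$values), ns)
  }
  flat <- simulate_experiment(mod, "multifactorial", n_samples = 5, tau = 0, seed = 44)
  wt <- steady_state(mod)
  for (j in 1:5) expect_equal(unname(flat$values[, j]), unname(wt), tolerance = 1e-12)
})

test_that("datasets are bitwise reproducible given the seed", {
  net <- generate_source_network(20, "scale_free", mean_degree = 2, seed = 51)
  mod <- assign_kinetics(net, seed = 52)
  d1 <- simulate_experiment(mod, "multifactorial", n_samples = 12, seed = 53)
  d2 <- simulate_experiment(mod, "multifactorial", n_samples = 12, seed = 53)
  expect_identical(d1$values, d2$values)
})

test_that("condition pairs plant exactly the requested switch structure", {
  net <- generate_source_network(40, "scale_free", tf_fraction = 0.12,
                                 mean_degree = 2, seed = 61)
  mod <- assign_kinetics(net, seed = 62)
  same <- make_condition_pair(mod, n_switches = 0)
  expect_identical(same$model_a, same$model_b)
  expect_equal(nrow(same$manifest), 0)

  pair <- make_condition_pair(mod, n_switches = 1, switch_size = 5, seed = 63)
  expect_equal(nrow(pair$manifest), 5)
  ka <- paste(pair$model_a$network$edges$regulator, pair$model_a$network$edges$target)
  kb <- paste(pair$model_b$network$edges$regulator, pair$model_b$network$edges$target)
  expect_equal(sum(!ka %in% kb), 5)  # exactly 5 edges each direction
  expect_equal(sum(!kb %in% ka), 5)
  expect_length(unique(pair$manifest$old_tf), 1)
  expect_error(make_condition_pair(mod, n_switches = 50, switch_size = 5, seed = 1),
               "infeasible")
})
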