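test_that("swarm initialization is deterministic and bootstrap-based", {
  sim <- tiny_sim(301)
  X <- sim$genotypes; y <- sim$phenotype
  s1 <- initialize_swarm(X, y, fslr_control(), seed = 7)
  s2 <- initialize_swarm(X, y, fslr_control(), seed = 7)
  expect_identical(lapply(s1$agents, function(a) format(a$tree)),
                   lapply(s2$agents, function(a) format(a$tree)))
  expect_identical(lapply(s1$agents, `[[`, "boot"),
                   lapply(s2$agents, `[[`, "boot"))
  for (a in s1$agents) {
    expect_length(a$boot, nrow(X))
    expect_true(all(a$oob %in% seq_len(nrow(X))))
    expect_length(intersect(unique(a$boot), a$oob), 0)
  }
  expect_error(initialize_swarm(X, y, fslr_control(n_fish = 2), seed = 1), NA)
  expect_error(fslr_control(n_fish = 1))
})

test_that("out-of-bag fraction is near 1/e for large M", {
  set.seed(302)
  X <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(2000, 1, 0.5))
  st <- initialize_swarm(X, y, fslr_control(n_fish = 12), seed = 3)
  fr <- mean(vapply(st$agents, function(a) length(a$oob) / 2000, 1.0))
  expect_equal(fr, exp(-1), tolerance = 0.02)
})

test_that("with a single available SNP every agent holds its literal", {
  X <- matrix(rep(0:1, 10), ncol = 1)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(20, 1, 0.5))
  st <- initialize_swarm(X, y, fslr_control(n_fish = 2, s_max = 1), seed = 4)
  for (a in st$agents) expect_equal(unique(tree_snps(a$tree)), 1L)
})

test_that("size density matches the clamped normal closed form", {
  expect_equal(size_density(3, 3, 1), 1 / sqrt(2 * pi))
  for (d in 1:4) expect_equal(size_density(5 + d, 5, 2), size_density(5 - d, 5, 2))
  expect_equal(size_density(4, 4, 0.01), 1)   # density > 1 clamps
  expect_error(size_density(3, 3, 0))
})

test_that("selection probabilities are a proper importance-monotone distribution", {
  expect_equal(selection_distribution(rep(0, 5)), rep(0.2, 5))
  p <- selection_distribution(c(10, 1, 1, 1))
  expect_equal(which.max(p), 1L)
  set.seed(303)
  for (i in 1:200) {
    v <- rnorm(sample(2:50, 1), sd = 10)
    expect_equal(sum(selection_distribution(v)), 1)
  }
})

test_that("importance is zero for absent SNPs and follows its definition", {
  sim <- tiny_sim(304)
  X <- sim$genotypes; y <- sim$phenotype
  st <- initialize_swarm(X, y, fslr_control(n_fish = 3, s_max = 2), seed = 5)
  imp <- compute_importance(st, X, y)
  held <- unique(unlist(lapply(st$agents, function(a) tree_snps(a$tree))))
  expect_true(all(imp$value[setdiff(1:12, held)] == 0))
  expect_equal(sum(imp$prob), 1)
  # single-agent arithmetic: V(j) = (N_k - N_k^{-j}) / F
  st$agents <- st$agents[1]
  ag <- st$agents[[1]]
  imp1 <- compute_importance(st, X, y)
  out <- eval_tree_rows(ag$tree, X)
  n_k <- sum(out[ag$oob] == y[ag$oob])
  for (j in unique(tree_snps(ag$tree))) {
    pruned <- swarmlr:::prune_snps(ag$tree, j)
    n_kj <- if (is.null(pruned)) {
      maj <- as.integer(mean(y[ag$boot]) >= 0.5)
      sum(maj == y[ag$oob])
    } else sum(eval_tree_rows(pruned, X)[ag$oob] == y[ag$oob])
    expect_equal(imp1$value[j], n_k - n_kj)
  }
})

test_that("agent distance is the importance-mass difference and a pseudometric", {
  imp <- tibble::tibble(snp = 1:6, value = c(5, 3, 2, 1, 0.5, 0),
                        prob = selection_distribution(c(5, 3, 2, 1, 0.5, 0)))
  expect_equal(agent_distance(lt_leaf(2), lt_leaf(2), imp), 0)
  expect_equal(agent_distance(lt_leaf(1), lt_leaf(3), imp), 3)
  set.seed(305)
  for (i in 1:100) {
    trees <- lapply(1:3, function(.) random_tree(6, size = sample(1:4, 1)))
    d12 <- agent_distance(trees[[1]], trees[[2]], imp)
    d21 <- agent_distance(trees[[2]], trees[[1]], imp)
    d13 <- agent_distance(trees[[1]], trees[[3]], imp)
    d32 <- agent_distance(trees[[3]], trees[[2]], imp)
    expect_equal(d12, d21)
    expect_lte(d12, d13 + d32 + 1e-12)
  }
})

test_that("the best agent HOLDs and others follow the behavior mixture", {
  expect_equal(choose_behavior(3, 3, c(0.2, 0.5, 0.3)), "HOLD")
  set.seed(306)
  expect_true(all(replicate(50, choose_behavior(1, 2, c(1, 0, 0))) == "RANDOM"))
  draws <- replicate(10000, choose_behavior(1, 2, c(0.2, 0.5, 0.3)))
  freq <- table(factor(draws, c("RANDOM", "FOLLOW", "KPDIST"))) / 10000
  for (k in 1:3) {
    p <- c(0.2, 0.5, 0.3)[k]
    expect_lt(abs(freq[k] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("RANDOM picks each feasible move with probability 1/4", {
  set.seed(307)
  tr <- random_tree(10, size = 3)
  deltas <- replicate(8000, tree_size(random_step(tr, 10)) - 3)
  # ADD -> +1, DEL -> -1, ALT_SNP / ALT_OPT -> 0
  p_add <- mean(deltas == 1)
  p_del <- mean(deltas == -1)
  p_alt <- mean(deltas == 0)
  se <- 3 * sqrt(0.25 * 0.75 / 8000)
  expect_lt(abs(p_add - 0.25), se)
  expect_lt(abs(p_del - 0.25), se)
  expect_lt(abs(p_alt - 0.5), 3 * sqrt(0.5 * 0.5 / 8000))
  # infeasible moves are resampled, and proposals always differ
  lone <- lt_leaf(2)
  props <- replicate(300, {
    p <- random_step(lone, 5)
    expect_false(identical(format(p), format(lone)))
    tree_size(p)
  })
  expect_true(all(props >= 1))
  expect_false(any(replicate(200, tree_size(random_step(lone, 5, s_max = 1))) > 1))
})

test_that("FOLLOW contracts toward the best size; equal sizes force ALT", {
  set.seed(308)
  probs <- rep(1 / 10, 10)
  # equal size: always ALT (size unchanged)
  tr <- random_tree(10, size = 4)
  szs <- replicate(200, tree_size(follow_step(tr, 4, 1, probs, 10)))
  expect_true(all(szs == 4))
  # larger than best: DEL with probability f(s), else ALT (size unchanged)
  szs <- replicate(2000, tree_size(follow_step(tr, 3, 1, probs, 10)))
  p_del <- mean(szs == 3)
  f_s <- size_density(4, 3, 1)
  expect_lt(abs(p_del - f_s), 3 * sqrt(f_s * (1 - f_s) / 2000))
  expect_true(all(szs %in% c(3, 4)))
  # Monte-Carlo contraction of the mean size gap under pure FOLLOW
  gap <- function(s0) {
    cur <- random_tree(10, size = s0)
    gaps <- numeric(200)
    for (i in 1:200) {
      cur <- follow_step(cur, 5, 2, probs, 10, s_max = 10)
      gaps[i] <- abs(tree_size(cur) - 5)
    }
    gaps
  }
  g <- gap(10)
  expect_lte(mean(g[151:200]), mean(g[1:50]))
})

test_that("KPDIST repels from the best size; equal sizes always change size", {
  set.seed(309)
  probs <- rep(1 / 10, 10)
  tr <- random_tree(10, size = 4)
  szs <- replicate(200, tree_size(kpdist_step(tr, 4, 1, probs, 10, s_max = 10)))
  expect_true(all(szs != 4))
  # an agent of size 1 below the best never proposes an empty tree
  lone <- lt_leaf(3)
  szs <- replicate(200, tree_size(kpdist_step(lone, 4, 1, probs, 10, s_max = 10)))
  expect_true(all(szs >= 1))
  # Monte-Carlo repulsion of the mean size gap under pure KPDIST
  cur <- random_tree(10, size = 5)
  gaps <- numeric(200)
  for (i in 1:200) {
    cur <- kpdist_step(cur, 5, 2, probs, 10, s_max = 10)
    gaps[i] <- abs(tree_size(cur) - 5)
  }
  expect_gte(mean(gaps[151:200]), mean(gaps[1:50]))
})

test_that("seeded runs are bit-identical", {
  sim <- tiny_sim(310)
  ctrl <- fslr_control(b_stable = 25)
  f1 <- fslr(sim$data, control = ctrl, seed = 11)
  f2 <- fslr(sim$data, control = ctrl, seed = 11)
  expect_equal(format(f1$best$tree), format(f2$best$tree))
  expect_equal(f1$best$score, f2$best$score)
  expect_equal(f1$importance, f2$importance)
  expect_equal(f1$iterations, f2$iterations)
  expect_identical(lapply(f1$agents, function(a) format(a$tree)),
                   lapply(f2$agents, function(a) format(a$tree)))
})

test_that("all final trees respect the size bounds and the report is coherent", {
  sim <- tiny_sim(311)
  ctrl <- fslr_control(b_stable = 25, s_max = 4)
  fit <- fslr(sim$data, control = ctrl, seed = 12)
  for (a in fit$agents) {
    expect_gte(tree_size(a$tree), 1)
    expect_lte(tree_size(a$tree_raw), 4)
  }
  expect_gte(fit$best$score, fit$n_obs / 2)   # at least the majority rule
  expect_true(all(fit$selected$best %in% fit$selected$union))
  expect_equal(sum(fit$importance$prob), 1)
  # interactions are conjunction-level pair/triple counts
  if (nrow(fit$interactions) > 0) {
    expect_true(all(fit$interactions$order %in% 2:3))
  }
})

test_that("a planted disjunction is recovered by the school", {
  sim <- tiny_sim(312)
  fit <- fslr(sim$data, seed = 13)
  expect_gte(count_identified(selected_snps(fit), sim$causal_indices), 1)
})

test_that("pure RANDOM behavior degrades to plain stochastic search but still works", {
  sim <- tiny_sim(313, n_sites = 8)
  ctrl <- fslr_control(behavior_probs = c(1, 0, 0), b_stable = 60)
  fit <- fslr(sim$data, control = ctrl, seed = 14)
  expect_gte(fit$best$score, 0.9 * fit$n_obs)
})
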