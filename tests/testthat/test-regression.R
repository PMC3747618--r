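test_that("predict applies the sigmoid link to the tree outputs", {
  A <- assignments(2)
  m0 <- logic_model(lt_leaf(1), beta0 = 0, betas = 0)
  expect_equal(predict(m0, A), rep(0.5, 4))
  m1 <- logic_model(lt_leaf(1), beta0 = 0, betas = 1)
  p <- predict(m1, rbind(c(1, 0)))
  expect_equal(p, 1 / (1 + exp(-1)))
  # saturation and monotonicity in the intercept
  m_hi <- logic_model(lt_leaf(1), beta0 = 50, betas = 0)
  expect_gt(predict(m_hi, rbind(c(0, 0))), 1 - 1e-10)
  b0s <- seq(-3, 3, by = 0.5)
  ps <- vapply(b0s, function(b)
    predict(logic_model(lt_leaf(1), beta0 = b, betas = 1), rbind(c(1, 0))), 1.0)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("score counts explanations and matches a row-by-row oracle", {
  set.seed(201)
  X <- matrix(rbinom(300, 1, 0.4), 50, 6)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(50, 1, 0.5))
  for (i in 1:10) {
    tr <- random_tree(6, size = sample(1:5, 1))
    oracle <- sum(vapply(seq_len(50), function(r)
      eval_tree(tr, X[r, ]) == y[r], TRUE))
    expect_equal(score_model(tr, X, y), oracle)
  }
  # a constant-0 tree explains exactly the controls
  zero_tree <- parse_tree("X1 & !X1")
  expect_equal(score_model(zero_tree, X, y), sum(y == 0))
  expect_error(score_model(zero_tree, X[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("the planted expression scores M under risk 1 and no noise", {
  sim <- tiny_sim(202)
  expect_equal(score_model(sim$truth_tree, sim$genotypes, sim$phenotype),
               nrow(sim$genotypes))
})

test_that("MAP coefficients match an independent optimizer to 1e-6", {
  set.seed(203)
  X <- matrix(rbinom(400, 1, 0.5), 100, 4)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(100, 1, 0.4))
  m <- logic_model(list(parse_tree("X1 & X2"), parse_tree("X3 | !X4")))
  fit <- fit_betas(m, X, y, v = 10)
  L <- cbind(1, vapply(m$trees, eval_tree_rows, integer(100), genotypes = X))
  negpost <- function(b) {
    eta <- drop(L %*% b)
    -(sum(y * eta - log1p(exp(eta))) - sum(b^2) / (2 * 10))
  }
  o <- optim(c(0, 0, 0), negpost, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(c(fit$beta0, fit$betas), o$par, tolerance = 1e-6)
})

test_that("a tree matching the phenotype gets a large positive coefficient", {
  sim <- tiny_sim(204)
  m <- fit_betas(logic_model(sim$truth_tree), sim$genotypes, sim$phenotype)
  expect_gt(m$betas[1], 2)
})

test_that("a phenotype-independent tree gets a near-zero coefficient", {
  set.seed(205)
  X <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(2000, 1, 0.5))
  m <- fit_betas(logic_model(lt_leaf(1)), X, y, v = 10)
  # 3 standard errors of a null logistic coefficient at this n
  expect_lt(abs(m$betas[1]), 3 * sqrt(4 / 2000) * 2)
})

test_that("the model prior decomposes as geometric size times combinatorics", {
  pr <- prior_config(alpha = 0.5, s_max = 5, n_max = 1, n_snps = 20)
  lp2 <- model_log_prior(logic_model(parse_tree("X1 & X2")), pr)
  lp3 <- model_log_prior(logic_model(parse_tree("X1 & X2 & X3")), pr)
  # one extra leaf: ratio = alpha * C(N,2)/C(N,3)
  expect_equal(lp3 - lp2, log(0.5) + lchoose(20, 2) - lchoose(20, 3))
  # strictly decreasing in size for a fixed indicator count is implied by
  # alpha < 1 once the combinatorial growth is removed
  expect_lt(lp3 + lchoose(20, 3), lp2 + lchoose(20, 2))
})

test_that("the prior normalizes to 1 over all models (N = 4, s_max = 2, k = 1)", {
  pr <- prior_config(alpha = 0.5, s_max = 2, n_max = 1, n_snps = 4)
  total <- 0
  for (j in 1:4) {
    total <- total + exp(model_log_prior(logic_model(lt_leaf(j)), pr))
  }
  for (pair in utils::combn(4, 2, simplify = FALSE)) {
    m <- logic_model(lt_node("and", lt_leaf(pair[1]), lt_leaf(pair[2])))
    total <- total + exp(model_log_prior(m, pr))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("impossible models have log prior -Inf", {
  pr <- prior_config(s_max = 2, n_max = 1, n_snps = 5)
  expect_equal(model_log_prior(logic_model(parse_tree("X1 & X2 & X3")), pr),
               -Inf)
})

test_that("acceptance probability is 1 for identical proposals", {
  set.seed(206)
  X <- matrix(rbinom(600, 1, 0.4), 100, 6)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(100, 1, 0.5))
  ap <- acceptance_params(logic_model(parse_tree("X1 & X2")), X, y)
  expect_equal(acceptance_probability(ap, ap), 1)
})

test_that("acceptance probability agrees with the direct determinant form", {
  set.seed(207)
  X <- matrix(rbinom(500, 1, 0.4), 100, 5)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(100, 1, 0.5))
  cur <- acceptance_params(logic_model(parse_tree("X1 | X2")), X, y, v = 10)
  prop <- acceptance_params(logic_model(list(parse_tree("X3"),
                                             parse_tree("X4 & X5"))), X, y,
                            v = 10)
  direct <- min(1, 10^((cur$k - prop$k) / 2) *
    sqrt(det(prop$posterior_cov) / det(cur$posterior_cov)) *
    exp(cur$error_term - prop$error_term))
  expect_equal(acceptance_probability(cur, prop), direct, tolerance = 1e-10)
})

test_that("acceptance is invariant to a common shift of the error terms", {
  set.seed(208)
  X <- matrix(rbinom(500, 1, 0.4), 100, 5)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(100, 1, 0.5))
  cur <- acceptance_params(logic_model(parse_tree("X1")), X, y)
  prop <- acceptance_params(logic_model(parse_tree("X2 & X3")), X, y)
  q1 <- acceptance_probability(cur, prop)
  cur$error_term <- cur$error_term + 7.5
  prop$error_term <- prop$error_term + 7.5
  expect_equal(acceptance_probability(cur, prop), q1)
})

test_that("a better-fitting proposal has a higher acceptance probability", {
  sim <- tiny_sim(209)
  X <- sim$genotypes; y <- sim$phenotype
  cur <- acceptance_params(logic_model(lt_leaf(setdiff(1:12,
    sim$causal_indices)[1])), X, y)
  good <- acceptance_params(logic_model(sim$truth_tree), X, y)
  bad <- acceptance_params(logic_model(parse_tree("X1 & !X1")), X, y)
  expect_gte(acceptance_probability(cur, good),
             acceptance_probability(cur, bad))
  expect_equal(acceptance_probability(cur, good), 1)
})

test_that("a duplicated design column always has partial F = 0", {
  set.seed(210)
  for (i in 1:20) {
    X <- matrix(rbinom(600, 1, 0.4), 200, 3)
    f <- partial_f_stats(cbind(X, X[, 2]), rbinom(200, 1, 0.5))
    expect_lt(f[2], 1e-6)
    expect_lt(f[4], 1e-6)
  }
})

test_that("partial F statistics match drop1's F-test on a fixed dataset", {
  set.seed(211)
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  y <- as.numeric(X[, 1] + rnorm(20, sd = 0.7) > 0.5)
  f <- partial_f_stats(X, y)
  d <- as.data.frame(X)
  dr <- drop1(lm(y ~ V1 + V2 + V3, data = d), test = "F")
  expect_equal(f, dr$`F value`[-1], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("stepwise elimination removes noise SNPs at F_out = 4", {
  set.seed(212)
  dropped <- 0
  for (i in 1:100) {
    X <- cbind(rbinom(2000, 1, 0.4), rbinom(2000, 1, 0.4))
    storage.mode(X) <- "integer"
    y <- as.integer(ifelse(runif(2000) < 0.9, X[, 1], 1 - X[, 1]))
    m <- logic_model(parse_tree("X1 | X2"))    # X2 is pure noise
    pruned <- stepwise_eliminate(m, X, y, f_out = 4)
    if (!2L %in% model_snps(pruned)) dropped <- dropped + 1
  }
  expect_gte(dropped, 90)
})

test_that("stepwise never empties the model", {
  set.seed(213)
  X <- matrix(rbinom(400, 1, 0.5), 200, 2)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(200, 1, 0.5))    # nothing is significant
  pruned <- stepwise_eliminate(logic_model(parse_tree("X1 | X2")), X, y)
  expect_gte(length(model_snps(pruned)), 1)
})

test_that("score is invariant under the OR-split forest rewrite", {
  set.seed(214)
  X <- matrix(rbinom(600, 1, 0.4), 100, 6)
  storage.mode(X) <- "integer"
  y <- as.integer(rbinom(100, 1, 0.5))
  for (i in 1:20) {
    tr <- random_tree(6, size = sample(2:5, 1))
    f <- split_to_forest(tr)
    expect_equal(score_model(tr, X, y), sum(eval_forest_rows(f, X) == y))
  }
})
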