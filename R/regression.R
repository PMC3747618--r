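#' Logic regression models
#'
#' A logic regression model links k logic trees to a binary phenotype
#' through a logistic (sigmoid) regression:
#' \deqn{g(E(P)) = \beta_0 + \sum_{i=1}^k \beta_i L_i, \quad
#'       g(\eta) = 1/(1+e^{-\eta}),}
#' where each \eqn{L_i} is the 0/1 output of logic tree i. The model size s
#' is the total number of SNP leaves over all trees.
#'
#' @param trees a list of `logic_tree` objects (or a single tree).
#' @param beta0,betas optional fitted coefficients; `NULL` until
#'   [fit_betas()] is called.
#' @return An object of class `logic_model`.
#' @export
logic_model <- function(trees, beta0 = NULL, betas = NULL) {
  if (inherits(trees, "logic_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1L, all(vapply(trees, inherits, TRUE, "logic_tree")))
  structure(list(trees = trees, beta0 = beta0, betas = betas,
                 stabilized = FALSE),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat("<logic_model> k =", length(x$trees), " size =", model_size(x), "\n")
  for (i in seq_along(x$trees)) {
    b <- if (is.null(x$betas)) "" else sprintf("  (beta = %.3f)", x$betas[i])
    cat("  L", i, ": ", format(x$trees[[i]]), b, "\n", sep = "")
  }
  if (!is.null(x$beta0)) cat("  intercept:", signif(x$beta0, 4), "\n")
  invisible(x)
}

#' @rdname logic_model
#' @param model a `logic_model`.
#' @export
model_size <- function(model) sum(vapply(model$trees, tree_size, 1L))

#' @rdname logic_model
#' @export
model_snps <- function(model) {
  sort(unique(unlist(lapply(model$trees, tree_snps))))
}

## M x k matrix of tree outputs
tree_outputs <- function(model, genotypes) {
  vapply(model$trees, eval_tree_rows, integer(nrow(genotypes)), genotypes = genotypes)
}

sigmoid <- function(eta) 1 / (1 + exp(-eta))

#' Predicted case probability
#'
#' Applies the sigmoid link to the linear predictor
#' \eqn{\beta_0 + \sum_i \beta_i L_i(genotype)}. For an unfitted single-tree
#' model the bare tree output is returned (the Boolean prediction itself).
#'
#' @param object a `logic_model`.
#' @param genotypes binary matrix (rows = individuals).
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.logic_model <- function(object, genotypes, ...) {
  if (is.vector(genotypes)) genotypes <- rbind(genotypes)
  L <- tree_outputs(object, genotypes)
  if (is.null(object$betas)) {
    if (length(object$trees) != 1L) {
      stop("multi-tree model must be fitted before prediction", call. = FALSE)
    }
    return(as.numeric(L[, 1L]))
  }
  sigmoid(object$beta0 + drop(L %*% object$betas))
}

#' Model score: the number of explanations
#'
#' The score of a model is the number of individuals whose predicted
#' phenotype equals the observed phenotype ("explanations"). Predictions
#' are thresholded at 0.5; for an unfitted single tree this is the direct
#' Boolean match count \eqn{\#\{i : L(h_i) = P_i\}}.
#'
#' @param model a `logic_model` or bare `logic_tree`.
#' @param genotypes binary matrix.
#' @param phenotype binary vector (1 = case).
#' @return Integer score in `[0, M]`.
#' @export
score_model <- function(model, genotypes, phenotype) {
  if (nrow(genotypes) == 0L) stop("empty dataset", call. = FALSE)
  if (inherits(model, "logic_tree")) {
    return(sum(eval_tree_rows(model, genotypes) == phenotype))
  }
  p <- predict(model, genotypes)
  sum((p >= 0.5) == (phenotype == 1L))
}

#' Fit model coefficients by penalized Newton iteration
#'
#' Maximum a posteriori logistic coefficients under independent zero-mean
#' normal priors with variance `v` on every coefficient (intercept
#' included), found by Newton-Raphson. The penalty makes the estimate exist
#' even under complete separation; if the Hessian is numerically singular a
#' ridge-stabilized step is taken and the result is flagged
#' (`$stabilized`).
#'
#' @param model a `logic_model`.
#' @param genotypes binary matrix.
#' @param phenotype binary vector.
#' @param v prior variance of the coefficients (default 10).
#' @param tol,max_iter Newton convergence controls.
#' @return The fitted `logic_model` (with `beta0`, `betas`, `stabilized`).
#' @export
fit_betas <- function(model, genotypes, phenotype, v = 10, tol = 1e-10,
                      max_iter = 100L) {
  L <- cbind(1, tree_outputs(model, genotypes))
  y <- as.numeric(phenotype)
  k <- ncol(L)
  beta <- numeric(k)
  stabilized <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(L %*% beta)
    mu <- sigmoid(eta)
    grad <- drop(crossprod(L, y - mu)) - beta / v
    W <- mu * (1 - mu)
    H <- crossprod(L * W, L) + diag(1 / v, k)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      stabilized <- TRUE
      step <- solve(H + diag(1e-6, k), grad)
    }
    beta <- beta + step
    if (max(abs(grad)) < tol) break
  }
  model$beta0 <- beta[1L]
  model$betas <- beta[-1L]
  model$stabilized <- stabilized
  model
}

## ---- model prior (size-penalized, factorized) ------------------------------

#' Prior configuration for logic-regression models
#'
#' Holds the parameters of the size-penalized model prior: `alpha` in (0,1)
#' penalizes large models (geometric decay \eqn{\alpha^s} in the total size
#' s, normalized over s in `[1, n_max * s_max]`); `s_max` bounds a single
#' tree's size; `n_max` bounds the number of trees (uniform prior); the
#' SNP-indicator vector of a size-\eqn{s_i} tree is uniform over the
#' \eqn{\binom{N}{s_i}} possibilities.
#'
#' @param alpha size-penalty in (0, 1).
#' @param s_max maximum leaves per tree.
#' @param n_max maximum number of trees.
#' @param n_snps number of SNP columns N.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(alpha = 0.5, s_max = 10L, n_max = 3L, n_snps) {
  stopifnot(alpha > 0, alpha < 1, s_max >= 1, n_max >= 1, n_snps >= 1)
  structure(list(alpha = alpha, s_max = as.integer(s_max),
                 n_max = as.integer(n_max), n_snps = as.integer(n_snps)),
            class = "prior_config")
}

## number of ordered compositions of s into n parts, each in [1, s_max]
n_compositions <- function(s, n, s_max) {
  counts <- numeric(s + 1L)      # counts[t+1] = ways to reach total t
  counts[1L] <- 1
  for (i in seq_len(n)) {
    nxt <- numeric(s + 1L)
    for (t in seq_len(s)) {
      lo <- max(0L, t - s_max)
      hi <- t - 1L
      if (hi >= lo) nxt[t + 1L] <- sum(counts[(lo:hi) + 1L])
    }
    counts <- nxt
  }
  counts[s + 1L]
}

#' Log prior density of a model
#'
#' Factorized model prior: uniform over the number of trees, a geometric
#' (alpha-decaying, theta-normalized) prior on the total size s, a uniform
#' prior over the compositions of s into per-tree sizes within
#' `[1, s_max]`, and a uniform prior over each tree's SNP-indicator vector
#' given its size. Returns `-Inf` for impossible models (any tree larger
#' than `s_max`, more than `n_max` trees).
#'
#' @param model a `logic_model`.
#' @param prior a [prior_config()].
#' @return Log prior density (finite or `-Inf`).
#' @export
model_log_prior <- function(model, prior) {
  sizes <- vapply(model$trees, tree_size, 1L)
  n_l <- length(sizes)
  s <- sum(sizes)
  S <- prior$n_max * prior$s_max
  if (n_l > prior$n_max || any(sizes > prior$s_max) || s > S) return(-Inf)
  log_alpha <- log(prior$alpha)
  # log theta*(1-alpha): normalizer of alpha^s over s in [1, S]
  log_norm <- -log(sum(prior$alpha^(1:S)))
  lp <- -log(prior$n_max) +                      # p(n_l)
    log_norm + s * log_alpha -                   # p(s)
    log(n_compositions(s, n_l, prior$s_max)) -   # p(s_1..s_n | s)
    sum(lchoose(prior$n_snps, sizes))            # p(q_i | s_i)
  lp
}

## ---- acceptance probability (Metropolis-style) -----------------------------

#' Posterior quantities entering the acceptance probability
#'
#' For a model with covariate matrix \eqn{\Omega} (the M x k matrix of tree
#' outputs) and response y, under the Gaussian working model with
#' coefficient prior variance `v`:
#' \eqn{\hat V = (\Omega'\Omega + I/v)^{-1}}, \eqn{\hat\beta = \hat V \Omega' y},
#' and the error term \eqn{a = y'y - \hat\beta'\hat V^{-1}\hat\beta}
#' measuring residual misfit.
#'
#' @param model a `logic_model`.
#' @param genotypes binary matrix.
#' @param phenotype binary vector.
#' @param v prior variance scale.
#' @return A list of class `acceptance_params` with `v`, `k`, `omega`,
#'   `beta_hat`, `posterior_cov`, `error_term`, `logdet_cov`.
#' @export
acceptance_params <- function(model, genotypes, phenotype, v = 10) {
  Omega <- tree_outputs(model, genotypes)
  y <- as.numeric(phenotype)
  k <- ncol(Omega)
  Vinv <- crossprod(Omega) + diag(1 / v, k)
  ch <- tryCatch(chol(Vinv), error = function(e) NULL)
  if (is.null(ch)) {
    stop("posterior covariance is not positive definite", call. = FALSE)
  }
  Vhat <- chol2inv(ch)
  beta_hat <- drop(Vhat %*% crossprod(Omega, y))
  a <- sum(y^2) - sum(beta_hat * drop(Vinv %*% beta_hat))
  structure(list(v = v, k = k, omega = Omega, beta_hat = beta_hat,
                 posterior_cov = Vhat, error_term = a,
                 logdet_cov = -2 * sum(log(diag(ch)))),
            class = "acceptance_params")
}

#' Acceptance probability for a proposed model
#'
#' The Metropolis-style acceptance probability comparing a proposal (*) to
#' the current model on the same data:
#' \deqn{Q = \min\{1,\;
#'   v^{(k - k^*)/2} \, |\hat V^*|^{1/2} / |\hat V|^{1/2}
#'   \, e^{a - a^*}\}.}
#' A proposal identical to the current model gives Q = 1, and a better fit
#' (smaller error term a*) increases Q. Computed in log space so that large
#' error terms never overflow.
#'
#' @param current,proposed [acceptance_params()] objects computed on the
#'   same data.
#' @return Probability Q in `[0, 1]`.
#' @export
acceptance_probability <- function(current, proposed) {
  stopifnot(inherits(current, "acceptance_params"),
            inherits(proposed, "acceptance_params"))
  log_q <- (current$k - proposed$k) / 2 * log(current$v) +
    (proposed$logdet_cov - current$logdet_cov) / 2 +
    (current$error_term - proposed$error_term)
  if (!is.finite(log_q)) stop("non-finite acceptance ratio", call. = FALSE)
  exp(min(0, log_q))
}

## ---- stepwise partial-F elimination ----------------------------------------

#' Partial F statistics of design columns
#'
#' For each column j of `X`, the partial F statistic from the linear
#' regression of `y` on all columns (plus intercept) versus the regression
#' with column j removed:
#' \eqn{F_j = (RSS_{-j} - RSS) / (RSS / df)} with `df` the residual degrees
#' of freedom of the full fit. A column that contributes nothing beyond the
#' others (for example an exact duplicate) has \eqn{F_j = 0}.
#'
#' @param X numeric design matrix (one column per candidate SNP).
#' @param y response vector.
#' @return Numeric vector of F statistics, one per column.
#' @export
partial_f_stats <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  Z <- cbind(1, X)
  p <- ncol(Z)
  # one pass of sufficient statistics; each drop-one fit is then a small
  # normal-equations solve, O(p^3) instead of O(n p^2)
  G <- crossprod(Z)
  h <- drop(crossprod(Z, y))
  yy <- sum(y^2)
  rss_of <- function(keep) {
    qr_g <- qr(G[keep, keep, drop = FALSE])
    b <- qr.coef(qr_g, h[keep])
    b[is.na(b)] <- 0
    max(yy - sum(h[keep] * b), 0)
  }
  qr_full <- qr(G)
  rank_full <- qr_full$rank
  b_full <- qr.coef(qr_full, h)
  b_full[is.na(b_full)] <- 0
  rss_full <- max(yy - sum(h * b_full), 0)
  df <- n - rank_full
  if (df <= 0 || rss_full <= 0) return(rep(0, ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    rss_red <- rss_of(setdiff(seq_len(p), j + 1L))
    f <- (rss_red - rss_full) / (rss_full / df)
    max(f, 0)
  }, 1.0)
}

#' Stepwise elimination of insignificant SNPs
#'
#' Computes the partial F statistic of every SNP active in the model (the
#' genotype columns of the model's distinct leaf SNPs, regressed on the
#' phenotype) and drops every SNP with \eqn{F_i \le F_{out}} from all
#' trees. A tree losing all leaves is removed; if every SNP would be
#' dropped, the single SNP with maximal F is retained so the model never
#' empties. Refits coefficients when the input model was fitted.
#'
#' @param model a `logic_model`.
#' @param genotypes binary matrix.
#' @param phenotype binary vector.
#' @param f_out drop threshold (default 4).
#' @param v prior variance for refitting.
#' @param rows optional row indices: compute the F statistics (and any
#'   refit) on this subset of the data, e.g. an agent's bootstrap rows.
#' @return The pruned `logic_model`, with attribute `"f_stats"` (a named
#'   vector of per-SNP F statistics).
#' @export
stepwise_eliminate <- function(model, genotypes, phenotype, f_out = 4, v = 10,
                               rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(genotypes))
  active <- model_snps(model)
  Xa <- genotypes[rows, active, drop = FALSE]
  f <- partial_f_stats(Xa, as.numeric(phenotype[rows]))
  names(f) <- active
  drop_snps <- active[f <= f_out]
  if (length(drop_snps) == length(active)) {
    drop_snps <- setdiff(active, active[which.max(f)])
  }
  if (length(drop_snps) > 0L) {
    trees <- lapply(model$trees, prune_snps, snps = drop_snps)
    trees <- trees[!vapply(trees, is.null, TRUE)]
    was_fitted <- !is.null(model$betas)
    model <- logic_model(trees)
    if (was_fitted) {
      model <- fit_betas(model, genotypes[rows, , drop = FALSE],
                         phenotype[rows], v = v)
    }
  }
  attr(model, "f_stats") <- f
  model
}
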