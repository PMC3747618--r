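#' Control parameters for the fish-swarm search
#'
#' Collects every tunable of the swarm optimizer with its default. Defaults
#' marked (*) are design choices of this package; the others follow the
#' method's published description.
#'
#' @param n_fish number of fish agents F (default 12; each agent holds one
#'   logic tree and a bootstrap/out-of-bag split of the data).
#' @param s_max maximum leaves per tree (*; default 10).
#' @param b_stable stop after the best score is unchanged for this many
#'   iterations. The default (`NULL`) scales the window with the search
#'   space as `max(100, 0.6 * N)` for N SNPs, so that the school can try
#'   each SNP several times between improvements (*).
#' @param i_max iterations between importance refreshes and stepwise
#'   elimination sweeps (*; default 10).
#' @param f_out partial-F threshold below which a SNP is dropped by the
#'   stepwise sweep (*; default 4).
#' @param v prior variance scale entering the acceptance probability and
#'   coefficient fitting (*; default 10).
#' @param behavior_probs probabilities of the RANDOM / FOLLOW / KPDIST
#'   swarm behaviors for non-best agents (*; default 0.2 / 0.5 / 0.3).
#' @param sigma2_floor lower bound on the size-density variance so the
#'   density stays proper when all agents share one size (*; default 0.25).
#' @param importance_eps floor added to importance values when converting
#'   them to SNP-selection probabilities, keeping every SNP reachable
#'   (*; default 0.01).
#' @param max_iter hard iteration cap (*; default 4000).
#' @param allow_negation may search moves introduce negated literals?
#' @param strict_literal_alt draw ALT replacement SNPs with weights
#'   `1 - P(j)` (the literal reading of the behavior description) instead
#'   of the default importance-seeking `P(j)`.
#' @return A list of class `fslr_control`.
#' @export
fslr_control <- function(n_fish = 12L, s_max = 10L, b_stable = NULL,
                         i_max = 10L, f_out = 4, v = 10,
                         behavior_probs = c(random = 0.2, follow = 0.5,
                                            kpdist = 0.3),
                         sigma2_floor = 0.25, importance_eps = 0.01,
                         max_iter = 4000L, allow_negation = TRUE,
                         strict_literal_alt = FALSE) {
  stopifnot(n_fish >= 2L, s_max >= 1L,
            is.null(b_stable) || b_stable >= 1L, i_max >= 1L,
            length(behavior_probs) == 3L, all(behavior_probs >= 0),
            sum(behavior_probs) > 0, sigma2_floor > 0)
  behavior_probs <- behavior_probs / sum(behavior_probs)
  names(behavior_probs) <- c("random", "follow", "kpdist")
  structure(list(n_fish = as.integer(n_fish), s_max = as.integer(s_max),
                 b_stable = if (is.null(b_stable)) NULL else
                   as.integer(b_stable),
                 i_max = as.integer(i_max),
                 f_out = f_out, v = v, behavior_probs = behavior_probs,
                 sigma2_floor = sigma2_floor, importance_eps = importance_eps,
                 max_iter = as.integer(max_iter),
                 allow_negation = isTRUE(allow_negation),
                 strict_literal_alt = isTRUE(strict_literal_alt)),
            class = "fslr_control")
}

## ---- swarm state -----------------------------------------------------------

#' Initialize a school of fish agents
#'
#' Creates `n_fish` agents, each holding a random initial logic tree (size
#' uniform on `1..s_max`, SNPs uniform) and an independent bootstrap sample
#' of the data rows (drawn with replacement, size M; the rows never drawn
#' form the agent's out-of-bag set). Deterministic given `seed`.
#'
#' @param genotypes binary matrix (M x N).
#' @param phenotype binary vector of length M.
#' @param control an [fslr_control()].
#' @param seed optional integer seed.
#' @return An object of class `swarm_state`.
#' @export
initialize_swarm <- function(genotypes, phenotype, control = fslr_control(),
                             seed = NULL) {
  if (control$n_fish < 2L) {
    stop("at least 2 fish agents are required (FOLLOW/KPDIST are undefined ",
         "for a single agent)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(genotypes)
  N <- ncol(genotypes)
  agents <- lapply(seq_len(control$n_fish), function(id) {
    size <- sample.int(control$s_max, 1L)
    tree <- random_tree(N, size = size, allow_negation = control$allow_negation)
    boot <- sort(sample.int(M, M, replace = TRUE))
    oob <- setdiff(seq_len(M), unique(boot))
    list(id = id, tree = tree, boot = boot, oob = oob,
         local_best = NULL, local_best_score = -Inf)
  })
  structure(list(agents = agents, iteration = 0L, stable_count = 0L,
                 best_id = NA_integer_, importance = NULL,
                 n_snps = N, control = control),
            class = "swarm_state")
}

#' Size-preference density
#'
#' The normal density in tree size centered at the best agent's size,
#' clamped to `[0, 1]` so it can be used directly as a behavior-mixing
#' probability:
#' \eqn{f(s) = \min(1, (2\pi\sigma^2)^{-1/2} e^{-(s-s_{best})^2/2\sigma^2}).}
#'
#' @param s tree size at which to evaluate.
#' @param mu the best agent's size \eqn{s_{best}}.
#' @param sigma2 variance (recomputed each iteration as the mean squared
#'   size deviation from the best agent, floored at `sigma2_floor`).
#' @return A probability in `[0, 1]`.
#' @export
size_density <- function(s, mu, sigma2) {
  stopifnot(sigma2 > 0)
  pmin(1, stats::dnorm(s, mean = mu, sd = sqrt(sigma2)))
}

#' Out-of-bag SNP importance
#'
#' For each agent k, \eqn{N_k} is the number of correctly classified
#' out-of-bag rows under its tree and \eqn{N_k^{-j}} the same count after
#' SNP j is removed from the tree (every occurrence pruned; an emptied tree
#' predicts the majority class of the agent's bootstrap rows). The
#' importance of SNP j is the average drop
#' \eqn{V(j) = F^{-1}\sum_k (N_k - N_k^{-j})}; SNPs absent from every
#' agent's tree have V = 0. Agents with an empty out-of-bag set contribute
#' 0.
#'
#' @param state a `swarm_state`.
#' @param genotypes,phenotype the data.
#' @return A tibble with columns `snp`, `value`, `prob` (the derived
#'   selection probabilities, see [selection_distribution()]).
#' @export
compute_importance <- function(state, genotypes, phenotype) {
  if (!is.integer(genotypes)) storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  N <- state$n_snps
  F_ <- length(state$agents)
  V <- numeric(N)
  for (ag in state$agents) {
    if (length(ag$oob) == 0L) next
    yo <- phenotype[ag$oob]
    rows0 <- ag$oob - 1L
    w <- rep(1, length(rows0))
    n_k <- .score_tree_c(genotypes, ag$tree, rows0, w, phenotype)[1L]
    maj <- as.integer(mean(phenotype[ag$boot]) >= 0.5)
    for (j in unique(tree_snps(ag$tree))) {
      pruned <- prune_snps(ag$tree, j)
      n_kj <- if (is.null(pruned)) {
        sum(maj == yo)
      } else {
        .score_tree_c(genotypes, pruned, rows0, w, phenotype)[1L]
      }
      V[j] <- V[j] + (n_k - n_kj)
    }
  }
  V <- V / F_
  tibble::tibble(snp = seq_len(N), value = V,
                 prob = selection_distribution(V, state$control$importance_eps))
}

#' SNP-selection probabilities from importance values
#'
#' Maps importance values to a proper probability distribution over SNPs:
#' \eqn{P(j) \propto \max(V(j), \epsilon) + \epsilon}. The floor keeps
#' every SNP reachable; equal importances give the uniform distribution.
#'
#' @param values numeric importance vector V.
#' @param eps floor (default 0.01).
#' @return Probability vector summing to 1.
#' @export
selection_distribution <- function(values, eps = 0.01) {
  w <- pmax(values, eps) + eps
  w / sum(w)
}

#' Distance between two fish agents
#'
#' The solution-space distance is the absolute difference of total
#' importance carried by each agent's SNP set:
#' \eqn{d = |\sum_{j \in S_a} V(j) - \sum_{j \in S_b} V(j)|}.
#'
#' @param a,b agents (elements of `state$agents`) or `logic_tree`s.
#' @param importance the importance tibble from [compute_importance()].
#' @return Non-negative distance; 0 for identical SNP sets.
#' @export
agent_distance <- function(a, b, importance) {
  tr_a <- if (inherits(a, "logic_tree")) a else a$tree
  tr_b <- if (inherits(b, "logic_tree")) b else b$tree
  V <- importance$value
  abs(sum(V[unique(tree_snps(tr_a))]) - sum(V[unique(tree_snps(tr_b))]))
}

#' Choose a swarm behavior for one agent
#'
#' The best agent always HOLDs (retains its tree); every other agent draws
#' RANDOM, FOLLOW or KPDIST from the configured behavior probabilities.
#'
#' @param agent_id the agent's id.
#' @param best_id id of the current best agent.
#' @param behavior_probs length-3 probability vector (random, follow,
#'   kpdist).
#' @return One of `"HOLD"`, `"RANDOM"`, `"FOLLOW"`, `"KPDIST"`.
#' @export
choose_behavior <- function(agent_id, best_id, behavior_probs) {
  if (agent_id == best_id) return("HOLD")
  sample(c("RANDOM", "FOLLOW", "KPDIST"), 1L, prob = behavior_probs)
}

## ---- behavior steps --------------------------------------------------------

## ALT move with importance-guided victim / replacement choices.
## `toward` importance: replacement drawn from P (FOLLOW's default reading);
## `away`: replacement drawn from 1 - P (KPDIST's diversity reading, also
## the strict-literal FOLLOW reading).
alt_guided <- function(tree, n_snps, sel_probs, allow_negation,
                       away = FALSE) {
  leaf_snps <- tree_snps(tree)
  w_leaf <- 1 - sel_probs[leaf_snps]
  if (all(w_leaf <= 0)) w_leaf <- NULL
  repl <- if (away) 1 - sel_probs else sel_probs
  repl[leaf_snps] <- 0
  if (all(repl <= 0)) repl <- NULL
  move_alt_snp(tree, n_snps, repl, w_leaf, allow_negation)
}

#' RANDOM behavior: one uniformly chosen feasible move
#'
#' Chooses one of the four moves with probability 1/4 each (infeasible
#' moves are resampled) and applies it with uniform SNP choices. The
#' proposal always differs structurally from the current tree.
#'
#' @param tree current `logic_tree`.
#' @param n_snps number of SNPs.
#' @param s_max maximum tree size (ADD beyond it is treated as infeasible).
#' @param allow_negation may new literals be negated?
#' @return Proposed `logic_tree`.
#' @export
random_step <- function(tree, n_snps, s_max = Inf, allow_negation = TRUE) {
  s <- tree_size(tree)
  repeat {
    m <- sample.int(4L, 1L)
    if (m == 1L) {
      if (s >= s_max) next
      return(move_add(tree, n_snps, NULL, allow_negation))
    }
    if (m == 2L) {
      if (s < 2L) next
      return(move_del(tree, NULL))
    }
    if (m == 3L) return(move_alt_snp(tree, n_snps, NULL, NULL, allow_negation))
    if (s < 2L) next
    return(move_alt_opt(tree))
  }
}

#' FOLLOW behavior: move toward the best agent
#'
#' Pulls the agent's size toward `s_best` and its SNPs toward important
#' ones: with size above `s_best`, DEL with probability `f(s)` (victim
#' drawn with weight `1 - P(j)`) else ALT; below, ADD with probability
#' `1 - f(s)` (new SNP drawn from `P`) else ALT; at equal size, always ALT.
#' Replacement SNPs are drawn from `P` over SNPs outside the tree (or
#' `1 - P` when `strict = TRUE`).
#'
#' @inheritParams random_step
#' @param s_best size of the best agent's tree.
#' @param sigma2 current size-density variance.
#' @param sel_probs SNP-selection probability vector P.
#' @param strict use the literal `1 - P` replacement weights.
#' @return Proposed `logic_tree`.
#' @export
follow_step <- function(tree, s_best, sigma2, sel_probs, n_snps,
                        s_max = Inf, allow_negation = TRUE, strict = FALSE) {
  s <- tree_size(tree)
  dens <- size_density(s, s_best, sigma2)
  if (s > s_best) {
    if (stats::runif(1) < dens && move_feasible(tree, "DEL_SNP")) {
      w <- 1 - sel_probs[tree_snps(tree)]
      if (all(w <= 0)) w <- NULL
      return(apply_move(tree, "DEL_SNP", n_snps, leaf_weights = w))
    }
  } else if (s < s_best) {
    if (stats::runif(1) < 1 - dens && s < s_max) {
      return(apply_move(tree, "ADD_SNP", n_snps, snp_probs = sel_probs,
                        allow_negation = allow_negation))
    }
  }
  alt_guided(tree, n_snps, sel_probs, allow_negation, away = strict)
}

#' KPDIST behavior: keep a distance from the best agent
#'
#' Pushes the agent's size away from `s_best`: above it, ADD with
#' probability `1 - f(s)` else ALT; below it, ALT with probability `f(s)`
#' else DEL; at equal size, ADD or DEL with probability 1/2 each (so the
#' proposal's size always differs from `s_best`). As the school's
#' diversity behavior, KPDIST draws its added / replacement SNPs with
#' weights `1 - P(j)`, preferring SNPs the school is not already
#' exploiting.
#'
#' @inheritParams follow_step
#' @return Proposed `logic_tree`.
#' @export
kpdist_step <- function(tree, s_best, sigma2, sel_probs, n_snps,
                        s_max = Inf, allow_negation = TRUE, strict = FALSE) {
  s <- tree_size(tree)
  dens <- size_density(s, s_best, sigma2)
  add_ok <- s < s_max
  del_ok <- move_feasible(tree, "DEL_SNP")
  anti <- 1 - sel_probs
  if (all(anti <= 0)) anti <- NULL
  do_add <- function() move_add(tree, n_snps, anti, allow_negation)
  do_del <- function() {
    w <- 1 - sel_probs[tree_snps(tree)]
    if (all(w <= 0)) w <- NULL
    move_del(tree, w)
  }
  if (s > s_best) {
    if (stats::runif(1) < 1 - dens && add_ok) return(do_add())
  } else if (s < s_best) {
    if (stats::runif(1) >= dens && del_ok) return(do_del())
    return(alt_guided(tree, n_snps, sel_probs, allow_negation, away = TRUE))
  } else {
    if (stats::runif(1) < 0.5) {
      if (add_ok) return(do_add())
      if (del_ok) return(do_del())
    } else {
      if (del_ok) return(do_del())
      if (add_ok) return(do_add())
    }
  }
  alt_guided(tree, n_snps, sel_probs, allow_negation, away = TRUE)
}

## scalar (single-tree) acceptance probability, Eq-7 form with k = k* = 1,
## from the binary-output sufficient statistics n1 = sum(out), n11 =
## sum(out * y) over the (weighted) training rows
q_stats <- function(n1_c, n11_c, n1_p, n11_p, yy, v) {
  vinv_c <- n1_c + 1 / v
  vinv_p <- n1_p + 1 / v
  a_c <- yy - n11_c^2 / vinv_c
  a_p <- yy - n11_p^2 / vinv_p
  log_q <- (log(vinv_c) - log(vinv_p)) / 2 + (a_c - a_p)
  exp(min(0, log_q))
}

## ---- the main fit ----------------------------------------------------------

#' Fit a fish-swarm logic regression
#'
#' Runs the full fish-swarm search on a case-control SNP dataset. A school
#' of agents, each holding one logic tree and a bootstrap/out-of-bag data
#' split, iterates: the best agent is announced; every other agent draws a
#' behavior (RANDOM / FOLLOW / KPDIST), proposes a tree edit, and accepts
#' it when its bootstrap score improves or otherwise with the
#' Metropolis-style probability Q; every `i_max` iterations the
#' out-of-bag SNP importances are refreshed and a stepwise partial-F sweep
#' prunes insignificant SNPs. The search stops when the best score has been
#' stable for `b_stable` iterations (or at `max_iter`).
#'
#' @param data a data frame whose columns are binary (0/1) SNPs plus one
#'   binary phenotype column, or a binary matrix (then supply `phenotype`
#'   as a vector).
#' @param phenotype the phenotype column name (default `"phenotype"`), or a
#'   0/1 vector when `data` is a matrix.
#' @param control an [fslr_control()] with the search settings.
#' @param seed optional integer seed; a seeded run is fully reproducible.
#' @param verbose print the best score each importance refresh.
#' @return An object of class `fslr_fit`; see [tidy.fslr_fit()],
#'   [glance.fslr_fit()], [selected_snps()], [autoplot.fslr_fit()].
#' @examples
#' sim <- simulate_epistasis(sim_config(n_pool = 2000, n_sites = 12,
#'   n_causal = 2, n_cases = 150, n_controls = 150), seed = 7)
#' fit <- fslr(sim$data, control = fslr_control(b_stable = 10), seed = 7)
#' glance(fit)
#' @export
fslr <- function(data, phenotype = "phenotype", control = fslr_control(),
                 seed = NULL, verbose = FALSE) {
  d <- prep_data(data, phenotype)
  X <- d$genotypes
  y <- d$phenotype
  M <- nrow(X)
  N <- ncol(X)
  ctrl <- control

  if (is.null(ctrl$b_stable)) {
    ctrl$b_stable <- max(100L, as.integer(ceiling(0.6 * N)))
  }
  state <- initialize_swarm(X, y, ctrl, seed = seed)
  agents <- state$agents
  F_ <- length(agents)

  # per-agent caches: bootstrap rows collapsed to (unique row, weight)
  # pairs, plus the sufficient statistics of the current tree
  all_rows0 <- seq_len(M) - 1L
  w_one <- rep(1, M)
  boot_rows0 <- vector("list", F_)
  boot_w <- vector("list", F_)
  boot_yy <- numeric(F_)
  for (i in seq_len(F_)) {
    tw <- tabulate(agents[[i]]$boot, nbins = M)
    keep <- which(tw > 0L)
    boot_rows0[[i]] <- keep - 1L
    boot_w[[i]] <- as.numeric(tw[keep])
    boot_yy[i] <- sum(tw[keep] * y[keep])
  }
  boot_stats <- function(i, tree) {
    .score_tree_c(X, tree, boot_rows0[[i]], boot_w[[i]], y)
  }
  full_score <- function(tree) {
    .score_tree_c(X, tree, all_rows0, w_one, y)[1L]
  }
  boot_scores <- full_scores <- boot_n1 <- boot_n11 <- numeric(F_)
  refresh_agent <- function(i) {
    st <- boot_stats(i, agents[[i]]$tree)
    boot_scores[i] <<- st[1L]
    boot_n1[i] <<- st[2L]
    boot_n11[i] <<- st[3L]
    full_scores[i] <<- full_score(agents[[i]]$tree)
  }
  for (i in seq_len(F_)) {
    refresh_agent(i)
    agents[[i]]$local_best <- agents[[i]]$tree
    agents[[i]]$local_best_score <- boot_scores[i]
  }

  best_tree <- NULL
  best_score <- -Inf
  best_iter <- 0L
  stable <- 0L
  importance <- NULL
  sel_probs <- rep(1 / N, N)
  iter <- 0L

  while (iter < ctrl$max_iter) {
    iter <- iter + 1L

    best_id <- which.max(full_scores)   # ties: lowest id
    if (full_scores[best_id] > best_score) {
      best_score <- full_scores[best_id]
      best_tree <- agents[[best_id]]$tree
      best_iter <- iter
      stable <- 0L
    } else {
      stable <- stable + 1L
    }
    if (stable >= ctrl$b_stable) break

    s_best <- tree_size(agents[[best_id]]$tree)
    sizes <- vapply(agents, function(a) tree_size(a$tree), 1L)
    sigma2 <- max(ctrl$sigma2_floor, mean((sizes - s_best)^2))

    if ((iter - 1L) %% ctrl$i_max == 0L) {
      state$agents <- agents
      importance <- compute_importance(state, X, y)
      sel_probs <- importance$prob
      if (verbose) {
        message(sprintf("iter %d: best score %d/%d", iter, best_score, M))
      }
    }

    for (i in seq_len(F_)) {
      beh <- choose_behavior(i, best_id, ctrl$behavior_probs)
      if (beh == "HOLD") next
      prop <- switch(beh,
        RANDOM = random_step(agents[[i]]$tree, N, ctrl$s_max,
                             ctrl$allow_negation),
        FOLLOW = follow_step(agents[[i]]$tree, s_best, sigma2, sel_probs, N,
                             ctrl$s_max, ctrl$allow_negation,
                             ctrl$strict_literal_alt),
        KPDIST = kpdist_step(agents[[i]]$tree, s_best, sigma2, sel_probs, N,
                             ctrl$s_max, ctrl$allow_negation,
                             ctrl$strict_literal_alt))
      st <- boot_stats(i, prop)
      new_bs <- st[1L]
      accept <- if (new_bs > boot_scores[i]) {
        TRUE
      } else {
        q <- q_stats(boot_n1[i], boot_n11[i], st[2L], st[3L],
                     boot_yy[i], ctrl$v)
        stats::runif(1) < q
      }
      if (accept) {
        agents[[i]]$tree <- prop
        boot_scores[i] <- new_bs
        boot_n1[i] <- st[2L]
        boot_n11[i] <- st[3L]
        full_scores[i] <- full_score(prop)
        if (new_bs > agents[[i]]$local_best_score) {
          agents[[i]]$local_best <- prop
          agents[[i]]$local_best_score <- new_bs
        }
      }
    }

    if (iter %% ctrl$i_max == 0L) {
      for (i in seq_len(F_)) {
        if (i == best_id) next                     # f_best HOLDs
        if (tree_size(agents[[i]]$tree) < 2L) next
        m <- stepwise_eliminate(logic_model(agents[[i]]$tree), X, y,
                                f_out = ctrl$f_out, v = ctrl$v,
                                rows = agents[[i]]$boot)
        if (!identical(m$trees[[1L]], agents[[i]]$tree)) {
          agents[[i]]$tree <- m$trees[[1L]]
          refresh_agent(i)
        }
      }
    }
  }
  converged <- stable >= ctrl$b_stable

  # final stepwise pruning (full data) defines the reported models
  prune_final <- function(tree) {
    if (tree_size(tree) < 2L) return(tree)
    stepwise_eliminate(logic_model(tree), X, y, f_out = ctrl$f_out,
                       v = ctrl$v)$trees[[1L]]
  }
  best_pruned <- prune_final(best_tree)
  agent_pruned <- lapply(agents, function(a) prune_final(a$tree))

  state$agents <- agents
  state$iteration <- iter
  importance <- compute_importance(state, X, y)

  best_model <- fit_betas(logic_model(best_pruned), X, y, v = ctrl$v)
  sel_best <- model_snps(best_model)
  sel_union <- sort(unique(c(sel_best, unlist(lapply(agent_pruned, tree_snps)))))

  structure(list(
    best = list(tree = best_pruned, tree_raw = best_tree, model = best_model,
                score = score_model(best_model, X, y), raw_score = best_score,
                found_iter = best_iter),
    agents = lapply(seq_len(F_), function(i) {
      list(id = i, tree = agent_pruned[[i]], tree_raw = agents[[i]]$tree,
           score = full_scores[i], local_best = agents[[i]]$local_best,
           local_best_score = agents[[i]]$local_best_score)
    }),
    selected = list(best = sel_best, union = sel_union),
    importance = importance,
    interactions = interaction_counts(c(list(best_pruned), agent_pruned)),
    iterations = iter, converged = converged,
    n_obs = M, n_snps = N, snp_ids = d$snp_ids,
    control = ctrl, seed = seed
  ), class = "fslr_fit")
}

## normalize data-frame / matrix input to (genotypes, phenotype, snp_ids)
prep_data <- function(data, phenotype) {
  if (is.matrix(data)) {
    X <- data
    y <- as.integer(phenotype)
    ids <- colnames(X)
    if (is.null(ids)) ids <- paste0("X", seq_len(ncol(X)))
  } else {
    data <- as.data.frame(data)
    if (!is.character(phenotype) || !phenotype %in% names(data)) {
      stop("phenotype column '", phenotype, "' not found in data", call. = FALSE)
    }
    y <- as.integer(data[[phenotype]])
    snp_cols <- setdiff(names(data), phenotype)
    X <- as.matrix(data[snp_cols])
    storage.mode(X) <- "integer"
    ids <- snp_cols
  }
  if (length(y) != nrow(X)) {
    stop("phenotype length does not match the number of rows", call. = FALSE)
  }
  if (!all(X %in% c(0L, 1L)) || !all(y %in% c(0L, 1L))) {
    stop("genotypes and phenotype must be binary 0/1", call. = FALSE)
  }
  list(genotypes = X, phenotype = y, snp_ids = ids)
}

## pairs/triples of distinct SNPs co-occurring inside single conjunctions,
## counted once per model
interaction_counts <- function(trees) {
  rows <- list()
  for (tr in trees) {
    forest <- split_to_forest(tr)
    seen <- character(0)
    for (cc in forest) {
      snps <- sort(unique(abs(cc)))
      if (length(snps) < 2L) next
      for (ord in 2:min(3L, length(snps))) {
        combos <- utils::combn(snps, ord, simplify = FALSE)
        for (cb in combos) {
          key <- paste(cb, collapse = ":")
          if (!key %in% seen) {
            seen <- c(seen, key)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              interaction = key, order = ord)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(interaction = character(), order = integer(),
                          count = integer()))
  }
  dplyr::arrange(
    dplyr::count(dplyr::bind_rows(rows), .data$interaction, .data$order,
                 name = "count"),
    dplyr::desc(.data$count), .data$interaction)
}

#' Selected SNPs of a fitted swarm
#'
#' The SNP set reported by the fit: either the union of SNPs over all
#' agents' final (stepwise-pruned) trees plus the best model (the school's
#' full output; default), or the SNPs of the global-best model only.
#'
#' @param fit an `fslr_fit`.
#' @param selection `"union"` or `"best"`.
#' @return Sorted integer vector of SNP column indices.
#' @export
selected_snps <- function(fit, selection = c("union", "best")) {
  selection <- match.arg(selection)
  fit$selected[[selection]]
}

#' @export
print.fslr_fit <- function(x, ...) {
  cat("<fslr_fit> fish-swarm logic regression\n")
  cat("  data: ", x$n_obs, " individuals x ", x$n_snps, " SNPs\n", sep = "")
  cat("  best model: ", format(x$best$tree), "\n", sep = "")
  cat("  score: ", x$best$score, "/", x$n_obs,
      sprintf("  (%.1f%% explained)", 100 * x$best$score / x$n_obs), "\n",
      sep = "")
  cat("  iterations: ", x$iterations,
      if (x$converged) "  (converged)" else "  (iteration cap reached)",
      "\n", sep = "")
  cat("  selected SNPs (union over school): ",
      paste(x$selected$union, collapse = ", "), "\n", sep = "")
  invisible(x)
}
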