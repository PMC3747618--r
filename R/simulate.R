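#' Simulation configuration
#'
#' Parameters of the case-control simulation protocol: a pool of haplotypes
#' with a fixed number of segregating sites, a planted causal Boolean
#' expression over randomly chosen sites, a risk level (the probability
#' that an individual's phenotype agrees with the expression output), a
#' per-allele noise level (flip probability, applied after case/control
#' sampling), and balanced case/control subsampling from the pool.
#'
#' The defaults are the study conditions of the protocol this package
#' reproduces: a pool of 40,000 haplotypes, 1,000 segregating sites, 10
#' causal sites, risk 1, noise 0, and 1,000 cases plus 1,000 controls.
#'
#' @param n_pool haplotypes in the source pool.
#' @param n_sites segregating sites per haplotype.
#' @param n_causal number of planted causal sites.
#' @param risk probability that the phenotype equals the causal
#'   expression's output (1 = deterministic phenotypes).
#' @param noise per-allele flip probability applied to the sampled
#'   genotype matrix.
#' @param n_cases,n_controls individuals sampled per class.
#' @param expression_shape operator policy for the planted expression:
#'   `"or"` (default: pure disjunction, the dominant genetic model in
#'   which every causal site independently confers risk — the regime
#'   whose identified-causal counts scale with the number of causal
#'   sites), `"dnf"` (causal sites partitioned into interaction units of
#'   1-3 sites, AND within a unit, OR across units — the forest structure
#'   itself; use for many causal sites, where a pure disjunction cannot
#'   keep the case prevalence below 95%), `"and"` (pure conjunction), or
#'   `"random"` (AND/OR uniform per internal node; deep AND branches
#'   typically leave most causal sites without any marginal signal).
#' @param allow_negation may the planted expression contain negated
#'   literals? Default `FALSE`: the causal model is mutation-driven.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pool = 40000L, n_sites = 1000L, n_causal = 10L,
                       risk = 1, noise = 0, n_cases = 1000L,
                       n_controls = 1000L, expression_shape = "or",
                       allow_negation = FALSE) {
  expression_shape <- match.arg(expression_shape,
                                c("or", "dnf", "and", "random"))
  stopifnot(risk >= 0, risk <= 1, noise >= 0, noise <= 1,
            n_causal >= 1, n_causal <= n_sites,
            n_cases + n_controls <= n_pool)
  structure(list(n_pool = as.integer(n_pool), n_sites = as.integer(n_sites),
                 n_causal = as.integer(n_causal), risk = risk, noise = noise,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 expression_shape = expression_shape,
                 allow_negation = isTRUE(allow_negation)),
            class = "sim_config")
}

## derived-allele counts under the neutral site-frequency spectrum
sfs_counts <- function(n_sites, n_pool) {
  i <- seq_len(n_pool - 1L)
  sample(i, n_sites, replace = TRUE, prob = 1 / i)
}

#' Simulate a pool of haplotypes
#'
#' Generates a binary haplotype matrix with every site segregating. Each
#' site's derived-allele count is drawn from the neutral site-frequency
#' spectrum, \eqn{P(\mathrm{count} = i) \propto 1/i} for
#' \eqn{i \in [1, n_{pool} - 1]}, and the carriers are placed uniformly;
#' sites are independent (no linkage disequilibrium).
#'
#' @param n_pool number of haplotypes (rows).
#' @param n_sites number of segregating sites (columns).
#' @return Integer 0/1 matrix `n_pool x n_sites`; every column has at
#'   least one mutant and one wild-type allele.
#' @export
simulate_haplotypes <- function(n_pool, n_sites) {
  counts <- sfs_counts(n_sites, n_pool)
  H <- matrix(0L, n_pool, n_sites)
  for (j in seq_len(n_sites)) {
    H[sample.int(n_pool, counts[j]), j] <- 1L
  }
  H
}

#' Plant a causal Boolean expression
#'
#' Builds a random logic tree whose leaf set is exactly `causal_indices`
#' (each site once), with AND/OR drawn uniformly at each internal node.
#' When `haplotypes` are supplied, a case-prevalence guard resamples the
#' shape until between 5% and 95% of the pool evaluates to 1, so that both
#' classes exist after phenotype assignment.
#'
#' @param causal_indices SNP column indices of the causal sites.
#' @param haplotypes optional pool matrix for the prevalence guard.
#' @param shape operator policy: `"random"`, `"and"`, `"or"`, or `"dnf"`
#'   (OR of AND-clauses of 1-3 sites).
#' @param allow_negation may leaves be negated? Default `FALSE`.
#' @param max_tries resampling budget for the prevalence guard.
#' @return A `logic_tree` whose distinct leaf SNPs equal `causal_indices`.
#' @export
plant_expression <- function(causal_indices, haplotypes = NULL,
                             shape = "random", allow_negation = FALSE,
                             max_tries = 1000L) {
  shape <- match.arg(shape, c("random", "and", "or", "dnf"))
  for (i in seq_len(max_tries)) {
    tree <- if (shape == "dnf") {
      random_dnf_tree(causal_indices, allow_negation)
    } else {
      random_tree(n_snps = max(causal_indices), snps = causal_indices,
                  allow_negation = allow_negation, op = shape)
    }
    if (is.null(haplotypes)) return(tree)
    prev <- mean(eval_tree_rows(tree, haplotypes))
    if (prev >= 0.05 && prev <= 0.95) return(tree)
  }
  stop("could not plant an expression with case prevalence in [5%, 95%] ",
       "after ", max_tries, " draws; try a different number of causal sites",
       call. = FALSE)
}

## OR of AND-clauses: causal sites partitioned into units of 1-3 sites
random_dnf_tree <- function(causal_indices, allow_negation = FALSE) {
  idx <- sample(as.integer(causal_indices))
  clauses <- list()
  while (length(idx) > 0L) {
    k <- sample.int(min(3L, length(idx)), 1L)
    clauses[[length(clauses) + 1L]] <- idx[seq_len(k)]
    idx <- idx[-seq_len(k)]
  }
  build_clause <- function(snps) {
    negs <- if (allow_negation) stats::runif(length(snps)) < 0.5 else
      rep(FALSE, length(snps))
    node <- lt_leaf(snps[1L], negs[1L])
    for (i in seq_along(snps)[-1L]) {
      node <- lt_node("and", node, lt_leaf(snps[i], negs[i]))
    }
    node
  }
  node <- build_clause(clauses[[1L]])
  for (i in seq_along(clauses)[-1L]) {
    node <- lt_node("or", node, build_clause(clauses[[i]]))
  }
  new_logic_tree(node)
}

#' Assign phenotypes from a causal expression at a given risk level
#'
#' Each individual's phenotype equals the expression output with
#' probability `risk` and its complement otherwise; `risk = 1` gives
#' deterministic phenotypes.
#'
#' @param haplotypes binary matrix.
#' @param expression a `logic_tree`.
#' @param risk agreement probability in `[0, 1]`.
#' @return Integer 0/1 phenotype vector.
#' @export
assign_phenotypes <- function(haplotypes, expression, risk) {
  stopifnot(risk >= 0, risk <= 1)
  e <- eval_tree_rows(expression, haplotypes)
  agree <- stats::rbinom(length(e), 1L, risk)
  as.integer(ifelse(agree == 1L, e, 1L - e))
}

#' Add allele-flip noise to a genotype matrix
#'
#' Flips each entry independently (wild type to mutant or back) with
#' probability `noise`. In the simulation pipeline this is applied after
#' case/control sampling.
#'
#' @param genotypes binary matrix.
#' @param noise flip probability in `[0, 1]`.
#' @return The perturbed binary matrix.
#' @export
add_noise <- function(genotypes, noise) {
  stopifnot(noise >= 0, noise <= 1)
  if (noise == 0) return(genotypes)
  flips <- matrix(stats::rbinom(length(genotypes), 1L, noise),
                  nrow(genotypes))
  out <- abs(genotypes - flips)
  storage.mode(out) <- "integer"
  out
}

#' Sample a balanced case-control dataset from a phenotyped pool
#'
#' Draws `n_cases` rows uniformly without replacement among cases and
#' `n_controls` among controls, then shuffles the output rows.
#'
#' @param haplotypes pool matrix.
#' @param phenotypes pool phenotype vector.
#' @param n_cases,n_controls counts to sample per class.
#' @return A list with `genotypes`, `phenotype`, and `pool_rows` (the
#'   sampled pool row indices, in output order).
#' @export
sample_case_control <- function(haplotypes, phenotypes, n_cases, n_controls) {
  cases <- which(phenotypes == 1L)
  controls <- which(phenotypes == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop("pool contains ", length(cases), " cases and ", length(controls),
         " controls; need ", n_cases, " and ", n_controls,
         " - use a larger pool or a different expression", call. = FALSE)
  }
  rows <- sample(c(sample(cases, n_cases), sample(controls, n_controls)))
  list(genotypes = haplotypes[rows, , drop = FALSE],
       phenotype = phenotypes[rows], pool_rows = rows)
}

#' Simulate a complete case-control dataset with a planted interaction
#'
#' Runs the full protocol: simulate the haplotype pool, pick the causal
#' sites, plant a Boolean expression over them (prevalence-guarded),
#' assign phenotypes at the configured risk, sample a balanced
#' case-control dataset, and add allele noise to the sampled genotypes.
#'
#' Two equivalent generation paths are available. `method = "subsample"`
#' (default) materializes the full pool only at the causal sites and draws
#' each non-causal site's sampled-row genotypes directly by hypergeometric
#' subsampling of its pool allele count; because sites are independent and
#' the sampled rows depend only on the causal columns, this is
#' distributionally identical to `method = "full"`, which materializes the
#' whole pool matrix, at a fraction of the memory and time.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; seeded runs are fully reproducible.
#' @param method `"subsample"` (fast, default) or `"full"` (materialize the
#'   entire pool).
#' @return An object of class `sim_dataset`: a list with `data` (tibble of
#'   SNP columns `X1..XN` plus `phenotype`), `genotypes`, `phenotype`,
#'   `causal_indices`, `truth_tree`, and `config`.
#' @export
simulate_epistasis <- function(config = sim_config(), seed = NULL,
                               method = c("subsample", "full")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config

  ## The causal-site set and the expression shape are rejection-sampled
  ## together until the planted expression's case prevalence in the pool
  ## lies in [5%, 95%] (rare sites alone can make any shape
  ## unsatisfiable); if the drawn pool itself carries no workable site
  ## set (e.g. no common sites for a conjunction), the pool is redrawn.
  draw_planted <- function(get_cols) {
    for (i in seq_len(200L)) {
      causal <- sort(sample.int(cfg$n_sites, cfg$n_causal))
      Hc <- get_cols(causal)
      tree <- tryCatch(
        plant_expression(seq_len(cfg$n_causal), Hc,
                         shape = cfg$expression_shape,
                         allow_negation = cfg$allow_negation, max_tries = 20L),
        error = function(e) NULL)
      if (!is.null(tree)) return(list(causal = causal, tree = tree, Hc = Hc))
    }
    NULL
  }

  if (method == "full") {
    planted <- NULL
    for (try_pool in seq_len(25L)) {
      H <- simulate_haplotypes(cfg$n_pool, cfg$n_sites)
      planted <- draw_planted(function(causal) H[, causal, drop = FALSE])
      if (!is.null(planted)) break
    }
    if (is.null(planted)) stop(no_plant_msg, call. = FALSE)
    causal <- planted$causal
    truth <- relabel_leaves(planted$tree, causal)
    y_pool <- assign_phenotypes(H, truth, cfg$risk)
    samp <- sample_case_control(H, y_pool, cfg$n_cases, cfg$n_controls)
    X <- samp$genotypes
  } else {
    planted <- NULL
    for (try_pool in seq_len(25L)) {
      counts <- sfs_counts(cfg$n_sites, cfg$n_pool)
      planted <- draw_planted(function(causal) {
        Hc <- matrix(0L, cfg$n_pool, cfg$n_causal)
        for (jj in seq_along(causal)) {
          Hc[sample.int(cfg$n_pool, counts[causal[jj]]), jj] <- 1L
        }
        Hc
      })
      if (!is.null(planted)) break
    }
    if (is.null(planted)) stop(no_plant_msg, call. = FALSE)
    causal <- planted$causal
    Hc <- planted$Hc
    truth <- relabel_leaves(planted$tree, causal)
    e <- eval_tree_rows(planted$tree, Hc)
    agree <- stats::rbinom(length(e), 1L, cfg$risk)
    y_pool <- as.integer(ifelse(agree == 1L, e, 1L - e))
    samp_rows <- {
      cases <- which(y_pool == 1L)
      controls <- which(y_pool == 0L)
      if (length(cases) < cfg$n_cases || length(controls) < cfg$n_controls) {
        stop("pool contains ", length(cases), " cases and ", length(controls),
             " controls; need ", cfg$n_cases, " and ", cfg$n_controls,
             call. = FALSE)
      }
      sample(c(sample(cases, cfg$n_cases), sample(controls, cfg$n_controls)))
    }
    M <- length(samp_rows)
    X <- matrix(0L, M, cfg$n_sites)
    X[, causal] <- Hc[samp_rows, , drop = FALSE]
    noncausal <- setdiff(seq_len(cfg$n_sites), causal)
    for (j in noncausal) {
      # hypergeometric subsample of the site's pool allele count
      k <- stats::rhyper(1L, counts[j], cfg$n_pool - counts[j], M)
      if (k > 0L) X[sample.int(M, k), j] <- 1L
    }
    samp <- list(phenotype = y_pool[samp_rows])
  }

  X <- add_noise(X, cfg$noise)
  colnames(X) <- paste0("X", seq_len(cfg$n_sites))
  data <- tibble::as_tibble(as.data.frame(X))
  data$phenotype <- samp$phenotype

  structure(list(data = data, genotypes = X, phenotype = samp$phenotype,
                 causal_indices = causal, truth_tree = truth,
                 config = cfg, seed = seed),
            class = "sim_dataset")
}

no_plant_msg <- paste0(
  "could not plant an expression with case prevalence in [5%, 95%]; ",
  "try a different number of causal sites or expression shape")

## relabel a tree's leaf SNPs: leaf j becomes map[j]
relabel_leaves <- function(tree, map) {
  if (is_leaf(tree)) {
    tree$snp <- as.integer(map[tree$snp])
    return(tree)
  }
  tree$left <- relabel_leaves(tree$left, map)
  tree$right <- relabel_leaves(tree$right, map)
  tree
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  cat("  causal sites: ", paste(x$causal_indices, collapse = ", "), "\n",
      sep = "")
  cat("  truth: ", format(x$truth_tree), "\n", sep = "")
  cat("  risk ", x$config$risk, ", noise ", x$config$noise, "\n", sep = "")
  invisible(x)
}
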