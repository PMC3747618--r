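# Independent truth-table oracle: evaluate the tree's infix text as an R
# logical expression over the assignment matrix (no shared code with the
# package's evaluators beyond the serialized text).
oracle_eval <- function(tree, X) {
  txt <- format(tree)
  env <- new.env()
  for (j in seq_len(ncol(X))) assign(paste0("X", j), X[, j] == 1L, envir = env)
  as.integer(eval(parse(text = txt), envir = env))
}

# all binary assignments over n variables, one row each
assignments <- function(n) {
  A <- as.matrix(expand.grid(rep(list(0:1), n)))
  storage.mode(A) <- "integer"
  colnames(A) <- NULL
  A
}

# small deterministic dataset: planted single conjunction, no noise
tiny_sim <- function(seed, n_sites = 12, n_causal = 2, n = 300,
                     shape = "or", n_pool = 4000) {
  simulate_epistasis(
    sim_config(n_pool = n_pool, n_sites = n_sites, n_causal = n_causal,
               n_cases = n / 2, n_controls = n / 2, expression_shape = shape),
    seed = seed)
}
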