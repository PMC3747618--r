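#' Accuracy metrics for a selected SNP set against a planted truth
#'
#' Given the SNP set selected by a fit and the planted causal set, several
#' error-rate conventions are in circulation; all are computed side by
#' side and clearly labeled:
#'
#' * `type_i` - missed causal sites as a percentage of all sites
#'   (`100 * |causal \ selected| / n_sites`). This is the convention whose
#'   algebra reproduces published type-I columns of this kind of
#'   simulation study row for row.
#' * `type_i_literal` - missed causal sites divided by the number of
#'   selected SNPs (`100 * |causal \ selected| / |selected|`); can exceed
#'   100%.
#' * `type_ii` - wrongly selected non-causal SNPs among all selected SNPs
#'   (`100 * |selected \ causal| / |selected|`; a false-discovery
#'   percentage).
#' * `miss_rate` - missed causal over causal
#'   (`100 * |causal \ selected| / |causal|`; the conventional type-II /
#'   miss rate).
#' * `n_identified` - `|selected` \eqn{\cap} `causal|`.
#'
#' @param selected integer vector of selected SNP indices (non-empty; an
#'   empty selection yields `NA` rates with a warning).
#' @param causal integer vector of planted causal indices.
#' @param n_sites total number of SNP sites N.
#' @return A one-row tibble with the columns above plus `n_selected` and
#'   `n_causal`.
#' @examples
#' type_errors(c(1, 2, 3), c(1, 2), n_sites = 100)
#' @export
type_errors <- function(selected, causal, n_sites) {
  selected <- unique(as.integer(selected))
  causal <- unique(as.integer(causal))
  n_id <- length(intersect(selected, causal))
  missed <- length(setdiff(causal, selected))
  wrong <- length(setdiff(selected, causal))
  if (length(selected) == 0L) {
    warning("empty selection: per-selected rates undefined", call. = FALSE)
    lit <- t2 <- NA_real_
  } else {
    lit <- 100 * missed / length(selected)
    t2 <- 100 * wrong / length(selected)
  }
  tibble::tibble(
    type_i = 100 * missed / n_sites,
    type_i_literal = lit,
    type_ii = t2,
    miss_rate = 100 * missed / length(causal),
    n_identified = n_id,
    n_selected = length(selected),
    n_causal = length(causal))
}

#' Number of successfully identified causal sites
#'
#' @inheritParams type_errors
#' @return `|selected` \eqn{\cap} `causal|` as an integer.
#' @export
count_identified <- function(selected, causal) {
  length(intersect(unique(as.integer(selected)), unique(as.integer(causal))))
}

#' Evaluate a fitted swarm against the planted truth
#'
#' Computes [type_errors()] for the fit's selected SNP set (swarm union by
#' default, or global-best only).
#'
#' @param fit an `fslr_fit`.
#' @param truth a `sim_dataset` (or a list with `causal_indices`).
#' @param selection `"union"` or `"best"`; see [selected_snps()].
#' @return A one-row tibble of metrics.
#' @export
evaluate_fit <- function(fit, truth, selection = c("union", "best")) {
  selection <- match.arg(selection)
  sel <- selected_snps(fit, selection)
  out <- type_errors(sel, truth$causal_indices, n_sites = fit$n_snps)
  out$selection <- selection
  out
}

#' Repeated-simulation experiment over a configuration grid
#'
#' For every row of `grid` (columns among `n_causal`, `risk`, `noise`;
#' missing columns take the [sim_config()] defaults), runs `n_repeats`
#' independent simulate-fit-evaluate cycles and averages the accuracy
#' metrics. Repeat seeds are derived deterministically from `seed`, so the
#' whole table is reproducible.
#'
#' @param grid data frame of simulation settings, one row per cell.
#' @param n_repeats repeats per cell.
#' @param seed master seed.
#' @param sim_defaults a [sim_config()] supplying the non-varying
#'   simulation parameters.
#' @param control an [fslr_control()] passed to [fslr()].
#' @param selection selection rule passed to [evaluate_fit()].
#' @param verbose print one line per completed repeat.
#' @return A tibble of class `fslr_experiment`, one row per cell, with the
#'   averaged metrics (`type_i`, `type_ii`, `n_identified`, ...), the
#'   number of completed repeats, and the per-repeat records in
#'   `attr(, "repeats")`. Failed repeats are recorded and the cell marked
#'   partial (`n_ok < n_repeats`).
#' @export
run_experiment <- function(grid, n_repeats = 10L, seed = 1L,
                           sim_defaults = sim_config(),
                           control = fslr_control(),
                           selection = "union", verbose = FALSE) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) stop("empty configuration grid", call. = FALSE)
  per_repeat <- list()
  cells <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    reps <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      rep_seed <- (seed * 997L + g * 131L + r) %% .Machine$integer.max
      res <- tryCatch({
        cfg <- sim_defaults
        for (fld in intersect(names(grid), c("n_causal", "risk", "noise"))) {
          cfg[[fld]] <- grid[[fld]][g]
        }
        cfg <- do.call(sim_config, unclass(cfg))
        sim <- simulate_epistasis(cfg, seed = rep_seed)
        fit <- fslr(sim$data, control = control, seed = rep_seed + 1L)
        ev <- evaluate_fit(fit, sim, selection = selection)
        ev$cell <- g
        ev$repeat_id <- r
        ev$error <- NA_character_
        ev
      }, error = function(e) {
        tibble::tibble(cell = g, repeat_id = r, error = conditionMessage(e))
      })
      if (verbose) {
        message(sprintf("cell %d repeat %d: %s", g, r,
                        if (is.na(res$error[1])) "ok" else res$error[1]))
      }
      reps[[r]] <- res
    }
    reps <- dplyr::bind_rows(reps)
    per_repeat[[g]] <- reps
    ok <- reps[is.na(reps$error), , drop = FALSE]
    cell <- grid[g, , drop = FALSE]
    cell$n_repeats <- n_repeats
    cell$n_ok <- nrow(ok)
    for (m in c("type_i", "type_i_literal", "type_ii", "miss_rate",
                "n_identified", "n_selected")) {
      cell[[m]] <- if (nrow(ok)) mean(ok[[m]], na.rm = TRUE) else NA_real_
    }
    cells[[g]] <- cell
  }
  out <- dplyr::bind_rows(cells)
  attr(out, "repeats") <- dplyr::bind_rows(per_repeat)
  class(out) <- c("fslr_experiment", class(out))
  out
}
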