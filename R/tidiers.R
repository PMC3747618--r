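#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted fish-swarm logic regression
#'
#' `tidy()` returns one row per SNP that appears in the school's final
#' models, with its importance value, selection probability, and whether it
#' belongs to the global-best model. `glance()` returns a one-row summary
#' of the fit.
#'
#' @param x an `fslr_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.fslr_fit <- function(x, ...) {
  sel <- x$selected$union
  out <- x$importance[x$importance$snp %in% sel, , drop = FALSE]
  out$snp_id <- x$snp_ids[out$snp]
  out$in_best <- out$snp %in% x$selected$best
  dplyr::arrange(out[c("snp", "snp_id", "value", "prob", "in_best")],
                 dplyr::desc(.data$value), .data$snp)
}

#' @rdname tidy.fslr_fit
#' @export
glance.fslr_fit <- function(x, ...) {
  tibble::tibble(
    best_score = x$best$score,
    prop_explained = x$best$score / x$n_obs,
    best_size = tree_size(x$best$tree),
    n_selected_union = length(x$selected$union),
    n_selected_best = length(x$selected$best),
    iterations = x$iterations,
    converged = x$converged,
    n_fish = x$control$n_fish,
    n_obs = x$n_obs,
    n_snps = x$n_snps)
}

#' Plot methods for swarm fits and experiments
#'
#' `autoplot()` on an `fslr_fit` draws the top SNP importances (bar chart,
#' best-model SNPs highlighted); on an `fslr_experiment` it draws the
#' averaged error rates against the varied simulation parameter.
#'
#' @param object an `fslr_fit` or `fslr_experiment`.
#' @param top_n number of SNPs to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fslr_fit <- function(object, top_n = 20L, ...) {
  df <- tidy(object)
  df <- utils::head(df, top_n)
  df$snp_id <- factor(df$snp_id, levels = rev(df$snp_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$snp_id,
                                   fill = .data$in_best)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "out-of-bag importance V(j)", y = NULL,
                  fill = "in best model",
                  title = "SNP importance (fish-swarm logic regression)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fslr_fit
#' @export
autoplot.fslr_experiment <- function(object, ...) {
  xvar <- intersect(c("n_causal", "risk", "noise"), names(object))
  xvar <- xvar[vapply(xvar, function(v) length(unique(object[[v]])) > 1L,
                      TRUE)][1]
  if (is.na(xvar)) xvar <- intersect(c("n_causal", "risk", "noise"),
                                     names(object))[1]
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c(xvar, "type_i", "type_ii", "miss_rate")],
    cols = c("type_i", "type_ii", "miss_rate"),
    names_to = "metric", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$rate,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "error rate (%)",
                  title = "Simulation-study accuracy") +
    ggplot2::theme_minimal()
}
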