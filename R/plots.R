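#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot posterior coefficient intervals
#'
#' Posterior means and equal-tailed credible intervals for the top `k` genes
#' by |posterior mean|, ordered by rank. The default view for deciding where
#' the signal stops.
#'
#' @param object A `bnr_fit`.
#' @param k Number of top genes to show (default 25, capped at p).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bnr_fit
#' @export
autoplot.bnr_fit <- function(object, k = 25, ...) {
  ranking <- object$ranking
  k <- min(k, nrow(ranking))
  df <- dplyr::slice_min(ranking, .data$rank, n = k)
  df$gene_id <- stats::reorder(df$gene_id, -df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$post_mean, y = .data$gene_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.25, colour = "grey40") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = "posterior mean coefficient (credible interval)",
                  y = NULL,
                  title = paste0("Top ", k, " genes by |posterior mean|")) +
    ggplot2::theme_minimal()
}

#' Trace plots of the chain
#'
#' Log joint posterior and the scalar parameters (sigma2, r, lambda2) over
#' iterations; the log-joint panel includes burn-in, the parameter panels show
#' retained draws. A flat, rapidly mixing log-joint trace after burn-in is
#' the first thing to check before trusting the ranking.
#'
#' @param fit A `bnr_fit`.
#' @return A ggplot object, faceted by parameter.
#' @export
plot_trace <- function(fit) {
  kept <- seq.int(fit$control$burn_in + 1, fit$control$n_iter,
                  by = fit$control$thin)
  df <- dplyr::bind_rows(
    tibble::tibble(iteration = seq_along(fit$log_joint_trace),
                   value = fit$log_joint_trace, parameter = "log joint"),
    tibble::tibble(iteration = kept, value = fit$draws$sigma2,
                   parameter = "sigma2"),
    tibble::tibble(iteration = kept, value = fit$draws$r, parameter = "r"),
    tibble::tibble(iteration = kept, value = fit$draws$lambda2,
                   parameter = "lambda2")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}
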