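#' Posterior gene ranking from retained draws
#'
#' Per-gene posterior mean, standard deviation, and equal-tailed credible
#' interval from the retained draws, ranked by |posterior mean| (largest
#' first). Ties are broken lexicographically by gene identifier so rankings
#' are deterministic across runs and platforms.
#'
#' @param fit A [bnr_fit()] object (or anything with a `draws$beta` matrix
#'   whose columns are named by gene).
#' @param level Credible level in (0, 1); default the fit's `ci_level`.
#' @return A tibble with columns `gene_id`, `rank`, `post_mean`, `post_sd`,
#'   `ci_lower`, `ci_upper`, ordered by `rank`.
#' @export
summarize_chain <- function(fit, level = NULL) {
  draws <- fit$draws$beta
  if (is.null(draws) || nrow(draws) < 2) {
    stop("Need at least 2 retained draws to summarize.", call. = FALSE)
  }
  if (is.null(level)) level <- fit$ci_level %||% 0.95
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- tibble::tibble(
    gene_id = colnames(draws),
    post_mean = unname(colMeans(draws)),
    post_sd = unname(apply(draws, 2, stats::sd)),
    ci_lower = unname(qs[1, ]),
    ci_upper = unname(qs[2, ])
  )
  out <- out[order(-abs(out$post_mean), out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  out[, c("gene_id", "rank", "post_mean", "post_sd", "ci_lower", "ci_upper")]
}

#' Select the top-ranked genes
#'
#' The first k gene identifiers by |posterior mean coefficient| — the paper's
#' selection rule (k = 50 there). Accepts a fitted model or a ranking tibble.
#' For k1 <= k2 the k1-selection is always a prefix of the k2-selection.
#'
#' @param x A `bnr_fit` or a ranking tibble from [summarize_chain()].
#' @param k Number of genes, 1 <= k <= p.
#' @return Character vector of k gene identifiers in rank order.
#' @export
select_top_k <- function(x, k = 50) {
  ranking <- if (inherits(x, "bnr_fit")) x$ranking else x
  p <- nrow(ranking)
  if (k < 1 || k > p) {
    stop("`k` must be between 1 and ", p, ".", call. = FALSE)
  }
  ranking$gene_id[order(ranking$rank)][seq_len(k)]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted network-constrained model
#'
#' Broom-style per-gene summary: one row per coefficient with its posterior
#' mean (`estimate`), posterior sd (`std.error`), equal-tailed credible bounds
#' (`conf.low`, `conf.high`) and selection `rank` by |estimate|.
#'
#' @param x A `bnr_fit`.
#' @param conf.level Credible level; defaults to the fit's `ci_level`.
#' @param ... Unused.
#' @return A tibble ordered by `rank`.
#' @method tidy bnr_fit
#' @export
tidy.bnr_fit <- function(x, conf.level = NULL, ...) {
  ranking <- summarize_chain(x, level = conf.level)
  tibble::tibble(term = ranking$gene_id,
                 estimate = ranking$post_mean,
                 std.error = ranking$post_sd,
                 conf.low = ranking$ci_lower,
                 conf.high = ranking$ci_upper,
                 rank = ranking$rank)
}

#' One-row summary of a fitted network-constrained model
#'
#' @param x A `bnr_fit`.
#' @param ... Unused.
#' @return A tibble with the data dimensions, chain settings, and posterior
#'   means of sigma2, r and lambda2, plus the mean retained log joint.
#' @method glance bnr_fit
#' @export
glance.bnr_fit <- function(x, ...) {
  kept <- seq.int(x$control$burn_in + 1, x$control$n_iter)
  tibble::tibble(
    n = length(x$sample_ids),
    p = length(x$gene_ids),
    family = x$family,
    n_iter = x$control$n_iter,
    burn_in = x$control$burn_in,
    n_draws = nrow(x$draws$beta),
    sigma2 = mean(x$draws$sigma2),
    r = mean(x$draws$r),
    lambda2 = mean(x$draws$lambda2),
    mean_log_joint = mean(x$log_joint_trace[kept])
  )
}

#' Prediction mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
pmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1) {
    stop("`y_true` and `y_pred` must be equal-length, nonempty.",
         call. = FALSE)
  }
  mean((y_true - y_pred)^2)
}

#' Classification accuracy at a probability threshold
#'
#' @param y_true 0/1 vector.
#' @param p_pred Predicted probabilities, same length.
#' @param threshold Classify as 1 when `p_pred > threshold` (default 0.5).
#' @return Fraction of correct classifications.
#' @export
acc <- function(y_true, p_pred, threshold = 0.5) {
  if (length(y_true) != length(p_pred)) {
    stop("Length mismatch between `y_true` and `p_pred`.", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("`y_true` must be coded 0/1.", call. = FALSE)
  }
  mean(as.integer(p_pred > threshold) == y_true)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the fraction of (positive, negative) pairs
#' in which the positive sample receives the higher score, ties counted 1/2.
#' Invariant to strictly monotone transformations of the scores.
#'
#' @param y_true 0/1 vector with both classes present.
#' @param p_pred Scores or probabilities, same length.
#' @return AUC in [0, 1].
#' @export
auc <- function(y_true, p_pred) {
  if (length(y_true) != length(p_pred)) {
    stop("Length mismatch between `y_true` and `p_pred`.", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || length(unique(y_true)) < 2) {
    stop("`y_true` must contain both classes coded 0/1.", call. = FALSE)
  }
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  ranks <- rank(p_pred, ties.method = "average")
  (sum(ranks[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
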