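#' Fit the Bayesian network-constrained regression model
#'
#' Estimates a hierarchical regression of a response on standardized gene
#' expression, with a coefficient prior
#' \eqn{\beta \sim N(0, (\sigma^2/r) \Lambda^{-1})},
#' \eqn{\Lambda = \mathrm{diag}(1/\tau^2) + L}, where L is the normalized
#' Laplacian of a gene-interaction network. The local scales tau_j^2 induce
#' l1-type sparsity; the Laplacian term encourages coefficients of interacting
#' genes to vary smoothly over the network. With no network (`network = NULL`,
#' so L = 0) the model reduces to the Bayesian lasso form; with L equal to the
#' identity, to the Bayesian elastic net form. Estimation is by Gibbs
#' sampling: all full conditionals are closed form (see [gibbs-draws]).
#' Binary (0/1) responses use probit data augmentation ([draw_latent()]).
#'
#' @param expression Samples x genes matrix, or a data frame whose first
#'   column holds sample identifiers and remaining columns one gene each.
#' @param response Length-n numeric vector (continuous, or 0/1 for
#'   `family = "binary"`), or a two-column data frame `(sample_id, value)`
#'   that is aligned to the expression samples by identifier.
#' @param network A [gene_network()], an edge data frame (`from`, `to`,
#'   optional `weight`), or `NULL` for no network (L = 0). The network is
#'   aligned to the expression gene set: genes missing from the network become
#'   isolated nodes, network nodes missing from the expression are dropped.
#' @param family `"gaussian"` or `"binary"`.
#' @param hyper A [hyperparameters()] object (all six default to 0.01).
#' @param control A [chain_control()] object; the default runs 6000
#'   iterations and retains the second half.
#' @param seed Integer seed making the chain bitwise reproducible.
#' @param ci_level Credible-interval level for summaries (default 0.95).
#' @param gig_index `"derived"` (default) samples the tau2 conditional implied
#'   by the joint posterior (GIG index 1); `"printed"` uses index 1/2, the
#'   inverse-Gaussian-style form familiar from lasso-type samplers.
#' @param fix_sigma2 Fix the latent-scale variance at 1 in the probit chain
#'   (the conventional identifiability constraint). Default `FALSE`: sigma2
#'   keeps its inverse-gamma layer in both families.
#' @param progress Emit a message every 1000 iterations.
#' @return An object of class `bnr_fit` with the retained draws, the log-joint
#'   trace, posterior summaries (see [tidy.bnr_fit()]), and the
#'   standardization constants needed by [predict.bnr_fit()].
#' @examples
#' sim <- simulate_pathway_data(n_samples = 40, n_pathways = 2,
#'                              genes_per_pathway = 3,
#'                              n_active_pathways = 1, seed = 1)
#' fit <- bnr_fit(sim$expression, sim$response, sim$network,
#'                control = chain_control(200), seed = 1)
#' tidy(fit)
#' @export
bnr_fit <- function(expression, response, network = NULL,
                    family = c("gaussian", "binary"),
                    hyper = hyperparameters(), control = chain_control(),
                    seed = NULL, ci_level = 0.95,
                    gig_index = c("derived", "printed"),
                    fix_sigma2 = FALSE, progress = FALSE) {
  family <- match.arg(family)
  gig_index <- switch(match.arg(gig_index), derived = 1, printed = 0.5)
  parsed <- parse_expression(expression)
  y <- align_response(response, parsed$sample_ids)
  if (family == "binary" && !all(y %in% c(0, 1))) {
    stop("`family = \"binary\"` requires a 0/1 response.", call. = FALSE)
  }

  std <- standardize_expression(parsed$X)
  L <- resolve_laplacian(network, parsed$gene_ids)

  y_center <- 0
  if (family == "gaussian") {
    y_center <- mean(y)
    y <- y - y_center
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  chain <- run_gibbs(std$X, y, L, hp = hyper, control = control,
                     family = family, gig_index = gig_index,
                     fix_sigma2 = fix_sigma2, progress = progress)

  fit <- structure(list(
    draws = chain$draws,
    log_joint_trace = chain$log_joint_trace,
    control = control,
    family = family,
    hyper = hyper,
    gene_ids = parsed$gene_ids,
    sample_ids = parsed$sample_ids,
    center = std$center,
    scale = std$scale,
    y_center = y_center,
    ci_level = ci_level,
    seed = seed,
    X = std$X,
    y = y + y_center
  ), class = "bnr_fit")
  fit$ranking <- summarize_chain(fit, level = ci_level)
  fit
}

# expression input -> list(X, gene_ids, sample_ids)
parse_expression <- function(expression) {
  if (is.data.frame(expression)) {
    first <- expression[[1]]
    if (is.character(first) || is.factor(first)) {
      sample_ids <- as.character(first)
      X <- as.matrix(expression[, -1, drop = FALSE])
    } else {
      sample_ids <- rownames(expression)
      X <- as.matrix(expression)
    }
  } else {
    X <- as.matrix(expression)
    sample_ids <- rownames(X)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("G", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("Need at least 2 samples.", call. = FALSE)
  if (anyDuplicated(colnames(X))) {
    stop("Duplicate gene identifiers in expression matrix.", call. = FALSE)
  }
  rownames(X) <- sample_ids
  list(X = X, gene_ids = colnames(X), sample_ids = sample_ids)
}

align_response <- function(response, sample_ids) {
  if (is.data.frame(response)) {
    if (ncol(response) == 1) {
      y <- as.numeric(response[[1]])
    } else {
      ids <- as.character(response[[1]])
      extra <- setdiff(ids, sample_ids)
      missing <- setdiff(sample_ids, ids)
      if (length(extra) || length(missing)) {
        stop("Sample identifiers do not align between expression and ",
             "response. Missing from response: ",
             paste(utils::head(missing, 5), collapse = ", "),
             "; unknown in response: ",
             paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
      }
      y <- as.numeric(response[[2]])[match(sample_ids, ids)]
    }
  } else {
    y <- as.numeric(response)
  }
  if (length(y) != length(sample_ids)) {
    stop("Response has ", length(y), " values but expression has ",
         length(sample_ids), " samples.", call. = FALSE)
  }
  if (anyNA(y)) stop("Response contains missing values.", call. = FALSE)
  y
}

resolve_laplacian <- function(network, gene_ids) {
  p <- length(gene_ids)
  if (is.null(network)) {
    L <- matrix(0, p, p, dimnames = list(gene_ids, gene_ids))
    return(L)
  }
  if (is.data.frame(network)) network <- gene_network(network)
  if (!inherits(network, "gene_network")) {
    stop("`network` must be a gene_network, an edge data frame, or NULL.",
         call. = FALSE)
  }
  unclass(normalized_laplacian(align_network(network, gene_ids)))
}

#' @export
print.bnr_fit <- function(x, ...) {
  cat("<bnr_fit> ", x$family, " model: ", length(x$sample_ids), " samples, ",
      length(x$gene_ids), " genes\n", sep = "")
  cat("chain: ", x$control$n_iter, " iterations, burn-in ", x$control$burn_in,
      ", ", nrow(x$draws$beta), " retained draws\n", sep = "")
  cat("posterior means: sigma2 = ", signif(mean(x$draws$sigma2), 4),
      ", r = ", signif(mean(x$draws$r), 4),
      ", lambda2 = ", signif(mean(x$draws$lambda2), 4), "\n", sep = "")
  cat("top genes by |posterior mean coefficient|:\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Predict from a fitted network-constrained model
#'
#' New expression values are standardized with the training means and scales.
#' Gaussian fits return the posterior-mean linear predictor (plus the training
#' response mean); binary fits return probit probabilities
#' Phi(x' beta / sigma) at the posterior means by default, or the latent
#' linear predictor with `type = "link"`.
#'
#' @param object A `bnr_fit`.
#' @param new_expression Samples x genes data (same layout as in [bnr_fit()]).
#'   Defaults to the training expression.
#' @param type `"response"` (default) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector with one value per row of `new_expression`.
#' @export
predict.bnr_fit <- function(object, new_expression = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(new_expression)) {
    Xs <- object$X
  } else {
    parsed <- parse_expression(new_expression)
    if (!identical(parsed$gene_ids, object$gene_ids)) {
      stop("new_expression genes must match the training genes (same order).",
           call. = FALSE)
    }
    Xs <- sweep(sweep(parsed$X, 2, object$center), 2, object$scale, "/")
  }
  beta_hat <- colMeans(object$draws$beta)
  eta <- drop(Xs %*% beta_hat)
  if (object$family == "gaussian") {
    return(eta + object$y_center)
  }
  if (type == "link") return(eta)
  predict_probability(beta_hat, mean(object$draws$sigma2), Xs)
}
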