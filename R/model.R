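#' Column-standardize an expression matrix
#'
#' Centres and scales each gene (column) to mean 0 and standard deviation 1,
#' the convention under which the shrinkage prior treats all genes on a common
#' scale. The sample standard deviation (denominator n - 1) is used; set
#' `population = TRUE` for the n denominator.
#'
#' @param X Numeric matrix or data frame, samples x genes.
#' @param population Use the population (n denominator) standard deviation.
#' @return A list with `X` (standardized matrix), `center` and `scale`
#'   (named per-gene vectors for the inverse transformation).
#' @export
standardize_expression <- function(X, population = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("Expression matrix contains missing values.", call. = FALSE)
  ctr <- colMeans(X)
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  if (population) sds <- sds * sqrt((n - 1) / n)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("Constant (zero-variance) column(s): ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  list(X = Xs, center = ctr, scale = sds)
}

#' Hyperparameters of the hierarchical model
#'
#' Shape-rate parameters of the three top-level priors: `a`, `b` for the
#' inverse-gamma prior on the residual variance sigma^2; `c`, `d` for the
#' gamma prior on the global penalty weight r; `e`, `f` for the gamma prior on
#' lambda^2, the rate governing the local scales tau_j^2. All default to 0.01,
#' a vague choice that lets the data dominate.
#'
#' @param a,b,c,d,e,f Strictly positive reals.
#' @return A named list of class `bnr_hyper`.
#' @export
hyperparameters <- function(a = 0.01, b = 0.01, c = 0.01, d = 0.01,
                            e = 0.01, f = 0.01) {
  hp <- list(a = a, b = b, c = c, d = d, e = e, f = f)
  vals <- unlist(hp)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("All hyperparameters must be strictly positive and finite.",
         call. = FALSE)
  }
  structure(hp, class = "bnr_hyper")
}

#' Prior precision structure of the coefficients
#'
#' The coefficient prior is beta ~ N(0, (sigma^2 / r) Lambda^{-1}) with
#' Lambda = diag(1/tau^2) + L. The diagonal part carries the l1-type scale
#' mixture; the Laplacian part penalizes differences of degree-scaled
#' coefficients across network edges, since
#' beta' Lambda beta = sum_j beta_j^2 / tau_j^2 +
#' sum_{u ~ v} w(u,v) (beta_u / sqrt(d_u) - beta_v / sqrt(d_v))^2.
#' Lambda is positive definite for any finite positive tau^2.
#'
#' @param tau2 Length-p vector of strictly positive local scales.
#' @param L p x p normalized Laplacian (see [normalized_laplacian()]).
#' @return The p x p matrix Lambda.
#' @export
precision_matrix <- function(tau2, L) {
  L <- unclass(L)
  p <- length(tau2)
  if (!is.matrix(L) || nrow(L) != p || ncol(L) != p) {
    stop("`L` must be a ", p, " x ", p, " matrix.", call. = FALSE)
  }
  if (any(!is.finite(tau2)) || any(tau2 <= 0)) {
    stop("All tau2 entries must be finite and > 0.", call. = FALSE)
  }
  Lam <- L
  diag(Lam) <- diag(Lam) + 1 / tau2
  Lam
}

#' Log of the unnormalized joint posterior
#'
#' Sum of the Gaussian log-likelihood, the network-constrained coefficient
#' prior, the exponential-kernel prior on the local scales, and the
#' inverse-gamma / gamma hyperpriors. The coefficient prior's |Lambda|^{1/2}
#' normalizer and the tau^2 prior's |Lambda|^{-1/2} factor cancel in the sum
#' and are omitted jointly (they must never be dropped singly). Finite for
#' every valid state.
#'
#' @param state Named list with elements `beta` (length p), `sigma2`, `tau2`
#'   (length p), `r`, `lambda2`.
#' @param X Standardized n x p design matrix.
#' @param y Length-n response (for the probit chain, the current latent z).
#' @param L p x p normalized Laplacian.
#' @param hp A [hyperparameters()] object.
#' @return A single finite number (log density up to an additive constant).
#' @export
log_joint <- function(state, X, y, L, hp = hyperparameters()) {
  beta <- state$beta; sigma2 <- state$sigma2; tau2 <- state$tau2
  r <- state$r; lambda2 <- state$lambda2
  n <- length(y); p <- length(beta)
  stopifnot(sigma2 > 0, all(tau2 > 0), r > 0, lambda2 > 0)
  Lam <- precision_matrix(tau2, L)
  resid <- y - X %*% beta
  quad <- sum(beta * (Lam %*% beta))
  ll <- -n / 2 * log(2 * pi * sigma2) - sum(resid^2) / (2 * sigma2)
  lp_beta <- -p / 2 * log(2 * pi) - p / 2 * log(sigma2) + p / 2 * log(r) -
    r * quad / (2 * sigma2)
  lp_tau2 <- sum(log(lambda2 / 2) - lambda2 * tau2 / 2)
  lp_sigma2 <- hp$a * log(hp$b) - lgamma(hp$a) -
    (hp$a + 1) * log(sigma2) - hp$b / sigma2
  lp_r <- stats::dgamma(r, shape = hp$c, rate = hp$d, log = TRUE)
  lp_lambda2 <- stats::dgamma(lambda2, shape = hp$e, rate = hp$f, log = TRUE)
  ll + lp_beta + lp_tau2 + lp_sigma2 + lp_r + lp_lambda2
}

#' Network-constrained penalized least-squares objective
#'
#' The loss whose minimizer is the maximum a posteriori coefficient vector of
#' the hierarchical model (residual variance fixed, local scales integrated
#' out): residual sum of squares plus an l1 penalty and the Laplacian
#' quadratic penalty,
#' \deqn{(y - X\beta)'(y - X\beta) + r\,\lambda \|\beta\|_1 + r\,\beta' L \beta.}
#' With `L = 0` this is the lasso objective; with `L = I` the elastic net.
#'
#' @param beta Length-p coefficient vector.
#' @param X Standardized n x p design matrix.
#' @param y Length-n response.
#' @param L p x p normalized Laplacian.
#' @param r Positive weight of the combined penalty.
#' @param lam Positive weight of the l1 component.
#' @return The scalar objective value.
#' @export
penalized_objective <- function(beta, X, y, L, r, lam) {
  L <- unclass(L)
  p <- length(beta)
  if (ncol(X) != p || nrow(L) != p || ncol(L) != p || nrow(X) != length(y)) {
    stop("Dimension mismatch between beta, X, y, L.", call. = FALSE)
  }
  resid <- y - X %*% beta
  sum(resid^2) + r * lam * sum(abs(beta)) +
    r * as.numeric(crossprod(beta, L %*% beta))
}
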