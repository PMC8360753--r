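#' Latent-variable draw for the probit model
#'
#' Binary outcomes are modelled as the sign of a latent Gaussian variable
#' z_i = X_i beta + eps_i, eps_i ~ N(0, sigma2): y_i = 1 exactly when
#' z_i > 0. Given beta and sigma2 the latent conditional factorizes over
#' observations into one-sided truncated normals — z_i ~ N(X_i beta, sigma2)
#' truncated to (0, Inf) when y_i = 1 and to (-Inf, 0] when y_i = 0 — so no
#' joint multivariate truncated-normal routine is needed. Replacing y with z
#' turns every Gaussian full conditional into its probit counterpart.
#'
#' @param X Standardized n x p design matrix.
#' @param y Length-n 0/1 response.
#' @param beta Current coefficient vector.
#' @param sigma2 Current residual variance.
#' @return Length-n latent vector satisfying the sign constraints exactly.
#' @export
draw_latent <- function(X, y, beta, sigma2) {
  if (!all(y %in% c(0, 1))) {
    stop("Binary response must be coded 0/1; got values: ",
         paste(utils::head(setdiff(unique(y), c(0, 1)), 5), collapse = ", "),
         call. = FALSE)
  }
  mu <- drop(X %*% beta)
  n <- length(y)
  z <- numeric(n)
  pos <- y == 1
  sd <- sqrt(sigma2)
  if (any(pos)) z[pos] <- rtnorm(sum(pos), mu[pos], sd, lower = 0)
  if (any(!pos)) z[!pos] <- rtnorm(sum(!pos), mu[!pos], sd, upper = 0)
  z
}

#' Probit predictive probabilities
#'
#' P(y = 1 | x) = Phi(x' beta / sigma), the success probability implied by the
#' latent-Gaussian mechanism. `Xnew` must be standardized with the training
#' means and scales.
#'
#' @param beta Length-p coefficient vector (e.g. posterior mean).
#' @param sigma2 Residual variance of the latent scale.
#' @param Xnew m x p matrix of standardized predictors.
#' @return Length-m vector of probabilities in [0, 1].
#' @export
predict_probability <- function(beta, sigma2, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(beta)) {
    stop("Xnew has ", ncol(Xnew), " columns but beta has length ",
         length(beta), ".", call. = FALSE)
  }
  stats::pnorm(drop(Xnew %*% beta) / sqrt(sigma2))
}
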