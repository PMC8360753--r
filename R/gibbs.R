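#' Chain settings for the Gibbs sampler
#'
#' @param n_iter Total Gibbs iterations (default 6000).
#' @param burn_in Iterations discarded before summarizing; defaults to half of
#'   `n_iter`, i.e. the second half of the chain is retained.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return A list of class `bnr_control`.
#' @export
chain_control <- function(n_iter = 6000, burn_in = n_iter %/% 2, thin = 1) {
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (n_iter < 1 || burn_in < 0 || burn_in >= n_iter || thin < 1) {
    stop("Require 0 <= burn_in < n_iter and thin >= 1.", call. = FALSE)
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "bnr_control")
}

# conditional parameters, kept separate from the draws so that reduction
# checks (L = 0 lasso form, L = I elastic-net form) can compare them exactly

beta_conditional <- function(X, y, sigma2, tau2, r, L) {
  Lam <- precision_matrix(tau2, L)
  M <- crossprod(X) + r * Lam
  R <- tryCatch(chol(M), error = function(e) {
    stop("X'X + r*Lambda is numerically singular (reciprocal condition ",
         format(1 / kappa(M)), ").", call. = FALSE)
  })
  mu <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  list(mean = drop(mu), chol_prec = R, sigma2 = sigma2)
}

sigma2_conditional <- function(X, y, beta, tau2, r, L, hp) {
  Lam <- precision_matrix(tau2, L)
  resid <- y - X %*% beta
  quad <- sum(beta * (Lam %*% beta))
  list(shape = (length(y) + length(beta)) / 2 + hp$a,
       rate = (sum(resid^2) + r * quad) / 2 + hp$b)
}

tau2_conditional <- function(beta, sigma2, r, lambda2, gig_index = 1) {
  list(nu = gig_index, chi = r * beta^2 / sigma2, psi = lambda2)
}

r_conditional <- function(beta, sigma2, tau2, L, hp) {
  Lam <- precision_matrix(tau2, L)
  quad <- sum(beta * (Lam %*% beta))
  list(shape = length(beta) / 2 + hp$c, rate = quad / (2 * sigma2) + hp$d)
}

lambda2_conditional <- function(tau2, hp) {
  list(shape = length(tau2) + hp$e, rate = sum(tau2) / 2 + hp$f)
}

#' Full-conditional draws of the Gibbs sampler
#'
#' One exact draw from each closed-form full conditional of the hierarchical
#' network-constrained model. These are the moving parts of [bnr_fit()],
#' exported so each can be validated in isolation.
#'
#' * `draw_beta()`: multivariate normal with mean
#'   \eqn{(X'X + r\Lambda)^{-1} X'y} and covariance
#'   \eqn{\sigma^2 (X'X + r\Lambda)^{-1}}, via one Cholesky factorization.
#' * `draw_sigma2()`: inverse-gamma with shape \eqn{(n+p)/2 + a} and rate
#'   \eqn{[(y - X\beta)'(y - X\beta) + r \beta'\Lambda\beta]/2 + b}.
#' * `draw_tau2()`: independent generalized-inverse-Gaussian draws with
#'   `chi = r beta_j^2 / sigma2`, `psi = lambda2` (see [rgig()]); the index is
#'   1 by default (`gig_index`), the value implied by the joint posterior.
#' * `draw_r()`: gamma with shape \eqn{p/2 + c} and rate
#'   \eqn{\beta'\Lambda\beta/(2\sigma^2) + d}.
#' * `draw_lambda2()`: gamma with shape \eqn{p + e} and rate
#'   \eqn{\sum_j \tau_j^2 / 2 + f}.
#'
#' @param X Standardized n x p design matrix.
#' @param y Length-n response (or current probit latent vector).
#' @param beta,sigma2,tau2,r,lambda2 Current values of the other parameters.
#' @param L p x p normalized Laplacian.
#' @param hp A [hyperparameters()] object.
#' @param gig_index Index of the GIG conditional for tau2 (power of x is
#'   `gig_index - 1`); 1 reproduces the joint exactly, 1/2 matches the
#'   inverse-Gaussian-style parameterization used by lasso-type samplers.
#' @return `draw_beta` and `draw_tau2` return length-p vectors; the others a
#'   single positive number.
#' @name gibbs-draws
NULL

#' @rdname gibbs-draws
#' @export
draw_beta <- function(X, y, sigma2, tau2, r, L) {
  cond <- beta_conditional(X, y, sigma2, tau2, r, L)
  p <- length(cond$mean)
  # solve R z = eps gives covariance sigma2 * (R'R)^{-1} = sigma2 * M^{-1}
  cond$mean + sqrt(sigma2) * backsolve(cond$chol_prec, stats::rnorm(p))
}

#' @rdname gibbs-draws
#' @export
draw_sigma2 <- function(X, y, beta, tau2, r, L, hp = hyperparameters()) {
  cond <- sigma2_conditional(X, y, beta, tau2, r, L, hp)
  stopifnot(cond$rate > 0)
  1 / stats::rgamma(1, shape = cond$shape, rate = cond$rate)
}

#' @rdname gibbs-draws
#' @export
draw_tau2 <- function(beta, sigma2, r, lambda2, gig_index = 1) {
  cond <- tau2_conditional(beta, sigma2, r, lambda2, gig_index)
  rgig(length(beta), nu = cond$nu, chi = cond$chi, psi = cond$psi)
}

#' @rdname gibbs-draws
#' @export
draw_r <- function(beta, sigma2, tau2, L, hp = hyperparameters()) {
  cond <- r_conditional(beta, sigma2, tau2, L, hp)
  stats::rgamma(1, shape = cond$shape, rate = cond$rate)
}

#' @rdname gibbs-draws
#' @export
draw_lambda2 <- function(tau2, hp = hyperparameters()) {
  cond <- lambda2_conditional(tau2, hp)
  stats::rgamma(1, shape = cond$shape, rate = cond$rate)
}

# One full Gibbs sweep in the canonical order beta -> sigma2 -> tau2 -> r ->
# lambda2; state is a plain list. Used by the chain runner and by the
# simulator-based sampler validation.
gibbs_sweep <- function(state, X, y, L, hp, gig_index = 1,
                        fix_sigma2 = FALSE) {
  state$beta <- draw_beta(X, y, state$sigma2, state$tau2, state$r, L)
  if (!fix_sigma2) {
    state$sigma2 <- draw_sigma2(X, y, state$beta, state$tau2, state$r, L, hp)
  }
  state$tau2 <- draw_tau2(state$beta, state$sigma2, state$r, state$lambda2,
                          gig_index)
  state$r <- draw_r(state$beta, state$sigma2, state$tau2, L, hp)
  state$lambda2 <- draw_lambda2(state$tau2, hp)
  state
}

initial_state <- function(p, init = NULL) {
  state <- list(beta = rep(0, p), sigma2 = 1, tau2 = rep(1, p), r = 1,
                lambda2 = 1)
  if (!is.null(init)) state[names(init)] <- init
  stopifnot(length(state$beta) == p, length(state$tau2) == p,
            state$sigma2 > 0, all(state$tau2 > 0), state$r > 0,
            state$lambda2 > 0)
  state
}

# Core chain runner shared by the Gaussian and probit fits. `family`
# "binary" augments each iteration with truncated-normal latent draws and
# regresses on them. Draw storage is dense; at microarray-selection scale
# (p in the hundreds to low thousands) this is a few MB.
run_gibbs <- function(X, y, L, hp = hyperparameters(),
                      control = chain_control(), family = "gaussian",
                      gig_index = 1, fix_sigma2 = FALSE, init = NULL,
                      progress = FALSE) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, nrow(L) == p, ncol(L) == p)
  if (family == "binary" && !all(y %in% c(0, 1))) {
    stop("Binary response must be coded 0/1.", call. = FALSE)
  }
  state <- initial_state(p, init)
  keep <- seq.int(control$burn_in + 1, control$n_iter, by = control$thin)
  n_keep <- length(keep)
  draws <- list(beta = matrix(NA_real_, n_keep, p),
                tau2 = matrix(NA_real_, n_keep, p),
                sigma2 = numeric(n_keep), r = numeric(n_keep),
                lambda2 = numeric(n_keep))
  if (family == "binary") draws$z <- matrix(NA_real_, n_keep, n)
  log_joint_trace <- numeric(control$n_iter)
  resp <- if (family == "binary") numeric(n) else y
  k <- 0
  for (it in seq_len(control$n_iter)) {
    if (family == "binary") {
      resp <- draw_latent(X, y, state$beta, state$sigma2)
    }
    state <- withCallingHandlers(
      gibbs_sweep(state, X, resp, L, hp, gig_index, fix_sigma2),
      error = function(e) {
        stop("Gibbs iteration ", it, ": ", conditionMessage(e), call. = FALSE)
      })
    log_joint_trace[it] <- log_joint(state, X, resp, L, hp)
    if (it > control$burn_in && (it - control$burn_in - 1) %% control$thin == 0) {
      k <- k + 1
      draws$beta[k, ] <- state$beta
      draws$tau2[k, ] <- state$tau2
      draws$sigma2[k] <- state$sigma2
      draws$r[k] <- state$r
      draws$lambda2[k] <- state$lambda2
      if (family == "binary") draws$z[k, ] <- resp
    }
    if (progress && it %% 1000 == 0) {
      message("iteration ", it, "/", control$n_iter,
              " log-joint ", format(log_joint_trace[it], digits = 6))
    }
  }
  colnames(draws$beta) <- colnames(X)
  colnames(draws$tau2) <- colnames(X)
  list(draws = draws, log_joint_trace = log_joint_trace, control = control,
       family = family)
}
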