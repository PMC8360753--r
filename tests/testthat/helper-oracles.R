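# Independent oracles used across the suite. Everything here is written
# directly from the model densities, separately from the package's samplers,
# so a test failure localizes to one side.

# Numerically normalized CDF of a 1-D density given by its log kernel on
# (lower, Inf); suitable for ks.test(x, cdf).
quadrature_cdf <- function(log_kernel, lower = 0, mode_hint = 1) {
  shift <- log_kernel(mode_hint)
  dens <- function(x) exp(log_kernel(x) - shift)
  Z <- stats::integrate(dens, lower, Inf, rel.tol = 1e-10)$value
  function(q) {
    vapply(q, function(qi) {
      if (qi <= lower) return(0)
      stats::integrate(dens, lower, qi, rel.tol = 1e-10)$value / Z
    }, numeric(1))
  }
}

# --- diagonal-precision (Bayesian-lasso-form) conditionals: Lambda = D^{-1}
blasso_beta_cond <- function(X, y, sigma2, tau2, r) {
  M <- crossprod(X) + r * diag(1 / tau2, length(tau2))
  list(mean = drop(solve(M, crossprod(X, y))), cov = sigma2 * solve(M))
}
blasso_sigma2_cond <- function(X, y, beta, tau2, r, hp) {
  rss <- sum((y - X %*% beta)^2)
  quad <- sum(beta^2 / tau2)
  list(shape = (length(y) + length(beta)) / 2 + hp$a,
       rate = (rss + r * quad) / 2 + hp$b)
}
blasso_r_cond <- function(beta, sigma2, tau2, hp) {
  list(shape = length(beta) / 2 + hp$c,
       rate = sum(beta^2 / tau2) / (2 * sigma2) + hp$d)
}

# --- elastic-net-form conditionals: Lambda = D^{-1} + I
benet_beta_cond <- function(X, y, sigma2, tau2, r) {
  M <- crossprod(X) + r * (diag(1 / tau2, length(tau2)) +
                             diag(length(tau2)))
  list(mean = drop(solve(M, crossprod(X, y))), cov = sigma2 * solve(M))
}
benet_sigma2_cond <- function(X, y, beta, tau2, r, hp) {
  rss <- sum((y - X %*% beta)^2)
  quad <- sum(beta^2 / tau2) + sum(beta^2)
  list(shape = (length(y) + length(beta)) / 2 + hp$a,
       rate = (rss + r * quad) / 2 + hp$b)
}
benet_r_cond <- function(beta, sigma2, tau2, hp) {
  list(shape = length(beta) / 2 + hp$c,
       rate = (sum(beta^2 / tau2) + sum(beta^2)) / (2 * sigma2) + hp$d)
}

# Term-by-term log joint for the diagonal-precision special case, written
# independently of log_joint(); additive constants may differ, so compare
# differences between states.
blasso_log_joint <- function(state, X, y, hp) {
  beta <- state$beta; sigma2 <- state$sigma2; tau2 <- state$tau2
  r <- state$r; lambda2 <- state$lambda2
  n <- length(y); p <- length(beta)
  quad <- sum(beta^2 / tau2)
  -n / 2 * log(2 * pi * sigma2) - sum((y - X %*% beta)^2) / (2 * sigma2) -
    p / 2 * log(2 * pi) - p / 2 * log(sigma2) + p / 2 * log(r) -
    r * quad / (2 * sigma2) +
    sum(log(lambda2 / 2) - lambda2 * tau2 / 2) +
    hp$a * log(hp$b) - lgamma(hp$a) - (hp$a + 1) * log(sigma2) -
    hp$b / sigma2 +
    stats::dgamma(r, hp$c, rate = hp$d, log = TRUE) +
    stats::dgamma(lambda2, hp$e, rate = hp$f, log = TRUE)
}

# random valid Gibbs state for property checks
random_state <- function(p, rng_scale = 1) {
  list(beta = stats::rnorm(p, sd = rng_scale),
       sigma2 = stats::rexp(1) + 0.2,
       tau2 = stats::rexp(p) + 0.2,
       r = stats::rexp(1) + 0.2,
       lambda2 = stats::rexp(1) + 0.2)
}

# random unit-weight gene network on p nodes with each pair connected w.p.
# edge_prob (no self loops)
random_network <- function(p, edge_prob = 0.3) {
  nodes <- sprintf("g%02d", seq_len(p))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  gene_network(tibble::tibble(from = pairs[1, keep], to = pairs[2, keep]),
               nodes = nodes)
}

# standardized random design
random_design <- function(n, p) {
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
  standardize_expression(X)$X
}

# batch-means standard error for an autocorrelated scalar chain
batch_se <- function(x, n_batch = 100) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(k) {
    mean(x[((k - 1) * b + 1):(k * b)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batch)
}
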