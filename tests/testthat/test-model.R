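test_that("standardization gives mean-0, sd-1 columns and is invertible", {
  out <- standardize_expression(cbind(g1 = c(1, 2, 3), g2 = c(5, -1, 2)))
  expect_equal(out$X[, "g1"], c(-1, 0, 1))
  expect_equal(out$center[["g1"]], 2)
  expect_equal(out$scale[["g1"]], 1)
  expect_equal(colMeans(out$X), c(g1 = 0, g2 = 0), tolerance = 1e-12)
  expect_equal(apply(out$X, 2, sd), c(g1 = 1, g2 = 1), tolerance = 1e-12)

  again <- standardize_expression(out$X)
  expect_equal(again$X, out$X, tolerance = 1e-12)

  # population-sd convention is available behind the flag
  pop <- standardize_expression(cbind(g1 = c(1, 2, 3)), population = TRUE)
  expect_equal(pop$X[, "g1"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  expect_error(standardize_expression(cbind(g1 = c(1, 1, 1))), "g1")
  expect_error(standardize_expression(cbind(g1 = c(1, NA, 3))), "missing")
})

test_that("precision matrix is diag(1/tau2) + L and positive definite", {
  expect_equal(precision_matrix(c(1, 1), matrix(0, 2, 2)), diag(2))
  L <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(precision_matrix(c(1, 1), L),
               matrix(c(2, -1, -1, 2), 2, 2))
  expect_error(precision_matrix(c(1, -1), L), "> 0")
  expect_error(precision_matrix(c(1, 1, 1), L), "matrix")

  set.seed(402)
  for (trial in 1:5) {
    p <- sample(3:12, 1)
    Lr <- unclass(normalized_laplacian(random_network(p)))
    tau2 <- rexp(p) + 0.05
    ev <- eigen(precision_matrix(tau2, Lr), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), 1 / max(tau2) - 1e-8)
  }
})

test_that("log joint isolates its terms and matches an independent form", {
  set.seed(403)
  n <- 15; p <- 4
  X <- random_design(n, p)
  y <- rnorm(n)
  hp <- hyperparameters(0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  L0 <- matrix(0, p, p)
  s1 <- random_state(p); s2 <- random_state(p)

  # adding a constant to y shifts only the Gaussian likelihood term
  lj <- log_joint(s1, X, y, L0, hp)
  ljc <- log_joint(s1, X, y + 3, L0, hp)
  lik <- function(yy) -n / 2 * log(2 * pi * s1$sigma2) -
    sum((yy - X %*% s1$beta)^2) / (2 * s1$sigma2)
  expect_equal(ljc - lj, lik(y + 3) - lik(y), tolerance = 1e-10)

  # with L = 0 the joint coincides with the diagonal-precision form
  expect_equal(log_joint(s1, X, y, L0, hp) - log_joint(s2, X, y, L0, hp),
               blasso_log_joint(s1, X, y, hp) - blasso_log_joint(s2, X, y, hp),
               tolerance = 1e-10)

  expect_true(is.finite(log_joint(s1, X, y,
                                  unclass(normalized_laplacian(
                                    random_network(p))), hp)))
})

test_that("determinant factors of the beta and tau2 priors cancel", {
  set.seed(404)
  p <- 5
  L <- unclass(normalized_laplacian(random_network(p)))
  s <- random_state(p)
  with_dets <- function(state) {
    Lam <- precision_matrix(state$tau2, L)
    ld <- as.numeric(determinant(Lam)$modulus)
    # beta prior carries +1/2 log|Lambda|, tau2 prior -1/2 log|Lambda|
    (0.5 * ld) + (-0.5 * ld)
  }
  for (trial in 1:10) {
    s$tau2 <- rexp(p) + 0.05
    expect_identical(with_dets(s), 0)
  }
})

test_that("tau2 prior is proper: quadrature converges as the domain grows", {
  # p = 1 with a self-contained scalar L (degree-1 node): kernel
  # (1/tau^2 + l)^{-1/2} * exp(-lambda2 tau^2 / 2) integrates finitely
  lambda2 <- 1.3
  for (l in c(0.5, 1)) {
    ker <- function(x) (1 / x + l)^(-1 / 2) * exp(-lambda2 * x / 2)
    vals <- vapply(c(25, 50, 100, 200), function(T) {
      integrate(ker, 0, T, rel.tol = 1e-10)$value
    }, numeric(1))
    expect_lt(abs(vals[4] - vals[3]) / vals[4], 1e-8)
    # bounded by the gamma-kernel envelope (drop the |Lambda|^{-1/2} <= tau)
    bound <- integrate(function(x) sqrt(x) * exp(-lambda2 * x / 2),
                       0, Inf)$value
    expect_lte(vals[4], bound * (1 + 1e-8))
  }

  # p = 2 with one unit edge: |Lambda|^{-1/2} kernel, nested quadrature
  L2 <- matrix(c(1, -1, -1, 1), 2, 2)
  ker2 <- function(x1, x2) {
    det <- (1 / x1 + 1) * (1 / x2 + 1) - 1
    det^(-1 / 2) * exp(-lambda2 * (x1 + x2) / 2)
  }
  inner <- function(x1, T) vapply(x1, function(a) {
    integrate(function(x2) ker2(a, x2), 0, T, rel.tol = 1e-8)$value
  }, numeric(1))
  vals2 <- vapply(c(25, 50, 100), function(T) {
    integrate(function(x1) inner(x1, T), 0, T, rel.tol = 1e-6)$value
  }, numeric(1))
  expect_lt(abs(vals2[3] - vals2[2]) / vals2[3], 1e-4)
})

test_that("penalized objective reduces to its closed-form special cases", {
  set.seed(405)
  n <- 12; p <- 3
  X <- random_design(n, p)
  y <- rnorm(n)
  L <- unclass(normalized_laplacian(
    gene_network(data.frame(from = "g01", to = "g02"),
                 nodes = colnames(X))))

  expect_equal(penalized_objective(rep(0, p), X, y, L, r = 2, lam = 1),
               sum(y^2))

  beta <- rnorm(p)
  expect_equal(penalized_objective(beta, X, y, matrix(0, p, p), 2, 0.7),
               sum((y - X %*% beta)^2) + 2 * 0.7 * sum(abs(beta)))
  expect_equal(penalized_objective(beta, X, y, L, 2, 0.7),
               sum((y - X %*% beta)^2) + 2 * 0.7 * sum(abs(beta)) +
                 2 * drop(t(beta) %*% L %*% beta))
  expect_error(penalized_objective(beta[1:2], X, y, L, 1, 1), "mismatch")
})
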