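test_that("beta conditional has the stated mean and covariance at X = 0", {
  set.seed(410)
  p <- 3
  X0 <- matrix(0, 40, p)
  L <- unclass(normalized_laplacian(
    gene_network(data.frame(from = "a", to = "b"), nodes = c("a", "b", "c"))))
  sigma2 <- 2; r <- 1.7
  tau2 <- c(0.5, 1.2, 2)
  y <- rnorm(40)
  n_draw <- 20000
  draws <- t(replicate(n_draw, draw_beta(X0, y, sigma2, tau2, r, L)))
  Sigma <- (sigma2 / r) * solve(precision_matrix(tau2, L))
  mc_se <- sqrt(diag(Sigma) / n_draw)
  expect_true(all(abs(colMeans(draws)) < 4 * mc_se))
  emp_cov <- cov(draws)
  cov_se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n_draw)
  expect_true(all(abs(emp_cov - Sigma) < 4 * cov_se))
})

test_that("scalar conditionals carry the derived shapes and rates", {
  set.seed(411)
  n <- 10; p <- 4
  X <- random_design(n, p)
  y <- rnorm(n)
  hp <- hyperparameters(0.7, 0.8, 0.9, 1.1, 1.2, 1.3)
  L <- unclass(normalized_laplacian(random_network(p, 0.5)))
  s <- random_state(p)

  # sigma2: rate reduces to y'y/2 + b at beta = 0
  cond <- bnreg:::sigma2_conditional(X, y, rep(0, p), s$tau2, s$r, L, hp)
  expect_equal(cond$rate, sum(y^2) / 2 + hp$b)
  expect_equal(cond$shape, (n + p) / 2 + hp$a)

  # r: Gamma(p/2 + c, d) at beta = 0, and empirical mean matches shape/rate
  draws_r <- replicate(5000, draw_r(rep(0, p), s$sigma2, s$tau2, L, hp))
  expect_lt(abs(mean(draws_r) - (p / 2 + hp$c) / hp$d),
            4 * sd(draws_r) / sqrt(5000))
  cr <- bnreg:::r_conditional(s$beta, s$sigma2, s$tau2, L, hp)
  draws_r2 <- replicate(5000, draw_r(s$beta, s$sigma2, s$tau2, L, hp))
  expect_lt(abs(mean(draws_r2) - cr$shape / cr$rate),
            4 * sd(draws_r2) / sqrt(5000))

  # lambda2: empirical mean (p + e) / (sum tau2 / 2 + f); doubling tau2
  # lowers the conditional mean
  cl <- bnreg:::lambda2_conditional(s$tau2, hp)
  draws_l <- replicate(5000, draw_lambda2(s$tau2, hp))
  expect_lt(abs(mean(draws_l) - cl$shape / cl$rate),
            4 * sd(draws_l) / sqrt(5000))
  cl2 <- bnreg:::lambda2_conditional(2 * s$tau2, hp)
  expect_lt(cl2$shape / cl2$rate, cl$shape / cl$rate)

  # sigma2 empirical mean = rate / (shape - 1)
  cs <- bnreg:::sigma2_conditional(X, y, s$beta, s$tau2, s$r, L, hp)
  draws_s <- replicate(5000, draw_sigma2(X, y, s$beta, s$tau2, s$r, L, hp))
  expect_lt(abs(mean(draws_s) - cs$rate / (cs$shape - 1)),
            4 * sd(draws_s) / sqrt(5000))

  # tau2 at beta_j = 0 is Exponential(lambda2 / 2)
  t0 <- draw_tau2(rep(0, 3000), sigma2 = 1, r = 1, lambda2 = 3)
  expect_gt(ks.test(t0, pexp, rate = 1.5)$p.value, 0.01)
})

test_that("degenerate p = 0 conditionals recover the priors", {
  set.seed(412)
  hp <- hyperparameters(0.5, 0.5, 1.5, 2, 2.5, 3)
  r0 <- replicate(4000, draw_r(numeric(0), 1, numeric(0),
                               matrix(0, 0, 0), hp))
  expect_gt(ks.test(r0, pgamma, shape = hp$c, rate = hp$d)$p.value, 0.01)
  l0 <- replicate(4000, draw_lambda2(numeric(0), hp))
  expect_gt(ks.test(l0, pgamma, shape = hp$e, rate = hp$f)$p.value, 0.01)
})

test_that("chains are bitwise reproducible and keep a finite log joint", {
  sim <- simulate_pathway_data(n_samples = 50, n_pathways = 6,
                               genes_per_pathway = 5, seed = 21)
  ctl <- chain_control(300)
  f1 <- bnr_fit(sim$expression, sim$response, sim$network, control = ctl,
                seed = 99)
  f2 <- bnr_fit(sim$expression, sim$response, sim$network, control = ctl,
                seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$ranking, f2$ranking)
  expect_true(all(is.finite(f1$log_joint_trace)))

  f3 <- bnr_fit(sim$expression, sim$response, sim$network, control = ctl,
                seed = 100)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("posterior mean shrinks toward, not past, least squares on an
           orthogonal design", {
  set.seed(413)
  n <- 60; p <- 4
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  X <- standardize_expression(Q)$X
  colnames(X) <- paste0("G", 1:p)
  beta_true <- c(4, -3, 2.5, 0)
  y <- drop(X %*% beta_true) + rnorm(n, sd = 0.5)
  fit <- bnr_fit(X, y, network = NULL, control = chain_control(1500),
                 seed = 5)
  b_ls <- drop(solve(crossprod(X), crossprod(X, y - mean(y))))
  b_post <- colMeans(fit$draws$beta)
  strong <- abs(b_ls) > 1
  expect_true(all(sign(b_post[strong]) == sign(b_ls[strong])))
  expect_true(all(abs(b_post[strong]) <= abs(b_ls[strong]) + 0.05))
  expect_gt(cor(b_post, b_ls), 0.99)
})

test_that("posterior mean recovers a network-smooth truth on synthetic data", {
  sim <- simulate_pathway_data(seed = 31)
  fit <- bnr_fit(sim$expression, sim$response, sim$network,
                 control = chain_control(1000), seed = 8)
  expect_gt(cor(colMeans(fit$draws$beta), sim$true_beta), 0.8)
})

test_that("update order and storage follow the chain contract", {
  sim <- simulate_pathway_data(n_samples = 30, n_pathways = 2,
                               genes_per_pathway = 3,
                               n_active_pathways = 1, seed = 77)
  fit <- bnr_fit(sim$expression, sim$response, sim$network,
                 control = chain_control(100, burn_in = 40, thin = 3),
                 seed = 3)
  expect_equal(nrow(fit$draws$beta), length(seq(41, 100, by = 3)))
  expect_equal(length(fit$log_joint_trace), 100)
  expect_true(all(fit$draws$sigma2 > 0))
  expect_true(all(fit$draws$tau2 > 0))
  expect_error(chain_control(100, burn_in = 100), "burn_in")
})
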