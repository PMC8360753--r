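#' Generalized inverse Gaussian random variates
#'
#' Draws from the density proportional to
#' \eqn{x^{\nu - 1} \exp\{-(\psi x + \chi / x) / 2\}} on \eqn{(0, \infty)}.
#' This is the conditional law of the local scales tau_j^2 in the Gibbs
#' sampler, with `chi = r beta_j^2 / sigma2` and `psi = lambda2`.
#'
#' Sampling works on the log scale: with \eqn{t = \log x} (after rescaling by
#' \eqn{\sqrt{\chi/\psi}}) the density is proportional to
#' \eqn{\exp\{\nu t - \omega \cosh t\}}, \eqn{\omega = \sqrt{\chi\psi}}, which
#' is strictly log-concave. A rejection envelope with a uniform centre piece
#' and two exponential tails hinged where the log-density has dropped by 1
#' below its mode yields a bounded expected number of trials for all
#' parameter values. When `chi = 0` the law degenerates to
#' Gamma(shape = nu, rate = psi / 2) and is drawn directly.
#'
#' @param n Number of draws.
#' @param nu Index (power of x is `nu - 1`); must be > 0 here.
#' @param chi Nonnegative coefficient of 1/x (may be a vector of length n).
#' @param psi Positive coefficient of x (scalar or length n).
#' @return Numeric vector of n positive draws.
#' @export
rgig <- function(n, nu, chi, psi) {
  stopifnot(nu > 0, all(chi >= 0), all(psi > 0))
  chi <- rep_len(chi, n)
  psi <- rep_len(psi, n)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- rgig_one(nu, chi[i], psi[i])
  out
}

# single draw; see rgig() for the construction
rgig_one <- function(nu, chi, psi) {
  # chi so small that omega underflows the envelope setup: gamma limit
  if (chi < 1e-14) return(stats::rgamma(1, shape = nu, rate = psi / 2))
  s <- sqrt(chi / psi)            # scale: x = s * exp(t)
  omega <- sqrt(chi * psi)
  t0 <- asinh(nu / omega)         # mode of g(t) = nu*t - omega*cosh(t)
  g0 <- nu * t0 - omega * cosh(t0)
  g <- function(t) nu * t - omega * cosh(t) - g0
  gp <- function(t) nu - omega * sinh(t)

  tr <- gig_drop_point(g, gp, t0, right = TRUE)
  tl <- gig_drop_point(g, gp, t0, right = FALSE)
  sr <- -gp(tr)                   # > 0: tail slope on the right
  sl <- gp(tl)                    # > 0: tail slope on the left
  a_mid <- tr - tl
  a_r <- exp(-1) / sr
  a_l <- exp(-1) / sl
  tot <- a_mid + a_r + a_l

  repeat {
    u <- stats::runif(1) * tot
    if (u < a_mid) {
      t <- tl + stats::runif(1) * a_mid
      log_env <- 0
    } else if (u < a_mid + a_r) {
      t <- tr + stats::rexp(1) / sr
      log_env <- -1 - sr * (t - tr)
    } else {
      t <- tl - stats::rexp(1) / sl
      log_env <- -1 + sl * (t - tl)
    }
    if (log(stats::runif(1)) <= g(t) - log_env) return(s * exp(t))
  }
}

# point on the requested side of the mode where the centred log-density
# equals -1; safeguarded Newton on a bisection bracket
gig_drop_point <- function(g, gp, t0, right) {
  step <- 1
  t1 <- t0
  repeat {
    t1 <- if (right) t1 + step else t1 - step
    if (g(t1) <= -1) break
    step <- step * 2
  }
  lo <- min(t0, t1); hi <- max(t0, t1)
  t <- (lo + hi) / 2
  for (it in 1:50) {
    val <- g(t) + 1
    if (abs(val) < 1e-10) break
    # maintain bracket: g + 1 > 0 on the mode side of the root
    if (val > 0) { if (right) lo <- t else hi <- t }
    else { if (right) hi <- t else lo <- t }
    d <- gp(t)
    tn <- if (abs(d) > 1e-300) t - val / d else NA_real_
    t <- if (!is.na(tn) && tn > lo && tn < hi) tn else (lo + hi) / 2
  }
  t
}
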