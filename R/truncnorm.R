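#' One-sided truncated normal draws
#'
#' Vectorized draws from Normal(mean, sd^2) truncated below (`lower`) or above
#' (`upper`); exactly one bound must be given. Uses the inverse CDF evaluated
#' in log space (`pnorm`/`qnorm` with `log.p = TRUE`), which stays accurate
#' when the untruncated mass beyond the bound underflows — i.e. for
#' |bound - mean| / sd far beyond 6 — so probit augmentation never stalls on
#' extreme linear predictors.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale (vectors recycled to length n).
#' @param lower,upper Truncation bound; draws satisfy `x > lower` or
#'   `x <= upper`.
#' @return Numeric vector of n draws.
#' @keywords internal
rtnorm <- function(n, mean = 0, sd = 1, lower = NULL, upper = NULL) {
  if (is.null(lower) == is.null(upper)) {
    stop("Give exactly one of `lower`, `upper`.", call. = FALSE)
  }
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  u <- stats::runif(n)
  if (!is.null(lower)) {
    a <- (lower - mean) / sd
    # tail mass beyond a, kept in logs; draw uniform within it
    log_tail <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    z <- stats::qnorm(log_tail + log(u), lower.tail = FALSE, log.p = TRUE)
    mean + sd * z
  } else {
    b <- (upper - mean) / sd
    log_tail <- stats::pnorm(b, lower.tail = TRUE, log.p = TRUE)
    z <- stats::qnorm(log_tail + log(u), lower.tail = TRUE, log.p = TRUE)
    mean + sd * z
  }
}
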