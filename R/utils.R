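## Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding in the style used for printed percent changes
#' (\code{0.5 -> 1}, \code{-0.5 -> -1}), as opposed to R's banker's rounding.
#'
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
roundHalfAwayFromZero <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## mean of a normal(mu, sd) truncated below at `lower`
.truncnormMean <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  ## log-space hazard ratio keeps this stable for a >> 0
  mu + sd * exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

## location mu such that the truncated-below-normal(mu, sd, lower) has mean
## `target`; sd is the underlying (not truncated) scale
.truncnormMatchMean <- function(target, sd, lower) {
  if (target <= lower)
    stop("target mean must exceed the truncation bound")
  f <- function(mu) .truncnormMean(mu, sd, lower) - target
  lo <- target - 8 * sd
  if (f(lo) > 0) return(lo)  # truncation negligible in double precision
  uniroot(f, c(lo, target), tol = 1e-10)$root
}

## inverse-CDF sampler for the truncated-below normal; deterministic given the
## RNG state
.rtruncnorm <- function(n, mu, sd, lower) {
  pLow <- pnorm(lower, mean = mu, sd = sd)
  u <- runif(n, pLow, 1)
  qnorm(u, mean = mu, sd = sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
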