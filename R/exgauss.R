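#' The exponentially modified Gaussian (exGauss) distribution
#'
#' Density, distribution function and random generation for the convolution
#' of a Gaussian(`mu`, `sigma`) and an exponential with rate `lam`, the
#' standard skewed response-time distribution. `sigma = 0` degenerates to a
#' shifted exponential starting at `mu`.
#'
#' The density is evaluated on the log scale,
#' `log f(x) = log(lam) + (lam*sigma)^2/2 - lam*(x - mu) + log Phi(u)` with
#' `u = (x - mu)/sigma - lam*sigma`, switching to an asymptotic expansion of
#' the Gaussian Mills ratio when `u` is very negative, where the naive
#' formula loses all floating-point precision (e.g. whenever `lam*sigma` is
#' large).
#'
#' @param x,q Quantiles (ms).
#' @param n Number of draws.
#' @param mu Gaussian mean (ms).
#' @param sigma Gaussian SD (ms), `>= 0`.
#' @param lam Exponential rate (1/ms), `> 0`.
#' @param log,lower.tail As in other distribution functions.
#' @return `dexgauss` the density (per ms), `pexgauss` the CDF, `rexgauss`
#'   random variates.
#' @examples
#' integrate(dexgauss, -Inf, Inf, mu = 300, sigma = 50, lam = 1 / 200)
#' @export
dexgauss <- function(x, mu, sigma, lam, log = FALSE) {
  stopifnot(sigma >= 0, lam > 0)
  if (sigma == 0) {
    lf <- ifelse(x >= mu, base::log(lam) - lam * (x - mu), -Inf)
  } else {
    v <- (x - mu) / sigma
    lf <- base::log(lam) + exg_log_tail(v, lam * sigma)
  }
  if (log) lf else exp(lf)
}

# log[ exp(k^2/2 - k*v) * Phi(v - k) ] with k = lam*sigma, evaluated in the
# parameterization that avoids cancellation: the direct formula is accurate
# unless u = v - k is very negative, where log Phi(u) ~ -u^2/2 and the
# Mills-ratio expansion takes over (rewriting via -v^2/2 + u^2/2 + log Phi(u))
exg_log_tail <- function(v, k) {
  u <- v - k
  out <- numeric(length(u))
  lo <- u < -8
  out[!lo] <- k^2 / 2 - k * v[!lo] + stats::pnorm(u[!lo], log.p = TRUE)
  if (any(lo)) {
    ul <- u[lo]
    out[lo] <- -v[lo]^2 / 2 - 0.5 * base::log(2 * pi) - base::log(-ul) +
      log1p(-1 / ul^2 + 3 / ul^4)
  }
  out
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, lam, lower.tail = TRUE) {
  stopifnot(sigma >= 0, lam > 0)
  if (sigma == 0) {
    p <- stats::pexp(pmax(q - mu, 0), rate = lam)
  } else {
    z <- (q - mu) / sigma
    # P(X <= q) = Phi(z) - exp(k^2/2 - k*z) * Phi(z - k), k = lam*sigma
    p <- stats::pnorm(z) - exp(exg_log_tail(z, lam * sigma))
    p <- pmin(pmax(p, 0), 1)
  }
  if (lower.tail) p else 1 - p
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, lam) {
  stopifnot(sigma >= 0, lam > 0)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = lam)
}
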