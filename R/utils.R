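# Internal numerical helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) stats::plogis(x)

#' @noRd
#' Central-difference numerical gradient; h scaled to parameter magnitude.
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    g[j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  g
}

#' @noRd
#' Composite Simpson rule on a fixed grid; fallback when adaptive quadrature
#' fails. n must be even.
simpson <- function(f, lower, upper, n = 2048L) {
  x <- seq(lower, upper, length.out = n + 1L)
  y <- f(x)
  h <- (upper - lower) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, by = 2)]) +
             2 * sum(y[seq(3, n - 1, by = 2)]))
}

#' @noRd
#' Adaptive quadrature with a deterministic Simpson fallback.
quad <- function(f, lower, upper, rel.tol = 1e-8) {
  out <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol,
                     subdivisions = 400L)$value,
    error = function(e) NA_real_
  )
  if (!is.finite(out)) out <- simpson(f, lower, upper)
  out
}

#' Asymptotic Cramer-von Mises distribution
#'
#' Limiting null distribution function of the one-sample Cramer-von Mises
#' statistic, evaluated with the classical Bessel-function series
#' (Csorgo and Faraway 1996). Used for goodness-of-fit p-values of fitted
#' detection functions.
#'
#' @param q quantile (the observed statistic), `q > 0`.
#' @param lower.tail if `FALSE`, returns the p-value `P(W > q)`.
#' @return probability.
#' @export
pcvm <- function(q, lower.tail = TRUE) {
  cdf1 <- function(x) {
    if (x <= 0) return(0)
    k <- 0:10
    a <- (4 * k + 1)^2 / (16 * x)
    terms <- exp(lgamma(k + 0.5) - lgamma(0.5) - lgamma(k + 1)) *
      sqrt(4 * k + 1) * exp(-a) * besselK(a, 0.25)
    s <- sum(terms[is.finite(terms)])
    min(1, max(0, s / (pi * sqrt(x))))
  }
  p <- vapply(q, cdf1, numeric(1))
  if (lower.tail) p else 1 - p
}
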