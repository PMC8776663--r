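# Information-theoretic model ranking and averaging: small-sample AIC,
# Akaike weights, and model-averaged estimates whose unconditional standard
# error carries model-selection uncertainty (Burnham-Anderson form).

#' Second-order (small-sample) Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (here: number of detected clusters); must exceed
#'   `k + 1`.
#' @return the criterion value.
#' @export
aicc <- function(loglik, k, n) {
  if (k > 0 && n <= k + 1) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + if (k > 0) 2 * k * (k + 1) / (n - k - 1) else 0
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` where `Delta_i` is each
#' criterion value minus the smallest. Invariant to adding a constant to
#' all criteria.
#'
#' @param criteria vector of AIC/AICc values (or ready-made deltas).
#' @return weights summing to 1, in the input order.
#' @export
akaike_weights <- function(criteria) {
  if (!length(criteria)) stop("at least one criterion value is required")
  d <- criteria - min(criteria)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-averaged estimate with unconditional standard error
#'
#' Averages estimates over a model set with (re)normalized Akaike weights;
#' the unconditional SE adds model-selection variance:
#' `se = sum_i w_i sqrt(v_i + (theta_i - avg)^2)`.
#'
#' @param estimates numeric vector of per-model estimates.
#' @param se per-model standard errors (conditional on the model).
#' @param weights Akaike weights; renormalized to sum to 1 over the
#'   supplied (sub)set.
#' @return list with `estimate`, `se`, `weights` (renormalized).
#' @export
model_average <- function(estimates, se, weights) {
  n <- length(estimates)
  if (!n) stop("empty model set")
  stopifnot(length(se) == n, length(weights) == n, all(se >= 0),
            all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  avg <- sum(w * estimates)
  se_u <- sum(w * sqrt(se^2 + (estimates - avg)^2))
  list(estimate = avg, se = se_u, weights = w)
}
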