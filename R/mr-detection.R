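# Double-observer mark-recapture detection submodel.
#
# Conditional on a cluster being detected by at least one team, its capture
# history omega in {10, 01, 11} is multinomial with
#   P(10) = pF(1-pR)/p*,  P(01) = (1-pF)pR/p*,  P(11) = pF pR / p*,
#   p*    = 1 - (1-pF)(1-pR),
# where pF, pR follow a logistic model in perpendicular distance with
# position-specific intercepts, a shared distance slope, and at most one
# extra covariate (full independence between teams). Distance enters the
# optimizer in kilometers for conditioning; reported coefficients are on
# the meter scale.

MR_SPECS <- c("none", "distance_sq", "cluster_size", "activity", "ice_rough",
              "visibility_bad", "cloud", "blind_spot", "distance_by_position")

BLIND_SPOT_M <- 75  # rear-observer blind spot extends to 75 m off the line

#' Candidate specifications for the double-observer submodel
#'
#' All nine candidate models contain position-specific intercepts and a
#' distance effect; each adds at most one extra term: squared distance,
#' one of the sighting covariates, a rear-observer blind-spot indicator
#' (distance <= 75 m), or a position-specific distance slope.
#'
#' @return character vector of specification names accepted by [fit_mr()].
#' @export
mr_model_specs <- function() MR_SPECS

mr_npar <- function(spec) if (spec == "none") 3L else 4L

# Per-cluster design pieces on the internal (km) scale.
mr_design <- function(dataset, spec) {
  obs <- dataset$observations
  if (!nrow(obs)) stop("empty dataset: cannot evaluate the MR likelihood")
  d <- obs$distance_m / 1000
  x <- switch(spec,
    none = , distance_by_position = , blind_spot = , distance_sq = numeric(nrow(obs)),
    cluster_size = as.numeric(obs$cluster_size),
    activity = as.numeric(obs$activity),
    ice_rough = as.numeric(obs$ice_rough),
    visibility_bad = as.numeric(obs$visibility_bad),
    cloud = as.numeric(obs$cloud_quartile),
    stop(sprintf("unknown MR specification '%s'", spec))
  )
  if (spec %in% c("cluster_size", "activity", "ice_rough", "visibility_bad",
                  "cloud") && anyNA(x)) {
    stop(sprintf(
      "covariate '%s' has missing values; covariate models require complete covariates",
      spec), call. = FALSE)
  }
  list(d = d, x = x, blind = as.numeric(obs$distance_m <= BLIND_SPOT_M),
       history = paste0(obs$seen_front, obs$seen_rear))
}

# Linear predictors at the observed distances (or at d = 0 when d0 = TRUE).
mr_eta <- function(par, des, spec, d0 = FALSE) {
  d <- if (d0) numeric(length(des$d)) else des$d
  b0f <- par[1]; b0r <- par[2]
  if (spec == "distance_by_position") {
    eta_f <- b0f + par[3] * d
    eta_r <- b0r + par[4] * d
  } else {
    eta_f <- b0f + par[3] * d
    eta_r <- b0r + par[3] * d
    if (spec == "distance_sq") {
      eta_f <- eta_f + par[4] * d^2
      eta_r <- eta_r + par[4] * d^2
    } else if (spec == "blind_spot") {
      # reduction applies to the rear team only, within the blind spot;
      # at distance 0 every cluster is inside it
      bl <- if (d0) rep(1, length(d)) else des$blind
      eta_r <- eta_r + par[4] * bl
    } else if (spec != "none") {
      eta_f <- eta_f + par[4] * des$x
      eta_r <- eta_r + par[4] * des$x
    }
  }
  list(f = eta_f, r = eta_r)
}

mr_probs <- function(par, des, spec, d0 = FALSE) {
  eta <- mr_eta(par, des, spec, d0 = d0)
  pf <- inv_logit(eta$f)
  pr <- inv_logit(eta$r)
  list(pf = pf, pr = pr, pstar = 1 - (1 - pf) * (1 - pr))
}

#' Conditional log-likelihood of the double-observer submodel
#'
#' @param coefficients parameter vector on the internal scale
#'   (front intercept, rear intercept, distance slope per km, optional
#'   extra term; for `distance_by_position`: front slope then rear slope).
#' @param dataset a truncated `survey_dataset`.
#' @param spec one of [mr_model_specs()].
#' @return the summed log multinomial probability of the observed capture
#'   histories conditional on detection.
#' @export
mr_loglik <- function(coefficients, dataset, spec = "none") {
  des <- mr_design(dataset, spec)
  if (length(coefficients) != mr_npar(spec)) {
    stop(sprintf("spec '%s' needs %d coefficients", spec, mr_npar(spec)))
  }
  eta <- mr_eta(coefficients, des, spec)
  if (any(!is.finite(eta$f)) || any(!is.finite(eta$r))) {
    stop("non-finite linear predictor")
  }
  pf <- inv_logit(eta$f); pr <- inv_logit(eta$r)
  pstar <- 1 - (1 - pf) * (1 - pr)
  lp <- ifelse(des$history == "10", log(pf) + log1p(-pr),
        ifelse(des$history == "01", log1p(-pf) + log(pr),
               log(pf) + log(pr)))
  sum(lp - log(pstar))
}

#' Probability of detection on the line by at least one observer
#'
#' `p0* = 1 - (1 - pF0)(1 - pR0)`: one minus the probability that both
#' teams miss a cluster located at perpendicular distance zero. The
#' standard error follows by the delta method when a 2x2 covariance of
#' `(pF0, pR0)` is supplied.
#'
#' @param p_f0,p_r0 on-line detection probabilities in (0, 1].
#' @param vcov optional 2x2 covariance matrix of the two inputs.
#' @return list with `estimate` and (if `vcov` given) `se`.
#' @examples
#' p0_star(0.842, 0.727)$estimate  # 0.957
#' @export
p0_star <- function(p_f0, p_r0, vcov = NULL) {
  if (p_f0 <= 0 || p_f0 > 1 || p_r0 <= 0 || p_r0 > 1) {
    stop("p_f0 and p_r0 must lie in (0, 1]")
  }
  est <- 1 - (1 - p_f0) * (1 - p_r0)
  out <- list(estimate = est)
  if (!is.null(vcov)) {
    grad <- c(1 - p_r0, 1 - p_f0)
    out$se <- sqrt(drop(t(grad) %*% vcov %*% grad))
  }
  out
}

# Deterministic multistart set: null start plus fixed offsets.
mr_starts <- function(k) {
  base <- numeric(k)
  offs <- rbind(0, 1, -1, c(2, 1, rep(-1, k - 2)),
                c(-1, -2, rep(1, k - 2)), c(1, -1, rep(0.5, k - 2)))
  lapply(seq_len(nrow(offs)), function(i) base + offs[i, seq_len(k)])
}

#' Fit the double-observer detection submodel
#'
#' Maximizes the conditional multinomial likelihood by BFGS from several
#' deterministic starts; the covariance matrix is the inverse observed
#' information. On-line detection probabilities `pF0`, `pR0` are reported
#' as the average over detected clusters of the per-cluster probability at
#' distance zero with the cluster's own covariates, and `p0*` as the
#' per-cluster average of `1-(1-pF0_i)(1-pR0_i)` (these coincide with the
#' plug-in values for covariate-free models). AICc uses the number of
#' detected clusters as sample size.
#'
#' @param dataset truncated `survey_dataset`.
#' @param spec one of [mr_model_specs()].
#' @return object of class `mr_fit`.
#' @export
fit_mr <- function(dataset, spec = "none") {
  des <- mr_design(dataset, spec)
  k <- mr_npar(spec)
  n <- length(des$d)
  if (n < k + 1) stop("too few observations to fit this specification")
  if (!any(des$history == "10") || !any(des$history == "01")) {
    stop(paste("degenerate capture histories: both observer asymmetries",
               "(front-only and rear-only detections) are required for",
               "identifiability"), call. = FALSE)
  }
  negll <- function(par) {
    v <- tryCatch(-mr_loglik(par, dataset, spec), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (st in mr_starts(k)) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best) || best$value >= 1e9) {
    stop(sprintf("MR fit for spec '%s' failed to converge from all starts", spec))
  }
  par <- best$par
  hess <- stats::optimHess(par, negll)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)) {
    stop(sprintf(paste("singular or invalid information matrix for spec '%s';",
                       "consider a simpler specification"), spec))
  }
  ll <- -best$value

  # p0 summaries averaged over clusters (delta-method SEs via the
  # numerical gradient of each summary in the parameters)
  mean_p0 <- function(p, which) {
    pr <- mr_probs(p, des, spec, d0 = TRUE)
    mean(pr[[which]])
  }
  p0f <- mean_p0(par, "pf"); p0r <- mean_p0(par, "pr")
  p0s <- mean_p0(par, "pstar")
  se_of <- function(which) {
    g <- num_grad(function(p) mean_p0(p, which), par)
    sqrt(max(0, drop(t(g) %*% vc %*% g)))
  }
  # meter-scale reporting: distance slopes were fitted per km
  scale <- rep(1, k)
  names_par <- c("b0_front", "b0_rear", "b_distance",
                 switch(spec, none = NULL, distance_by_position = "b_distance_rear",
                        paste0("b_", spec)))
  if (spec == "distance_by_position") {
    names_par <- c("b0_front", "b0_rear", "b_distance_front", "b_distance_rear")
    scale[3:4] <- 1 / 1000
  } else {
    scale[3] <- 1 / 1000
    if (spec == "distance_sq") scale[4] <- 1 / 1e6
  }
  coefs <- par * scale
  names(coefs) <- names_par
  vcov_rep <- diag(scale) %*% vc %*% diag(scale)
  dimnames(vcov_rep) <- list(names_par, names_par)

  structure(list(
    spec = spec, coefficients = coefs, par_internal = par,
    vcov = vcov_rep, vcov_internal = vc,
    loglik = ll, k = k, n = n, aicc = aicc(ll, k, n),
    p0_front = c(estimate = p0f, se = se_of("pf")),
    p0_rear = c(estimate = p0r, se = se_of("pr")),
    p0_star = c(estimate = p0s, se = se_of("pstar")),
    dataset = dataset), class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Double-observer MR fit, spec '%s' (k = %d, n = %d)\n",
              x$spec, x$k, x$n))
  cat(sprintf("  logLik %.3f  AICc %.2f\n", x$loglik, x$aicc))
  cat(sprintf("  pF0 %.3f (SE %.3f)  pR0 %.3f (SE %.3f)  p0* %.3f (SE %.3f)\n",
              x$p0_front[1], x$p0_front[2], x$p0_rear[1], x$p0_rear[2],
              x$p0_star[1], x$p0_star[2]))
  invisible(x)
}

#' Fit and rank the nine-model candidate set
#'
#' Fits every specification in [mr_model_specs()], ranks the successful fits
#' by AICc and attaches Akaike weights. A one-parameter addition whose AICc
#' improvement over the distance-and-position base model is less than 2 and
#' whose extra coefficient satisfies |coef|/SE < 1.28 is flagged as carrying
#' an uninformative parameter, to be excluded from model averaging.
#'
#' @param dataset truncated `survey_dataset`.
#' @param specs specifications to attempt (default all nine).
#' @return list with `fits` (ranked `mr_fit` objects), `table` (ranking
#'   data.frame with `delta_aicc`, `weight`, `uninformative`), `failed`
#'   (named character vector of per-spec error messages).
#' @export
mr_model_set <- function(dataset, specs = mr_model_specs()) {
  fits <- list(); failed <- character()
  for (sp in specs) {
    f <- tryCatch(fit_mr(dataset, sp), error = function(e) conditionMessage(e))
    if (inherits(f, "mr_fit")) fits[[sp]] <- f else failed[sp] <- f
  }
  if (!length(fits)) stop("no MR specification could be fitted")
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  ord <- order(aiccs, vapply(fits, function(f) f$k, numeric(1)))
  fits <- fits[ord]; aiccs <- aiccs[ord]
  delta <- aiccs - aiccs[1]
  w <- akaike_weights(aiccs)
  base_aicc <- if ("none" %in% names(fits)) fits[["none"]]$aicc else NA_real_
  uninf <- vapply(fits, function(f) {
    if (f$spec == "none" || is.na(base_aicc)) return(FALSE)
    extra <- f$k
    z <- abs(f$coefficients[extra]) / sqrt(f$vcov[extra, extra])
    (base_aicc - f$aicc) < 2 && z < 1.28
  }, logical(1))
  tab <- data.frame(
    spec = names(fits), aicc = aiccs, delta_aicc = delta, weight = w,
    p_f0 = vapply(fits, function(f) unname(f$p0_front[1]), numeric(1)),
    se_p_f0 = vapply(fits, function(f) unname(f$p0_front[2]), numeric(1)),
    p_r0 = vapply(fits, function(f) unname(f$p0_rear[1]), numeric(1)),
    se_p_r0 = vapply(fits, function(f) unname(f$p0_rear[2]), numeric(1)),
    p0_star = vapply(fits, function(f) unname(f$p0_star[1]), numeric(1)),
    se_p0_star = vapply(fits, function(f) unname(f$p0_star[2]), numeric(1)),
    uninformative = uninf, row.names = NULL)
  list(fits = fits, table = tab, failed = failed)
}

#' Pearson chi-square goodness of fit for a double-observer fit
#'
#' Compares observed and expected capture-history frequencies (front-only,
#' rear-only, both) within perpendicular-distance bins. Within each bin,
#' history cells with expected count below `min_expected` are merged with
#' the next-smallest cell; bins whose pooled total expectation is still
#' below the threshold are merged into the neighbouring bin. Because each
#' bin's cluster total is fixed (the model describes histories conditional
#' on detection), every retained bin contributes its cells minus one to
#' the degrees of freedom: df = cells - bins - k.
#'
#' @param fit an `mr_fit`.
#' @param bin_width_m distance bin width in meters.
#' @param min_expected pooling threshold (default 2).
#' @return list with `chi2`, `df`, `p_value`, `cells`.
#' @export
mr_gof <- function(fit, bin_width_m = 200, min_expected = 2) {
  stopifnot(inherits(fit, "mr_fit"))
  des <- mr_design(fit$dataset, fit$spec)
  pr <- mr_probs(fit$par_internal, des, fit$spec)
  # per-cluster conditional history probabilities
  p10 <- pr$pf * (1 - pr$pr) / pr$pstar
  p01 <- (1 - pr$pf) * pr$pr / pr$pstar
  p11 <- pr$pf * pr$pr / pr$pstar
  dist_m <- des$d * 1000
  breaks <- seq(0, ceiling(max(dist_m, bin_width_m) / bin_width_m) * bin_width_m,
                by = bin_width_m)
  bin <- cut(dist_m, breaks, include.lowest = TRUE)
  obs_hist <- des$history
  bins <- levels(bin)[table(bin) > 0]
  obs_cells <- list(); exp_cells <- list()
  for (b in bins) {
    idx <- which(bin == b)
    o <- c(`10` = sum(obs_hist[idx] == "10"), `01` = sum(obs_hist[idx] == "01"),
           `11` = sum(obs_hist[idx] == "11"))
    e <- c(`10` = sum(p10[idx]), `01` = sum(p01[idx]), `11` = sum(p11[idx]))
    # pool within bin: merge smallest expected cell into the next smallest
    while (length(e) > 1 && min(e) < min_expected) {
      i <- which.min(e)
      j <- which.min(replace(e, i, Inf))
      e[j] <- e[j] + e[i]; o[j] <- o[j] + o[i]
      e <- e[-i]; o <- o[-i]
    }
    obs_cells[[b]] <- o; exp_cells[[b]] <- e
  }
  # a bin whose total expectation is still too small has collapsed to one
  # cell; fold it into the smallest cell of the neighbouring bin
  i <- 1
  while (i <= length(exp_cells)) {
    if (sum(exp_cells[[i]]) < min_expected && length(exp_cells) > 1) {
      j <- if (i < length(exp_cells)) i + 1 else i - 1
      tgt <- which.min(exp_cells[[j]])
      exp_cells[[j]][tgt] <- exp_cells[[j]][tgt] + sum(exp_cells[[i]])
      obs_cells[[j]][tgt] <- obs_cells[[j]][tgt] + sum(obs_cells[[i]])
      exp_cells[[i]] <- NULL; obs_cells[[i]] <- NULL
    } else i <- i + 1
  }
  o <- unlist(obs_cells); e <- unlist(exp_cells)
  cells <- length(e)
  df <- cells - length(exp_cells) - fit$k
  if (df < 1) stop("fewer pooled cells than parameters; widen the bins")
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, df = df, p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       cells = cells, bins = length(exp_cells))
}
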