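# Stratified Horvitz-Thompson abundance with the full variance pipeline:
# combined detection probability pa = p0* x pd with delta-method variance;
# cluster abundance C_S = sum_k c_k / pa in the surveyed strips, scaled to
# each stratum by A_k/a_k; detection variance propagated per stratum;
# encounter-rate variance from systematic paired transects (Fewster-style
# "S2" grouping); total bears N = C_Total x mean cluster size, with
# variances combined by the product rule; lognormal interval on N.

#' Combined detection probability
#'
#' `pa = p0* x pd` with delta-method variance
#' `var(pa) = p0*^2 var(pd) + pd^2 var(p0*)`.
#'
#' @param p0_star on-line detection probability (at least one observer),
#'   in (0, 1].
#' @param var_p0_star its variance.
#' @param pd mean detection probability within the strip, in (0, 1].
#' @param var_pd its variance.
#' @return list with `estimate`, `var`, `se`.
#' @export
combined_pa <- function(p0_star, var_p0_star, pd, var_pd) {
  if (p0_star <= 0 || p0_star > 1 || pd <= 0 || pd > 1) {
    stop("p0_star and pd must lie in (0, 1]")
  }
  if (var_p0_star < 0 || var_pd < 0) stop("variances must be non-negative")
  pa <- p0_star * pd
  v <- p0_star^2 * var_pd + pd^2 * var_p0_star
  list(estimate = pa, var = v, se = sqrt(v))
}

#' Mean cluster (group) size
#'
#' Arithmetic mean of detected cluster sizes with SE = sample SD / sqrt(n).
#'
#' @param x a `survey_dataset`, or a numeric vector of cluster sizes.
#' @return list with `estimate`, `se`, `n`.
#' @export
mean_group <- function(x) {
  sizes <- if (inherits(x, "survey_dataset")) x$observations$cluster_size else x
  n <- length(sizes)
  if (!n) stop("no observations: cannot estimate mean cluster size")
  se <- if (n > 1) stats::sd(sizes) / sqrt(n) else 0
  list(estimate = mean(sizes), se = se, n = n)
}

#' Encounter-rate variance for systematic transects (paired-sample form)
#'
#' Treats adjacent transects (by position along the systematic design) as
#' paired samples: transects are grouped into non-overlapping adjacent
#' pairs (a trailing triple if their number is odd) and within each group
#' the length-weighted estimator
#' `var_h(n/L) = K_h / (L_h^2 (K_h - 1)) * sum_j l_j^2 (n_j/l_j - n_h/L_h)^2`
#' is applied; groups combine as `var(n/L) = sum_h (L_h/L)^2 var_h`.
#'
#' @param counts per-transect detected cluster counts.
#' @param lengths_km per-transect lengths (km).
#' @param design_order position of each transect along the design.
#' @return list with `var_rate` (variance of the encounter rate n/L),
#'   `var_count` (variance of the total count, `L^2 var_rate`),
#'   `rate` (n/L), `n`, `L`.
#' @export
encounter_var_s2 <- function(counts, lengths_km, design_order = seq_along(counts)) {
  K <- length(counts)
  stopifnot(length(lengths_km) == K, length(design_order) == K)
  if (K < 2) stop("encounter-rate variance requires at least 2 transects")
  ord <- order(design_order)
  counts <- counts[ord]; lengths_km <- lengths_km[ord]
  # non-overlapping adjacent pairs; trailing group of 3 when K is odd
  grp <- rep(seq_len(K %/% 2), each = 2, length.out = K - K %% 2)
  if (K %% 2 == 1) grp <- c(grp, K %/% 2)
  L <- sum(lengths_km)
  var_rate <- 0
  for (h in unique(grp)) {
    idx <- which(grp == h)
    Kh <- length(idx)
    Lh <- sum(lengths_km[idx])
    rh <- sum(counts[idx]) / Lh
    vh <- Kh / (Lh^2 * (Kh - 1)) *
      sum(lengths_km[idx]^2 * (counts[idx] / lengths_km[idx] - rh)^2)
    var_rate <- var_rate + (Lh / L)^2 * vh
  }
  list(var_rate = var_rate, var_count = L^2 * var_rate,
       rate = sum(counts) / L, n = sum(counts), L = L)
}

#' Lognormal confidence interval from a coefficient of variation
#'
#' `C = exp(z sqrt(ln(1 + cv^2)))`; the interval is
#' `(estimate/C, estimate x C)`.
#'
#' @param estimate positive point estimate.
#' @param cv its coefficient of variation (>= 0).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
lognormal_ci <- function(estimate, cv, level = 0.95) {
  stopifnot(estimate > 0, cv >= 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(low = estimate / C, high = estimate * C)
}

#' Stratified Horvitz-Thompson abundance estimate
#'
#' Applies a single combined detection probability and a single mean
#' cluster size across strata (appropriate when too few detections exist
#' to estimate them per stratum), with per-stratum scaling `A_k / a_k`
#' where the surveyed strip area is `a_k = 2 w L_k`. Variance components:
#' detection (delta method per stratum), encounter rate
#' ([encounter_var_s2()] per stratum, scaled to the stratum total by
#' `(A_k/a_k)/pa` held fixed), and cluster size (product rule on
#' `N = C_Total x g`).
#'
#' @param dataset a truncated `survey_dataset` (the stratum `truncation_m`
#'   supplies `w`).
#' @param pa combined detection probability (scalar in (0, 1]).
#' @param var_pa its variance.
#' @param gbar mean cluster size (default: [mean_group()] of the dataset).
#' @param var_gbar its variance.
#' @param level confidence level for the lognormal interval on N.
#' @return object of class `abundance_estimate`: cluster abundance in the
#'   surveyed strips (`clusters_surveyed`) and whole area
#'   (`clusters_total`), bears (`n_total`) with `se`, `cv` and lognormal
#'   `ci`, the variance components on the cluster scale
#'   (`var_detection`, `var_encounter`, `var_total`), and a `strata` table
#'   with per-stratum clusters, bears and densities per 1000 km^2.
#' @export
ht_abundance <- function(dataset, pa, var_pa, gbar = NULL, var_gbar = NULL,
                         level = 0.95) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (pa <= 0 || pa > 1) stop("pa must lie in (0, 1]")
  if (var_pa < 0) stop("var_pa must be non-negative")
  obs <- dataset$observations
  if (!nrow(obs)) stop("no detections in any stratum")
  if (is.null(gbar)) {
    g <- mean_group(dataset)
    gbar <- g$estimate; var_gbar <- g$se^2
  }
  if (is.null(var_gbar)) var_gbar <- 0

  strata <- dataset$strata
  w_km <- strata$truncation_m / 1000
  if (any(!is.finite(w_km))) stop("strata must carry a finite truncation_m")

  per <- lapply(seq_len(nrow(strata)), function(i) {
    sid <- strata$id[i]
    tr <- dataset$transects[dataset$transects$stratum_id == sid, , drop = FALSE]
    L_k <- sum(tr$length_km)
    if (L_k <= 0) stop(sprintf("stratum '%s' has no surveyed effort", sid))
    a_k <- 2 * w_km[i] * L_k
    c_k <- sum(obs$stratum_id == sid)
    scale_k <- strata$area_km2[i] / a_k
    # detection variance on the stratum total (delta method in pa)
    var_det_k <- scale_k^2 * (c_k / pa^2)^2 * var_pa
    # encounter variance on the stratum total, pa and A/a held fixed
    counts <- vapply(tr$id, function(tid) sum(obs$transect_id == tid),
                     numeric(1))
    if (nrow(tr) < 2) {
      stop(sprintf(
        "stratum '%s' has a single transect; encounter variance undefined", sid))
    }
    enc <- encounter_var_s2(counts, tr$length_km, tr$design_order)
    var_enc_k <- (scale_k / pa)^2 * enc$var_count
    C_k <- scale_k * c_k / pa
    list(id = sid, c_k = c_k, L_k = L_k, a_k = a_k, A_k = strata$area_km2[i],
         C_k = C_k, var_det = var_det_k, var_enc = var_enc_k)
  })

  c_k <- vapply(per, `[[`, numeric(1), "c_k")
  C_k <- vapply(per, `[[`, numeric(1), "C_k")
  var_det <- sum(vapply(per, `[[`, numeric(1), "var_det"))
  var_enc <- sum(vapply(per, `[[`, numeric(1), "var_enc"))
  C_S <- sum(c_k) / pa
  C_total <- sum(C_k)
  var_C <- var_det + var_enc
  N <- C_total * gbar
  var_N <- C_total^2 * var_gbar + gbar^2 * var_C
  cv <- sqrt(var_N) / N
  ci <- lognormal_ci(N, cv, level)

  strata_tab <- data.frame(
    id = vapply(per, `[[`, character(1), "id"),
    c_k = c_k,
    effort_km = vapply(per, `[[`, numeric(1), "L_k"),
    a_km2 = vapply(per, `[[`, numeric(1), "a_k"),
    area_km2 = vapply(per, `[[`, numeric(1), "A_k"),
    clusters = C_k,
    bears = C_k * gbar,
    density_1000km2 = 1000 * C_k * gbar /
      vapply(per, `[[`, numeric(1), "A_k"),
    se_density_1000km2 = 1000 * sqrt(
      C_k^2 * var_gbar + gbar^2 *
        (vapply(per, `[[`, numeric(1), "var_det") +
         vapply(per, `[[`, numeric(1), "var_enc"))) /
      vapply(per, `[[`, numeric(1), "A_k"))

  structure(list(
    clusters_surveyed = C_S, clusters_total = C_total, n_total = N,
    mean_group = c(estimate = gbar, se = sqrt(var_gbar)),
    pa = c(estimate = pa, se = sqrt(var_pa)),
    var_detection = var_det, var_encounter = var_enc, var_total = var_C,
    se = sqrt(var_N), cv = cv, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    level = level, strata = strata_tab), class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance: %.0f bears (SE %.0f, CV %.0f%%, %d%% lognormal CI %.0f-%.0f)\n",
              x$n_total, x$se, 100 * x$cv, round(100 * x$level),
              x$ci_low, x$ci_high))
  cat(sprintf("  clusters: %.1f surveyed strips, %.1f total; mean size %.2f (SE %.2f); pa %.3f\n",
              x$clusters_surveyed, x$clusters_total,
              x$mean_group[1], x$mean_group[2], x$pa[1]))
  cat(sprintf("  variance (clusters): detection %.1f + encounter %.1f = %.1f\n",
              x$var_detection, x$var_encounter, x$var_total))
  invisible(x)
}

#' Extrapolate a density estimate to an unsurveyed area
#'
#' @param density bears per 1000 km^2.
#' @param se_density its standard error.
#' @param area_km2 area to extrapolate to (km^2).
#' @param level confidence level for the lognormal interval.
#' @return list with `n` (bears), `se`, `cv`, `ci`.
#' @export
extrapolate_density <- function(density, se_density, area_km2, level = 0.95) {
  stopifnot(density >= 0, se_density >= 0, area_km2 > 0)
  n <- density * area_km2 / 1000
  if (n == 0) {
    return(list(n = 0, se = 0, cv = NA_real_, ci = c(low = 0, high = 0)))
  }
  cv <- se_density / density
  list(n = n, se = n * cv, cv = cv, ci = lognormal_ci(n, cv, level))
}

#' Coefficient-of-variation decomposition of an abundance estimate
#'
#' Composes component CVs exactly the way the abundance variance pipeline
#' does: `cv(pa)^2 = cv(p0*)^2 + cv(pd)^2` (product, delta method),
#' `cv(C)^2 = cv(pa)^2 + cv(enc)^2` (detection plus encounter variance),
#' `cv(N)^2 = cv(C)^2 + cv(g)^2` (product with mean cluster size).
#'
#' @param cv_p0_star CV of the on-line detection probability.
#' @param cv_pd CV of the distance-sampling detection probability.
#' @param cv_enc CV of the encounter rate.
#' @param cv_g CV of mean cluster size.
#' @return data.frame with one row per component (`p0_star`, `pd`, `pa`,
#'   `encounter`, `C_total`, `g`, `N_total`), its CV, and a flag on the
#'   largest individually estimated component.
#' @export
cv_components <- function(cv_p0_star, cv_pd, cv_enc, cv_g) {
  cv_pa <- sqrt(cv_p0_star^2 + cv_pd^2)
  cv_C <- sqrt(cv_pa^2 + cv_enc^2)
  cv_N <- sqrt(cv_C^2 + cv_g^2)
  out <- data.frame(
    component = c("p0_star", "pd", "pa", "encounter", "C_total", "g", "N_total"),
    cv = c(cv_p0_star, cv_pd, cv_pa, cv_enc, cv_C, cv_g, cv_N))
  indiv <- out$component %in% c("p0_star", "pd", "encounter", "g")
  out$largest <- FALSE
  out$largest[indiv][which.max(out$cv[indiv])] <- TRUE
  out
}

#' Effort multiplier to reach a target precision
#'
#' Survey precision improves with effort as `1/sqrt(n)`, so reaching a
#' target CV requires `(cv_now / cv_target)^2` times the current effort.
#'
#' @param cv_now current coefficient of variation, in (0, 1].
#' @param cv_target desired coefficient of variation, in (0, 1].
#' @return the multiplicative effort factor.
#' @export
effort_for_cv <- function(cv_now, cv_target) {
  stopifnot(cv_now > 0, cv_now <= 1, cv_target > 0, cv_target <= 1)
  (cv_now / cv_target)^2
}
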