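# Synthetic stratified double-observer line-transect surveys with known
# truth. Each stratum is modelled as a square region with east-west
# transects at the design spacing and a uniform random start; cluster
# centers follow a homogeneous Poisson process. Detection is composed in
# two stages mirroring the estimation model: a cluster at perpendicular
# distance y is "available" with probability g(y) (the distance-sampling
# curve), and, given availability, each observer team detects it
# independently with its logistic on-line probability declining in
# distance (the mark-recapture curves). The union detection probability is
# therefore g(y) * [1 - (1-pF(y))(1-pR(y))], the MR stage consistently
# recovers the logistic curves (availability cancels from the conditional
# capture-history likelihood), and the DS stage sees the product shape.

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the 2014 Kane Basin design: two strata (18,870 and
#' 9,110 km^2) with 6 and 18 km transect spacing, truncation 1400 m,
#' cluster sizes 1:2:3 in proportions 13:9:6 (mean 1.75), a half-normal
#' availability curve with 700 m scale (strip-mean detection ~0.6), and
#' logistic observer curves with on-line probabilities ~0.84 (front) and
#' ~0.73 (rear) declining with distance.
#'
#' @param strata data.frame with `area_km2`, `density_1000km2` (bears per
#'   1000 km^2) and `spacing_km` per stratum.
#' @param w_m truncation / strip half-width (meters).
#' @param group_size_probs probability vector over cluster sizes 1, 2, ...
#' @param mr_coef named vector `b0_front`, `b0_rear`, `b_distance_km`
#'   (logit-scale intercepts and shared slope per km).
#' @param ds_sigma_m scale of the half-normal availability curve (meters).
#' @param covariate_probs Bernoulli rates for the binary sighting
#'   covariates recorded on each cluster.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(strata = data.frame(
                         area_km2 = c(18870, 9110),
                         density_1000km2 = c(10, 1.7),
                         spacing_km = c(6, 18)),
                       w_m = 1400,
                       group_size_probs = c(13, 9, 6) / 28,
                       mr_coef = c(b0_front = 1.66, b0_rear = 0.98,
                                   b_distance_km = -1.2),
                       ds_sigma_m = 700,
                       covariate_probs = c(activity = 0.15, ice_rough = 0.5,
                                           visibility_bad = 0.2)) {
  stopifnot(all(strata$density_1000km2 >= 0), all(strata$area_km2 > 0),
            all(strata$spacing_km > 0), w_m > 0, ds_sigma_m > 0,
            abs(sum(group_size_probs) - 1) < 1e-8)
  structure(list(strata = strata, w_m = w_m,
                 group_size_probs = group_size_probs, mr_coef = mr_coef,
                 ds_sigma_m = ds_sigma_m, covariate_probs = covariate_probs),
            class = "sim_config")
}

sim_g <- function(y_m, config) exp(-y_m^2 / (2 * config$ds_sigma_m^2))

sim_p_obs <- function(y_m, config) {
  eta_f <- config$mr_coef[["b0_front"]] + config$mr_coef[["b_distance_km"]] * y_m / 1000
  eta_r <- config$mr_coef[["b0_rear"]] + config$mr_coef[["b_distance_km"]] * y_m / 1000
  list(pf = inv_logit(eta_f), pr = inv_logit(eta_r))
}

#' Expected number of detected clusters under a configuration
#'
#' Closed-form expectation: per stratum, cluster intensity times strip
#' area times the strip-mean union detection probability
#' `E_y[g(y) (1 - (1-pF(y))(1-pR(y)))]`, using the deterministic transect
#' count and length implied by the square-stratum geometry.
#'
#' @param config a `sim_config`.
#' @return expected detected clusters (scalar).
#' @export
expected_detections <- function(config) {
  gbar <- sum(seq_along(config$group_size_probs) * config$group_size_probs)
  w_km <- config$w_m / 1000
  p_incl <- quad(function(y) {
    p <- sim_p_obs(y, config)
    sim_g(y, config) * (1 - (1 - p$pf) * (1 - p$pr))
  }, 0, config$w_m) / config$w_m
  total <- 0
  for (i in seq_len(nrow(config$strata))) {
    side <- sqrt(config$strata$area_km2[i])
    # uniform random design start: expected transect count is side/spacing
    K <- max(2, side / config$strata$spacing_km[i])
    strip <- 2 * w_km * side * K
    lambda <- config$strata$density_1000km2[i] / gbar / 1000  # clusters/km^2
    total <- total + lambda * strip * p_incl
  }
  total
}

#' Generate a synthetic double-observer line-transect survey
#'
#' @param config a `sim_config`.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with `dataset` (a `survey_dataset` holding only clusters
#'   detected by at least one observer) and `truth` (list: `true_n` =
#'   expected bears over the whole study area, `true_clusters` = realized
#'   clusters inside the surveyed strips, `placements` = all simulated
#'   clusters with distances and detection outcomes).
#' @export
generate_survey <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  gbar <- sum(seq_along(config$group_size_probs) * config$group_size_probs)
  w_km <- config$w_m / 1000
  transects <- list(); placements <- list(); obs <- list()
  oid <- 0L
  for (i in seq_len(nrow(config$strata))) {
    sid <- paste0("s", i)
    side <- sqrt(config$strata$area_km2[i])
    sp <- config$strata$spacing_km[i]
    start <- stats::runif(1, 0, sp)
    ypos <- seq(start, side, by = sp)
    if (length(ypos) < 2) ypos <- c(start, min(side, start + sp))
    K <- length(ypos)
    transects[[i]] <- data.frame(
      id = sprintf("%s_t%02d", sid, seq_len(K)), stratum_id = sid,
      length_km = side, design_order = seq_len(K), is_ferry = 0L)
    lambda <- config$strata$density_1000km2[i] / gbar / 1000
    n_clust <- stats::rpois(1, lambda * 2 * w_km * side * K)
    if (n_clust == 0) next
    t_idx <- sample.int(K, n_clust, replace = TRUE)
    y <- stats::runif(n_clust, 0, config$w_m)
    avail <- stats::rbinom(n_clust, 1, sim_g(y, config))
    p <- sim_p_obs(y, config)
    sf <- stats::rbinom(n_clust, 1, p$pf) * avail
    sr <- stats::rbinom(n_clust, 1, p$pr) * avail
    size <- sample(seq_along(config$group_size_probs), n_clust,
                   replace = TRUE, prob = config$group_size_probs)
    covs <- lapply(config$covariate_probs, function(pr)
      stats::rbinom(n_clust, 1, pr))
    cloud <- sample(0:4, n_clust, replace = TRUE)
    pl <- data.frame(stratum_id = sid,
                     transect_id = transects[[i]]$id[t_idx],
                     distance_m = y, cluster_size = size,
                     seen_front = sf, seen_rear = sr,
                     activity = covs$activity, ice_rough = covs$ice_rough,
                     visibility_bad = covs$visibility_bad,
                     cloud_quartile = cloud)
    placements[[i]] <- pl
    det <- pl[pl$seen_front + pl$seen_rear >= 1, , drop = FALSE]
    if (nrow(det)) {
      det$id <- sprintf("obs%05d", oid + seq_len(nrow(det)))
      oid <- oid + nrow(det)
      obs[[i]] <- det
    }
  }
  transects <- do.call(rbind, transects)
  placements <- if (length(placements)) do.call(rbind, placements) else NULL
  obs <- if (length(obs)) do.call(rbind, obs) else NULL
  if (is.null(obs)) {
    warning("no clusters detected under this configuration")
    obs <- data.frame(id = character(), transect_id = character(),
                      stratum_id = character(), distance_m = numeric(),
                      seen_front = integer(), seen_rear = integer(),
                      cluster_size = integer())
  }
  strata <- data.frame(id = paste0("s", seq_len(nrow(config$strata))),
                       area_km2 = config$strata$area_km2,
                       truncation_m = config$w_m)
  dataset <- survey_dataset(obs, transects, strata)
  true_n <- sum(config$strata$density_1000km2 * config$strata$area_km2 / 1000)
  truth <- list(true_n = true_n,
                true_clusters = if (is.null(placements)) 0L else nrow(placements),
                placements = placements)
  list(dataset = dataset, truth = truth)
}

#' Fit the full estimation pipeline to one synthetic survey
#'
#' Double-observer submodel (distance-and-position specification), one or
#' more distance-sampling keys with forward adjustment selection, Akaike
#' averaging across the keys, combined detection probability and
#' stratified Horvitz-Thompson abundance.
#'
#' @param dataset a `survey_dataset`.
#' @param keys distance-sampling keys to fit and average over.
#' @param pa_known optional known combined detection probability (with
#'   `var_pa_known`); when supplied the detection stages are skipped, e.g.
#'   for census checks under perfect detection.
#' @param var_pa_known variance of `pa_known`.
#' @return an `abundance_estimate`.
#' @export
estimate_abundance <- function(dataset, keys = "half_normal",
                               pa_known = NULL, var_pa_known = 0) {
  if (!is.null(pa_known)) {
    return(ht_abundance(dataset, pa_known, var_pa_known))
  }
  w <- max(dataset$strata$truncation_m)
  mr <- fit_mr(dataset, "none")
  ds_fits <- lapply(keys, function(k)
    select_adjustments(dataset$observations$distance_m, k, w))
  if (length(ds_fits) > 1) {
    aics <- vapply(ds_fits, function(f) f$aic, numeric(1))
    wts <- akaike_weights(aics)
    pd <- model_average(vapply(ds_fits, function(f) unname(f$pd[1]), numeric(1)),
                        vapply(ds_fits, function(f) unname(f$pd[2]), numeric(1)),
                        wts)
  } else {
    pd <- list(estimate = unname(ds_fits[[1]]$pd[1]),
               se = unname(ds_fits[[1]]$pd[2]))
  }
  pa <- combined_pa(unname(mr$p0_star[1]), unname(mr$p0_star[2])^2,
                    pd$estimate, pd$se^2)
  ht_abundance(dataset, pa$estimate, pa$var)
}

#' Parameter-recovery study over replicated synthetic surveys
#'
#' Generates `n_reps` surveys (seeds `seed + 1, ..., seed + n_reps`), runs
#' the full pipeline on each, and summarizes recovery of total abundance:
#' relative bias, relative RMSE, empirical CV and coverage of the nominal
#' 95% lognormal interval. Replicate-level estimation failures are
#' recorded, not fatal.
#'
#' @param config a `sim_config`.
#' @param n_reps number of replicates (>= 2).
#' @param seed base integer seed.
#' @param keys distance-sampling keys passed to [estimate_abundance()].
#' @param ... further arguments for [estimate_abundance()] (e.g.
#'   `pa_known = 1` for perfect-detection census checks).
#' @return list with `summary` (one-row data.frame) and `replicates`
#'   (per-replicate estimates and intervals).
#' @export
recovery_study <- function(config, n_reps, seed = 1, keys = "half_normal",
                           ...) {
  stopifnot(n_reps >= 2)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- generate_survey(config, seed + r)
    est <- tryCatch(estimate_abundance(sim$dataset, keys = keys, ...),
                    error = function(e) conditionMessage(e))
    if (inherits(est, "abundance_estimate")) {
      rows[[r]] <- data.frame(
        rep = r, n_hat = est$n_total, cv = est$cv,
        ci_low = est$ci_low, ci_high = est$ci_high,
        true_n = sim$truth$true_n,
        covered = est$ci_low <= sim$truth$true_n &
          sim$truth$true_n <= est$ci_high,
        error = NA_character_)
    } else {
      rows[[r]] <- data.frame(rep = r, n_hat = NA_real_, cv = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              true_n = sim$truth$true_n, covered = NA,
                              error = as.character(est))
    }
  }
  reps <- do.call(rbind, rows)
  ok <- !is.na(reps$n_hat)
  rel_err <- (reps$n_hat[ok] - reps$true_n[ok]) / reps$true_n[ok]
  summary <- data.frame(
    n_reps = n_reps, n_failed = sum(!ok),
    rel_bias = mean(rel_err),
    rel_rmse = sqrt(mean(rel_err^2)),
    empirical_cv = stats::sd(reps$n_hat[ok]) / mean(reps$n_hat[ok]),
    mean_model_cv = mean(reps$cv[ok]),
    coverage = mean(reps$covered[ok]),
    mc_se_coverage = sqrt(mean(reps$covered[ok]) *
                            (1 - mean(reps$covered[ok])) / sum(ok)))
  list(summary = summary, replicates = reps)
}
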