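# Published summary tables from the April-May 2014 on-ice aerial survey of
# the Kane Basin polar bear subpopulation. Raw perpendicular distances were
# never deposited, so these printed summaries are the reproducible inputs:
# the binned double-observer sighting frequencies, per-stratum effort and
# areas, the cluster-size composition, and the per-model detection and
# abundance rows used for model averaging.

#' Kane Basin binned double-observer sighting frequencies
#'
#' Frequencies of sightings and sighting failures of polar bear clusters by
#' the front and rear observer teams in 200 m perpendicular-distance bins,
#' after truncation at 1400 m (28 clusters).
#'
#' @return data.frame in the [binned_summary()] layout (without the
#'   Combined row, which [binned_summary()] recomputes).
#' @export
kb_sighting_bins <- function() {
  data.frame(
    bin = c("0-200", "200-400", "400-600", "600-800", "800-1000",
            "1000-1200", "1200-1400"),
    seen_f = c(8, 6, 3, 1, 1, 1, 2),
    missed_f = c(0, 0, 2, 1, 2, 1, 0),
    seen_r = c(4, 3, 4, 2, 2, 1, 0),
    missed_r = c(4, 3, 1, 0, 1, 1, 2),
    seen_both = c(4, 3, 2, 1, 0, 0, 0),
    total = c(8, 6, 5, 2, 3, 2, 2))
}

#' Kane Basin survey strata
#'
#' High-density stratum: landfast ice and nearshore pack ice within ~30 km
#' of land; low-density stratum: offshore pack ice out to the North Water
#' polynya edge. Truncation 1400 m.
#' @return data.frame of stratum specifications.
#' @export
kb_strata <- function() {
  data.frame(id = c("high", "low"),
             area_km2 = c(18870, 9110),
             label = c("high density", "low density"),
             truncation_m = 1400)
}

#' Kane Basin transect effort by stratum
#'
#' Linear kilometers flown: a priori transects in each stratum plus ferry
#' flights over ice included as transects in the high-density stratum.
#' @return data.frame with `stratum_id`, `type`, `n_transects`, `length_km`.
#' @export
kb_transect_effort <- function() {
  data.frame(stratum_id = c("high", "low", "high"),
             type = c("a_priori", "a_priori", "ferry"),
             n_transects = c(222L, 14L, 9L),
             length_km = c(3389, 681, 90))
}

#' Kane Basin cluster sizes and cub-of-the-year litter sizes
#'
#' The 28 retained clusters comprised 13 lone bears, 9 groups of two and 6
#' groups of three; cub-of-the-year litters were 6 twins and 5 singletons.
#'
#' @return list with integer vectors `cluster_sizes` (length 28) and
#'   `litter_sizes` (length 11).
#' @export
kb_cluster_sizes <- function() {
  list(cluster_sizes = rep(c(1L, 2L, 3L), times = c(13L, 9L, 6L)),
       litter_sizes = rep(c(2L, 1L), times = c(6L, 5L)))
}

#' Kane Basin mark-recapture model-selection results
#'
#' Per-model on-line detection probabilities from the double-observer
#' submodel: the three AICc-supported models (ice structure, rear blind
#' spot, distance-and-position only) with their Akaike weights.
#' @return data.frame with model label, `delta_aicc`, `weight`, `p_f0`,
#'   `se_p_f0`, `p_r0`, `se_p_r0`, `p0_star`, `se_p0_star`.
#' @export
kb_mr_table <- function() {
  data.frame(
    model = c("ice_structure", "blind_spot", "none"),
    delta_aicc = c(0.00, 0.35, 0.98),
    weight = c(0.41, 0.34, 0.25),
    p_f0 = c(0.826, 0.891, 0.842),
    se_p_f0 = c(0.116, 0.080, 0.097),
    p_r0 = c(0.720, 0.774, 0.727),
    se_p_r0 = c(0.142, 0.113, 0.133),
    p0_star = c(0.932, 0.975, 0.957),
    se_p0_star = c(0.077, 0.029, 0.044))
}

#' Kane Basin distance-sampling model results
#'
#' The four supported detection functions with goodness of fit, AIC ranking
#' and mean detection probability within the 1400 m strip.
#' @return data.frame with `model`, `cvm`, `cvm_p`, `df`, `delta_aic`,
#'   `weight`, `pd`, `se_pd`.
#' @export
kb_ds_table <- function() {
  data.frame(
    model = c("uniform_cos", "hazard_rate", "half_normal", "uniform_poly"),
    cvm = c(0.13, 0.04, 0.14, 0.31),
    cvm_p = c(0.45, 0.94, 0.42, 0.12),
    df = c(4L, 5L, 4L, 4L),
    delta_aic = c(0.00, 0.27, 0.84, 2.58),
    weight = c(0.356, 0.311, 0.234, 0.098),
    pd = c(0.614, 0.426, 0.623, 0.751),
    se_pd = c(0.077, 0.198, 0.088, 0.070))
}

#' Kane Basin per-model abundance estimates
#'
#' Total abundance and stratum densities (bears per 1000 km^2) per detection
#' function, used for the model-averaged abundance.
#' @return data.frame with `model`, `weight`, densities with SEs, `n_hat`,
#'   `se_n_hat`, `cv`.
#' @export
kb_abundance_table <- function() {
  data.frame(
    model = c("uniform_cos", "hazard_rate", "half_normal", "uniform_poly"),
    weight = c(0.356, 0.311, 0.234, 0.098),
    density_high = c(8.2, 11.9, 8.1, 6.7),
    se_density_high = c(1.9, 6.0, 1.9, 1.4),
    density_low = c(1.6, 2.3, 1.5, 1.3),
    se_density_low = c(1.6, 2.5, 1.6, 1.3),
    density_total = c(6.1, 8.8, 6.0, 5.0),
    se_density_total = c(1.4, 4.4, 1.4, 1.1),
    n_hat = c(170, 245, 167, 139),
    se_n_hat = c(40, 124, 40, 30),
    cv = c(0.23, 0.50, 0.24, 0.22))
}

#' Unsurveyed sea-ice areas adjacent to the Kane Basin survey
#'
#' Areas (km^2) of the sea ice near Qaanaaq in southeastern Kane Basin and
#' of the unsampled central North Water polynya, to which the low-density
#' stratum density is extrapolated.
#' @return named numeric vector of areas in km^2.
#' @export
kb_unsurveyed_areas <- function() {
  c(qaanaaq = 3245, north_water_polynya = 27214)
}

#' Kane Basin analysis fixture
#'
#' A `survey_dataset` rebuilt from the printed binned sighting table
#' ([kb_sighting_bins()]), with distances at bin midpoints, the printed
#' cluster-size composition assigned largest-first by distance rank (sizes
#' are exchangeable in the printed summaries), and the published stratum
#' geometry. 27 clusters sit in the high-density stratum and 1 in the
#' low-density stratum, matching the published stratum counts. Covariates
#' are absent: covariate detection models cannot be fitted to it.
#'
#' @return a `survey_dataset` with 28 observations.
#' @export
kb_survey_fixture <- function() {
  eff <- kb_transect_effort()
  transects <- data.frame(
    id = c("high_1", "high_2", "low_1", "low_2"),
    stratum_id = c("high", "high", "low", "low"),
    length_km = c(eff$length_km[1] / 2 + eff$length_km[3],
                  eff$length_km[1] / 2,
                  eff$length_km[2] / 2, eff$length_km[2] / 2),
    design_order = c(1, 2, 1, 2))
  d <- survey_from_bins(kb_sighting_bins(), transects = transects,
                        strata = kb_strata())
  obs <- d$observations
  # published composition: 13 singles, 9 pairs, 6 triples
  obs$cluster_size <- sort(kb_cluster_sizes()$cluster_sizes)
  # one cluster was on a low-density transect; the rest high-density
  obs$transect_id <- "high_1"
  obs$stratum_id <- "high"
  obs$transect_id[nrow(obs)] <- "low_1"
  obs$stratum_id[nrow(obs)] <- "low"
  survey_dataset(obs, transects, d$strata)
}
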