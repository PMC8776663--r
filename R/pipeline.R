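# End-to-end analysis: load -> truncate -> double-observer model set ->
# distance-sampling model set -> model averaging -> stratified abundance ->
# extrapolation -> table-style CSV and JSON outputs.

#' Run the full mark-recapture distance sampling analysis
#'
#' Orchestrates every stage behind one call. The configuration is a list
#' (or path to a YAML file) with entries:
#' \describe{
#'   \item{obs_path, transect_path, strata}{inputs for [load_survey()];
#'     alternatively pass a ready `survey_dataset` as `dataset`.}
#'   \item{truncation_m}{right-truncation distance (default 1400).}
#'   \item{mr_specs}{double-observer specifications to attempt (default
#'     all nine; reduced automatically when covariates are absent).}
#'   \item{ds_keys}{named list of key/adjustment pairs; default the four
#'     standard candidates (uniform-cosine, uniform-polynomial,
#'     half-normal, hazard-rate).}
#'   \item{delta_threshold}{averaging rule: models within this many
#'     criterion units of the best (default 4).}
#'   \item{exclude_models}{distance-sampling models to drop from a second,
#'     renormalized model average (e.g. `"hazard_rate"`).}
#'   \item{extrapolation_areas}{named vector of unsurveyed areas (km^2) to
#'     which the low-density-stratum density is extrapolated.}
#'   \item{out_dir}{optional output directory for CSV/JSON reports.}
#'   \item{seed}{integer seed (stages are deterministic; recorded in the
#'     bundle for provenance).}
#' }
#' Stage failures abort with an error naming the stage; outputs already
#' written are preserved.
#'
#' @param config list or YAML path as described above.
#' @return invisibly, the results bundle (list with `sightings`, `mr`,
#'   `ds`, `averages`, `abundance`, `extrapolations`, `log`).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    truncation_m = 1400, delta_threshold = 4, exclude_models = character(),
    extrapolation_areas = NULL, out_dir = NULL, seed = 1,
    ds_keys = list(uniform_cos = c("uniform", "cosine"),
                   uniform_poly = c("uniform", "simple_poly"),
                   half_normal = c("half_normal", "cosine"),
                   hazard_rate = c("hazard_rate", "cosine"))), config)
  set.seed(as.integer(cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  dataset <- stage("load", {
    if (!is.null(cfg$dataset)) cfg$dataset
    else load_survey(cfg$obs_path, cfg$transect_path, cfg$strata)
  })
  n0 <- nrow(dataset$observations)
  dataset <- stage("truncate", truncate_survey(dataset, cfg$truncation_m))
  note("truncation at %g m: %d of %d clusters retained", cfg$truncation_m,
       nrow(dataset$observations), n0)
  sightings <- stage("summarize", binned_summary(dataset, 200))

  has_cov <- !anyNA(dataset$observations[, OBS_COV_COLS])
  mr_specs <- cfg$mr_specs
  if (is.null(mr_specs)) {
    mr_specs <- if (has_cov) mr_model_specs() else
      c("none", "distance_sq", "blind_spot", "distance_by_position")
  }
  mr <- stage("fit-mr", mr_model_set(dataset, mr_specs))
  for (nm in names(mr$failed)) note("MR spec '%s' failed: %s", nm, mr$failed[nm])
  mr_keep <- mr$table$delta_aicc < cfg$delta_threshold & !mr$table$uninformative
  p0_avg <- stage("average-p0", model_average(
    mr$table$p0_star[mr_keep], mr$table$se_p0_star[mr_keep],
    mr$table$weight[mr_keep]))
  note("MR averaging set: %s", paste(mr$table$spec[mr_keep], collapse = ", "))

  w <- max(dataset$strata$truncation_m)
  ds_fits <- stage("fit-ds", {
    out <- list()
    for (nm in names(cfg$ds_keys)) {
      kk <- cfg$ds_keys[[nm]]
      f <- tryCatch(select_adjustments(dataset$observations$distance_m,
                                       kk[1], w, adjustment = kk[2]),
                    error = function(e) conditionMessage(e))
      if (inherits(f, "ds_fit")) out[[nm]] <- f
      else note("DS model '%s' failed: %s", nm, f)
    }
    if (!length(out)) stop("no detection function could be fitted")
    out
  })
  ds_tab <- data.frame(
    model = names(ds_fits),
    cvm = vapply(ds_fits, function(f) f$cvm_stat, numeric(1)),
    cvm_p = vapply(ds_fits, function(f) f$cvm_p, numeric(1)),
    k = vapply(ds_fits, function(f) f$k, numeric(1)),
    aic = vapply(ds_fits, function(f) f$aic, numeric(1)),
    pd = vapply(ds_fits, function(f) unname(f$pd[1]), numeric(1)),
    se_pd = vapply(ds_fits, function(f) unname(f$pd[2]), numeric(1)),
    row.names = NULL)
  ds_tab$delta_aic <- ds_tab$aic - min(ds_tab$aic)
  ds_tab$weight <- akaike_weights(ds_tab$aic)
  ds_tab <- ds_tab[order(ds_tab$aic), ]
  ds_keep <- ds_tab$delta_aic < cfg$delta_threshold
  pd_avg <- stage("average-pd", model_average(
    ds_tab$pd[ds_keep], ds_tab$se_pd[ds_keep], ds_tab$weight[ds_keep]))

  gbar <- stage("mean-group", mean_group(dataset))
  pa <- stage("combine-pa", combined_pa(p0_avg$estimate, p0_avg$se^2,
                                        pd_avg$estimate, pd_avg$se^2))
  abund <- stage("abundance", ht_abundance(dataset, pa$estimate, pa$var,
                                           gbar$estimate, gbar$se^2))

  # second average with configured exclusions (renormalized weights)
  abund_excl <- NULL
  keep2 <- ds_keep & !(ds_tab$model %in% cfg$exclude_models)
  if (any(!keep2 & ds_keep)) {
    pd2 <- model_average(ds_tab$pd[keep2], ds_tab$se_pd[keep2],
                         ds_tab$weight[keep2])
    pa2 <- combined_pa(p0_avg$estimate, p0_avg$se^2, pd2$estimate, pd2$se^2)
    abund_excl <- ht_abundance(dataset, pa2$estimate, pa2$var,
                               gbar$estimate, gbar$se^2)
  }

  extrapolations <- NULL
  if (!is.null(cfg$extrapolation_areas)) {
    low <- abund$strata[which.min(abund$strata$density_1000km2), ]
    extrapolations <- do.call(rbind, lapply(
      names(cfg$extrapolation_areas), function(nm) {
        ex <- extrapolate_density(low$density_1000km2, low$se_density_1000km2,
                                  cfg$extrapolation_areas[[nm]])
        data.frame(region = nm, area_km2 = cfg$extrapolation_areas[[nm]],
                   n = ex$n, se = ex$se, ci_low = ex$ci["low"],
                   ci_high = ex$ci["high"], row.names = NULL)
      }))
  }

  bundle <- list(sightings = sightings, mr = mr$table, ds = ds_tab,
                 averages = list(p0_star = p0_avg[c("estimate", "se")],
                                 pd = pd_avg[c("estimate", "se")],
                                 pa = pa[c("estimate", "se")]),
                 abundance = abund, abundance_excluded = abund_excl,
                 extrapolations = extrapolations,
                 mean_group = gbar, seed = cfg$seed, log = log)

  if (!is.null(cfg$out_dir)) {
    stage("write", write_bundle(bundle, cfg$out_dir))
  }
  invisible(bundle)
}

# Writes the table-style CSVs and a JSON summary; numeric values fixed to
# 6 significant digits so re-runs are byte-identical.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$sightings, file.path(out_dir, "sighting_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$mr, file.path(out_dir, "mr_models.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$ds, file.path(out_dir, "ds_models.csv"),
                   row.names = FALSE)
  ab <- bundle$abundance
  utils::write.csv(ab$strata, file.path(out_dir, "abundance_strata.csv"),
                   row.names = FALSE)
  sig <- function(x) {
    if (is.list(x)) lapply(x, sig)
    else if (is.numeric(x)) signif(x, 6)
    else x
  }
  summary <- list(
    n_total = ab$n_total, se = ab$se, cv = ab$cv,
    ci = c(ab$ci_low, ab$ci_high),
    clusters_total = ab$clusters_total,
    mean_group = unname(ab$mean_group["estimate"]),
    pa = unname(ab$pa["estimate"]),
    var_detection = ab$var_detection, var_encounter = ab$var_encounter,
    densities = stats::setNames(ab$strata$density_1000km2, ab$strata$id),
    averages = lapply(bundle$averages, function(a)
      c(estimate = a$estimate, se = a$se)),
    seed = bundle$seed, log = bundle$log)
  if (!is.null(bundle$abundance_excluded)) {
    ab2 <- bundle$abundance_excluded
    summary$excluded_models <- list(n_total = ab2$n_total, se = ab2$se,
                                    cv = ab2$cv, ci = c(ab2$ci_low, ab2$ci_high))
  }
  if (!is.null(bundle$extrapolations)) {
    utils::write.csv(bundle$extrapolations,
                     file.path(out_dir, "extrapolations.csv"),
                     row.names = FALSE)
    summary$extrapolations <- stats::setNames(
      bundle$extrapolations$n, bundle$extrapolations$region)
  }
  jsonlite::write_json(sig(summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
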