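# Survey data model: detected clusters, flown transects, strata, and the
# container tying them together. Distances are stored in meters, transect
# lengths in kilometers, stratum areas in km^2; unit conversions happen
# inside the estimation functions.

OBS_COLS <- c("id", "transect_id", "stratum_id", "distance_m",
              "seen_front", "seen_rear", "cluster_size")
OBS_COV_COLS <- c("activity", "ice_rough", "visibility_bad", "cloud_quartile")
TRANSECT_COLS <- c("id", "stratum_id", "length_km", "design_order")
STRATA_COLS <- c("id", "area_km2", "truncation_m")

#' Assemble and validate a line-transect survey dataset
#'
#' Bundles per-cluster sighting records, per-transect effort records and
#' per-stratum specifications into a validated `survey_dataset`. Only
#' clusters detected by at least one observer are recorded; each observation
#' must reference an existing transect, and each transect an existing
#' stratum.
#'
#' @param observations data.frame with columns `id`, `transect_id`,
#'   `stratum_id`, `distance_m` (perpendicular distance, meters),
#'   `seen_front`, `seen_rear` (0/1), `cluster_size` (integer >= 1), and
#'   optionally the detection covariates `activity` (moving = 1),
#'   `ice_rough` (rough = 1), `visibility_bad` (compromised = 1),
#'   `cloud_quartile` (0-4).
#' @param transects data.frame with columns `id`, `stratum_id`, `length_km`
#'   (> 0), `design_order` (position along the systematic design, unique
#'   within stratum) and optionally `is_ferry` (0/1).
#' @param strata data.frame with columns `id`, `area_km2` (> 0), optionally
#'   `label` and `truncation_m` (strip half-width, meters).
#' @return an object of class `survey_dataset` (a list with elements
#'   `observations`, `transects`, `strata`).
#' @examples
#' d <- survey_dataset(
#'   observations = data.frame(id = "o1", transect_id = "t1",
#'     stratum_id = "high", distance_m = 250, seen_front = 1, seen_rear = 0,
#'     cluster_size = 2),
#'   transects = data.frame(id = "t1", stratum_id = "high", length_km = 40,
#'     design_order = 1),
#'   strata = data.frame(id = "high", area_km2 = 18870, truncation_m = 1400))
#' d
#' @export
survey_dataset <- function(observations, transects, strata) {
  observations <- as.data.frame(observations)
  transects <- as.data.frame(transects)
  strata <- as.data.frame(strata)

  check_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing required column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  check_cols(strata, STRATA_COLS[1:2], "strata")
  if (is.null(strata$truncation_m)) strata$truncation_m <- Inf
  if (is.null(strata$label)) strata$label <- as.character(strata$id)
  check_cols(transects, TRANSECT_COLS, "transects")
  if (is.null(transects$is_ferry)) transects$is_ferry <- 0L
  check_cols(observations, OBS_COLS, "observations")
  for (cv in OBS_COV_COLS) {
    if (is.null(observations[[cv]])) {
      observations[[cv]] <- rep(NA_real_, nrow(observations))
    }
  }

  if (any(strata$area_km2 <= 0)) stop("stratum area_km2 must be positive")
  if (any(strata$truncation_m <= 0)) stop("truncation_m must be positive")
  if (anyDuplicated(strata$id)) stop("duplicate stratum id")
  if (any(transects$length_km <= 0)) stop("transect length_km must be positive")
  if (anyDuplicated(transects$id)) stop("duplicate transect id")
  dup_ord <- tapply(transects$design_order, transects$stratum_id,
                    function(x) anyDuplicated(x) > 0)
  if (any(unlist(dup_ord))) {
    stop("design_order must be unique within each stratum")
  }

  orphan_t <- setdiff(transects$stratum_id, strata$id)
  if (length(orphan_t)) {
    stop(sprintf("transect references unknown stratum: %s",
                 paste(orphan_t, collapse = ", ")), call. = FALSE)
  }
  if (nrow(observations)) {
    orphan_o <- setdiff(observations$transect_id, transects$id)
    if (length(orphan_o)) {
      stop(sprintf("observation references unknown transect: %s",
                   paste(orphan_o, collapse = ", ")), call. = FALSE)
    }
    orphan_s <- setdiff(observations$stratum_id, strata$id)
    if (length(orphan_s)) {
      stop(sprintf("observation references unknown stratum: %s",
                   paste(orphan_s, collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(observations$distance_m)) ||
        any(observations$distance_m < 0)) {
      stop("distance_m must be finite and non-negative")
    }
    if (any(observations$cluster_size < 1)) stop("cluster_size must be >= 1")
    if (any(observations$seen_front + observations$seen_rear < 1)) {
      stop("every recorded cluster must be seen by at least one observer")
    }
  }

  structure(list(observations = observations, transects = transects,
                 strata = strata), class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("Line-transect survey: %d detected clusters, %d transects (%.0f km), %d strata\n",
              nrow(x$observations), nrow(x$transects),
              sum(x$transects$length_km), nrow(x$strata)))
  w <- unique(x$strata$truncation_m)
  if (all(is.finite(w))) {
    cat(sprintf("Truncation: %s m\n", paste(w, collapse = ", ")))
  }
  invisible(x)
}

#' Load a survey from CSV files
#'
#' Reads the observation and transect tables from CSV (headers must match
#' the field names documented in [survey_dataset()]) and combines them with
#' a stratum specification supplied either as a data.frame or as the path
#' to a YAML file with a `strata:` list.
#'
#' @param obs_path path to observations.csv.
#' @param transect_path path to transects.csv.
#' @param strata data.frame of strata, or path to a YAML config whose
#'   `strata` entry is a list of `id`/`area_km2`/`truncation_m` records.
#' @return a validated `survey_dataset`.
#' @export
load_survey <- function(obs_path, transect_path, strata) {
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  trn <- utils::read.csv(transect_path, stringsAsFactors = FALSE)
  if (is.character(strata) && length(strata) == 1L) {
    cfg <- yaml::read_yaml(strata)
    if (!is.null(cfg$strata)) cfg <- cfg$strata
    strata <- do.call(rbind, lapply(cfg, function(s) {
      as.data.frame(s, stringsAsFactors = FALSE)
    }))
  }
  survey_dataset(obs, trn, strata)
}

#' Right-truncate a survey at a perpendicular distance
#'
#' Drops observations beyond `w_m` meters from the line and records `w_m` as
#' the strip half-width of every stratum. Transects and strata are otherwise
#' unchanged. Idempotent.
#'
#' @param dataset a `survey_dataset`.
#' @param w_m truncation distance in meters (> 0).
#' @return the truncated `survey_dataset`.
#' @export
truncate_survey <- function(dataset, w_m) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!is.numeric(w_m) || length(w_m) != 1L || w_m <= 0) {
    stop("w_m must be a single positive number")
  }
  dataset$observations <-
    dataset$observations[dataset$observations$distance_m <= w_m, , drop = FALSE]
  rownames(dataset$observations) <- NULL
  dataset$strata$truncation_m <- w_m
  dataset
}

#' Binned double-observer sighting summary
#'
#' Tabulates, per perpendicular-distance bin, how many clusters the front
#' team saw ("seen F") or failed to see ("missed F" = detected by the rear
#' team only), the same for the rear team, and how many both teams saw,
#' with a final Combined row. Within every bin,
#' seen F + missed F = seen R + missed R = total clusters.
#'
#' @param dataset a `survey_dataset`.
#' @param bin_width_m bin width in meters (> 0).
#' @return data.frame with columns `bin`, `seen_f`, `missed_f`, `seen_r`,
#'   `missed_r`, `seen_both`, `total`.
#' @export
binned_summary <- function(dataset, bin_width_m = 200) {
  stopifnot(inherits(dataset, "survey_dataset"), bin_width_m > 0)
  obs <- dataset$observations
  w <- max(dataset$strata$truncation_m)
  if (!is.finite(w)) w <- if (nrow(obs)) max(obs$distance_m) else bin_width_m
  breaks <- seq(0, ceiling(w / bin_width_m) * bin_width_m, by = bin_width_m)
  labels <- sprintf("%d-%d", utils::head(breaks, -1), breaks[-1])
  if (nrow(obs)) {
    bin <- cut(obs$distance_m, breaks = breaks, labels = labels,
               include.lowest = TRUE, right = TRUE)
    agg <- function(v) as.vector(tapply(v, bin, sum, default = 0L))
    out <- data.frame(
      bin = labels,
      seen_f = agg(obs$seen_front),
      missed_f = agg(1L - obs$seen_front),
      seen_r = agg(obs$seen_rear),
      missed_r = agg(1L - obs$seen_rear),
      seen_both = agg(obs$seen_front * obs$seen_rear),
      total = agg(rep(1L, nrow(obs))))
  } else {
    out <- data.frame(bin = labels, seen_f = 0L, missed_f = 0L, seen_r = 0L,
                      missed_r = 0L, seen_both = 0L, total = 0L)
  }
  comb <- data.frame(bin = "Combined", t(colSums(out[, -1])))
  names(comb) <- names(out)
  rbind(out, comb)
}

#' Reconstruct a survey from a binned sighting table
#'
#' Builds one observation per counted cluster from a binned double-observer
#' frequency table (the layout produced by [binned_summary()], without the
#' Combined row), placing each cluster at its bin midpoint with the recorded
#' capture history. Covariates are absent (NA). Intended for smoke tests and
#' oracle construction when raw distances are unavailable; midpoint
#' placement is unbiased under within-bin uniformity.
#'
#' @param bins data.frame with columns `bin` (labels like "0-200", meters),
#'   `seen_f`, `seen_r`, `seen_both`, `total`.
#' @param transects,strata optional tables passed to [survey_dataset()];
#'   defaults create a single placeholder transect/stratum.
#' @return a `survey_dataset`.
#' @export
survey_from_bins <- function(bins, transects = NULL, strata = NULL) {
  bins <- bins[tolower(bins$bin) != "combined", , drop = FALSE]
  lims <- t(vapply(strsplit(as.character(bins$bin), "-"),
                   function(x) as.numeric(x), numeric(2)))
  mid <- rowMeans(lims)
  both <- bins$seen_both
  front_only <- bins$seen_f - both
  rear_only <- bins$seen_r - both
  if (any(front_only < 0) || any(rear_only < 0)) {
    stop("inconsistent counts: seen_both exceeds seen_f or seen_r in a bin")
  }
  if (any(front_only + rear_only + both != bins$total)) {
    stop("inconsistent counts: capture histories do not sum to total")
  }
  n <- sum(bins$total)
  if (is.null(strata)) {
    strata <- data.frame(id = "high", area_km2 = 1,
                         truncation_m = max(lims))
  }
  if (is.null(transects)) {
    transects <- data.frame(id = "t1", stratum_id = strata$id[1],
                            length_km = 1, design_order = 1)
  }
  if (n == 0) {
    obs <- data.frame(id = character(), transect_id = character(),
                      stratum_id = character(), distance_m = numeric(),
                      seen_front = integer(), seen_rear = integer(),
                      cluster_size = integer())
    return(survey_dataset(obs, transects, strata))
  }
  dist <- rep(mid, times = bins$total)
  sf <- unlist(mapply(function(fo, ro, bo) c(rep(1L, fo), rep(0L, ro), rep(1L, bo)),
                      front_only, rear_only, both, SIMPLIFY = FALSE))
  sr <- unlist(mapply(function(fo, ro, bo) c(rep(0L, fo), rep(1L, ro), rep(1L, bo)),
                      front_only, rear_only, both, SIMPLIFY = FALSE))
  obs <- data.frame(id = sprintf("obs%03d", seq_len(n)),
                    transect_id = transects$id[1],
                    stratum_id = transects$stratum_id[1],
                    distance_m = dist, seen_front = sf, seen_rear = sr,
                    cluster_size = 1L)
  survey_dataset(obs, transects, strata)
}
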