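# Shared fixtures and independent oracles, built in code at test time.

# Small handmade survey with covariates: 8 clusters on 2 transects.
toy_dataset <- function() {
  survey_dataset(
    observations = data.frame(
      id = paste0("o", 1:8),
      transect_id = rep(c("t1", "t2"), each = 4),
      stratum_id = "s1",
      distance_m = c(50, 200, 420, 800, 120, 610, 1000, 1350),
      seen_front = c(1, 1, 1, 0, 1, 1, 0, 1),
      seen_rear =  c(1, 0, 1, 1, 0, 1, 1, 0),
      cluster_size = c(1, 2, 1, 3, 1, 1, 2, 1),
      activity = c(0, 1, 0, 0, 1, 0, 0, 1),
      ice_rough = c(1, 0, 1, 1, 0, 0, 1, 0),
      visibility_bad = c(0, 0, 1, 0, 0, 1, 0, 0),
      cloud_quartile = c(0, 2, 4, 1, 3, 2, 0, 1)),
    transects = data.frame(id = c("t1", "t2"), stratum_id = "s1",
                           length_km = c(60, 80), design_order = 1:2),
    strata = data.frame(id = "s1", area_km2 = 5000, truncation_m = 1400))
}

# Independent mark-recapture conditional likelihood: plain per-cluster loop
# over the three-term multinomial, written without any shared code path.
mr_loglik_oracle <- function(par, dataset, spec = "none") {
  obs <- dataset$observations
  total <- 0
  for (i in seq_len(nrow(obs))) {
    d <- obs$distance_m[i] / 1000
    x <- switch(spec,
      none = 0, distance_sq = d^2,
      cluster_size = obs$cluster_size[i], activity = obs$activity[i],
      ice_rough = obs$ice_rough[i], visibility_bad = obs$visibility_bad[i],
      cloud = obs$cloud_quartile[i],
      blind_spot = as.numeric(obs$distance_m[i] <= 75), 0)
    if (spec == "distance_by_position") {
      ef <- par[1] + par[3] * d
      er <- par[2] + par[4] * d
    } else if (spec == "blind_spot") {
      ef <- par[1] + par[3] * d
      er <- par[2] + par[3] * d + par[4] * x
    } else if (spec == "none") {
      ef <- par[1] + par[3] * d
      er <- par[2] + par[3] * d
    } else {
      ef <- par[1] + par[3] * d + par[4] * x
      er <- par[2] + par[3] * d + par[4] * x
    }
    pf <- 1 / (1 + exp(-ef)); pr <- 1 / (1 + exp(-er))
    pstar <- 1 - (1 - pf) * (1 - pr)
    pr_hist <- if (obs$seen_front[i] == 1 && obs$seen_rear[i] == 0) {
      pf * (1 - pr) / pstar
    } else if (obs$seen_front[i] == 0 && obs$seen_rear[i] == 1) {
      (1 - pf) * pr / pstar
    } else pf * pr / pstar
    total <- total + log(pr_hist)
  }
  total
}

# Riemann-sum oracle for the integral of a detection function.
riemann_mu <- function(spec, params, w, n = 1e6) {
  y <- (seq_len(n) - 0.5) * w / n
  mean(key_g(y, spec, params, w)) * w
}

# Double-observer capture histories generated directly from the logistic
# model, conditional on detection; distances uniform on [0, w].
sim_mr_data <- function(n, b0f, b0r, b1_km, w = 1400, seed = 1,
                        ice_effect = 0) {
  set.seed(seed)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- 2 * n
    y <- runif(m, 0, w)
    ice <- rbinom(m, 1, 0.5)
    ef <- b0f + b1_km * y / 1000 + ice_effect * ice
    er <- b0r + b1_km * y / 1000 + ice_effect * ice
    sf <- rbinom(m, 1, plogis(ef))
    sr <- rbinom(m, 1, plogis(er))
    keep <- sf + sr >= 1
    new <- data.frame(distance_m = y[keep], seen_front = sf[keep],
                      seen_rear = sr[keep], ice_rough = ice[keep])
    out <- rbind(out, new)
  }
  out <- out[seq_len(n), ]
  obs <- data.frame(id = paste0("o", seq_len(n)),
                    transect_id = rep(c("t1", "t2"), length.out = n),
                    stratum_id = "s1", distance_m = out$distance_m,
                    seen_front = out$seen_front, seen_rear = out$seen_rear,
                    cluster_size = 1L, activity = 0L,
                    ice_rough = out$ice_rough, visibility_bad = 0L,
                    cloud_quartile = 0L)
  survey_dataset(obs,
                 data.frame(id = c("t1", "t2"), stratum_id = "s1",
                            length_km = 100, design_order = 1:2),
                 data.frame(id = "s1", area_km2 = 1000, truncation_m = w))
}
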