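test_that("conditional likelihood matches the direct-sum oracle", {
  d <- toy_dataset()
  set.seed(42)
  for (spec in mr_model_specs()) {
    k <- if (spec == "none") 3 else 4
    for (r in 1:5) {
      par <- rnorm(k, 0, 1.5)
      expect_equal(mr_loglik(par, d, spec), mr_loglik_oracle(par, d, spec),
                   tolerance = 1e-10, info = spec)
    }
  }
})

test_that("null coefficients give each capture history probability 1/3", {
  d <- kb_survey_fixture()
  n <- nrow(d$observations)
  expect_equal(mr_loglik(c(0, 0, 0), d, "none"), n * log(1 / 3),
               tolerance = 1e-12)
})

test_that("capture-history probabilities sum to one for any coefficients", {
  base <- toy_dataset()
  one <- function(h) {
    obs <- base$observations[1, ]
    obs$seen_front <- h[1]; obs$seen_rear <- h[2]
    survey_dataset(obs, base$transects, base$strata)
  }
  set.seed(7)
  for (r in 1:20) {
    par <- rnorm(3, 0, 2)
    p <- sum(vapply(list(c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(h)
      exp(mr_loglik(par, one(h), "none")), numeric(1)))
    expect_equal(p, 1, tolerance = 1e-12)
  }
})

test_that("a front intercept at +infinity kills the rear-only probability", {
  d <- toy_dataset()  # contains rear-only detections
  ll <- mr_loglik(c(30, 0, 0), d, "none")
  expect_lt(ll, -40)  # P(01) -> 0, so the likelihood collapses
})

test_that("p0_star matches the published worked examples and its bounds", {
  expect_equal(round(p0_star(0.842, 0.727)$estimate, 3), 0.957)
  expect_equal(round(p0_star(0.891, 0.774)$estimate, 3), 0.975)
  expect_equal(p0_star(1.0, 0.3)$estimate, 1.0)
  expect_error(p0_star(0, 0.5), "0, 1")
  expect_error(p0_star(0.5, 1.2), "0, 1")

  # monotone nondecreasing in each argument and >= each argument
  set.seed(11)
  p <- matrix(runif(40, 0.05, 0.99), ncol = 2)
  for (i in seq_len(nrow(p))) {
    v <- p0_star(p[i, 1], p[i, 2])$estimate
    expect_gte(v, max(p[i, ]))
    expect_gte(p0_star(min(p[i, 1] + 0.01, 1), p[i, 2])$estimate, v)
    expect_gte(p0_star(p[i, 1], min(p[i, 2] + 0.01, 1))$estimate, v)
  }

  # delta-method SE reduces to the exact gradient for independent inputs
  v <- p0_star(0.8, 0.6, vcov = diag(c(0.01, 0.04)))
  expect_equal(v$se, sqrt(0.4^2 * 0.01 + 0.2^2 * 0.04))
})

test_that("fitting recovers known coefficients within 3 SEs at n = 2000", {
  truth <- c(1.4, 0.8, -1.0)
  d <- sim_mr_data(2000, truth[1], truth[2], truth[3], seed = 99)
  fit <- fit_mr(d, "none")
  est <- fit$par_internal
  se <- sqrt(diag(fit$vcov_internal))
  expect_true(all(abs(est - truth) < 3 * se))
  expect_equal(unname(fit$coefficients["b_distance"]) * 1000, est[3])
})

test_that("Wald intervals for the distance slope attain nominal coverage", {
  truth <- c(1.4, 0.8, -1.0)
  hits <- 0; tries <- 0
  for (r in 1:200) {
    d <- sim_mr_data(300, truth[1], truth[2], truth[3], seed = 5000 + r)
    fit <- tryCatch(fit_mr(d, "none"), error = function(e) NULL)
    if (is.null(fit)) next
    tries <- tries + 1
    se <- sqrt(fit$vcov_internal[3, 3])
    if (abs(fit$par_internal[3] - truth[3]) < 1.96 * se) hits <- hits + 1
  }
  expect_gte(hits / tries, 0.90)
  expect_lte(hits / tries, 0.99)
})

test_that("degenerate capture histories are rejected as non-identifiable", {
  d <- toy_dataset()
  obs <- d$observations
  obs$seen_rear <- obs$seen_front  # rear saw exactly what front saw
  obs$seen_front <- 1L
  dd <- survey_dataset(obs, d$transects, d$strata)
  expect_error(fit_mr(dd, "none"), "identifiability|degenerate")
})

test_that("covariate models demand complete covariates", {
  d <- kb_survey_fixture()  # rebuilt from bins: covariates are NA
  expect_error(fit_mr(d, "ice_rough"), "missing values")
})

test_that("AICc uses detected clusters as n, with the exact k = 3 penalty", {
  d <- kb_survey_fixture()
  fit <- fit_mr(d, "none")
  n <- nrow(d$observations)
  expect_equal(fit$aicc,
               -2 * fit$loglik + 2 * 3 + 2 * 3 * 4 / (n - 4))
})

test_that("adding a parameter never decreases the maximized likelihood", {
  d <- sim_mr_data(150, 1.4, 0.8, -1.0, seed = 21)
  base <- fit_mr(d, "none")
  for (spec in c("distance_sq", "ice_rough", "distance_by_position")) {
    fit <- fit_mr(d, spec)
    expect_gte(fit$loglik, base$loglik - 1e-6)
  }
})

test_that("the model set ranks, weights and flags uninformative additions", {
  d <- sim_mr_data(400, 1.4, 0.8, -1.0, seed = 31)
  ms <- mr_model_set(d)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(ms$table$aicc) >= 0))
  # data have no real extra effects: flagged additions must be weak ones
  flagged <- ms$table[ms$table$uninformative, ]
  if (nrow(flagged)) {
    expect_true(all(flagged$delta_aicc > 0 |
                      flagged$spec != "none"))
  }
})

test_that("a strong ice effect puts the ice-structure model first", {
  wins <- 0
  for (r in 1:50) {
    d <- sim_mr_data(1000, 1.4, 0.8, -1.0, seed = 7000 + r, ice_effect = -1)
    ms <- mr_model_set(d, specs = c("none", "distance_sq", "ice_rough",
                                    "activity", "blind_spot",
                                    "distance_by_position"))
    if (ms$table$spec[1] == "ice_rough") wins <- wins + 1
  }
  expect_gte(wins / 50, 0.8)
})

test_that("goodness of fit is exact on balanced histories and pools cells", {
  # 2 of each history per bin at null coefficients: expected = observed = 2
  obs <- data.frame(
    id = paste0("o", 1:18), transect_id = "t1", stratum_id = "s1",
    distance_m = rep(c(100, 300, 500), each = 6),
    seen_front = rep(c(1, 0, 1), times = 6),
    seen_rear = rep(c(0, 1, 1), times = 6),
    cluster_size = 1L)
  d <- survey_dataset(obs,
    data.frame(id = "t1", stratum_id = "s1", length_km = 10, design_order = 1),
    data.frame(id = "s1", area_km2 = 100, truncation_m = 600))
  fake <- structure(list(spec = "none", par_internal = c(0, 0, 0), k = 3,
                         dataset = d), class = "mr_fit")
  g <- mr_gof(fake, 200)
  expect_equal(g$chi2, 0, tolerance = 1e-12)
  expect_equal(g$cells, 9)  # 3 bins x 3 histories, each expected exactly 2
  # bin totals are fixed under the conditional likelihood
  expect_equal(g$df, 9 - 3 - 3)

  # sparse fifth bin: 3 clusters at expected (1,1,1) pool to a single cell
  obs2 <- rbind(obs,
    data.frame(id = paste0("x", 1:21), transect_id = "t1", stratum_id = "s1",
               distance_m = rep(c(700, 900), times = c(18, 3)),
               seen_front = rep(c(1, 0, 1), times = 7),
               seen_rear = rep(c(0, 1, 1), times = 7),
               cluster_size = 1L))
  d2 <- survey_dataset(obs2, d$transects,
    data.frame(id = "s1", area_km2 = 100, truncation_m = 1000))
  fake2 <- structure(list(spec = "none", par_internal = c(0, 0, 0), k = 3,
                          dataset = d2), class = "mr_fit")
  g2 <- mr_gof(fake2, 200, min_expected = 2)
  expect_equal(g2$cells, 4 * 3 + 1)  # hand-checked pooling
  expect_equal(g2$bins, 5)
  expect_equal(g2$df, 13 - 5 - 3)
})

test_that("the chi-square statistic is calibrated under the null", {
  stats <- dfs <- numeric(0)
  for (r in 1:150) {
    d <- sim_mr_data(250, 1.4, 0.8, -1.0, seed = 9000 + r)
    fit <- tryCatch(fit_mr(d, "none"), error = function(e) NULL)
    if (is.null(fit)) next
    g <- tryCatch(mr_gof(fit, 280), error = function(e) NULL)
    if (is.null(g)) next
    stats <- c(stats, g$chi2); dfs <- c(dfs, g$df)
  }
  # mean of a chi-square is its df; allow Monte-Carlo slack
  expect_equal(mean(stats) / mean(dfs), 1, tolerance = 0.2)
})
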