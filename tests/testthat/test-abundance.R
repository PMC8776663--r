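test_that("combined detection probability follows the product delta rule", {
  # perfect on-line detection passes the distance stage through
  v <- combined_pa(1.0, 0, 0.6, 0.02)
  expect_equal(v$estimate, 0.6)
  expect_equal(v$var, 0.02)

  # published model-average composition
  v <- combined_pa(0.953, 0.056^2, 0.571, 0.151^2)
  expect_equal(v$estimate, 0.544, tolerance = 0.001)
  expect_lt(abs(v$se - 0.147), 0.0005)  # printed precision

  # symmetric inputs: var = 2 p^2 v
  v <- combined_pa(0.7, 0.01, 0.7, 0.01)
  expect_equal(v$var, 2 * 0.7^2 * 0.01)

  expect_error(combined_pa(1.2, 0, 0.5, 0), "0, 1")
})

test_that("mean cluster size and its SE are the plain moments", {
  sizes <- kb_cluster_sizes()$cluster_sizes
  g <- mean_group(sizes)
  expect_equal(g$estimate, 1.75)
  expect_equal(g$se, sd(sizes) / sqrt(28))

  expect_equal(mean_group(rep(1, 10))$se, 0)
  g3 <- mean_group(c(1, 2, 3))
  expect_equal(g3$estimate, 2)
  expect_equal(g3$se, 1 / sqrt(3))
  expect_error(mean_group(numeric(0)), "no observations")
})

test_that("paired-transect encounter variance matches hand computation", {
  expect_equal(encounter_var_s2(c(2, 2, 2, 2), rep(10, 4))$var_rate, 0)

  v <- encounter_var_s2(c(2, 0, 2, 0), rep(10, 4))
  expect_equal(v$var_rate, 0.005)
  expect_equal(v$var_count, 40^2 * 0.005)

  # ordering comes from design order, not input order
  v2 <- encounter_var_s2(c(2, 2, 0, 0), rep(10, 4), design_order = c(1, 3, 2, 4))
  expect_equal(v2$var_rate, 0.005)

  # odd K: trailing group of three
  v3 <- encounter_var_s2(c(1, 1, 1, 1, 1), rep(10, 5))
  expect_equal(v3$var_rate, 0)

  expect_error(encounter_var_s2(3, 10), "at least 2")
})

test_that("the paired estimator is nearly unbiased for Poisson counts", {
  set.seed(13)
  K <- 20; len <- rep(10, K); lam <- 0.8
  est <- replicate(500, {
    n <- rpois(K, lam)
    encounter_var_s2(n, len)$var_count
  })
  true_var <- K * lam  # variance of the total of K Poisson(lam) counts
  expect_equal(mean(est), true_var, tolerance = 0.1 * true_var)
})

test_that("lognormal intervals follow the CV closed form", {
  expect_equal(unname(lognormal_ci(100, 0)), c(100, 100))
  ci <- lognormal_ci(190, 0.39)
  expect_equal(unname(ci), c(91, 397), tolerance = 0.01)
  C <- 100 / lognormal_ci(100, 0.2474)[["low"]]
  expect_equal(C, 1.62, tolerance = 0.01)
})

test_that("the census limit returns the summed cluster sizes exactly", {
  obs <- data.frame(id = paste0("o", 1:28), transect_id = "t1",
                    stratum_id = "s1", distance_m = runif(28, 0, 500),
                    seen_front = 1L, seen_rear = 0L,
                    cluster_size = rep(c(1L, 2L, 3L), times = c(13, 9, 6)))
  obs$transect_id[28] <- "t3"; obs$stratum_id[28] <- "s2"
  d <- survey_dataset(obs,
    data.frame(id = c("t1", "t2", "t3", "t4"),
               stratum_id = c("s1", "s1", "s2", "s2"),
               length_km = c(60, 40, 30, 20), design_order = c(1, 2, 1, 2)),
    data.frame(id = c("s1", "s2"),
               area_km2 = c(2 * 1.4 * 100, 2 * 1.4 * 50),  # A = a
               truncation_m = 1400))
  est <- ht_abundance(d, pa = 1, var_pa = 0)
  expect_equal(est$n_total, sum(obs$cluster_size) * 1, tolerance = 1e-10)
  expect_equal(est$var_detection, 0)
  expect_equal(est$clusters_surveyed, 28)
})

test_that("a one-stratum toy reproduces the hand-derived pipeline", {
  obs <- data.frame(id = paste0("o", 1:5), transect_id = c("t1", "t1", "t2", "t2", "t2"),
                    stratum_id = "s1", distance_m = c(100, 300, 200, 400, 600),
                    seen_front = 1L, seen_rear = 0L, cluster_size = 2L)
  var_pa <- 0.01
  d <- survey_dataset(obs,
    data.frame(id = c("t1", "t2"), stratum_id = "s1",
               length_km = c(17.857142857, 17.857142857), design_order = 1:2),
    data.frame(id = "s1", area_km2 = 1000, truncation_m = 1400))
  # a = 2 * 1.4 * 35.714... = 100 km^2; A/a = 10; c = 5; pa = 0.5; g = 2
  est <- ht_abundance(d, pa = 0.5, var_pa = var_pa, gbar = 2, var_gbar = 0)
  expect_equal(est$clusters_total, 10 * 5 / 0.5, tolerance = 1e-6)
  expect_equal(est$n_total, 200, tolerance = 1e-4)
  expect_equal(est$var_detection, 10^2 * (5 / 0.5^2)^2 * var_pa,
               tolerance = 1e-6)
  # additivity of the variance decomposition is exact
  expect_equal(est$var_total, est$var_detection + est$var_encounter)
  # N = C x g feeds the product-rule variance
  expect_equal(est$se^2, est$clusters_total^2 * 0 + 2^2 * est$var_total,
               tolerance = 1e-8)
})

test_that("doubling every stratum area doubles the estimate exactly", {
  d <- kb_survey_fixture()
  e1 <- ht_abundance(d, 0.544, 0.147^2)
  d2 <- d; d2$strata$area_km2 <- 2 * d2$strata$area_km2
  e2 <- ht_abundance(d2, 0.544, 0.147^2)
  expect_equal(e2$clusters_total, 2 * e1$clusters_total)
  expect_equal(e2$n_total, 2 * e1$n_total)
})

test_that("published geometry and detection reproduce the per-model abundances", {
  d <- kb_survey_fixture()
  tab <- kb_abundance_table()
  # combined detection per model: p = p0* x pd with the averaged p0* 0.953
  ds <- kb_ds_table()
  for (i in seq_len(nrow(ds))) {
    pa_i <- 0.953 * ds$pd[i]
    est <- ht_abundance(d, pa_i, 0, gbar = 1.75, var_gbar = 0)
    expect_equal(est$n_total, tab$n_hat[i], tolerance = 0.02,
                 info = ds$model[i])
    expect_equal(est$strata$density_1000km2[est$strata$id == "high"],
                 tab$density_high[i], tolerance = 0.05, info = ds$model[i])
    expect_equal(est$strata$density_1000km2[est$strata$id == "low"],
                 tab$density_low[i], tolerance = 0.1, info = ds$model[i])
  }
})

test_that("single-transect strata are refused for encounter variance", {
  d <- toy_dataset()
  tr <- d$transects[1, ]
  obs <- d$observations[d$observations$transect_id == "t1", ]
  dd <- survey_dataset(obs, tr, d$strata)
  expect_error(ht_abundance(dd, 0.5, 0.01), "single transect")
})

test_that("density extrapolation scales linearly with area", {
  ex <- extrapolate_density(1.7, 1.9, 27214)
  expect_equal(ex$n, 46.3, tolerance = 0.01)
  expect_equal(extrapolate_density(0, 0, 1000)$n, 0)
  expect_equal(extrapolate_density(2.0, 0.5, 500)$n, 1.0)
})

test_that("CV components compose the way the variance pipeline does", {
  tab <- cv_components(0.06, 0.13, 0.16, 0.09)
  # published 0.24 was composed from rounded inputs; allow that rounding
  expect_lt(abs(tab$cv[tab$component == "N_total"] - 0.24), 0.01)
  expect_equal(tab$cv[tab$component == "pa"],
               sqrt(0.06^2 + 0.13^2), tolerance = 1e-12)
  expect_equal(tab$component[tab$largest], "encounter")

  zero <- cv_components(0, 0, 0, 0)
  expect_equal(zero$cv[zero$component == "N_total"], 0)

  # hand-checked composite at equal CVs
  t2 <- cv_components(0.1, 0.1, 0, 0)
  expect_equal(t2$cv[t2$component == "pa"], sqrt(0.02))
})

test_that("effort scales with the square of the precision ratio", {
  expect_equal(effort_for_cv(0.39, 0.25), 2.4336)
  expect_equal(effort_for_cv(0.3, 0.3), 1)
  expect_equal(effort_for_cv(0.5, 0.25), 4)
  expect_lt(effort_for_cv(0.2, 0.4), 1)
})
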