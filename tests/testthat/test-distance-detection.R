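test_that("detection-function values match closed forms", {
  hn <- ds_spec("half_normal")
  expect_equal(key_g(0, hn, log(700), 1400), 1)
  expect_equal(key_g(700, hn, log(700), 1400), exp(-0.5))

  # uniform + one cosine term, a1 = 0.5, at y = w: (1 - 0.5)/(1 + 0.5)
  uc <- ds_spec("uniform", "cosine", 1)
  expect_equal(key_g(1400, uc, 0.5, 1400), (1 + 0.5 * cos(pi)) / 1.5)

  hr <- ds_spec("hazard_rate")
  expect_equal(key_g(0, hr, c(log(500), log(1)), 1400), 1)
})

test_that("spec validity rules hold", {
  expect_error(ds_spec("uniform", "none", 0), "at least one adjustment")
  expect_error(ds_spec("hazard_rate", "hermite", 1), "half-normal")
  expect_error(key_g(100, ds_spec("half_normal"), c(1, 2), 1400), "parameters")
})

test_that("quadrature agrees with a brute-force Riemann sum", {
  set.seed(5)
  cases <- list(
    list(ds_spec("half_normal"), log(600)),
    list(ds_spec("half_normal", "cosine", 1), c(log(600), 0.2)),
    list(ds_spec("half_normal", "hermite", 1), c(log(600), 0.05)),
    list(ds_spec("hazard_rate"), c(log(500), log(1.5))),
    list(ds_spec("uniform", "cosine", 2), c(0.4, 0.1)),
    list(ds_spec("uniform", "simple_poly", 1), -0.6))
  for (cs in cases) {
    mu_quad <- integrate(function(y) key_g(y, cs[[1]], cs[[2]], 1400),
                         0, 1400, rel.tol = 1e-8)$value
    expect_equal(mu_quad, riemann_mu(cs[[1]], cs[[2]], 1400),
                 tolerance = 1e-6)
  }
})

test_that("uniform distances imply a flat fitted detection function", {
  set.seed(81)
  y <- runif(5000, 0, 1400)
  fit <- fit_ds(y, ds_spec("half_normal"), 1400)
  expect_gt(unname(fit$pd[1]), 0.95)  # within Monte-Carlo error of flat
})

test_that("half-normal fitting recovers scale and mean detection", {
  set.seed(82)
  y <- abs(rnorm(12000, 0, 500)); y <- y[y <= 1400][1:5000]
  fit <- fit_ds(y, ds_spec("half_normal"), 1400)
  sig <- exp(fit$params[1])
  se_sig <- sig * sqrt(fit$vcov[1, 1])  # delta method from the log scale
  expect_lt(abs(sig - 500), 3 * se_sig)
  pd_closed <- sqrt(pi / 2) * 500 * (2 * pnorm(1400 / 500) - 1) / 1400
  expect_equal(unname(fit$pd[1]), pd_closed, tolerance = 0.02)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_ds(700, ds_spec("half_normal"), 1400), "too few")
  expect_error(fit_ds(rep(300, 50), ds_spec("half_normal"), 1400),
               "identical")
  expect_error(fit_ds(c(100, 2000), ds_spec("half_normal"), 1400),
               "\\[0, w\\]")
})

test_that("mean detection probability is scale invariant and has the right limits", {
  set.seed(83)
  y <- abs(rnorm(600, 0, 400)); y <- y[y <= 1400]
  f1 <- fit_ds(y, ds_spec("half_normal"), 1400)
  f2 <- fit_ds(y / 1000, ds_spec("half_normal"), 1.4)
  expect_equal(unname(f1$pd[1]), unname(f2$pd[1]), tolerance = 1e-4)

  hn <- ds_spec("half_normal")
  pd_at <- function(sig) integrate(function(t) key_g(t, hn, log(sig), 1400),
                                   0, 1400)$value / 1400
  expect_gt(pd_at(1e6), 0.999)
  expect_lt(pd_at(5), 0.01)
})

test_that("forward AIC selection keeps the half-normal unadorned on its own data", {
  plain <- 0
  for (r in 1:50) {
    set.seed(300 + r)
    y <- abs(rnorm(600, 0, 450)); y <- y[y <= 1400][1:200]
    fit <- select_adjustments(y, "half_normal", 1400)
    if (fit$spec$n_adjustments == 0) plain <- plain + 1
  }
  expect_gte(plain / 50, 0.9)
})

test_that("the uniform key always carries at least one term, more when needed", {
  set.seed(84)
  y <- runif(200, 0, 1400)
  fit <- select_adjustments(y, "uniform", 1400)
  expect_gte(fit$spec$n_adjustments, 1)

  # bimodal mixture: one cosine term cannot express two humps
  y2 <- c(abs(rnorm(300, 0, 150)), rnorm(300, 1000, 120))
  y2 <- y2[y2 >= 0 & y2 <= 1400]
  fit2 <- select_adjustments(y2, "uniform", 1400)
  expect_gte(fit2$spec$n_adjustments, 2)
})

test_that("the four standard candidates carry the expected parameter counts", {
  y <- kb_survey_fixture()$observations$distance_m
  ks <- c(uniform_cos = NA, hazard_rate = NA, half_normal = NA,
          uniform_poly = NA)
  ks["uniform_cos"] <- select_adjustments(y, "uniform", 1400, "cosine")$k
  ks["hazard_rate"] <- select_adjustments(y, "hazard_rate", 1400)$k
  ks["half_normal"] <- select_adjustments(y, "half_normal", 1400)$k
  ks["uniform_poly"] <- select_adjustments(y, "uniform", 1400, "simple_poly")$k
  expect_equal(unname(ks), c(1, 2, 1, 1))
})

test_that("CvM statistic attains its minimum on perfect quantile data", {
  set.seed(85)
  y <- abs(rnorm(400, 0, 500)); y <- y[y <= 1400][1:100]
  fit <- fit_ds(y, ds_spec("half_normal"), 1400)
  # invert the fitted CDF at the plotting positions i/(n+1)... the statistic
  # at F(y_i) = (2i-1)/(2n) equals exactly 1/(12n)
  n <- 50
  targets <- (2 * seq_len(n) - 1) / (2 * n)
  Fy <- function(q) integrate(function(t) key_g(t, fit$spec, fit$params, fit$w),
                              0, q)$value / fit$mu
  yq <- vapply(targets, function(p)
    uniroot(function(q) Fy(q) - p, c(1e-6, 1400))$root, numeric(1))
  out <- cvm_test(fit, yq)
  expect_equal(out$statistic, 1 / (12 * n), tolerance = 1e-6)

  # gross misfit: a pile of on-line distances against a broad half-normal
  bad <- cvm_test(fit, rep(c(0, 1, 2), 10))
  expect_gt(bad$statistic, 1)
  expect_lt(bad$p_value, 0.01)
})

test_that("CvM p-values are calibrated under the null at survey sample size", {
  rej <- 0; n_ok <- 0
  for (r in 1:500) {
    set.seed(10000 + r)
    y <- abs(rnorm(120, 0, 500)); y <- y[y <= 1400][1:28]
    fit <- tryCatch(fit_ds(y, ds_spec("half_normal"), 1400),
                    error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1
    if (fit$cvm_p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_ok, 0.0)
  expect_lte(rej / n_ok, 0.09)
})
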