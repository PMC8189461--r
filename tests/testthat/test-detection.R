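test_that("half-normal fit recovers sigma and f(0) from simulated data", {
  w <- 500
  x <- sim_hn_distances(5000, sigma = 200, w = w, seed = 101)
  fit <- fit_detection_function(
    x, spec = det_spec("half_normal", "none", truncation_w_m = w))
  expect_lt(abs(fit$sigma_by_class - 200) / 200, 0.05)
  true_f0 <- 1 / integrate(function(u) exp(-u^2 / (2 * 200^2)), 0, w,
                           rel.tol = 1e-10)$value
  expect_lt(abs(fit$f0_per_m - true_f0) / true_f0, 0.05)
  expect_equal(fit$esw_m, 1 / fit$f0_per_m)
  expect_lte(fit$esw_m, w)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_gt(fit$se_f0, 0)
})

test_that("untruncated half-normal f(0) approaches the closed form", {
  # w >> sigma: f(0) -> 1/(sigma sqrt(pi/2)); sigma = 100 gives 0.007979/m
  x <- sim_hn_distances(6000, sigma = 100, w = 600, seed = 202)
  fit <- fit_detection_function(
    x, spec = det_spec("half_normal", "none", truncation_w_m = 600))
  expect_lt(abs(fit$f0_per_m - 1 / (100 * sqrt(pi / 2))) /
              (1 / (100 * sqrt(pi / 2))), 0.05)
  expect_equal(1 / (100 * sqrt(pi / 2)), 0.007979, tolerance = 1e-4)
})

test_that("Beaufort covariate on the scale is recovered within 3 SE", {
  set.seed(303)
  n <- 4000
  bss <- sample(0:2, n, replace = TRUE)
  true_beta <- c(log(150), 0, log(2))  # sigma doubles from BSS0 to BSS2
  sig <- exp(true_beta[1] + c(0, 0.0, true_beta[3])[bss + 1])
  x <- abs(rnorm(n, 0, sig))
  keep <- x <= 600
  fit <- fit_detection_function(
    x[keep], bss[keep],
    det_spec("half_normal", "none", covariates = "beaufort",
             truncation_w_m = 600))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$par[3] - log(2)), 3 * se[3])
  expect_lt(abs(fit$par[1] - log(150)), 3 * se[1])
  # CDS equals MCDS with zero covariates on identical data
  cds <- fit_detection_function(
    x[keep], spec = det_spec("half_normal", "none", truncation_w_m = 600))
  mcds_nocov <- fit_detection_function(
    x[keep], covariate_values = NULL,
    spec = det_spec("half_normal", "none", covariates = character(),
                    truncation_w_m = 600))
  expect_equal(cds$loglik, mcds_nocov$loglik, tolerance = 1e-6)
})

test_that("detection loglik matches a brute-force quadrature oracle", {
  w <- 400
  x <- c(12, 35, 60, 90, 120, 150, 180, 210, 250, 290, 310, 350, 30, 75,
         140, 200, 260, 330, 15, 95)
  for (key in c("half_normal", "hazard_rate")) {
    spec <- det_spec(key, "none", truncation_w_m = w)
    fit <- fit_detection_function(x, spec = spec)
    oracle <- oracle_detection_loglik(
      x, sigma = fit$sigma_by_class, w = w, key = key, shape = fit$shape)
    expect_equal(fit$loglik, oracle, tolerance = 1e-8)
  }
  # with a cosine adjustment term
  spec <- det_spec("half_normal", "cosine", 1L, truncation_w_m = w)
  fit <- tryCatch(fit_detection_function(x, spec = spec),
                  sealcount_error = function(e) NULL)
  if (!is.null(fit)) {
    oracle <- oracle_detection_loglik(
      x, sigma = fit$sigma_by_class, w = w, key = "half_normal",
      adjustment = "cosine", acoef = fit$acoef)
    expect_equal(fit$loglik, oracle, tolerance = 1e-8)
  }
})

test_that("fitted density normalizes and g stays within (0, 1]", {
  w <- 500
  x <- sim_hn_distances(800, sigma = 180, w = w, seed = 404)
  for (spec in list(det_spec("half_normal", "cosine", 1L, truncation_w_m = w),
                    det_spec("hazard_rate", "none", truncation_w_m = w))) {
    fit <- fit_detection_function(x, spec = spec)
    dens_int <- integrate(function(u)
      detection_g(fit, u) * fit$f0_per_m, 0, w, rel.tol = 1e-9)$value
    expect_equal(dens_int, 1, tolerance = 1e-6)
    gg <- detection_g(fit, seq(0, w, length.out = 200))
    expect_true(all(gg >= 0 & gg <= 1 + 1e-9))
    expect_true(fit$esw_m <= w)
  }
})

test_that("ESW increases with sigma for the plain half-normal", {
  esw <- vapply(c(50, 100, 200, 400), function(s) {
    mu <- integrate(function(u) exp(-u^2 / (2 * s^2)), 0, 500)$value
    mu
  }, numeric(1))
  x <- sim_hn_distances(1500, 120, 500, seed = 505)
  f1 <- fit_detection_function(x, spec = det_spec("half_normal", "none",
                                                  truncation_w_m = 500))
  x2 <- sim_hn_distances(1500, 240, 500, seed = 505)
  f2 <- fit_detection_function(x2, spec = det_spec("half_normal", "none",
                                                   truncation_w_m = 500))
  expect_true(all(diff(esw) > 0))
  expect_gt(f2$esw_m, f1$esw_m)
})

test_that("model selection uses AIC with documented tie-breaks", {
  mk <- function(aic, k, key = "half_normal")
    structure(list(aic = aic, k = k,
                   spec = list(key = key)), class = "detection_fit")
  expect_equal(select_model(list(mk(101.2, 3), mk(99.8, 3)))$aic, 99.8)
  expect_equal(select_model(list(mk(100, 3), mk(100, 2)))$k, 2)
  tie <- select_model(list(mk(100, 2, "hazard_rate"),
                           mk(100, 2, "half_normal")))
  expect_identical(tie$spec$key, "half_normal")
  single <- mk(55, 1)
  expect_identical(select_model(list(single)), single)
  expect_error(select_model(list()), class = "sc_invalid_argument")
})

test_that("truncation strategies behave as documented", {
  expect_equal(choose_truncation(1:100), 95.05)
  expect_equal(choose_truncation(rep(50, 7)), 50)
  # pilot half-normal with sigma ~100 -> w = 100 sqrt(-2 log .15) ~ 194.8
  x <- sim_hn_distances(8000, 100, 1000, seed = 606)
  w <- choose_truncation(x, "g_at_w_0.15")
  expect_lt(abs(w - 100 * sqrt(-2 * log(0.15))), 10)
  expect_error(choose_truncation(1:10, "bogus"), class = "sc_invalid_argument")
  expect_error(choose_truncation(numeric()), class = "sc_invalid_argument")
})

test_that("invalid key/adjustment pairings and data are rejected", {
  expect_error(det_spec("hazard_rate", "hermite", 1L, truncation_w_m = 100),
               class = "sc_invalid_spec")
  expect_error(det_spec("half_normal", "simple_poly", 1L,
                        truncation_w_m = 100),
               class = "sc_invalid_spec")
  expect_error(
    fit_detection_function(c(10, 600),
                           spec = det_spec("half_normal", "none",
                                           truncation_w_m = 500)),
    class = "sc_invalid_argument")
  expect_error(
    fit_detection_function(c(10, 20, 30),
                           spec = det_spec("hazard_rate", "cosine", 2L,
                                           truncation_w_m = 500)),
    class = "sc_insufficient_data")
})

test_that("the AIC menu returns a usable best model", {
  x <- sim_hn_distances(600, 150, 450, seed = 707)
  menu <- fit_detection_menu(x, truncation_w_m = 450, max_adjust_terms = 1L)
  expect_s3_class(menu$best, "detection_fit")
  expect_gte(length(menu$candidates), 2L)
  aics <- vapply(menu$candidates, `[[`, numeric(1), "aic")
  expect_equal(menu$best$aic, min(aics))
  hist <- detection_hist_data(menu$best, x, n_bins = 10L)
  expect_equal(sum(hist$count), length(x))
  expect_equal(sum(hist$fitted), length(x), tolerance = 0.01)
})
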