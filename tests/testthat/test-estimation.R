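test_that("O2 variance is zero for identical rates and ranks arrangements", {
  same <- data.frame(line_id = 1:5, n_i = c(2, 4, 6, 8, 10),
                     l_i = c(1, 2, 3, 4, 5))  # constant rate 2/km
  expect_equal(encounter_rate_variance(same), 0)
  flat <- data.frame(line_id = 1:4, n_i = c(2, 2, 8, 8), l_i = 1)
  alt <- data.frame(line_id = 1:4, n_i = c(2, 8, 2, 8), l_i = 1)
  expect_gt(encounter_rate_variance(alt), encounter_rate_variance(flat))
  expect_equal(encounter_rate_variance(flat), 24)
  expect_equal(encounter_rate_variance(alt), 72)
})

test_that("single-line data fall back to Poisson variance with a warning", {
  one <- data.frame(line_id = 1, n_i = 7, l_i = 10)
  expect_warning(v <- encounter_rate_variance(one), "Poisson")
  expect_equal(v, 7)
})

test_that("O2 tracks the replicate variance of n under a spatial trend", {
  # systematic design with a smooth density trend across 20 lines
  k <- 20L
  lam <- 5 + 4 * sin(seq(0, pi, length.out = k))
  set.seed(99)
  n_rep <- 500L
  totals <- numeric(n_rep)
  o2 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    n_i <- rpois(k, lam)
    totals[r] <- sum(n_i)
    o2[r] <- encounter_rate_variance(
      data.frame(line_id = seq_len(k), n_i = n_i, l_i = 10))
  }
  expect_lt(abs(mean(o2) - var(totals)) / var(totals), 0.25)
})

test_that("density and abundance plug-ins are exact on a hand example", {
  # n = 10, f0 = 1 per km, E(s) = 1, L = 10 km, A = 100 km2 -> D = 0.5, N = 50
  er <- structure(list(n = 10, L_km = 10, var_n = 0,
                       per_line = NULL), class = "encounter_rate")
  fit <- make_hn_fit(150, 400)
  fit$f0_per_m <- 1 / 1000  # 1 per km
  fit$se_f0 <- 0
  gs <- structure(list(e_s = 1, se_e_s = 0, method = "arithmetic_mean"),
                  class = "group_size_estimate")
  est <- estimate_density_abundance(er, fit, gs, stratum("TestA", 100),
                                    season = "spring")
  expect_equal(est$density_per_km2, 0.5)
  expect_equal(est$abundance, 50)
  expect_equal(est$cv, 0)
  # four component CVs of 0.1 combine to 0.2
  er$var_n <- (0.1 * er$n)^2
  fit$se_f0 <- 0.1 * fit$f0_per_m
  gs$se_e_s <- 0.1 * gs$e_s
  g0 <- correction_factor("spring", 0.5, se = 0.05)
  est2 <- estimate_density_abundance(er, fit, gs, stratum("TestA", 100),
                                     g0 = g0, season = "spring")
  expect_equal(est2$cv, 0.2)
  expect_equal(est2$abundance, 100)  # doubled by availability 0.5
})

test_that("CV is invariant to area while N scales linearly", {
  er <- structure(list(n = 25, L_km = 40, var_n = 30, per_line = NULL),
                  class = "encounter_rate")
  fit <- make_hn_fit(150, 400)
  fit$se_f0 <- 0.08 * fit$f0_per_m
  gs <- structure(list(e_s = 1.4, se_e_s = 0.1, method = "arithmetic_mean"),
                  class = "group_size_estimate")
  e1 <- estimate_density_abundance(er, fit, gs, stratum("A", 100))
  e2 <- estimate_density_abundance(er, fit, gs, stratum("A", 500))
  expect_equal(e1$cv, e2$cv)
  expect_equal(e2$abundance, 5 * e1$abundance)
})

test_that("lognormal intervals match the closed form", {
  expect_equal(lognormal_ci(1000, 0), c(lo = 1000, hi = 1000))
  ci <- lognormal_ci(1000, 0.2)
  expect_equal(round(ci), c(lo = 678, hi = 1474))
  expect_equal(unname(ci["lo"] * ci["hi"]), 1000^2, tolerance = 1e-9)
  expect_error(lognormal_ci(0, 0.2), class = "sc_invalid_argument")
})

test_that("availability correction reproduces the printed spring row", {
  # uncorrected 698 at availability 0.429 -> 1627 corrected
  unc <- structure(list(stratum = "SouthernPugetSound",
                        stock = "SouthernPugetSound", season = "spring",
                        area_km2 = 455, n = 100, L_km = 100,
                        density_per_km2 = 698 / 455, abundance = 698,
                        cv = 0.089, ci_lo = 564, ci_hi = 865,
                        corrected = FALSE, g0 = NULL),
                   class = "stratum_season_estimate")
  g0 <- correction_factor("spring", 0.429, se = 0.429 * 0.0112)
  corr <- apply_correction(unc, g0)
  expect_equal(round(corr$abundance), 1627)
  expect_equal(round(100 * corr$cv, 2), round(100 * sqrt(0.089^2 + 0.0112^2), 2))
  expect_equal(round(100 * corr$cv, 1), 9.0)  # 8.97 to printed precision
  # zero-SE factor leaves the CV unchanged
  corr0 <- apply_correction(unc, correction_factor("spring", 0.429, 0))
  expect_equal(corr0$cv, unc$cv)
  expect_equal(corr0$abundance, unc$abundance / 0.429)
})

test_that("winter can never be corrected", {
  unc <- structure(list(stratum = "HoodCanal", stock = "HoodCanal",
                        season = "winter", area_km2 = 390, n = 10, L_km = 50,
                        density_per_km2 = 0.78, abundance = 307, cv = 0.116,
                        ci_lo = 219, ci_hi = 428, corrected = FALSE,
                        g0 = NULL),
                   class = "stratum_season_estimate")
  expect_error(apply_correction(unc, correction_factor("spring", 0.4)),
               class = "sc_no_winter_correction")
  expect_error(correction_factor("winter", 0.4),
               class = "sc_no_winter_correction")
})

mk_est <- function(N, cv = 0.1, season = "spring", strat = "A", area = 100,
                   corrected = FALSE, ci = NULL) {
  ci <- if (!is.null(ci)) ci else if (is.na(cv) || N <= 0)
    c(NA_real_, NA_real_) else lognormal_ci(N, cv)
  structure(list(stratum = strat, stock = stratum(strat, max(area, 1))$stock,
                 season = season,
                 area_km2 = area, n = 10, L_km = 10,
                 density_per_km2 = N / area, abundance = N, cv = cv,
                 ci_lo = unname(ci[1]), ci_hi = unname(ci[2]),
                 corrected = corrected, g0 = NULL),
            class = "stratum_season_estimate")
}

test_that("stratum pooling reproduces the northern inland waters rows", {
  unc <- pool_strata(list(mk_est(1156, 0.1119, strat = "NorthernPugetSound"),
                          mk_est(2068, 0.1171, strat = "SanJuans_StraitJDF")))
  expect_equal(unc$abundance, 3224)
  corr <- pool_strata(list(
    mk_est(2694, 0.1124, strat = "NorthernPugetSound", corrected = TRUE),
    mk_est(4819, 0.1176, strat = "SanJuans_StraitJDF", corrected = TRUE)))
  expect_equal(corr$abundance, 7513)
  expect_identical(corr$stock, "WANorthernInlandWaters")
  # pooling with a zero stratum changes nothing
  z <- pool_strata(list(mk_est(1156, 0.1, strat = "NorthernPugetSound"),
                        mk_est(0, NA_real_, strat = "SanJuans_StraitJDF")))
  expect_equal(z$abundance, 1156)
  expect_error(pool_strata(list(mk_est(10), mk_est(10, season = "summer"))),
               class = "sc_invalid_argument")
  expect_error(pool_strata(list(mk_est(10), mk_est(10, corrected = TRUE))),
               class = "sc_invalid_argument")
})

test_that("year-round averaging reproduces the printed year-round rows", {
  sps <- year_round_average(list(mk_est(1627, corrected = TRUE),
                                 mk_est(2189, season = "summer",
                                        corrected = TRUE),
                                 mk_est(2113, season = "autumn",
                                        corrected = TRUE)))
  expect_equal(round(sps$abundance), 1976)
  hc <- year_round_average(list(mk_est(307, season = "winter"),
                                mk_est(590), mk_est(501, season = "summer"),
                                mk_est(345, season = "autumn")))
  expect_equal(round(hc$abundance), 436)
  # CV and CI bounds average arithmetically too
  hc_corr <- year_round_average(list(
    mk_est(1376, 0.1164, corrected = TRUE, ci = c(1038, 1824)),
    mk_est(1342, 0.1855, season = "summer", corrected = TRUE,
           ci = c(845, 2132)),
    mk_est(1385, 0.2005, season = "autumn", corrected = TRUE,
           ci = c(876, 2187))))
  expect_equal(round(100 * hc_corr$cv, 2), 16.75)
  expect_equal(round(hc_corr$ci_hi), 2048)
  expect_equal(round(hc_corr$ci_lo), 920)
  single <- year_round_average(list(mk_est(500)))
  expect_equal(single$abundance, 500)
  expect_error(year_round_average(list()), class = "sc_invalid_argument")
})

test_that("pooling and year-round averaging commute for abundance", {
  a <- list(mk_est(100, strat = "NorthernPugetSound"),
            mk_est(200, season = "summer", strat = "NorthernPugetSound"))
  b <- list(mk_est(300, strat = "SanJuans_StraitJDF"),
            mk_est(500, season = "summer", strat = "SanJuans_StraitJDF"))
  pooled_then_avg <- year_round_average(list(
    pool_strata(list(a[[1]], b[[1]])), pool_strata(list(a[[2]], b[[2]]))))
  avg_then_pooled <- pool_strata(list(year_round_average(a),
                                      year_round_average(b)),
                                 name = "NorthernPugetSound+SanJuans_StraitJDF")
  expect_equal(pooled_then_avg$abundance, avg_then_pooled$abundance)
})

test_that("corrected abundance is exactly factor times uncorrected", {
  for (pr in c(0.25, 0.429, 0.8)) {
    unc <- mk_est(777, 0.15)
    corr <- apply_correction(unc, correction_factor("spring", pr, 0.01))
    expect_equal(corr$abundance, unc$abundance / pr, tolerance = 1e-12)
    expect_gte(1 / pr, 1)
  }
})

test_that("per-line counts follow the effort-file order", {
  eff <- make_effort_df(4)
  sgt <- make_sightings_df(c("seg002", "seg002", "seg004"), c(10, 20, 30))
  pl <- per_line_counts(eff, sgt)
  expect_identical(pl$line_id, eff$line_id)
  expect_equal(pl$n_i, c(0, 2, 0, 1))
  expect_equal(pl$l_i, rep(10, 4))
})
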