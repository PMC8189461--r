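# Self-contained simulation studies used to verify that the estimators
# recover known truth.  Problem sizes are chosen to give tight Monte-Carlo
# error while remaining quick on a single core: 5,000 distances for the
# detection recovery, 15 animals over 20 weeks for the availability
# recovery, and 200 replicate surveys for the calibration study.

#' Detection-function recovery study
#'
#' Simulates truncated half-normal perpendicular distances with known scale
#' and refits them, and separately simulates a Beaufort effect on the scale
#' (sigma doubling from Beaufort 0 to 2) and refits the covariate model.
#'
#' @param seed integer seed.
#' @param n_cds distances for the plain half-normal recovery (default 5000).
#' @param sigma_m,w_m generating scale and truncation (defaults 200/500).
#' @return list with `sigma_true`, `sigma_hat`, `sigma_rel_err`, `f0_hat`,
#'   `f0_true`, and for the covariate fit `beta_true`, `beta_hat`,
#'   `beta_se`, `beta_z` (absolute standardized error).
#' @export
detection_recovery_study <- function(seed, n_cds = 5000L, sigma_m = 200,
                                     w_m = 500) {
  set.seed(seed)
  x <- abs(rnorm(ceiling(n_cds * 2.2), 0, sigma_m))
  x <- x[x <= w_m][seq_len(n_cds)]
  fit <- fit_detection_function(
    x, spec = det_spec("half_normal", "none", truncation_w_m = w_m))
  f0_true <- 1 / integrate(function(u) exp(-u^2 / (2 * sigma_m^2)), 0, w_m,
                           rel.tol = 1e-10)$value

  # MCDS: sigma doubles from Beaufort 0 to Beaufort 2
  n_mcds <- 4000L
  bss <- sample(0:2, n_mcds, replace = TRUE)
  beta_true <- log(2)
  sig_i <- sigma_m * ifelse(bss == 2L, 2, ifelse(bss == 1L, 1.4, 1))
  xm <- abs(rnorm(n_mcds, 0, sig_i))
  keep <- xm <= 2 * w_m
  mfit <- fit_detection_function(
    xm[keep], bss[keep],
    det_spec("half_normal", "none", covariates = "beaufort",
             truncation_w_m = 2 * w_m))
  i2 <- match("beaufort2", colnames(mfit$vcov))
  if (is.na(i2)) i2 <- 3L
  beta_se <- sqrt(mfit$vcov[i2, i2])
  list(sigma_true = sigma_m, sigma_hat = unname(fit$sigma_by_class[1L]),
       sigma_rel_err = abs(fit$sigma_by_class[[1L]] - sigma_m) / sigma_m,
       f0_hat = fit$f0_per_m, f0_true = f0_true,
       beta_true = beta_true, beta_hat = unname(mfit$par[i2]),
       beta_se = beta_se,
       beta_z = abs(mfit$par[[i2]] - beta_true) / beta_se)
}

#' Availability-recovery study
#'
#' Simulates the full tag chain at the deployment's scale (15 animals, 20
#' weeks by default), fits both GLMMs, predicts availability over the
#' covered dates, and compares the seasonal correction factor against the
#' generating truth (an average seal, random effects at zero, averaged over
#' the same weeks the estimate used).
#'
#' @param seed integer seed.
#' @param n_animals,weeks scenario size.
#' @param season season to evaluate (default `"spring"`).
#' @param n_draws Monte-Carlo draws for the intervals.
#' @return list with `factor_hat`, `factor_true`, `rel_err`,
#'   `pr_available_hat`, `pr_available_true`, and the fitted
#'   `correction_factor`.
#' @export
availability_recovery_study <- function(seed, n_animals = 15L,
                                        weeks = 14:33, season = "spring",
                                        n_draws = 10000L) {
  scn <- tag_scenario(n_animals = n_animals, weeks = weeks, seed = seed)
  sim <- simulate_tags(scn)
  recs <- bin_weeks_and_filter(sim$wetdry, sim$divehours)
  model <- availability_model(fit_haulout_glmm(recs$haulout),
                              fit_dive_glmm(recs$dive),
                              animal_weeks = recs$animal_weeks)
  dates <- seq(week_start_date(min(weeks), scn$year),
               week_start_date(max(weeks), scn$year) + 6L, by = "day")
  grid <- predict_availability(model, dates, n_draws = n_draws,
                               seed = seed + 1L)
  cf <- seasonal_correction(grid, season)
  truth <- tag_truth_grid(scn)
  used_weeks <- unique(grid$week[!is.na(grid$pr_available) &
                                   assign_season(grid$date) == season])
  a_true <- mean(truth$pr_available[truth$week %in% used_weeks])
  list(factor_hat = cf$factor, factor_true = 1 / a_true,
       rel_err = abs(cf$factor - 1 / a_true) / (1 / a_true),
       pr_available_hat = cf$pr_available, pr_available_true = a_true,
       correction_factor = cf)
}

# one-stratum spring scenario used by the calibration study
sc_calibration_scenario <- function(seed, density = 3.5, avail = 0.45) {
  survey_scenario(
    strata = list(list(name = "SouthernPugetSound", area_km2 = 400,
                       density_per_km2 = c(spring = density),
                       spacing_km = 2.5, line_length_km = 15)),
    availability = c(spring = avail),
    detection = list(key = "half_normal",
                     sigma_m = setNames(rep(200, 7), 0:6), w_m = 600),
    group_size_lambda = 0.6,
    beaufort_dist = c(0.4, 0.35, 0.25, 0, 0, 0, 0),
    glare_rate = 0, n_extra_segments = 0L, seasons = "spring", seed = seed)
}

#' End-to-end calibration study
#'
#' Simulates replicate surveys of one stratum with known total density and
#' availability, runs the full estimation chain per replicate (filtering,
#' truncation, half-normal fit, group size, O2 variance, correction), and
#' summarizes bias of the corrected density and empirical coverage of the
#' 95% lognormal interval.  The correction factor uses the generating
#' availability with a small standard error, so the study isolates the
#' calibration of the survey estimator itself (the tag chain has its own
#' recovery study).
#'
#' @param seed integer seed.
#' @param n_rep replicate surveys (default 200).
#' @param density,avail generating total density (seals per km2) and
#'   availability.
#' @return list with `mean_density_hat`, `density_true`, `rel_err`,
#'   `coverage` (proportion of intervals covering the true abundance), and
#'   the per-replicate table.
#' @export
calibration_study <- function(seed, n_rep = 200L, density = 3.5,
                              avail = 0.45) {
  g0 <- correction_factor("spring", avail, se = 0.005)
  strt <- stratum("SouthernPugetSound", 400)
  rows <- t(vapply(seq_len(n_rep), function(r) {
    sim <- simulate_survey(sc_calibration_scenario(seed + r, density, avail))
    filt <- suppressMessages(
      filter_for_analysis(sim$effort, sim$sightings))
    d <- filt$sightings$perpendicular_distance_m
    w <- choose_truncation(d)
    keep <- d <= w
    fit <- fit_detection_function(
      d[keep], spec = det_spec("half_normal", "none", truncation_w_m = w))
    gs <- suppressWarnings(expected_group_size(filt$sightings[keep, ], fit))
    er <- encounter_rate(per_line_counts(filt$effort,
                                         filt$sightings[keep, ]))
    est <- estimate_density_abundance(er, fit, gs, strt, g0 = g0,
                                      season = "spring")
    c(D = est$density_per_km2, lo = est$ci_lo, hi = est$ci_hi,
      n = er$n, cv = est$cv)
  }, numeric(5)))
  true_N <- density * strt$area_km2
  list(mean_density_hat = mean(rows[, "D"]), density_true = density,
       rel_err = abs(mean(rows[, "D"]) - density) / density,
       coverage = mean(rows[, "lo"] <= true_N & true_N <= rows[, "hi"]),
       replicates = as.data.frame(rows))
}
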