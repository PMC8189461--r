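test_that("haul-out state machine follows the 30s/45s/5-minute rules", {
  # all wet: no intervals
  expect_equal(nrow(detect_haulout_states(make_wetdry(rep(0, 30)))), 0L)
  # 10 fully dry minutes flanked by wet -> one interval of exactly 10 min
  wd <- make_wetdry(c(0, 0, rep(60, 10), 0, 0))
  iv <- detect_haulout_states(wd)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, wd$timestamp[3])
  expect_equal(iv$end, wd$timestamp[13])  # closes at the first wet minute
  expect_equal(as.numeric(difftime(iv$end, iv$start, units = "mins")), 10)
  # 4 dry, 1 wet, 4 dry: neither run reaches 5 minutes
  expect_equal(nrow(detect_haulout_states(
    make_wetdry(c(rep(60, 4), 0, rep(60, 4))))), 0L)
})

test_that("state machine handles thresholds, mid-range minutes and gaps", {
  # 45 dry seconds counts as dry; 30 is the boundary; 29 breaks a run
  expect_equal(nrow(detect_haulout_states(make_wetdry(rep(45, 5)))), 1L)
  expect_equal(nrow(detect_haulout_states(make_wetdry(rep(30, 5)))), 1L)
  expect_equal(nrow(detect_haulout_states(
    make_wetdry(c(60, 60, 29, 60, 60, 60, 60)))), 0L)
  # 16-29 s dry does not close an open state; <=15 s does
  wd <- make_wetdry(c(rep(60, 5), 20, 20, 60, 10, 60))
  iv <- detect_haulout_states(wd)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$end, wd$timestamp[9])
  # a recording gap closes the open state at the last observed minute
  wd2 <- make_wetdry(rep(60, 6))
  wd2$timestamp[6] <- wd2$timestamp[6] + 3600  # gap after minute 5
  iv2 <- detect_haulout_states(wd2)
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$end, wd2$timestamp[5] + 60)
  # unordered timestamps error
  wd3 <- make_wetdry(rep(60, 5))[c(2, 1, 3, 4, 5), ]
  expect_error(detect_haulout_states(wd3), class = "sc_validation_error")
})

test_that("hauled-out minutes never exceed dry minutes", {
  set.seed(5)
  for (r in 1:10) {
    wd <- make_wetdry(sample(c(0, 10, 20, 40, 60), 120, replace = TRUE))
    iv <- detect_haulout_states(wd)
    hauled_min <- if (nrow(iv)) sum(as.numeric(difftime(iv$end, iv$start,
                                                        units = "mins"))) else 0
    # dry minutes here include boundary minutes an interval may span
    expect_lte(hauled_min, sum(wd$dry_seconds > 15))
  }
})

test_that("dive fractions and event filtering follow the tag rules", {
  dh <- data.frame(animal_id = "a",
                   hour_start = as.POSIXct("2016-05-06 10:00:00", tz = "UTC"),
                   minutes_in_dive = c(0, 30, 60))
  dh <- dh[rep(1, 3), ]; dh$minutes_in_dive <- c(0, 30, 60)
  out <- dive_fraction_per_hour(dh)
  expect_equal(out$fraction, c(0, 0.5, 1))
  expect_error(dive_fraction_per_hour(transform(dh, minutes_in_dive = 61)),
               class = "sc_data_error")
  # events: {2.5 m/60 s, 10 m/15 s, 10 m/120 s} -> only the third counts
  t0 <- as.POSIXct("2016-05-06 10:00:00", tz = "UTC")
  ev <- data.frame(animal_id = "a",
                   start = c(t0, t0 + 300, t0 + 600),
                   end = c(t0 + 60, t0 + 315, t0 + 720),
                   max_depth_m = c(2.5, 10, 10))
  dm <- dive_minutes_from_events(ev)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$minutes_in_dive, 2)
  expect_equal(dive_fraction_per_hour(dm)$fraction, 2 / 60)
})

test_that("week binning drops weeks with fewer than five seals", {
  t0 <- as.POSIXct("2016-04-08 09:00:00", tz = "UTC")
  wk1 <- week_of_year(as.Date("2016-04-08"))
  mk <- function(animals, week_offset = 0) {
    do.call(rbind, lapply(animals, function(a)
      make_wetdry(rep(60, 10), animal = a,
                  start = t0 + week_offset * 7 * 86400)))
  }
  wd <- rbind(mk(sprintf("s%d", 1:4)),            # first week: 4 animals
              mk(sprintf("s%d", 1:5), 1))         # next week: 5 animals
  recs <- bin_weeks_and_filter(wd, NULL, min_animals = 5L)
  expect_false(wk1 %in% recs$haulout$week)
  expect_true((wk1 + 1L) %in% recs$haulout$week)  # exactly 5 is retained
  # with everything abundant, nothing is dropped
  recs2 <- bin_weeks_and_filter(wd, NULL, min_animals = 2L)
  expect_setequal(unique(recs2$haulout$week), c(wk1, wk1 + 1L))
  expect_equal(nrow(recs2$animal_weeks), 9L)
})

test_that("degenerate GLMM inputs raise classed errors", {
  rec <- expand.grid(animal = c("a", "b"), week = 1:2, hour = 9:10,
                     KEEP.OUT.ATTRS = FALSE)
  rec$success <- 1L; rec$trials <- 1L
  expect_error(fit_haulout_glmm(rec), class = "sc_degenerate_data")
  rec$success <- 0L
  expect_error(fit_haulout_glmm(rec), class = "sc_degenerate_data")
  recd <- expand.grid(animal = c("a", "b"), week = 1:2, hour = 9:10,
                      KEEP.OUT.ATTRS = FALSE)
  recd$fraction <- 0.3
  expect_error(fit_dive_glmm(recd), class = "sc_degenerate_data")
  rec1 <- rec[rec$animal == "a", ]
  rec1$success <- rep(0:1, length.out = nrow(rec1))
  expect_error(fit_haulout_glmm(rec1), class = "sc_insufficient_data")
})

test_that("GLMMs recover known fixed effects and probabilities", {
  scn <- tag_scenario(n_animals = 10L, weeks = 15:22, hours = 7:18,
                      deploy_spread_days = 3L, re_sd_animal = 0.4,
                      re_sd_animal_week = 0.3, seed = 21L)
  sim <- simulate_tags(scn)
  recs <- bin_weeks_and_filter(sim$wetdry, sim$divehours, min_animals = 5L)
  mh <- fit_haulout_glmm(recs$haulout)
  md <- fit_dive_glmm(recs$dive)
  # fixed hour contrast (13:00 vs the reference hour) against the
  # generating cosine effect, allowing 3 SE of estimation noise
  h0 <- min(recs$haulout$hour)
  eta <- function(h) {
    g <- tag_truth_grid(scn, hours = h)
    qlogis(g$pr_haulout[g$week == min(g$week)][1])
  }
  ii <- match("hour_f13", names(mh$beta))
  true_c <- eta(13L) - eta(h0)
  expect_lt(abs(mh$beta[ii] - true_c), 3 * sqrt(mh$vcov[ii, ii]) + 0.15)
  # random-effect SDs in the right ballpark (within 60% at this small n)
  expect_lt(abs(mh$re_sd[["animal"]] - 0.4), 0.4 * 0.6 + 0.15)
  expect_gt(md$phi, 0)
  expect_true(all(mh$re_sd >= 0, na.rm = TRUE))
})

test_that("intercept-only simulated data recover the marginal probability", {
  set.seed(55)
  rec <- expand.grid(animal = sprintf("a%02d", 1:12), week = 1:6,
                     hour = 9:14, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  p_true <- 0.35
  rec$trials <- 6L
  rec$success <- rbinom(nrow(rec), rec$trials, p_true)
  mh <- fit_haulout_glmm(rec)
  # no simulated hour/week effects: inverse-logit intercept ~ p_true
  se_int <- sqrt(mh$vcov[1, 1])
  expect_lt(abs(plogis(mh$beta[1]) - p_true),
            2 * se_int * p_true * (1 - p_true) + 0.03)
  recd <- rec
  mu <- 0.25; phi <- 12
  recd$fraction <- rbeta(nrow(recd), mu * phi, (1 - mu) * phi)
  md <- fit_dive_glmm(recd)
  expect_lt(abs(plogis(md$beta[1]) - mu), 0.03)
  expect_lt(abs(md$phi - phi) / phi, 0.35)
})

test_that("availability prediction obeys the product rule on point masses", {
  part <- function(p, resp) availability_part(
    beta = c(qlogis(p), 0, 0), vcov = matrix(0, 3, 3),
    hour_levels = c(9L, 10L), week_levels = c(20L, 21L), response = resp)
  dates <- as.Date("2016-05-20") + 0:3  # week 20/21
  # haulout 0 and dive 0 -> availability exactly 1
  m0 <- availability_model(part(1e-12, "haulout"), part(1e-12, "dive"))
  g0 <- predict_availability(m0, dates, hours = 9:10, n_draws = 50L,
                             seed = 1L)
  expect_true(all(abs(g0$pr_available - 1) < 1e-9))
  # point masses h = d = 0.5 -> availability 0.25
  m5 <- availability_model(part(0.5, "haulout"), part(0.5, "dive"))
  g5 <- predict_availability(m5, dates, hours = 9:10, n_draws = 50L,
                             seed = 1L)
  expect_true(all(abs(g5$pr_available - 0.25) < 1e-12))
  expect_true(all(abs(g5$pr_haulout - 0.5) < 1e-12))
  # dates outside the fitted weeks are NA, not extrapolated
  gx <- predict_availability(m5, as.Date("2016-08-01"), hours = 9:10,
                             n_draws = 50L, seed = 1L)
  expect_true(all(is.na(gx$pr_available)))
})

test_that("Monte-Carlo availability matches a quadrature delta oracle", {
  # smooth case: one cell, normal uncertainty on both logits
  mu_h <- qlogis(0.3); sd_h <- 0.15
  mu_d <- qlogis(0.25); sd_d <- 0.10
  ph <- availability_part(c(mu_h, 0, 0), diag(c(sd_h^2, 0, 0)),
                          hour_levels = c(9L, 10L), week_levels = c(20L, 21L),
                          response = "haulout")
  pd <- availability_part(c(mu_d, 0, 0), diag(c(sd_d^2, 0, 0)),
                          hour_levels = c(9L, 10L), week_levels = c(20L, 21L),
                          response = "dive")
  grid <- predict_availability(availability_model(ph, pd),
                               as.Date("2016-05-20"), hours = 9L,
                               n_draws = 20000L, seed = 77L)
  # independent-quadrature oracle for E[(1-h)(1-d)]
  gh <- seq(-5, 5, length.out = 2001)
  wts <- exp(-gh^2 / 2); wts <- wts / sum(wts)
  Eh <- sum(wts * plogis(mu_h + sd_h * gh))
  Ed <- sum(wts * plogis(mu_d + sd_d * gh))
  oracle <- (1 - Eh) * (1 - Ed)  # independence factorizes the expectation
  draws <- attr(grid, "avail_draws")
  mc_se <- sd(draws[1, ]) / sqrt(ncol(draws))
  expect_lt(abs(grid$pr_available[1] - oracle), 3 * mc_se)
})

test_that("seasonal correction factors reproduce the published arithmetic", {
  expect_equal(round(correction_factor("spring", 0.429)$factor, 2), 2.33)
  aut <- correction_factor("autumn", 0.249)$factor
  expect_gte(round(aut, 2), 4.01)
  expect_lte(round(aut, 2), 4.02)
  expect_equal(correction_factor("summer", 1)$factor, 1)
  f <- correction_factor("spring", 0.37, 0.01)
  expect_equal(f$factor * f$pr_available, 1, tolerance = 1e-12)
})

test_that("seasonal_correction averages cells and refuses winter", {
  part <- function(p) availability_part(
    c(qlogis(p), 0.3, 0.1), matrix(0, 3, 3), hour_levels = c(9L, 10L),
    week_levels = c(16L, 17L), response = "x")
  m <- availability_model(part(0.4), part(0.3))
  dates <- as.Date("2016-04-20") + 0:6
  g <- predict_availability(m, dates, hours = 9:10, n_draws = 100L, seed = 2L)
  cf <- seasonal_correction(g, "spring")
  expect_equal(cf$pr_available,
               mean(g$pr_available[!is.na(g$pr_available)]))
  expect_equal(cf$factor, 1 / cf$pr_available)
  expect_gte(cf$factor, 1)
  expect_error(seasonal_correction(g, "winter"),
               class = "sc_no_winter_correction")
  expect_error(seasonal_correction(g, "autumn"), class = "sc_invalid_argument")
})

test_that("factors decrease as availability increases", {
  f <- vapply(c(0.2, 0.4, 0.6, 0.9),
              function(p) correction_factor("spring", p)$factor, numeric(1))
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 1))
})
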