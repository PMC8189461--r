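# Seeded synthetic survey and tag-data generators with known truth.
#
# Geometry is deliberately one-dimensional per stratum: systematic parallel
# lines of fixed length are laid across the stratum's extent with a uniform
# random start, and groups receive a position along the cross-line axis
# only.  Availability enters the survey purely as a thinning of detectable
# groups (the instantaneous-availability assumption of the estimator).

# zero-truncated Poisson sampler
rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

e_ztpois <- function(lambda) {
  if (lambda <= 0) return(1)
  lambda / (1 - exp(-lambda))
}

#' Define a synthetic survey scenario
#'
#' Defaults emulate the 2013-2016 Washington inland-waters design: four
#' strata with systematic east-west lines spaced 3.7 km apart (1.8 km in
#' Hood Canal after in-fill, 5.55 km in the San Juans and 11.1 km in the
#' Strait of Juan de Fuca portion, represented by their mean here), total
#' seasonal densities in the range the corrected estimates report,
#' availability thinning by season, half-normal detection with sightability
#' degrading as Beaufort sea state rises, and mostly-singleton groups.
#'
#' @param strata list of stratum definitions, each a list with `name`,
#'   `area_km2`, `density_per_km2` (named by season; total seals, in water
#'   and ashore), `spacing_km`, `line_length_km`.
#' @param availability named seasonal probabilities that a seal is in the
#'   water and not diving at an instant; detectable density is
#'   `density * availability`.
#' @param detection list with `key` (`"half_normal"`), `sigma_m` (named by
#'   Beaufort level), `w_m` (maximum detectable distance).
#' @param group_size_lambda zero-truncated Poisson parameter for group size.
#' @param beaufort_dist probabilities over Beaufort 0-6 per segment.
#' @param glare_rate proportion of segments flagged glare-excluded.
#' @param n_extra_segments connector/transit segments emitted per stratum to
#'   exercise effort-type filtering.
#' @param seasons seasons to survey.
#' @param seed integer seed; identical scenarios and seeds give identical
#'   output.
#' @return a `survey_scenario`.
#' @export
survey_scenario <- function(
    strata = list(
      list(name = "SouthernPugetSound", area_km2 = 455,
           density_per_km2 = c(spring = 3.57, summer = 4.80, autumn = 4.64,
                               winter = 0.62),
           spacing_km = 3.7, line_length_km = 15),
      list(name = "HoodCanal", area_km2 = 390,
           density_per_km2 = c(spring = 3.52, summer = 3.43, autumn = 3.54,
                               winter = 0.78),
           spacing_km = 1.8, line_length_km = 10),
      list(name = "NorthernPugetSound", area_km2 = 1780,
           density_per_km2 = c(spring = 1.51, summer = 1.24, autumn = 1.69,
                               winter = 0.42),
           spacing_km = 3.7, line_length_km = 25),
      list(name = "SanJuans_StraitJDF", area_km2 = 4700,
           density_per_km2 = c(spring = 1.03),
           spacing_km = 8.3, line_length_km = 30)),
    availability = c(spring = 0.429, summer = 0.373, autumn = 0.249,
                     winter = 1),
    detection = list(key = "half_normal",
                     sigma_m = c(`0` = 230, `1` = 200, `2` = 170,
                                 `3` = 140, `4` = 120, `5` = 110, `6` = 100),
                     w_m = 700),
    group_size_lambda = 0.6,
    beaufort_dist = c(0.25, 0.30, 0.25, 0.12, 0.05, 0.02, 0.01),
    glare_rate = 0.05,
    n_extra_segments = 2L,
    seasons = c("spring", "summer", "autumn", "winter"),
    seed = 1L) {
  stopifnot(abs(sum(beaufort_dist) - 1) < 1e-9, length(beaufort_dist) == 7L)
  for (st in strata) {
    if (st$spacing_km <= 0)
      sc_abort("line spacing must be > 0", "sc_invalid_argument")
    if (any(st$density_per_km2 < 0))
      sc_abort("densities must be >= 0", "sc_invalid_argument")
  }
  if (any(availability < 0 | availability > 1))
    sc_abort("availability must lie in [0, 1]", "sc_invalid_argument")
  structure(list(strata = strata, availability = availability,
                 detection = detection,
                 group_size_lambda = group_size_lambda,
                 beaufort_dist = beaufort_dist, glare_rate = glare_rate,
                 n_extra_segments = as.integer(n_extra_segments),
                 seasons = seasons, seed = as.integer(seed)),
            class = "survey_scenario")
}

# mid-season survey dates, echoing the survey-period calendar
SC_SEASON_DATE <- c(spring = "-04-20", summer = "-07-24",
                    autumn = "-09-17", winter = "-01-20")

#' Simulate an aerial line-transect survey
#'
#' Groups are placed by a homogeneous Poisson process per stratum-season
#' with intensity `density * availability / E(group size)`; seals that are
#' hauled out or diving (the `1 - availability` complement) are never
#' detectable and are simply not placed.  Systematic parallel lines at the
#' scenario spacing with a uniform random start sample the stratum; each
#' group within `w` of a line is detected with probability
#' `g(distance; sigma[Beaufort])` and emits a sighting with its exact
#' perpendicular distance.
#'
#' @param scn a [survey_scenario()].
#' @param year calendar year stamped on the effort dates.
#' @return list with `effort`, `sightings` (data frames matching the CSV
#'   schemas) and `truth` (generating parameters and per stratum-season
#'   tallies).
#' @export
simulate_survey <- function(scn, year = 2015L) {
  stopifnot(inherits(scn, "survey_scenario"))
  set.seed(scn$seed)
  sigma_m <- scn$detection$sigma_m
  w <- scn$detection$w_m
  es <- e_ztpois(scn$group_size_lambda)
  effort <- list(); sightings <- list(); truth_rows <- list()
  seg_counter <- 0L; sgt_counter <- 0L
  for (st in scn$strata) {
    extent <- st$area_km2 / st$line_length_km
    for (season in intersect(scn$seasons, names(st$density_per_km2))) {
      date <- as.Date(paste0(year, SC_SEASON_DATE[[season]]))
      u0 <- runif(1, 0, st$spacing_km)
      ypos <- seq(u0, extent, by = st$spacing_km)
      if (length(ypos) < 2L) ypos <- c(u0, u0 + st$spacing_km)
      n_lines <- length(ypos)
      bss <- sample(0:6, n_lines, replace = TRUE, prob = scn$beaufort_dist)
      glare <- runif(n_lines) < scn$glare_rate
      seg_ids <- sprintf("%s_%s_S%03d", st$name, season,
                         seg_counter + seq_len(n_lines))
      seg_counter <- seg_counter + n_lines
      eff <- data.frame(
        segment_id = seg_ids,
        line_id = sprintf("%s_%s_L%03d", st$name, season, seq_len(n_lines)),
        stratum = st$name, date = date,
        start_time = sprintf("%02d:00:00", 9L + (seq_len(n_lines) - 1L) %% 8L),
        end_time = sprintf("%02d:30:00", 9L + (seq_len(n_lines) - 1L) %% 8L),
        length_km = st$line_length_km, beaufort = bss,
        glare_excluded = glare, effort_type = "transect")
      # a few connector/transit segments to exercise the filters
      if (scn$n_extra_segments > 0L) {
        nex <- scn$n_extra_segments
        eff_extra <- eff[rep(1L, nex), , drop = FALSE]
        eff_extra$segment_id <- sprintf("%s_%s_X%03d", st$name, season,
                                        seq_len(nex))
        eff_extra$line_id <- sprintf("%s_%s_XL%02d", st$name, season,
                                     seq_len(nex))
        eff_extra$length_km <- 2
        eff_extra$effort_type <- rep(c("connector", "transit"),
                                     length.out = nex)
        eff <- rbind(eff, eff_extra)
      }
      effort[[length(effort) + 1L]] <- eff

      avail <- unname(scn$availability[season])
      if (is.na(avail)) avail <- 1
      dens_groups <- st$density_per_km2[[season]] * avail / es
      n_groups <- rpois(1, dens_groups * st$area_km2)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        stratum = st$name, season = season, area_km2 = st$area_km2,
        density_total = st$density_per_km2[[season]],
        availability = avail,
        density_inwater = st$density_per_km2[[season]] * avail,
        n_groups_placed = n_groups, n_lines = n_lines)
      if (n_groups == 0L) next
      gy <- runif(n_groups, 0, extent)
      nearest <- vapply(gy, function(y) which.min(abs(ypos - y)), integer(1))
      dist_km <- abs(gy - ypos[nearest])
      within <- dist_km <= w / 1000
      if (!any(within)) next
      gy <- gy[within]; nearest <- nearest[within]
      dist_m <- dist_km[within] * 1000
      sig <- sigma_m[as.character(bss[nearest])]
      p_det <- if (identical(scn$detection$key, "uniform")) 1 else
        exp(-dist_m^2 / (2 * sig^2))
      det <- runif(length(dist_m)) < p_det
      if (!any(det)) next
      nd <- sum(det)
      sightings[[length(sightings) + 1L]] <- data.frame(
        sighting_id = sprintf("SGT%06d", sgt_counter + seq_len(nd)),
        segment_id = seg_ids[nearest[det]],
        species = "harbor_seal",
        group_size = rztpois(nd, scn$group_size_lambda),
        declination_deg = NA_real_,
        perpendicular_distance_m = dist_m[det],
        beaufort = bss[nearest[det]],
        observer = sample(c("left", "right", "belly"), nd, replace = TRUE))
      sgt_counter <- sgt_counter + nd
    }
  }
  effort <- do.call(rbind, effort)
  rownames(effort) <- NULL
  sightings <- if (length(sightings)) do.call(rbind, sightings) else
    data.frame(sighting_id = character(), segment_id = character(),
               species = character(), group_size = integer(),
               declination_deg = numeric(),
               perpendicular_distance_m = numeric(),
               beaufort = integer(), observer = character())
  rownames(sightings) <- NULL
  list(effort = effort, sightings = sightings,
       truth = list(scenario = unclass(scn), e_group_size = es,
                    per_stratum_season = do.call(rbind, truth_rows)))
}

#' Define a synthetic tag-data scenario
#'
#' Defaults emulate the 2016 deployment: 15 adult seals (10 males, 5
#' females) tagged in April-early May, transmitting daily from April 15 to
#' July 31 and every sixth day otherwise, with haul-out probability lowest
#' and availability highest around midday, haul-out rising toward the
#' autumn molt, and between-animal and animal-by-week heterogeneity on the
#' logit scale.
#'
#' @param n_animals number of tagged seals (first 2/3 male, rest female).
#' @param year calendar year of the deployment.
#' @param weeks week-of-year bins covered.
#' @param hours hours of day the tags record (0-23).
#' @param haul_intercept,dive_intercept logit-scale intercepts.
#' @param haul_hour_amp,dive_hour_amp amplitudes of the cosine hour-of-day
#'   effect (peak at `peak_hour`).
#' @param haul_week_slope,dive_week_slope total logit change across `weeks`
#'   (linear ramp).
#' @param peak_hour hour at which haul-out and diving are lowest.
#' @param re_sd_animal,re_sd_animal_week random-effect SDs (shared by both
#'   processes).
#' @param beta_phi Beta precision of hourly dive fractions.
#' @param duty_daily_start,duty_daily_end date window of daily transmission;
#'   outside it tags report every `duty_cycle_days` days.
#' @param duty_cycle_days reporting cadence outside the daily window.
#' @param deploy_spread_days deployments are staggered over this many days
#'   from the start of `weeks`.
#' @param seed integer seed.
#' @return a `tag_scenario`.
#' @export
tag_scenario <- function(n_animals = 15L, year = 2016L, weeks = 14:40,
                         hours = 0:23,
                         haul_intercept = qlogis(0.30),
                         dive_intercept = qlogis(0.25),
                         haul_hour_amp = 0.8, dive_hour_amp = 0.4,
                         haul_week_slope = 1.7, dive_week_slope = 0.3,
                         peak_hour = 13L,
                         re_sd_animal = 0.6, re_sd_animal_week = 0.4,
                         beta_phi = 15,
                         duty_daily_start = paste0(year, "-04-15"),
                         duty_daily_end = paste0(year, "-07-31"),
                         duty_cycle_days = 6L,
                         deploy_spread_days = 28L,
                         seed = 1L) {
  if (n_animals < 2L)
    sc_abort("need at least 2 animals", "sc_invalid_argument")
  if (re_sd_animal < 0 || re_sd_animal_week < 0)
    sc_abort("random-effect SDs must be >= 0", "sc_invalid_argument")
  structure(list(n_animals = as.integer(n_animals), year = as.integer(year),
                 weeks = as.integer(weeks), hours = as.integer(hours),
                 haul_intercept = haul_intercept,
                 dive_intercept = dive_intercept,
                 haul_hour_amp = haul_hour_amp, dive_hour_amp = dive_hour_amp,
                 haul_week_slope = haul_week_slope,
                 dive_week_slope = dive_week_slope,
                 peak_hour = as.integer(peak_hour),
                 re_sd_animal = re_sd_animal,
                 re_sd_animal_week = re_sd_animal_week,
                 beta_phi = beta_phi,
                 duty_daily_start = as.Date(duty_daily_start),
                 duty_daily_end = as.Date(duty_daily_end),
                 duty_cycle_days = as.integer(duty_cycle_days),
                 deploy_spread_days = as.integer(deploy_spread_days),
                 seed = as.integer(seed)),
            class = "tag_scenario")
}

# fixed-effect linear predictors for an average seal (random effects 0)
sc_tag_eta <- function(scn, week, hour, process = c("haulout", "dive")) {
  process <- match.arg(process)
  wk <- scn$weeks
  ramp <- (week - wk[1L]) / max(wk[length(wk)] - wk[1L], 1L)
  hour_shape <- -cos(2 * pi * (hour - scn$peak_hour) / 24)  # trough at peak_hour
  if (process == "haulout")
    scn$haul_intercept + scn$haul_hour_amp * hour_shape +
      scn$haul_week_slope * ramp
  else
    scn$dive_intercept + scn$dive_hour_amp * hour_shape +
      scn$dive_week_slope * ramp
}

#' True availability grid of a tag scenario
#'
#' Availability of an average seal (random effects at zero) per (week,
#' hour): `(1 - Pr(haulout)) * (1 - Pr(dive))`.
#'
#' @param scn a [tag_scenario()].
#' @param hours hours to tabulate (default the 0900-1700 survey window).
#' @return data frame `week, hour, pr_haulout, pr_dive, pr_available`.
#' @export
tag_truth_grid <- function(scn, hours = 9:17) {
  g <- expand.grid(week = scn$weeks, hour = as.integer(hours),
                   KEEP.OUT.ATTRS = FALSE)
  g$pr_haulout <- plogis(sc_tag_eta(scn, g$week, g$hour, "haulout"))
  g$pr_dive <- plogis(sc_tag_eta(scn, g$week, g$hour, "dive"))
  g$pr_available <- (1 - g$pr_haulout) * (1 - g$pr_dive)
  g[order(g$week, g$hour), ]
}

#' Simulate seal-tag wet/dry and dive-summary streams
#'
#' Per animal-week random effects are drawn for the haul-out and dive
#' processes; each recorded hour is hauled-out with its logit-linear
#' probability, and hourly dive minutes are Beta draws scaled to 60.  The
#' per-minute wet/dry stream is fully dry inside haul-out intervals and
#' fully wet outside, with threshold-exercising boundary minutes: the first
#' minute of an interval records 45 dry seconds (still a dry minute) and the
#' first minute after it 10 (a haul-out exit).  Dive minutes are drawn
#' independently of the haul-out state, matching the independence assumption
#' of the availability model.
#'
#' @param scn a [tag_scenario()].
#' @param emit_minutes emit the per-minute wet/dry stream? (Disable for
#'   speed when only hourly summaries are needed.)
#' @return list with `wetdry` (`animal_id, timestamp, dry_seconds`),
#'   `divehours` (`animal_id, hour_start, minutes_in_dive`),
#'   `haulout_hours` (the hourly haul-out indicators actually drawn) and
#'   `truth` (scenario, true grid, per-animal random effects).
#' @export
simulate_tags <- function(scn, emit_minutes = TRUE) {
  stopifnot(inherits(scn, "tag_scenario"))
  set.seed(scn$seed)
  animals <- sprintf("seal%02d", seq_len(scn$n_animals))
  sex <- rep(c("M", "F"), c(ceiling(scn$n_animals * 2 / 3),
                            scn$n_animals - ceiling(scn$n_animals * 2 / 3)))
  wk0 <- scn$weeks[1L]; wk1 <- scn$weeks[length(scn$weeks)]
  period_start <- week_start_date(wk0, scn$year)
  period_end <- week_start_date(wk1, scn$year) + 6L
  deploy_start <- period_start +
    sort(sample.int(scn$deploy_spread_days + 1L, scn$n_animals,
                    replace = TRUE) - 1L)
  # recoveries staggered over the last third of the period
  span <- as.integer(period_end - period_start)
  deploy_end <- period_end -
    (sample.int(max(span %/% 3L, 1L), scn$n_animals, replace = TRUE) - 1L)

  re <- data.frame(animal = animals,
                   a_haul = rnorm(scn$n_animals, 0, scn$re_sd_animal),
                   a_dive = rnorm(scn$n_animals, 0, scn$re_sd_animal))

  wet <- list(); dive <- list(); haul_hr <- list()
  for (i in seq_len(scn$n_animals)) {
    days <- seq(deploy_start[i], deploy_end[i], by = "day")
    in_window <- days >= scn$duty_daily_start & days <= scn$duty_daily_end
    cyc <- (as.integer(days - deploy_start[i]) %% scn$duty_cycle_days) == 0L
    days <- days[in_window | cyc]
    days <- days[week_of_year(days) %in% scn$weeks]
    if (!length(days)) next
    weeks_i <- sort(unique(week_of_year(days)))
    gw_h <- setNames(rnorm(length(weeks_i), 0, scn$re_sd_animal_week),
                     weeks_i)
    gw_d <- setNames(rnorm(length(weeks_i), 0, scn$re_sd_animal_week),
                     weeks_i)
    grid <- expand.grid(date = days, hour = scn$hours,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$date, grid$hour), , drop = FALSE]
    gw <- as.character(week_of_year(grid$date))
    eta_h <- sc_tag_eta(scn, week_of_year(grid$date), grid$hour, "haulout") +
      re$a_haul[i] + gw_h[gw]
    eta_d <- sc_tag_eta(scn, week_of_year(grid$date), grid$hour, "dive") +
      re$a_dive[i] + gw_d[gw]
    hauled <- rbinom(nrow(grid), 1L, plogis(eta_h))
    mu_d <- plogis(eta_d)
    frac <- rbeta(nrow(grid), mu_d * scn$beta_phi, (1 - mu_d) * scn$beta_phi)
    hour_start <- as.POSIXct(grid$date, tz = "UTC") + grid$hour * 3600
    dive[[i]] <- data.frame(animal_id = animals[i], hour_start = hour_start,
                            minutes_in_dive = 60 * frac)
    haul_hr[[i]] <- data.frame(animal_id = animals[i],
                               hour_start = hour_start, hauled = hauled)
    if (emit_minutes) {
      nh <- nrow(grid)
      n_hours_day <- length(scn$hours)
      M <- matrix(hauled, ncol = n_hours_day, byrow = TRUE)
      prev <- cbind(0L, M[, -n_hours_day, drop = FALSE])
      run_start <- M == 1L & prev == 0L
      run_exit <- M == 0L & prev == 1L
      dry <- rep(as.integer(t(M)) * 60L, each = 60L)
      first_min <- (seq_len(nh) - 1L) * 60L + 1L
      dry[first_min[as.vector(t(run_start))]] <- 45L
      dry[first_min[as.vector(t(run_exit))]] <- 10L
      ts <- rep(as.numeric(hour_start), each = 60L) +
        rep(0:59 * 60, times = nh)
      wet[[i]] <- data.frame(animal_id = animals[i],
                             timestamp = as.POSIXct(ts, tz = "UTC",
                                                    origin = "1970-01-01"),
                             dry_seconds = dry)
    }
  }
  wetdry <- if (emit_minutes) do.call(rbind, wet) else NULL
  divehours <- do.call(rbind, dive)
  haulout_hours <- do.call(rbind, haul_hr)
  rownames(divehours) <- NULL
  truth_grid <- tag_truth_grid(scn, hours = 9:17)
  seas <- vapply(truth_grid$week, season_of_week, character(1),
                 year = scn$year)
  seasonal <- aggregate(pr_available ~ season,
                        cbind(truth_grid, season = seas), mean)
  list(wetdry = wetdry, divehours = divehours,
       haulout_hours = haulout_hours,
       truth = list(scenario = unclass(scn),
                    animals = cbind(re, sex = sex,
                                    deploy_start = deploy_start,
                                    deploy_end = deploy_end),
                    grid = truth_grid, seasonal = seasonal))
}
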