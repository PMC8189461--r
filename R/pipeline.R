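# End-to-end orchestration: filter -> detection -> availability ->
# estimation -> report files.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for the recognized fields.
#' @return a config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    sc_abort(sprintf("config file not found: %s", path), "sc_io_error")
  yaml::read_yaml(path)
}

sc_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    sc_abort(sprintf("pipeline stage `%s` failed: %s", stage,
                     conditionMessage(e)),
             "sc_pipeline_error")
  })
}

#' Run the full estimation pipeline
#'
#' Stages: read and filter survey data (`survey_io`), fit the AIC menu of
#' detection functions per stratum pooled across seasons (`detection`), fit
#' the availability GLMMs and derive seasonal correction factors
#' (`availability`), estimate density and abundance per stratum-season with
#' uncorrected and corrected versions, pool the northern strata into the
#' Washington Northern Inland Waters stock and average seasons
#' (`estimation`), and write `estimates.csv`, `stocks.csv`,
#' `correction_factors.csv`, `detection_fit.json` and `run_log.txt` into
#' `out_dir`.  Winter rows are never corrected (no winter tag data exist).
#'
#' Config fields: `effort_csv`, `sightings_csv`, `tags_wetdry_csv`,
#' `tags_divehours_csv` (paths), or `simulate: true` with optional
#' `survey_scenario` / `tag_scenario` overrides; `strata_areas` (named
#' areas in km2), `truncation_strategy`, `max_beaufort`, `min_animals`,
#' `n_draws`, `seed`.
#'
#' @param config a config list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the estimates, correction factors and
#'   file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(out_dir, c("estimates.csv", "stocks.csv",
                                  "correction_factors.csv",
                                  "detection_fit.json", "run_log.txt"))
  on_failure <- function() unlink(outputs[file.exists(outputs)])
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  log_lines <- c(sprintf("sealcount %s", as.character(packageVersion("sealcount"))),
                 sprintf("R %s", getRversion()), sprintf("seed %d", seed))

  res <- tryCatch({
    ## ---- survey_io -------------------------------------------------------
    dat <- sc_stage("survey_io", {
      if (isTRUE(config$simulate)) {
        scn <- do.call(survey_scenario,
                       c(config$survey_scenario,
                         if (is.null(config$survey_scenario$seed))
                           list(seed = seed)))
        sim <- simulate_survey(scn)
        list(effort = sim$effort, sightings = sim$sightings)
      } else {
        list(effort = read_effort(config$effort_csv),
             sightings = read_sightings(config$sightings_csv))
      }
    })
    cfg_filter <- filter_config(
      max_beaufort = if (is.null(config$max_beaufort)) 2L else
        config$max_beaufort)
    filt <- sc_stage("survey_io",
                     filter_for_analysis(dat$effort, dat$sightings,
                                         cfg_filter))
    log_lines <- c(log_lines,
                   sprintf("effort segments retained: %d of %d",
                           nrow(filt$effort), nrow(dat$effort)),
                   sprintf("sightings retained: %d of %d",
                           nrow(filt$sightings), nrow(dat$sightings)))

    ## ---- availability ----------------------------------------------------
    factors <- sc_stage("availability", {
      tags <- if (isTRUE(config$simulate)) {
        tscn <- do.call(tag_scenario,
                        c(config$tag_scenario,
                          if (is.null(config$tag_scenario$seed))
                            list(seed = seed + 1L)))
        simulate_tags(tscn)
      } else if (!is.null(config$tags_wetdry_csv)) {
        list(wetdry = read_tags_wetdry(config$tags_wetdry_csv),
             divehours = read_tags_divehours(config$tags_divehours_csv))
      } else NULL
      if (is.null(tags)) NULL else {
        recs <- bin_weeks_and_filter(
          tags$wetdry, tags$divehours,
          min_animals = if (is.null(config$min_animals)) 5L else
            config$min_animals)
        model <- availability_model(fit_haulout_glmm(recs$haulout),
                                    fit_dive_glmm(recs$dive),
                                    animal_weeks = recs$animal_weeks)
        grid <- predict_availability(
          model, dates = unique(filt$effort$date),
          n_draws = if (is.null(config$n_draws)) 10000L else
            as.integer(config$n_draws),
          seed = seed + 2L)
        seasons <- setdiff(unique(assign_season(filt$effort$date)), "winter")
        fl <- list()
        for (s in seasons) {
          f <- tryCatch(seasonal_correction(grid, s),
                        sealcount_error = function(e) NULL)
          if (!is.null(f)) fl[[s]] <- f
        }
        fl
      }
    })

    ## ---- detection + estimation per stratum ------------------------------
    estimates <- sc_stage("detection", {
      out <- list()
      fits <- list()
      for (str_name in unique(filt$effort$stratum)) {
        eff_s <- filt$effort[filt$effort$stratum == str_name, , drop = FALSE]
        sgt_s <- filt$sightings[
          filt$sightings$segment_id %in% eff_s$segment_id, , drop = FALSE]
        if (nrow(sgt_s) < 10L) {
          log_lines <- c(log_lines, sprintf(
            "stratum %s skipped: only %d sightings", str_name, nrow(sgt_s)))
          next
        }
        w <- choose_truncation(
          sgt_s$perpendicular_distance_m,
          strategy = if (is.null(config$truncation_strategy)) "quantile_95"
          else config$truncation_strategy)
        keep <- sgt_s$perpendicular_distance_m <= w
        sgt_t <- sgt_s[keep, , drop = FALSE]
        menu <- fit_detection_menu(
          sgt_t$perpendicular_distance_m, sgt_t$beaufort,
          truncation_w_m = w,
          max_adjust_terms = if (is.null(config$max_adjust_terms)) 2L else
            as.integer(config$max_adjust_terms))
        fit <- menu$best
        fits[[str_name]] <- fit
        gs <- expected_group_size(sgt_t, fit)
        area <- config$strata_areas[[str_name]]
        if (is.null(area)) area <- 1000
        strt <- stratum(str_name, area)
        for (season in unique(assign_season(eff_s$date))) {
          eff_ss <- eff_s[assign_season(eff_s$date) == season, , drop = FALSE]
          sgt_ss <- sgt_t[sgt_t$segment_id %in% eff_ss$segment_id, ,
                          drop = FALSE]
          er <- encounter_rate(per_line_counts(eff_ss, sgt_ss))
          unc <- estimate_density_abundance(er, fit, gs, strt,
                                            season = season)
          out[[length(out) + 1L]] <- unc
          if (season != "winter" && !is.null(factors[[season]]))
            out[[length(out) + 1L]] <- apply_correction(unc,
                                                        factors[[season]])
        }
      }
      list(estimates = out, fits = fits)
    })

    ## ---- aggregation -----------------------------------------------------
    agg <- sc_stage("estimation", {
      ests <- estimates$estimates
      season_of <- vapply(ests, `[[`, character(1), "season")
      strat_of <- vapply(ests, `[[`, character(1), "stratum")
      corr_of <- vapply(ests, `[[`, logical(1), "corrected")
      extra <- list()
      # pool the two northern strata where both exist for a season/status
      for (season in unique(season_of)) for (corr in c(FALSE, TRUE)) {
        idx <- which(season_of == season & corr_of == corr &
                       strat_of %in% c("NorthernPugetSound",
                                       "SanJuans_StraitJDF"))
        if (length(idx) == 2L)
          extra[[length(extra) + 1L]] <-
            pool_strata(ests[idx], name = "WANorthernInlandWaters")
      }
      # year-round averages per stratum/status with > 1 season
      for (str_name in unique(strat_of)) for (corr in c(FALSE, TRUE)) {
        idx <- which(strat_of == str_name & corr_of == corr)
        if (length(idx) > 1L)
          extra[[length(extra) + 1L]] <- year_round_average(ests[idx])
      }
      c(ests, extra)
    })

    ## ---- outputs ---------------------------------------------------------
    sc_stage("report", {
      tab <- estimates_table(agg)
      write_estimates(outputs[1L], tab)
      stocks <- tab[tab$corrected &
                      (tab$season == "year_round" |
                         tab$stratum == "WANorthernInlandWaters"), ,
                    drop = FALSE]
      write_estimates(outputs[2L],
                      stocks[c("stock", "stratum", "season", "abundance",
                               "ci_lo", "ci_hi", "cv_pct")])
      if (length(factors))
        write_correction_factors(outputs[3L], factors)
      else
        write_estimates(outputs[3L],
                        data.frame(season = character(),
                                   n_seal_periods = integer(),
                                   pr_available = numeric(),
                                   pr_available_se = numeric(),
                                   factor = numeric()))
      jsonlite::write_json(
        lapply(estimates$fits, function(f)
          list(spec = unclass(f$spec), params = f$par, f0_per_m = f$f0_per_m,
               se_f0 = f$se_f0, esw_m = f$esw_m, aic = f$aic,
               n_used = f$n_used)),
        outputs[4L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
      writeLines(log_lines, outputs[5L])
    })
    list(estimates = agg, factors = factors, fits = estimates$fits,
         files = outputs)
  }, sealcount_error = function(e) {
    on_failure()
    stop(e)
  })
  invisible(res)
}

#' Read tag wet/dry minutes from CSV
#'
#' Columns: `animal_id, timestamp, dry_seconds` with ISO timestamps (UTC).
#'
#' @param path CSV path.
#' @return data frame with `POSIXct` timestamps.
#' @export
read_tags_wetdry <- function(path) {
  df <- sc_read_csv(path, c("animal_id", "timestamp", "dry_seconds"),
                    "tags_wetdry")
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df$dry_seconds <- sc_parse_num(df$dry_seconds, "dry_seconds", "tags_wetdry")
  if (any(is.na(df$timestamp)))
    sc_abort("tags_wetdry: unparsable timestamp", "sc_parse_error")
  df
}

#' Read hourly dive summaries from CSV
#'
#' Columns: `animal_id, hour_start, minutes_in_dive` (ISO timestamps, UTC).
#'
#' @param path CSV path.
#' @return data frame with `POSIXct` hour starts.
#' @export
read_tags_divehours <- function(path) {
  df <- sc_read_csv(path, c("animal_id", "hour_start", "minutes_in_dive"),
                    "tags_divehours")
  df$hour_start <- as.POSIXct(df$hour_start, tz = "UTC")
  df$minutes_in_dive <- sc_parse_num(df$minutes_in_dive, "minutes_in_dive",
                                     "tags_divehours")
  if (any(is.na(df$hour_start)))
    sc_abort("tags_divehours: unparsable hour_start", "sc_parse_error")
  df
}

#' Simulate a scenario and write its files to a directory
#'
#' Writes `effort.csv`, `sightings.csv`, `tags_wetdry.csv`,
#' `tags_divehours.csv` and `truth.json`.
#'
#' @param out_dir output directory.
#' @param survey a [survey_scenario()] (or `NULL` to skip).
#' @param tags a [tag_scenario()] (or `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
run_simulate <- function(out_dir, survey = survey_scenario(),
                         tags = tag_scenario()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  truth <- list()
  if (!is.null(survey)) {
    sim <- simulate_survey(survey)
    write_estimates(file.path(out_dir, "effort.csv"), sim$effort)
    write_estimates(file.path(out_dir, "sightings.csv"), sim$sightings)
    truth$survey <- sim$truth
    paths <- c(paths, file.path(out_dir, c("effort.csv", "sightings.csv")))
  }
  if (!is.null(tags)) {
    sim <- simulate_tags(tags)
    wd <- sim$wetdry
    wd$timestamp <- format(wd$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    write_estimates(file.path(out_dir, "tags_wetdry.csv"), wd)
    dh <- sim$divehours
    dh$hour_start <- format(dh$hour_start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    write_estimates(file.path(out_dir, "tags_divehours.csv"), dh)
    truth$tags <- sim$truth[c("scenario", "seasonal")]
    paths <- c(paths, file.path(out_dir, c("tags_wetdry.csv",
                                           "tags_divehours.csv")))
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, truth_path))
}
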