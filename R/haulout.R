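# Turning raw tag streams into haul-out states, dive fractions, and weekly
# analysis records.

#' Detect haul-out intervals from per-minute wet/dry records
#'
#' Tag convention: a minute counts as *dry* when the sensor was dry for at
#' least 30 s of it, and triggers a haul-out *exit* when wet for at least
#' 45 s (dry for at most 15 s).  A haul-out state opens once five
#' consecutive dry minutes have accrued, backfilled to the start of that dry
#' run; it closes at the first exit minute, or at any gap in the record.
#' Minutes with 16-29 dry seconds neither extend a dry run nor close an open
#' state.
#'
#' @param wetdry data frame with columns `animal_id`, `timestamp`
#'   (minute-resolution `POSIXct`), `dry_seconds` (0-60), time-ordered
#'   within animal.
#' @return data frame `animal_id`, `start`, `end` (`POSIXct`); intervals per
#'   animal are non-overlapping with `end > start`.
#' @export
detect_haulout_states <- function(wetdry) {
  stopifnot(all(c("animal_id", "timestamp", "dry_seconds") %in% names(wetdry)))
  if (any(wetdry$dry_seconds < 0 | wetdry$dry_seconds > 60))
    sc_abort("dry_seconds must lie in [0, 60]", "sc_validation_error")
  out <- lapply(split(wetdry, wetdry$animal_id), function(d) {
    tt <- as.numeric(d$timestamp)
    if (is.unsorted(tt, strictly = TRUE))
      sc_abort(sprintf("wet/dry timestamps for animal %s are not strictly increasing",
                       d$animal_id[1L]), "sc_validation_error")
    # contiguous blocks: consecutive minutes 60 s apart
    block <- cumsum(c(1L, as.integer(diff(tt) != 60)))
    ivals <- lapply(split(seq_along(tt), block), function(idx) {
      ds <- d$dry_seconds[idx]
      dry <- ds >= 30
      exit <- ds <= 15
      r <- rle(dry)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cand <- starts[r$values & r$lengths >= 5L]  # qualifying dry runs
      if (!length(cand)) return(NULL)
      exits <- which(exit)
      res <- list()
      cursor <- 0L
      for (s in cand) {
        if (s <= cursor) next  # run begins inside an open interval
        e <- exits[exits > s]
        if (length(e)) {
          res[[length(res) + 1L]] <-
            c(start = tt[idx[s]], end = tt[idx[e[1L]]])
          cursor <- e[1L]
        } else {
          res[[length(res) + 1L]] <-
            c(start = tt[idx[s]], end = tt[idx[length(idx)]] + 60)
          cursor <- length(idx)
        }
      }
      do.call(rbind, res)
    })
    ivals <- do.call(rbind, ivals)
    if (is.null(ivals)) return(NULL)
    data.frame(animal_id = d$animal_id[1L],
               start = as.POSIXct(ivals[, "start"], tz = "UTC",
                                  origin = "1970-01-01"),
               end = as.POSIXct(ivals[, "end"], tz = "UTC",
                                origin = "1970-01-01"))
  })
  out <- do.call(rbind, Filter(Negate(is.null), unname(out)))
  if (is.null(out))
    out <- data.frame(animal_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"))
  rownames(out) <- NULL
  out
}

#' Fraction of each hour spent in a dive state
#'
#' @param dive_hours data frame with `animal_id`, `hour_start` (`POSIXct`),
#'   `minutes_in_dive` (0-60).
#' @return the input with an added `fraction` column (`minutes_in_dive/60`).
#' @export
dive_fraction_per_hour <- function(dive_hours) {
  stopifnot(all(c("animal_id", "hour_start", "minutes_in_dive") %in%
                  names(dive_hours)))
  if (any(dive_hours$minutes_in_dive < 0 | dive_hours$minutes_in_dive > 60))
    sc_abort("minutes_in_dive must lie in [0, 60]", "sc_data_error")
  dive_hours$fraction <- dive_hours$minutes_in_dive / 60
  dive_hours
}

#' Hourly dive minutes from raw dive events
#'
#' Used in synthetic mode when an event list is supplied instead of hourly
#' summaries.  Events with maximum depth shallower than 3 m or duration
#' shorter than 20 s are ignored (the tags themselves open and close dives
#' at a 1.5 m depth threshold).  Event time is apportioned to the hours it
#' overlaps.
#'
#' @param events data frame with `animal_id`, `start`, `end` (`POSIXct`),
#'   `max_depth_m`.
#' @param min_depth_m minimum maximum-depth for a valid dive (default 3).
#' @param min_duration_s minimum duration for a valid dive (default 20).
#' @return data frame `animal_id`, `hour_start`, `minutes_in_dive`.
#' @export
dive_minutes_from_events <- function(events, min_depth_m = 3,
                                     min_duration_s = 20) {
  stopifnot(all(c("animal_id", "start", "end", "max_depth_m") %in%
                  names(events)))
  dur <- as.numeric(events$end) - as.numeric(events$start)
  keep <- events$max_depth_m >= min_depth_m & dur >= min_duration_s
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0L)
    return(data.frame(animal_id = character(),
                      hour_start = as.POSIXct(character(), tz = "UTC"),
                      minutes_in_dive = numeric()))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    s <- as.numeric(events$start[i]); e <- as.numeric(events$end[i])
    h0 <- (s %/% 3600) * 3600
    hours <- seq(h0, ((e - 1e-9) %/% 3600) * 3600, by = 3600)
    mins <- vapply(hours, function(h)
      (min(e, h + 3600) - max(s, h)) / 60, numeric(1))
    data.frame(animal_id = events$animal_id[i], hour = hours,
               minutes = mins)
  })
  agg <- aggregate(minutes ~ animal_id + hour, do.call(rbind, rows), sum)
  data.frame(animal_id = agg$animal_id,
             hour_start = as.POSIXct(agg$hour, tz = "UTC",
                                     origin = "1970-01-01"),
             minutes_in_dive = pmin(agg$minutes, 60))
}

#' Bin tag data into weeks and drop sparse weeks
#'
#' Weeks are fixed seven-day day-of-year bins (see [week_of_year()]).  Weeks
#' in which fewer than `min_animals` distinct animals contribute data are
#' dropped entirely (separately for the wet/dry and dive datasets).  Wet/dry
#' minutes are aggregated to binomial cells per (animal, week, hour):
#' by default each observed (animal, date, hour) contributes one Bernoulli
#' trial whose success means the hour was predominantly dry (hauled out);
#' `unit = "minute"` instead counts every minute as a trial.
#'
#' @param wetdry per-minute wet/dry data frame (`animal_id`, `timestamp`,
#'   `dry_seconds`), or `NULL`.
#' @param divehours per-hour dive data frame (`animal_id`, `hour_start`,
#'   `minutes_in_dive`), or `NULL`.
#' @param min_animals minimum distinct animals for a week to be retained
#'   (default 5).
#' @param unit `"hour"` (default) or `"minute"` Bernoulli trials for the
#'   haul-out response.
#' @return list with `haulout` (`animal, week, hour, success, trials`),
#'   `dive` (`animal, week, hour, fraction`), and `animal_weeks` (distinct
#'   retained animal-week pairs, the "seal periods" a correction factor is
#'   based on).
#' @export
bin_weeks_and_filter <- function(wetdry = NULL, divehours = NULL,
                                 min_animals = 5L,
                                 unit = c("hour", "minute")) {
  unit <- match.arg(unit)
  drop_sparse <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    by_week <- tapply(df$animal, df$week, function(a) length(unique(a)))
    keep_weeks <- as.integer(names(by_week)[by_week >= min_animals])
    df[df$week %in% keep_weeks, , drop = FALSE]
  }
  haul <- NULL
  if (!is.null(wetdry) && nrow(wetdry) > 0L) {
    ts <- wetdry$timestamp
    date <- as.Date(ts, tz = "UTC")
    hour <- as.integer(format(ts, "%H", tz = "UTC"))
    dry <- wetdry$dry_seconds >= 30
    if (unit == "hour") {
      key <- paste(wetdry$animal_id, date, hour, sep = "|")
      dsh <- rowsum(cbind(dry = as.integer(dry), tot = 1L), key)
      parts <- do.call(rbind, strsplit(rownames(dsh), "|", fixed = TRUE))
      haul <- data.frame(animal = parts[, 1L],
                         week = week_of_year(as.Date(parts[, 2L])),
                         hour = as.integer(parts[, 3L]),
                         success = as.integer(dsh[, "dry"] / dsh[, "tot"] >= 0.5),
                         trials = 1L)
    } else {
      haul <- data.frame(animal = wetdry$animal_id,
                         week = week_of_year(date), hour = hour,
                         success = as.integer(dry), trials = 1L)
    }
    # collapse to one binomial cell per (animal, week, hour)
    key <- paste(haul$animal, haul$week, haul$hour, sep = "|")
    agg <- rowsum(cbind(success = haul$success, trials = haul$trials), key)
    parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
    haul <- data.frame(animal = parts[, 1L], week = as.integer(parts[, 2L]),
                       hour = as.integer(parts[, 3L]),
                       success = as.integer(agg[, "success"]),
                       trials = as.integer(agg[, "trials"]))
    haul <- drop_sparse(haul)
    rownames(haul) <- NULL
  }
  dive <- NULL
  if (!is.null(divehours) && nrow(divehours) > 0L) {
    dv <- dive_fraction_per_hour(divehours)
    dive <- data.frame(animal = dv$animal_id,
                       week = week_of_year(as.Date(dv$hour_start, tz = "UTC")),
                       hour = as.integer(format(dv$hour_start, "%H",
                                                tz = "UTC")),
                       fraction = dv$fraction)
    dive <- drop_sparse(dive)
    rownames(dive) <- NULL
  }
  aw <- unique(rbind(
    if (!is.null(haul)) haul[c("animal", "week")],
    if (!is.null(dive)) dive[c("animal", "week")]))
  list(haulout = haul, dive = dive, animal_weeks = aw)
}
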