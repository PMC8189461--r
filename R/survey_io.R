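# Reading, validating and filtering aerial-survey effort and sighting data.

EFFORT_COLUMNS <- c("segment_id", "line_id", "stratum", "date", "start_time",
                    "end_time", "length_km", "beaufort", "glare_excluded",
                    "effort_type")
SIGHTING_COLUMNS <- c("sighting_id", "segment_id", "species", "group_size",
                      "declination_deg", "perpendicular_distance_m",
                      "beaufort", "observer")

#' Convert a declination angle to a perpendicular distance
#'
#' Observers record the declination angle from the horizontal to a sighting
#' abeam of the aircraft with an inclinometer; at survey altitude `h` the
#' perpendicular distance to the trackline is `h / tan(angle)`.  An angle of
#' 90 degrees is directly below the aircraft and maps to exactly 0 m.
#'
#' @param declination_deg declination angle(s) in degrees, in `(0, 90]`.
#' @param altitude_m survey altitude in meters (default 234 m, the fixed-wing
#'   altitude flown in these surveys).
#' @return perpendicular distance(s) in meters.
#' @export
#' @examples
#' angle_to_perpendicular_distance(45, 234)  # 234 m
#' angle_to_perpendicular_distance(90, 234)  # 0 m
angle_to_perpendicular_distance <- function(declination_deg, altitude_m = 234) {
  if (!is.numeric(altitude_m) || any(altitude_m <= 0))
    sc_abort("`altitude_m` must be > 0", "sc_invalid_angle")
  if (!is.numeric(declination_deg) || any(is.na(declination_deg)) ||
      any(declination_deg <= 0) || any(declination_deg > 90))
    sc_abort("declination angles must lie in (0, 90] degrees",
             "sc_invalid_angle")
  out <- altitude_m / tan(declination_deg * pi / 180)
  out[declination_deg == 90] <- 0
  out
}

#' Assign a solar season to a date
#'
#' Seasons follow calendar months: spring is March-May, summer June-August,
#' autumn September-November, winter December-February.
#'
#' @param date a `Date` vector (or coercible).
#' @return character vector of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @export
assign_season <- function(date) {
  m <- as.integer(strftime(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer",
    "autumn", "autumn", "autumn", "winter")[m]
}

#' Filter configuration for line-transect analysis
#'
#' The defaults implement the standard treatment for these surveys: keep only
#' systematic transect effort (no connectors or transits), Beaufort sea
#' states 0-2, and segments without hard glare over a substantial part of an
#' observer's field of view.
#'
#' @param max_beaufort highest Beaufort sea state retained (default 2).
#' @param allowed_effort_types effort types retained (default `"transect"`).
#' @param apply_glare_filter drop segments flagged `glare_excluded`?
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_beaufort = 2L,
                          allowed_effort_types = "transect",
                          apply_glare_filter = TRUE) {
  sc_stopifnot_scalar_number(max_beaufort, "max_beaufort", 0, 6)
  if (!all(allowed_effort_types %in% SC_EFFORT_TYPES))
    sc_abort("unknown effort type in `allowed_effort_types`",
             "sc_invalid_argument")
  structure(list(max_beaufort = as.integer(max_beaufort),
                 allowed_effort_types = allowed_effort_types,
                 apply_glare_filter = isTRUE(apply_glare_filter)),
            class = "filter_config")
}

#' Filter effort and sightings for line-transect analysis
#'
#' Retains effort segments whose type is allowed, whose Beaufort sea state
#' does not exceed the maximum, and (optionally) that are not glare-excluded;
#' sightings are retained only when their segment is retained.  Counts of
#' removed segments by reason are reported via [message()] and attached as
#' the `"removed"` attribute of the result.
#'
#' @param segments effort data frame as returned by [read_effort()].
#' @param sightings sightings data frame as returned by [read_sightings()].
#' @param cfg a [filter_config()].
#' @return list with elements `effort`, `sightings` and attribute `removed`.
#' @export
filter_for_analysis <- function(segments, sightings, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  orphan <- !(sightings$segment_id %in% segments$segment_id)
  if (any(orphan))
    sc_abort(sprintf("sightings reference unknown segments: %s",
                     paste(head(sightings$sighting_id[orphan], 5L),
                           collapse = ", ")),
             "sc_referential_integrity")

  bad_type <- !(segments$effort_type %in% cfg$allowed_effort_types)
  bad_bss  <- segments$beaufort > cfg$max_beaufort
  bad_glare <- if (cfg$apply_glare_filter) segments$glare_excluded else
    rep(FALSE, nrow(segments))

  # a segment is counted once, under the first rule that removes it
  removed <- c(effort_type = sum(bad_type),
               beaufort    = sum(!bad_type & bad_bss),
               glare       = sum(!bad_type & !bad_bss & bad_glare))
  keep <- !(bad_type | bad_bss | bad_glare)
  out_seg <- segments[keep, , drop = FALSE]
  out_sgt <- sightings[sightings$segment_id %in% out_seg$segment_id, ,
                       drop = FALSE]
  removed <- c(removed, sightings = nrow(sightings) - nrow(out_sgt))
  message(sprintf(
    "filter_for_analysis: removed %d segment(s) [effort_type %d, beaufort %d, glare %d] and %d sighting(s)",
    sum(!keep), removed[["effort_type"]], removed[["beaufort"]],
    removed[["glare"]], removed[["sightings"]]))
  structure(list(effort = out_seg, sightings = out_sgt), removed = removed)
}

# shared reader: schema check + row-numbered parse errors
sc_read_csv <- function(path, required, what) {
  if (!file.exists(path))
    sc_abort(sprintf("%s file not found: %s", what, path), "sc_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    sc_abort(sprintf("%s file %s is missing required column(s): %s",
                     what, path, paste(missing, collapse = ", ")),
             "sc_schema_error")
  df
}

sc_parse_num <- function(x, col, what, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(allow_na & (is.na(x) | x == "" | x == "NA"))
  if (any(bad))
    sc_abort(sprintf("%s: unparsable value in column `%s` at row %d",
                     what, col, which(bad)[1L]), "sc_parse_error")
  out
}

#' Read survey effort segments
#'
#' Reads a comma-delimited effort file with columns `segment_id, line_id,
#' stratum, date, start_time, end_time, length_km, beaufort, glare_excluded,
#' effort_type`.  Dates must be ISO-8601 (`YYYY-MM-DD`); times are local
#' clock times and are kept as text.
#'
#' @param path path to `effort.csv`.
#' @return a data frame of validated effort segments.
#' @export
read_effort <- function(path) {
  df <- sc_read_csv(path, EFFORT_COLUMNS, "effort")
  if (nrow(df) == 0L) {
    df$date <- as.Date(character()); df$length_km <- numeric()
    df$beaufort <- integer(); df$glare_excluded <- logical()
    return(df[EFFORT_COLUMNS])
  }
  df$length_km <- sc_parse_num(df$length_km, "length_km", "effort")
  df$beaufort <- as.integer(sc_parse_num(df$beaufort, "beaufort", "effort"))
  gl <- toupper(trimws(df$glare_excluded))
  if (!all(gl %in% c("TRUE", "FALSE")))
    sc_abort(sprintf("effort: unparsable value in column `glare_excluded` at row %d",
                     which(!gl %in% c("TRUE", "FALSE"))[1L]), "sc_parse_error")
  df$glare_excluded <- gl == "TRUE"
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (any(is.na(date)))
    sc_abort(sprintf("effort: unparsable value in column `date` at row %d",
                     which(is.na(date))[1L]), "sc_parse_error")
  df$date <- date
  if (any(df$length_km <= 0))
    sc_abort("effort: length_km must be > 0", "sc_validation_error")
  if (any(df$beaufort < 0L | df$beaufort > 6L))
    sc_abort("effort: beaufort must be in 0..6", "sc_validation_error")
  if (!all(df$stratum %in% SC_STRATA))
    sc_abort(sprintf("effort: unknown stratum `%s`",
                     setdiff(df$stratum, SC_STRATA)[1L]), "sc_validation_error")
  if (!all(df$effort_type %in% SC_EFFORT_TYPES))
    sc_abort("effort: effort_type must be transect, connector or transit",
             "sc_validation_error")
  if (anyDuplicated(df$segment_id))
    sc_abort("effort: duplicated segment_id", "sc_validation_error")
  df[EFFORT_COLUMNS]
}

#' Read sightings
#'
#' Reads a comma-delimited sightings file with columns `sighting_id,
#' segment_id, species, group_size, declination_deg,
#' perpendicular_distance_m, beaufort, observer`.  Exactly one of
#' `declination_deg` / `perpendicular_distance_m` may be blank per row; a
#' missing distance is computed from the declination angle at the survey
#' altitude.  Sightings without a group size are rejected.
#'
#' @param path path to `sightings.csv`.
#' @param altitude_m survey altitude used for angle conversion (default 234).
#' @return a data frame of validated sightings with
#'   `perpendicular_distance_m` filled in.
#' @export
read_sightings <- function(path, altitude_m = 234) {
  df <- sc_read_csv(path, SIGHTING_COLUMNS, "sightings")
  if (nrow(df) == 0L) {
    for (col in c("group_size", "declination_deg", "perpendicular_distance_m",
                  "beaufort"))
      df[[col]] <- numeric()
    return(df[SIGHTING_COLUMNS])
  }
  df$group_size <- sc_parse_num(df$group_size, "group_size", "sightings",
                                allow_na = TRUE)
  if (any(is.na(df$group_size)))
    sc_abort(sprintf("sightings: missing group_size at row %d (not imputed)",
                     which(is.na(df$group_size))[1L]), "sc_validation_error")
  if (any(df$group_size < 1 | df$group_size != round(df$group_size)))
    sc_abort("sightings: group_size must be an integer >= 1",
             "sc_validation_error")
  df$declination_deg <- sc_parse_num(df$declination_deg, "declination_deg",
                                     "sightings", allow_na = TRUE)
  df$perpendicular_distance_m <- sc_parse_num(
    df$perpendicular_distance_m, "perpendicular_distance_m", "sightings",
    allow_na = TRUE)
  both_na <- is.na(df$declination_deg) & is.na(df$perpendicular_distance_m)
  if (any(both_na))
    sc_abort(sprintf(
      "sightings: row %d has neither declination_deg nor perpendicular_distance_m",
      which(both_na)[1L]), "sc_validation_error")
  need <- is.na(df$perpendicular_distance_m)
  if (any(need))
    df$perpendicular_distance_m[need] <-
      angle_to_perpendicular_distance(df$declination_deg[need], altitude_m)
  if (any(df$perpendicular_distance_m < 0))
    sc_abort("sightings: negative perpendicular distance", "sc_validation_error")
  df$beaufort <- as.integer(sc_parse_num(df$beaufort, "beaufort", "sightings"))
  if (any(df$beaufort < 0L | df$beaufort > 6L))
    sc_abort("sightings: beaufort must be in 0..6", "sc_validation_error")
  if (!all(df$observer %in% c("left", "right", "belly")))
    sc_abort("sightings: observer must be left, right or belly",
             "sc_validation_error")
  df[SIGHTING_COLUMNS]
}

#' Write a table of estimates (or any results table) as CSV
#'
#' UTF-8, comma-delimited, header row, no row names.  Numeric columns are
#' written at full double precision so that write/read round-trips preserve
#' values to better than 1e-9.
#'
#' @param path output path.
#' @param estimates a data frame.
#' @export
write_estimates <- function(path, estimates) {
  stopifnot(is.data.frame(estimates))
  out <- estimates
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.15g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
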