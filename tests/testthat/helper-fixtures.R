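# Programmatic fixtures and independent oracles used across test files.

make_effort_df <- function(n = 4L, stratum = "SouthernPugetSound",
                           date = as.Date("2015-04-20"), beaufort = 1L,
                           effort_type = "transect", glare = FALSE,
                           length_km = 10) {
  data.frame(
    segment_id = sprintf("seg%03d", seq_len(n)),
    line_id = sprintf("line%03d", seq_len(n)),
    stratum = stratum, date = date,
    start_time = "09:00:00", end_time = "09:30:00",
    length_km = length_km,
    beaufort = rep_len(beaufort, n),
    glare_excluded = rep_len(glare, n),
    effort_type = rep_len(effort_type, n))
}

make_sightings_df <- function(segment_ids, distances_m,
                              group_size = 1L, beaufort = 1L) {
  n <- length(distances_m)
  data.frame(
    sighting_id = sprintf("sgt%04d", seq_len(n)),
    segment_id = rep_len(segment_ids, n),
    species = "harbor_seal",
    group_size = rep_len(group_size, n),
    declination_deg = NA_real_,
    perpendicular_distance_m = distances_m,
    beaufort = rep_len(beaufort, n),
    observer = "left")
}

# minute stream builder: dry_seconds vector starting at a given time
make_wetdry <- function(dry_seconds, animal = "sealA",
                        start = as.POSIXct("2016-05-06 08:00:00",
                                           tz = "UTC")) {
  data.frame(animal_id = animal,
             timestamp = start + (seq_along(dry_seconds) - 1L) * 60,
             dry_seconds = dry_seconds)
}

# Independent brute-force loglik oracle for the detection model: evaluates
# the same density with its own g(x) code and stats::integrate only.
oracle_detection_loglik <- function(x, sigma, w, key = "half_normal",
                                    shape = NULL, adjustment = "none",
                                    acoef = numeric()) {
  g1 <- function(u, s) {
    k <- if (key == "half_normal") exp(-u^2 / (2 * s^2)) else
      1 - exp(-(pmax(u, 1e-12) / s)^(-shape))
    adj <- rep(1, length(u))
    if (adjustment == "cosine" && length(acoef))
      for (j in seq_along(acoef))
        adj <- adj + acoef[j] * cos((j + 1) * pi * u / w)
    k * adj
  }
  ll <- 0
  for (i in seq_along(x)) {
    s <- if (length(sigma) == 1L) sigma else sigma[i]
    g0 <- g1(0, s)
    mu <- integrate(function(u) g1(u, s) / g0, 0, w, rel.tol = 1e-12)$value
    ll <- ll + log(g1(x[i], s) / g0) - log(mu)
  }
  ll
}

# deterministic half-normal "fit" with known parameters, for tests that
# need a detection function without fitting one
make_hn_fit <- function(sigma, w) {
  spec <- det_spec("half_normal", "none", truncation_w_m = w)
  mu <- integrate(function(u) exp(-u^2 / (2 * sigma^2)), 0, w,
                  rel.tol = 1e-10)$value
  structure(list(spec = spec, par = log(sigma),
                 vcov = matrix(0, 1, 1),
                 sigma_by_class = sigma, shape = NA_real_,
                 acoef = numeric(), levels = "all",
                 f0_per_m = 1 / mu, se_f0 = 0, esw_m = mu,
                 loglik = NA_real_, aic = NA_real_, k = 1L, n_used = 0L),
            class = "detection_fit")
}

make_cf <- function(season = "spring", pr = 0.5, se = 0) {
  correction_factor(season, pr, se)
}

# simulated half-normal distances truncated at w
sim_hn_distances <- function(n, sigma, w, seed) {
  set.seed(seed)
  x <- abs(rnorm(ceiling(n * 1.6), 0, sigma))
  x <- x[x <= w]
  stopifnot(length(x) >= n)
  x[seq_len(n)]
}
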