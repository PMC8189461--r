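# GLMM modelling of haul-out and dive probabilities and the seasonal g(0)
# correction factors derived from them.
#
# Both responses are modelled on the logit scale with hour of day and week
# of year as fixed-effect factors shared across animals, plus random
# intercepts for animal and for the animal-by-week interaction:
#   haul-out: Bernoulli/binomial GLMM on the dry/wet indicator
#   dive:     Beta GLMM on the fraction of each hour spent in a dive state
# Predictions are made for an average untagged seal (random effects at 0),
# and the two processes are combined under the independence assumption
#   Pr(available) = (1 - Pr(haulout)) * (1 - Pr(dive)).

# availability model part: fixed effects + their covariance + metadata
new_availability_part <- function(beta, vcov, hour_levels, week_levels,
                                  response, re_sd = c(animal = NA_real_,
                                                      animal_week = NA_real_),
                                  phi = NA_real_, fit = NULL) {
  stopifnot(length(beta) == nrow(vcov), nrow(vcov) == ncol(vcov))
  structure(list(beta = beta, vcov = vcov,
                 hour_levels = as.integer(hour_levels),
                 week_levels = as.integer(week_levels),
                 response = response, re_sd = re_sd, phi = phi, fit = fit),
            class = "availability_part")
}

#' Construct an availability model part from explicit coefficients
#'
#' Mainly useful for tests and for degenerate/known-truth scenarios; the
#' coefficient layout is `(Intercept)`, then hour dummies (levels after the
#' first), then week dummies (levels after the first), all on the logit
#' scale.
#'
#' @param beta fixed-effect coefficients.
#' @param vcov fixed-effect covariance matrix (use a zero matrix for a point
#'   mass).
#' @param hour_levels,week_levels the factor levels the coefficients refer
#'   to, in order.
#' @param response `"haulout"` or `"dive"`.
#' @return an `availability_part`.
#' @export
availability_part <- function(beta, vcov, hour_levels, week_levels,
                              response = "haulout") {
  p_expected <- 1L + (length(hour_levels) - 1L) + (length(week_levels) - 1L)
  if (length(beta) != p_expected)
    sc_abort(sprintf(
      "beta must have %d coefficients for %d hour and %d week levels",
      p_expected, length(hour_levels), length(week_levels)),
      "sc_invalid_argument")
  new_availability_part(beta, vcov, hour_levels, week_levels, response)
}

sc_check_glmm_records <- function(rec, cols) {
  stopifnot(all(cols %in% names(rec)))
  if (length(unique(rec$animal)) < 2L || length(unique(rec$week)) < 2L ||
      length(unique(rec$hour)) < 2L)
    sc_abort("GLMM needs >= 2 animals, >= 2 weeks and >= 2 hours represented",
             "sc_insufficient_data")
}

sc_extract_part <- function(fit, rec, response, phi = NA_real_) {
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0)
    sc_abort(sprintf("%s GLMM did not converge", response), "sc_fit_failure")
  if (isFALSE(fit$sdr$pdHess))
    sc_abort(sprintf("%s GLMM Hessian not positive definite", response),
             "sc_fit_failure")
  vc <- glmmTMB::VarCorr(fit)$cond
  re_sd <- c(animal = tryCatch(attr(vc$animal, "stddev")[[1]],
                               error = function(e) NA_real_),
             animal_week = tryCatch(attr(vc$animal_week, "stddev")[[1]],
                                    error = function(e) NA_real_))
  new_availability_part(glmmTMB::fixef(fit)$cond,
                        as.matrix(vcov(fit)$cond),
                        sort(unique(rec$hour)), sort(unique(rec$week)),
                        response, re_sd, phi, fit)
}

#' Fit the haul-out GLMM
#'
#' Binomial (Bernoulli trials) GLMM with logit link on the aggregated
#' haul-out records from [bin_weeks_and_filter()]: fixed factors for hour of
#' day and week of year, random intercepts for animal and animal-by-week,
#' estimated by maximum likelihood with the Laplace approximation
#' (glmmTMB).
#'
#' @param records data frame `animal, week, hour, success, trials`.
#' @return an `availability_part` for the haul-out process.
#' @export
fit_haulout_glmm <- function(records) {
  sc_check_glmm_records(records, c("animal", "week", "hour", "success",
                                   "trials"))
  if (all(records$success == records$trials) || all(records$success == 0L))
    sc_abort("haul-out response is constant (all dry or all wet)",
             "sc_degenerate_data")
  d <- records
  d$hour_f <- factor(d$hour)
  d$week_f <- factor(d$week)
  d$animal_week <- interaction(d$animal, d$week, drop = TRUE)
  fit <- glmmTMB::glmmTMB(
    cbind(success, trials - success) ~ hour_f + week_f + (1 | animal) +
      (1 | animal_week),
    data = d, family = binomial())
  sc_extract_part(fit, d, "haulout")
}

#' Fit the dive-fraction GLMM
#'
#' Beta GLMM with logit link on the hourly dive fractions, same fixed and
#' random structure as the haul-out model.  Fractions are squeezed off the
#' boundary with the usual transform `y' = (y (n - 1) + 0.5) / n`, `n` being
#' the number of hourly observations in the fit.
#'
#' @param records data frame `animal, week, hour, fraction`.
#' @return an `availability_part` for the dive process (with precision
#'   `phi`).
#' @export
fit_dive_glmm <- function(records) {
  sc_check_glmm_records(records, c("animal", "week", "hour", "fraction"))
  if (var(records$fraction) < 1e-12)
    sc_abort("dive response is constant", "sc_degenerate_data")
  d <- records
  n <- nrow(d)
  d$y <- (d$fraction * (n - 1) + 0.5) / n
  d$hour_f <- factor(d$hour)
  d$week_f <- factor(d$week)
  d$animal_week <- interaction(d$animal, d$week, drop = TRUE)
  fit <- glmmTMB::glmmTMB(
    y ~ hour_f + week_f + (1 | animal) + (1 | animal_week),
    data = d, family = glmmTMB::beta_family())
  sc_extract_part(fit, d, "dive", phi = glmmTMB::sigma(fit))
}

#' Combine haul-out and dive parts into an availability model
#'
#' @param haulout,dive `availability_part`s from [fit_haulout_glmm()] /
#'   [fit_dive_glmm()] (or [availability_part()]).
#' @param animal_weeks optional data frame of the distinct (animal, week)
#'   pairs underlying the fits, as returned by [bin_weeks_and_filter()];
#'   used to report how many seal-weeks each seasonal correction factor is
#'   based on.
#' @return an `availability_model`.
#' @export
availability_model <- function(haulout, dive, animal_weeks = NULL) {
  stopifnot(inherits(haulout, "availability_part"),
            inherits(dive, "availability_part"))
  structure(list(haulout = haulout, dive = dive,
                 animal_weeks = animal_weeks),
            class = "availability_model")
}

# linear predictor design row(s) for (hour, week) under a part's levels;
# returns NULL when the cell lies outside the fitted levels.
sc_part_X <- function(part, hour, week) {
  if (!(hour %in% part$hour_levels) || !(week %in% part$week_levels))
    return(NULL)
  p <- length(part$beta)
  X <- numeric(p)
  X[1L] <- 1
  nh <- length(part$hour_levels)
  hi <- match(hour, part$hour_levels)
  if (hi > 1L) X[hi] <- 1  # columns 2..nh are hour dummies
  wi <- match(week, part$week_levels)
  if (wi > 1L) X[nh + wi - 1L] <- 1
  X
}

#' Predict availability over survey dates and hours
#'
#' For each (date, hour) cell within the fitted weeks, forms the fixed-effect
#' linear predictor with random effects at zero (an average untagged seal),
#' draws `n_draws` multivariate-normal samples of the fixed effects in link
#' space, inverse-logit transforms each, and combines the two processes per
#' draw as `avail = (1 - h) * (1 - d)` under the independence assumption.
#' Cells whose week lies outside the fitted weeks of either model are
#' returned as `NA` rather than extrapolated.
#'
#' @param model an [availability_model()].
#' @param dates `Date` vector of survey dates.
#' @param hours integer hours of day (default `9:17`, the 0900-1700 survey
#'   prediction window).
#' @param n_draws Monte-Carlo draws (default 10000).
#' @param seed required integer seed for the draws (recorded in the output).
#' @return an `availability_grid` data frame with one row per (date, hour)
#'   and columns `pr_haulout`, `pr_dive`, `pr_available` (means) plus
#'   `*_lo` / `*_hi` 95% bounds; per-(week, hour) availability draws are
#'   attached for downstream seasonal summaries.
#' @export
predict_availability <- function(model, dates, hours = 9:17,
                                 n_draws = 10000L, seed) {
  stopifnot(inherits(model, "availability_model"))
  if (missing(seed)) sc_abort("`seed` is required for the Monte-Carlo draws",
                              "sc_invalid_argument")
  set.seed(seed)
  dates <- as.Date(dates)
  cells <- expand.grid(date = unique(dates), hour = as.integer(hours),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$date, cells$hour), , drop = FALSE]
  cells$week <- week_of_year(cells$date)

  draw_beta <- function(part) {
    if (all(part$vcov == 0))
      matrix(part$beta, nrow = n_draws, ncol = length(part$beta),
             byrow = TRUE)
    else
      MASS::mvrnorm(n_draws, part$beta, part$vcov)
  }
  bh <- draw_beta(model$haulout)
  bd <- draw_beta(model$dive)

  wh <- unique(cells[c("week", "hour")])
  rownames(wh) <- NULL
  avail_draws <- matrix(NA_real_, nrow(wh), n_draws)
  summ <- matrix(NA_real_, nrow(wh), 9L,
                 dimnames = list(NULL, c("pr_haulout", "pr_haulout_lo",
                                         "pr_haulout_hi", "pr_dive",
                                         "pr_dive_lo", "pr_dive_hi",
                                         "pr_available", "pr_available_lo",
                                         "pr_available_hi")))
  for (i in seq_len(nrow(wh))) {
    Xh <- sc_part_X(model$haulout, wh$hour[i], wh$week[i])
    Xd <- sc_part_X(model$dive, wh$hour[i], wh$week[i])
    if (is.null(Xh) || is.null(Xd)) next  # outside fitted weeks: unavailable
    h <- plogis(drop(bh %*% Xh))
    d <- plogis(drop(bd %*% Xd))
    a <- (1 - h) * (1 - d)
    avail_draws[i, ] <- a
    q <- function(v) quantile(v, c(0.025, 0.975), names = FALSE)
    summ[i, ] <- c(mean(h), q(h), mean(d), q(d), mean(a), q(a))
  }
  key <- paste(cells$week, cells$hour)
  idx <- match(key, paste(wh$week, wh$hour))
  grid <- cbind(cells, as.data.frame(summ[idx, , drop = FALSE]))
  rownames(grid) <- NULL
  structure(grid, class = c("availability_grid", "data.frame"),
            wh = wh, avail_draws = avail_draws, seed = seed,
            n_draws = n_draws, animal_weeks = model$animal_weeks)
}

#' Construct a correction factor directly
#'
#' @param season season label (`"spring"`, `"summer"` or `"autumn"`).
#' @param pr_available seasonal mean availability in `(0, 1]`.
#' @param se its standard error.
#' @param n_seal_periods animal-week count behind the estimate.
#' @return a `correction_factor` with `factor = 1 / pr_available`.
#' @export
correction_factor <- function(season, pr_available, se = 0,
                              n_seal_periods = NA_integer_) {
  if (identical(season, "winter"))
    sc_abort("no winter correction factor can be formed (no winter tag data)",
             "sc_no_winter_correction")
  sc_stopifnot_scalar_number(pr_available, "pr_available", 1e-12, 1)
  sc_stopifnot_scalar_number(se, "se", 0)
  structure(list(season = season, pr_available = pr_available, se = se,
                 factor = 1 / pr_available,
                 n_seal_periods = n_seal_periods),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("%s: Pr(available) = %.3f (SE %.4f), correction factor = %.2f\n",
              x$season, x$pr_available, x$se, x$factor))
  invisible(x)
}

#' Seasonal availability correction factor from a predicted grid
#'
#' The seasonal availability is the unweighted mean of the cell means over
#' the season's (date, hour) cells; the correction factor is its
#' reciprocal.  The standard error is propagated through the Monte-Carlo
#' draws of the seasonal mean itself.
#'
#' @param grid an `availability_grid` from [predict_availability()].
#' @param season `"spring"`, `"summer"` or `"autumn"`; winter raises an
#'   error because no winter tag data exist to support a factor.
#' @return a `correction_factor`.
#' @export
seasonal_correction <- function(grid, season) {
  stopifnot(inherits(grid, "availability_grid"))
  if (identical(season, "winter"))
    sc_abort("no winter correction factor can be formed (no winter tag data)",
             "sc_no_winter_correction")
  in_season <- assign_season(grid$date) == season & !is.na(grid$pr_available)
  if (!any(in_season))
    sc_abort(sprintf("no availability cells in season `%s`", season),
             "sc_invalid_argument")
  cells <- grid[in_season, , drop = FALSE]
  pr <- mean(cells$pr_available)
  wh <- attr(grid, "wh")
  draws <- attr(grid, "avail_draws")
  idx <- match(paste(cells$week, cells$hour), paste(wh$week, wh$hour))
  counts <- tabulate(idx, nbins = nrow(wh))
  use <- which(counts > 0)
  # per-draw seasonal mean over the season's cells (weights = cell counts)
  seasonal_draws <- drop((counts[use] / sum(counts)) %*%
                           draws[use, , drop = FALSE])
  se <- sd(seasonal_draws)
  aw <- attr(grid, "animal_weeks")
  nsp <- if (is.null(aw)) NA_integer_ else {
    yr <- as.integer(format(cells$date[1L], "%Y"))
    sum(vapply(aw$week, season_of_week, character(1), year = yr) == season)
  }
  correction_factor(season, pr, se, nsp)
}

#' Write correction factors as CSV
#'
#' One row per season: `season, n_seal_periods, pr_available,
#' pr_available_se, factor`.
#'
#' @param path output path.
#' @param factors list of `correction_factor`s.
#' @export
write_correction_factors <- function(path, factors) {
  rows <- lapply(factors, function(f)
    data.frame(season = f$season, n_seal_periods = f$n_seal_periods,
               pr_available = f$pr_available, pr_available_se = f$se,
               factor = f$factor))
  write_estimates(path, do.call(rbind, rows))
}
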