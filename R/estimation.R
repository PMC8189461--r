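# Density/abundance estimation and aggregation to stocks.
#
# The core estimators are the standard line-transect plug-ins
#   D = n f(0) E(s) / (2 L g0),    N = D A,
# with the squared CV assembled from the component squared CVs of n, f(0),
# E(s) and (for corrected estimates) g0, and 95% confidence intervals from
# the lognormal method.

#' Define a survey stratum
#'
#' @param name one of `SouthernPugetSound`, `HoodCanal`,
#'   `NorthernPugetSound`, `SanJuans_StraitJDF` (or any label for synthetic
#'   work).
#' @param area_km2 stratum area in square kilometers.
#' @param stock management stock the stratum belongs to; defaults to the
#'   standard mapping, under which the two northern survey strata pool into
#'   the Washington Northern Inland Waters stock.
#' @return a `stratum` object.
#' @export
stratum <- function(name, area_km2, stock = NULL) {
  sc_stopifnot_scalar_number(area_km2, "area_km2", lower = 1e-12)
  if (is.null(stock))
    stock <- if (name %in% names(SC_STOCK_OF_STRATUM))
      SC_STOCK_OF_STRATUM[[name]] else name
  structure(list(name = name, area_km2 = as.numeric(area_km2),
                 stock = stock), class = "stratum")
}

#' Encounter-rate variance by the O2 successive-difference estimator
#'
#' Implements the overlapping post-stratification ("O2") estimator of
#' Fewster et al. (2009, Biometrics 65:225-236) for systematic transect
#' designs: adjacent lines in their geographic order form overlapping pairs,
#' and the variance is assembled from length-weighted squared deviations of
#' the per-line encounter rates about each pair's pooled rate,
#'
#'   var(n) = k/(k-1) * sum over pairs of
#'            (l1^2 (r1 - rbar)^2 + l2^2 (r2 - rbar)^2),
#'
#' where `r = n / l` per line and `rbar` is the pair's pooled rate
#' `(n1 + n2) / (l1 + l2)`.
#' This is unbiased for independent Poisson counts and tracks local trends
#' through the successive-difference structure.  With a single line it falls
#' back to the Poisson variance `var(n) = n` with a warning.
#'
#' @param per_line data frame with columns `line_id`, `n_i`, `l_i`, rows in
#'   geographic order.
#' @param design variance design; only `"O2"` is implemented.
#' @return estimated variance of the total count `n`.
#' @export
encounter_rate_variance <- function(per_line, design = "O2") {
  if (!identical(design, "O2"))
    sc_abort("only the O2 variance design is implemented", "sc_invalid_argument")
  stopifnot(all(c("n_i", "l_i") %in% names(per_line)))
  k <- nrow(per_line)
  if (any(per_line$l_i <= 0))
    sc_abort("line lengths must be > 0", "sc_invalid_argument")
  if (k < 2L) {
    sc_warn("O2 variance needs >= 2 lines; falling back to Poisson var(n) = n")
    return(sum(per_line$n_i))
  }
  n_i <- per_line$n_i
  l_i <- per_line$l_i
  r <- n_i / l_i
  j <- 2:k
  rbar <- (n_i[j - 1] + n_i[j]) / (l_i[j - 1] + l_i[j])
  terms <- l_i[j - 1]^2 * (r[j - 1] - rbar)^2 + l_i[j]^2 * (r[j] - rbar)^2
  k / (k - 1) * sum(terms)
}

#' Build an encounter-rate summary for one stratum-season
#'
#' @param per_line data frame with `line_id`, `n_i`, `l_i` in geographic
#'   order (the order of the effort file).
#' @param design passed to [encounter_rate_variance()].
#' @return an `encounter_rate` object with `n`, `L_km`, `var_n`, `per_line`.
#' @export
encounter_rate <- function(per_line, design = "O2") {
  structure(list(n = sum(per_line$n_i), L_km = sum(per_line$l_i),
                 var_n = encounter_rate_variance(per_line, design),
                 per_line = per_line),
            class = "encounter_rate")
}

#' Lognormal confidence interval for an abundance estimate
#'
#' `C = exp(z * sqrt(log(1 + cv^2)))`; the interval is `(N / C, N * C)`,
#' multiplicatively symmetric about `N`.
#'
#' @param N point estimate (> 0).
#' @param cv coefficient of variation as a proportion (>= 0).
#' @param z normal quantile (default 1.96 for a 95% interval).
#' @return numeric vector `c(lo, hi)`.
#' @export
lognormal_ci <- function(N, cv, z = 1.96) {
  sc_stopifnot_scalar_number(N, "N", lower = 1e-300)
  sc_stopifnot_scalar_number(cv, "cv", lower = 0)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(lo = N / C, hi = N * C)
}

# internal constructor for a stratum-season estimate
new_sse <- function(stratum_name, stock, season, area_km2, n, L_km,
                    density, abundance, cv, corrected, g0 = NULL) {
  ci <- if (is.finite(cv) && abundance > 0) lognormal_ci(abundance, cv) else
    c(lo = NA_real_, hi = NA_real_)
  structure(list(stratum = stratum_name, stock = stock, season = season,
                 area_km2 = area_km2, n = n, L_km = L_km,
                 density_per_km2 = density, abundance = abundance,
                 cv = cv, ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
                 corrected = corrected, g0 = g0),
            class = "stratum_season_estimate")
}

#' Construct a stratum-season estimate from known quantities
#'
#' Builds the estimate object directly from an abundance, CV and (optional)
#' interval — for example when aggregating previously published per-season
#' numbers with [year_round_average()] or [pool_strata()] rather than
#' re-estimating from raw survey data.  If the interval is omitted it is
#' recomputed lognormally from `abundance` and `cv`.
#'
#' @param stratum_name,season labels.
#' @param abundance point estimate.
#' @param cv coefficient of variation (proportion).
#' @param ci_lo,ci_hi optional 95% bounds.
#' @param area_km2 stratum area (default 1; only ratios matter for
#'   aggregation of abundances).
#' @param corrected is this an availability-corrected estimate?
#' @param stock stock label (defaults to the standard stratum-stock map).
#' @return a `stratum_season_estimate`.
#' @export
stratum_season_estimate <- function(stratum_name, season, abundance, cv,
                                    ci_lo = NULL, ci_hi = NULL,
                                    area_km2 = 1, corrected = FALSE,
                                    stock = NULL) {
  if (is.null(stock))
    stock <- if (stratum_name %in% names(SC_STOCK_OF_STRATUM))
      SC_STOCK_OF_STRATUM[[stratum_name]] else stratum_name
  out <- new_sse(stratum_name, stock, season, area_km2,
                 NA_integer_, NA_real_, abundance / area_km2, abundance,
                 cv, corrected, NULL)
  if (!is.null(ci_lo)) out$ci_lo <- ci_lo
  if (!is.null(ci_hi)) out$ci_hi <- ci_hi
  out
}

#' @export
print.stratum_season_estimate <- function(x, ...) {
  cat(sprintf("%s %s [%s]: D = %.3f /km2, N = %.0f (95%% CI %.0f-%.0f), CV = %.2f%%\n",
              x$stratum, x$season,
              if (x$corrected) "corrected" else "uncorrected",
              x$density_per_km2, x$abundance, x$ci_lo, x$ci_hi, 100 * x$cv))
  invisible(x)
}

#' Estimate density and abundance for one stratum-season
#'
#' Plugs the encounter rate, detection fit, expected group size and
#' (optionally) an availability correction factor into the line-transect
#' estimators.  `f(0)` is converted from per-meter to per-kilometer
#' internally so that effort in kilometers and area in square kilometers
#' yield density per square kilometer.
#'
#' @param er an [encounter_rate()].
#' @param fit a `detection_fit` (its `f0_per_m` and `se_f0` are used).
#' @param gs a group-size estimate from [expected_group_size()].
#' @param stratum a [stratum()].
#' @param g0 a `correction_factor` from [seasonal_correction()], or `NULL`
#'   for an uncorrected (in-water) estimate.
#' @param season season label attached to the estimate.
#' @return a `stratum_season_estimate`.
#' @export
estimate_density_abundance <- function(er, fit, gs, stratum, g0 = NULL,
                                       season = "all") {
  stopifnot(inherits(er, "encounter_rate"), inherits(stratum, "stratum"))
  if (er$var_n < 0)
    sc_abort("negative encounter-rate variance", "sc_invalid_argument")
  f0_km <- fit$f0_per_m * 1000
  se_f0_km <- fit$se_f0 * 1000
  g0p <- if (is.null(g0)) 1 else g0$pr_available
  if (er$n == 0) {
    out <- new_sse(stratum$name, stratum$stock, season, stratum$area_km2,
                   0L, er$L_km, 0, 0, NA_real_, !is.null(g0), g0)
    sc_warn("zero sightings: density 0 with undefined CV")
    return(out)
  }
  D <- er$n * f0_km * gs$e_s / (2 * er$L_km * g0p)
  N <- D * stratum$area_km2
  cv2 <- er$var_n / er$n^2 + (se_f0_km / f0_km)^2 + (gs$se_e_s / gs$e_s)^2
  if (!is.null(g0)) cv2 <- cv2 + (g0$se / g0$pr_available)^2
  new_sse(stratum$name, stratum$stock, season, stratum$area_km2,
          er$n, er$L_km, D, N, sqrt(cv2), !is.null(g0), g0)
}

#' Apply an availability correction factor to an uncorrected estimate
#'
#' Divides density and abundance by the seasonal availability (equivalently,
#' multiplies by the correction factor), recombines the CV with the
#' availability CV in quadrature, and recomputes the lognormal interval.
#'
#' @param unc an uncorrected `stratum_season_estimate`.
#' @param g0 a `correction_factor` for the matching season.
#' @return a corrected `stratum_season_estimate`.
#' @export
apply_correction <- function(unc, g0) {
  stopifnot(inherits(unc, "stratum_season_estimate"),
            inherits(g0, "correction_factor"))
  if (unc$corrected)
    sc_abort("estimate is already corrected", "sc_invalid_argument")
  if (identical(unc$season, "winter"))
    sc_abort("no winter correction factor exists; winter estimates stay uncorrected",
             "sc_no_winter_correction")
  if (!identical(g0$season, unc$season) && !identical(unc$season, "all"))
    sc_abort(sprintf("correction factor season (%s) does not match estimate (%s)",
                     g0$season, unc$season), "sc_invalid_argument")
  cv <- sqrt(unc$cv^2 + (g0$se / g0$pr_available)^2)
  new_sse(unc$stratum, unc$stock, unc$season, unc$area_km2, unc$n, unc$L_km,
          unc$density_per_km2 * g0$factor, unc$abundance * g0$factor,
          cv, TRUE, g0)
}

#' Pool stratum estimates for the same season
#'
#' Abundances and areas add; density is the pooled `N / A`; the variance
#' combines under independence (`var = sum var_i`), so the pooled CV is
#' `sqrt(sum (cv_i N_i)^2) / sum N_i`; the interval is lognormal.
#'
#' @param parts list of `stratum_season_estimate`s, same season and
#'   correction status, disjoint strata.
#' @param name label for the pooled stratum (default joins the part names).
#' @return a pooled `stratum_season_estimate`.
#' @export
pool_strata <- function(parts, name = NULL) {
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "stratum_season_estimate")))
  seasons <- unique(vapply(parts, `[[`, character(1), "season"))
  if (length(seasons) != 1L)
    sc_abort("pool_strata requires a single season", "sc_invalid_argument")
  corr <- unique(vapply(parts, `[[`, logical(1), "corrected"))
  if (length(corr) != 1L)
    sc_abort("cannot pool corrected with uncorrected estimates",
             "sc_invalid_argument")
  N <- sum(vapply(parts, `[[`, numeric(1), "abundance"))
  A <- sum(vapply(parts, `[[`, numeric(1), "area_km2"))
  v <- sum(vapply(parts, function(p)
    if (is.finite(p$cv)) (p$cv * p$abundance)^2 else 0, numeric(1)))
  cv <- if (N > 0) sqrt(v) / N else NA_real_
  stocks <- unique(vapply(parts, `[[`, character(1), "stock"))
  if (is.null(name))
    name <- paste(vapply(parts, `[[`, character(1), "stratum"),
                  collapse = "+")
  new_sse(name, if (length(stocks) == 1L) stocks else "pooled", seasons, A,
          sum(vapply(parts, `[[`, numeric(1), "n")),
          sum(vapply(parts, `[[`, numeric(1), "L_km")),
          if (A > 0) N / A else NA_real_, N, cv, corr,
          if (corr) parts[[1L]]$g0 else NULL)
}

#' Year-round average of seasonal estimates
#'
#' The year-round row is an averaging convention, not a variance law:
#' abundance, density, CV and both interval bounds are each the arithmetic
#' mean of the corresponding seasonal values.
#'
#' @param seasonals list of `stratum_season_estimate`s for one stratum.
#' @return a `stratum_season_estimate` with `season = "year_round"`.
#' @export
year_round_average <- function(seasonals) {
  if (length(seasonals) == 0L)
    sc_abort("no seasonal estimates to average", "sc_invalid_argument")
  stopifnot(all(vapply(seasonals, inherits, logical(1),
                       "stratum_season_estimate")))
  get <- function(f) vapply(seasonals, `[[`, numeric(1), f)
  corr <- unique(vapply(seasonals, `[[`, logical(1), "corrected"))
  if (length(corr) != 1L)
    sc_abort("cannot average corrected with uncorrected estimates",
             "sc_invalid_argument")
  out <- new_sse(seasonals[[1L]]$stratum, seasonals[[1L]]$stock, "year_round",
                 seasonals[[1L]]$area_km2, sum(get("n")), mean(get("L_km")),
                 mean(get("density_per_km2")), mean(get("abundance")),
                 mean(get("cv")), corr, NULL)
  # interval bounds are means of the seasonal bounds, by convention
  out$ci_lo <- mean(get("ci_lo"))
  out$ci_hi <- mean(get("ci_hi"))
  out
}

#' Flatten stratum-season estimates into a report table
#'
#' @param estimates list of `stratum_season_estimate`s.
#' @param round_report round abundances to integers and densities/CVs to two
#'   decimals (report convention)?  Defaults to `FALSE` (full precision).
#' @return a data frame with one row per estimate.
#' @export
estimates_table <- function(estimates, round_report = FALSE) {
  rows <- lapply(estimates, function(e) {
    data.frame(stratum = e$stratum, stock = e$stock, season = e$season,
               corrected = e$corrected, n = e$n, L_km = e$L_km,
               area_km2 = e$area_km2, density_per_km2 = e$density_per_km2,
               abundance = e$abundance, ci_lo = e$ci_lo, ci_hi = e$ci_hi,
               cv_pct = 100 * e$cv)
  })
  out <- do.call(rbind, rows)
  if (round_report) {
    out$abundance <- round(out$abundance)
    out$ci_lo <- round(out$ci_lo)
    out$ci_hi <- round(out$ci_hi)
    out$density_per_km2 <- round(out$density_per_km2, 2)
    out$cv_pct <- round(out$cv_pct, 2)
  }
  out
}

#' Per-line counts for one stratum-season from filtered data
#'
#' Tallies sightings per effort line (lines in effort-file order, the
#' documented geographic ordering contract for the O2 variance).
#'
#' @param effort filtered effort data frame.
#' @param sightings filtered sightings data frame.
#' @return data frame `line_id`, `n_i`, `l_i` in effort-file order.
#' @export
per_line_counts <- function(effort, sightings) {
  line_of_segment <- setNames(effort$line_id, effort$segment_id)
  lines <- unique(effort$line_id)
  l_i <- vapply(lines, function(li)
    sum(effort$length_km[effort$line_id == li]), numeric(1))
  sgt_line <- line_of_segment[sightings$segment_id]
  n_i <- vapply(lines, function(li) sum(sgt_line == li, na.rm = TRUE),
                numeric(1))
  data.frame(line_id = lines, n_i = as.numeric(n_i), l_i = as.numeric(l_i))
}
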