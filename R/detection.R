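# Detection-function fitting for line-transect distance sampling.
#
# The detection model is g(x) = key(x) * series(x), renormalized so that
# g(0) = 1, with the scale parameter of the key modelled on the log scale as
# a linear function of covariates (here Beaufort sea state as a factor):
#   sigma_i = exp(beta0 + sum_c beta_c z_ic).
# Keys: half-normal  g(x) = exp(-x^2 / (2 sigma^2))
#       hazard-rate  g(x) = 1 - exp(-(x / sigma)^-b),  b > 1.
# Series adjustments (orders follow the conventional pairings):
#   cosine       terms cos(j pi x / w),        j = 2, 3, ...
#   hermite      terms H4(x/sigma), H6(x/sigma)   (half-normal only)
#   simple_poly  terms (x/w)^4, (x/w)^6           (hazard-rate only)
# The perpendicular-distance likelihood conditions on detection:
#   f_i(x) = g_i(x) / mu_i,  mu_i = integral of g_i over [0, w].

#' Specify a detection-function model
#'
#' @param key `"half_normal"` or `"hazard_rate"`.
#' @param adjustment `"none"`, `"cosine"`, `"hermite"` (half-normal only) or
#'   `"simple_poly"` (hazard-rate only).
#' @param n_adjust_terms number of adjustment terms (0 forces
#'   `adjustment = "none"` semantics).
#' @param covariates character vector of covariate names entering the scale
#'   parameter; currently only `"beaufort"` is supported.
#' @param truncation_w_m right-truncation distance in meters.
#' @return a `det_spec` object.
#' @export
det_spec <- function(key = c("half_normal", "hazard_rate"),
                     adjustment = c("none", "cosine", "hermite", "simple_poly"),
                     n_adjust_terms = 0L,
                     covariates = character(),
                     truncation_w_m) {
  key <- match.arg(key)
  adjustment <- match.arg(adjustment)
  if (adjustment == "hermite" && key != "half_normal")
    sc_abort("hermite adjustments pair only with the half-normal key",
             "sc_invalid_spec")
  if (adjustment == "simple_poly" && key != "hazard_rate")
    sc_abort("simple polynomial adjustments pair only with the hazard-rate key",
             "sc_invalid_spec")
  n_adjust_terms <- as.integer(n_adjust_terms)
  if (n_adjust_terms < 0L)
    sc_abort("n_adjust_terms must be >= 0", "sc_invalid_spec")
  if (adjustment == "none") n_adjust_terms <- 0L
  if (adjustment != "none" && n_adjust_terms == 0L) adjustment <- "none"
  if (!all(covariates %in% "beaufort"))
    sc_abort("only `beaufort` is supported as a detection covariate",
             "sc_invalid_spec")
  sc_stopifnot_scalar_number(truncation_w_m, "truncation_w_m", lower = 1e-9)
  structure(list(key = key, adjustment = adjustment,
                 n_adjust_terms = n_adjust_terms,
                 covariates = covariates,
                 truncation_w_m = as.numeric(truncation_w_m)),
            class = "det_spec")
}

# Hermite polynomials (probabilists') of order 4 and 6.
sc_hermite <- function(z, order) {
  switch(as.character(order),
         "4" = z^4 - 6 * z^2 + 3,
         "6" = z^6 - 15 * z^4 + 45 * z^2 - 15,
         stop("unsupported hermite order"))
}

# Series adjustment multiplier (before g(0) renormalization).
sc_series <- function(x, w, sigma, adjustment, acoef) {
  if (adjustment == "none" || length(acoef) == 0L) return(rep(1, length(x)))
  s <- rep(1, length(x))
  for (j in seq_along(acoef)) {
    term <- switch(adjustment,
      cosine = cos((j + 1) * pi * x / w),
      hermite = sc_hermite(x / sigma, 2L * (j + 1L)),
      simple_poly = (x / w)^(2L * (j + 1L)))
    s <- s + acoef[j] * term
  }
  s
}

# Unnormalized key * series; sigma may be scalar, x a vector.
sc_g_raw <- function(x, sigma, shape, spec, acoef) {
  key <- switch(spec$key,
    half_normal = exp(-x^2 / (2 * sigma^2)),
    hazard_rate = 1 - exp(-(pmax(x, 1e-12) / sigma)^(-shape)))
  key * sc_series(x, spec$truncation_w_m, sigma, spec$adjustment, acoef)
}

# Detection probability g(x) with g(0) = 1 for one covariate class.
sc_g <- function(x, sigma, shape, spec, acoef) {
  g0 <- sc_g_raw(0, sigma, shape, spec, acoef)
  sc_g_raw(x, sigma, shape, spec, acoef) / g0
}

# Effective strip width integral mu = int_0^w g(x) dx for one class.
sc_mu <- function(sigma, shape, spec, acoef) {
  val <- tryCatch(
    integrate(function(x) sc_g(x, sigma, shape, spec, acoef),
              lower = 0, upper = spec$truncation_w_m,
              rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L)$value,
    error = function(e) NA_real_)
  val
}

# Unpack the parameter vector given the model structure.
sc_unpack <- function(par, struct) {
  beta <- par[seq_len(struct$n_beta)]
  shape <- if (struct$has_shape) 1 + exp(par[struct$n_beta + 1L]) else NA_real_
  acoef <- if (struct$n_adj > 0L)
    par[(struct$n_beta + struct$has_shape) + seq_len(struct$n_adj)] else numeric()
  sigma_by_class <- exp(drop(struct$Xclass %*% beta))
  list(beta = beta, shape = shape, acoef = acoef,
       sigma_by_class = sigma_by_class)
}

# Negative conditional log-likelihood of the perpendicular distances.
sc_detection_nll <- function(par, struct, spec, x, class_idx) {
  p <- sc_unpack(par, struct)
  if (struct$has_shape && (p$shape <= 1 || p$shape > 50)) return(1e10)
  mu <- vapply(p$sigma_by_class, sc_mu, numeric(1),
               shape = p$shape, spec = spec, acoef = p$acoef)
  if (any(!is.finite(mu)) || any(mu <= 0)) return(1e10)
  gx <- sc_g(x, p$sigma_by_class[class_idx], p$shape, spec, p$acoef)
  if (any(!is.finite(gx)) || any(gx <= 1e-300)) return(1e10)
  nll <- -(sum(log(gx)) - sum(log(mu[class_idx])))
  if (!is.finite(nll)) return(1e10)
  nll
}

# f(0) = mean over sightings of 1 / mu_i (per meter), the covariate-model
# analogue of 1/ESW.
sc_f0_from_par <- function(par, struct, spec, class_idx) {
  p <- sc_unpack(par, struct)
  mu <- vapply(p$sigma_by_class, sc_mu, numeric(1),
               shape = p$shape, spec = spec, acoef = p$acoef)
  mean(1 / mu[class_idx])
}

#' Fit a detection function to perpendicular distances
#'
#' Maximizes the conditional likelihood of the observed perpendicular
#' distances under the model given by `spec` (see [det_spec()]).  With
#' covariates, the scale parameter varies by sighting through a log-linear
#' model with the first observed covariate level as reference; with none,
#' this reduces exactly to conventional distance sampling.  Optimization is
#' quasi-Newton (BFGS) from three documented starting points on the log
#' scale; the parameter covariance comes from the inverse observed
#' information and `se_f0` by the delta method.  Adjustment fits whose
#' detection function is non-monotone or negative anywhere on a 1,000-point
#' grid are rejected.
#'
#' @param distances_m perpendicular distances in meters, all within
#'   `[0, spec$truncation_w_m]`.
#' @param covariate_values vector of Beaufort values aligned with
#'   `distances_m` (required when `spec$covariates` is non-empty).
#' @param spec a [det_spec()].
#' @return a `detection_fit` object with elements `spec`, `par`, `vcov`,
#'   `f0_per_m`, `se_f0`, `esw_m`, `loglik`, `aic`, `n_used`, `levels`.
#' @export
fit_detection_function <- function(distances_m, covariate_values = NULL,
                                   spec) {
  stopifnot(inherits(spec, "det_spec"))
  x <- as.numeric(distances_m)
  w <- spec$truncation_w_m
  if (any(is.na(x)) || any(x < 0) || any(x > w))
    sc_abort("distances must lie in [0, truncation_w_m]", "sc_invalid_argument")
  has_cov <- length(spec$covariates) > 0L
  if (has_cov) {
    if (is.null(covariate_values) || length(covariate_values) != length(x))
      sc_abort("covariate_values must align with distances_m",
               "sc_invalid_argument")
    fac <- factor(covariate_values)
  } else {
    fac <- factor(rep("all", length(x)))
  }
  levels_used <- levels(fac)
  n_class <- nlevels(fac)
  class_idx <- as.integer(fac)
  # design matrix mapping class -> log sigma (treatment contrasts)
  Xclass <- matrix(0, n_class, n_class)
  Xclass[, 1L] <- 1
  if (n_class > 1L) Xclass[cbind(2:n_class, 2:n_class)] <- 1
  colnames(Xclass) <- c("(Intercept)",
                        if (n_class > 1L) paste0("beaufort", levels_used[-1]))
  struct <- list(n_beta = ncol(Xclass),
                 has_shape = spec$key == "hazard_rate",
                 n_adj = spec$n_adjust_terms,
                 Xclass = Xclass)
  k <- struct$n_beta + struct$has_shape + struct$n_adj
  n <- length(x)
  if (n < 2L * k)
    sc_abort(sprintf("insufficient data: %d observations for %d parameters",
                     n, k), "sc_insufficient_data")

  s0 <- log(max(sqrt(mean(x^2)), w / 50))
  starts <- lapply(c(0, -0.7, 0.7), function(d) {
    c(s0 + d, rep(0, struct$n_beta - 1L),
      if (struct$has_shape) 0,  # shape b = 2
      rep(0, struct$n_adj))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, sc_detection_nll, struct = struct, spec = spec, x = x,
            class_idx = class_idx, method = "BFGS",
            control = list(maxit = 500L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best))
    sc_abort(sprintf("detection fit failed to converge (%s, %s, %d terms)",
                     spec$key, spec$adjustment, spec$n_adjust_terms),
             "sc_fit_failure")

  p <- sc_unpack(best$par, struct)
  # monotonicity / positivity screen on a fine grid, per covariate class
  grid <- seq(0, w, length.out = 1000L)
  for (ci in seq_len(n_class)) {
    gg <- sc_g(grid, p$sigma_by_class[ci], p$shape, spec, p$acoef)
    if (any(gg < -1e-9) || any(diff(gg) > 1e-7))
      sc_abort(sprintf(
        "detection fit rejected: non-monotone or negative g(x) (%s, %s, %d terms)",
        spec$key, spec$adjustment, spec$n_adjust_terms),
        "sc_fit_rejected")
  }

  H <- tryCatch(optimHess(best$par, sc_detection_nll, struct = struct,
                          spec = spec, x = x, class_idx = class_idx),
                error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k)) else
      matrix(NA_real_, k, k)

  f0 <- sc_f0_from_par(best$par, struct, spec, class_idx)
  # delta-method SE of f(0): numerical gradient wrt the parameters
  gr <- vapply(seq_len(k), function(j) {
    h <- max(1e-5, abs(best$par[j]) * 1e-5)
    pp <- best$par; pm <- best$par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (sc_f0_from_par(pp, struct, spec, class_idx) -
       sc_f0_from_par(pm, struct, spec, class_idx)) / (2 * h)
  }, numeric(1))
  var_f0 <- if (all(is.finite(V))) drop(t(gr) %*% V %*% gr) else NA_real_
  se_f0 <- if (is.finite(var_f0) && var_f0 >= 0) sqrt(var_f0) else NA_real_

  loglik <- -best$value
  structure(list(spec = spec, par = best$par, vcov = V,
                 sigma_by_class = p$sigma_by_class, shape = p$shape,
                 acoef = p$acoef, levels = levels_used,
                 f0_per_m = f0, se_f0 = se_f0, esw_m = 1 / f0,
                 loglik = loglik, aic = 2 * k - 2 * loglik,
                 k = k, n_used = n),
            class = "detection_fit")
}

#' Evaluate a fitted detection function
#'
#' @param fit a `detection_fit`.
#' @param x distances in meters.
#' @param covariate_value a single covariate (Beaufort) level; `NULL` for
#'   fits without covariates.
#' @return detection probabilities `g(x)` in `(0, 1]`.
#' @export
detection_g <- function(fit, x, covariate_value = NULL) {
  stopifnot(inherits(fit, "detection_fit"))
  lev <- if (is.null(covariate_value)) 1L else
    match(as.character(covariate_value), fit$levels)
  if (is.na(lev))
    sc_abort("covariate level not present in the fit", "sc_invalid_argument")
  sc_g(x, fit$sigma_by_class[lev], fit$shape, fit$spec, fit$acoef)
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection function: %s key, %s adjustment (%d term(s))\n",
              x$spec$key, x$spec$adjustment, x$spec$n_adjust_terms))
  cat(sprintf("  n = %d, w = %.0f m, loglik = %.3f, AIC = %.3f\n",
              x$n_used, x$spec$truncation_w_m, x$loglik, x$aic))
  cat(sprintf("  f(0) = %.6g /m (SE %.3g), ESW = %.1f m\n",
              x$f0_per_m, x$se_f0, x$esw_m))
  invisible(x)
}

#' Select a detection fit by AIC
#'
#' Lowest AIC wins; exact ties are broken by fewer parameters, then by key
#' order half-normal before hazard-rate.
#'
#' @param fits a list of `detection_fit` objects fitted to the same data and
#'   truncation.
#' @return the selected `detection_fit`.
#' @export
select_model <- function(fits) {
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    sc_abort("no candidate detection fits to select from", "sc_invalid_argument")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  keyrank <- vapply(fits, function(f)
    match(f$spec$key, c("half_normal", "hazard_rate")), numeric(1))
  fits[[order(aic, k, keyrank)[1L]]]
}

#' Choose a right-truncation distance
#'
#' `"quantile_95"` returns the 95th percentile of the observed distances
#' (type-7 linear interpolation).  `"g_at_w_0.15"` fits a pilot half-normal
#' detection function without adjustments and returns the distance at which
#' its detection probability falls to 0.15, i.e. `sigma * sqrt(-2 log 0.15)`.
#'
#' @param distances_m perpendicular distances in meters.
#' @param strategy `"quantile_95"` (default) or `"g_at_w_0.15"`.
#' @return truncation distance in meters.
#' @export
choose_truncation <- function(distances_m, strategy = "quantile_95") {
  x <- as.numeric(distances_m)
  if (length(x) == 0L)
    sc_abort("no distances supplied", "sc_invalid_argument")
  if (strategy == "quantile_95") {
    unname(quantile(x, 0.95, type = 7))
  } else if (strategy == "g_at_w_0.15") {
    pilot <- fit_detection_function(
      x, spec = det_spec("half_normal", "none",
                         truncation_w_m = max(x) * 1.001))
    unname(pilot$sigma_by_class[1L] * sqrt(-2 * log(0.15)))
  } else {
    sc_abort(sprintf("unknown truncation strategy `%s`", strategy),
             "sc_invalid_argument")
  }
}

#' Fit the standard menu of detection models and select by AIC
#'
#' The menu pairs the half-normal key with cosine and Hermite-polynomial
#' adjustments and the hazard-rate key with cosine and simple-polynomial
#' adjustments, each with 0-2 adjustment terms, optionally with Beaufort sea
#' state as a scale covariate.  Fits that fail or are rejected (monotonicity)
#' are dropped silently from the candidate set.
#'
#' @param distances_m perpendicular distances in meters.
#' @param covariate_values Beaufort values aligned with distances, or `NULL`.
#' @param truncation_w_m right truncation in meters.
#' @param covariates covariates to include (default `"beaufort"` when
#'   `covariate_values` supplied, otherwise none).
#' @param max_adjust_terms maximum number of adjustment terms (default 2).
#' @return list with `best` (the selected fit) and `candidates`.
#' @export
fit_detection_menu <- function(distances_m, covariate_values = NULL,
                               truncation_w_m,
                               covariates = if (is.null(covariate_values))
                                 character() else "beaufort",
                               max_adjust_terms = 2L) {
  menu <- list(list("half_normal", "none", 0L),
               list("hazard_rate", "none", 0L))
  for (m in seq_len(max_adjust_terms)) {
    menu <- c(menu,
              list(list("half_normal", "cosine", m),
                   list("half_normal", "hermite", m),
                   list("hazard_rate", "cosine", m),
                   list("hazard_rate", "simple_poly", m)))
  }
  fits <- lapply(menu, function(m) {
    spec <- det_spec(m[[1]], m[[2]], m[[3]], covariates = covariates,
                     truncation_w_m = truncation_w_m)
    tryCatch(fit_detection_function(distances_m, covariate_values, spec),
             sealcount_error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    sc_abort("no detection model in the menu converged", "sc_fit_failure")
  list(best = select_model(fits), candidates = fits)
}

#' Histogram-with-fitted-curve data for a detection fit
#'
#' Returns the binned distance counts together with the fitted expected
#' counts per bin, suitable for plotting a detection-function diagnostic.
#'
#' @param fit a `detection_fit`.
#' @param distances_m the distances the fit used.
#' @param covariate_values aligned covariate values (or `NULL`).
#' @param n_bins number of equal-width bins on `[0, w]`.
#' @return data frame with `bin_lo`, `bin_hi`, `count`, `fitted`.
#' @export
detection_hist_data <- function(fit, distances_m, covariate_values = NULL,
                                n_bins = 20L) {
  w <- fit$spec$truncation_w_m
  breaks <- seq(0, w, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(distances_m, breaks,
                                  rightmost.closed = TRUE), n_bins)
  lev <- if (is.null(covariate_values)) rep(1L, length(distances_m)) else
    match(as.character(covariate_values), fit$levels)
  mu <- vapply(fit$sigma_by_class, sc_mu, numeric(1), shape = fit$shape,
               spec = fit$spec, acoef = fit$acoef)
  fitted <- vapply(seq_len(n_bins), function(b) {
    sum(vapply(seq_along(fit$sigma_by_class), function(ci) {
      n_ci <- sum(lev == ci)
      if (n_ci == 0L) return(0)
      int <- integrate(function(x) sc_g(x, fit$sigma_by_class[ci], fit$shape,
                                        fit$spec, fit$acoef),
                       breaks[b], breaks[b + 1L], rel.tol = 1e-8)$value
      n_ci * int / mu[ci]
    }, numeric(1)))
  }, numeric(1))
  data.frame(bin_lo = breaks[-(n_bins + 1L)], bin_hi = breaks[-1L],
             count = counts, fitted = fitted)
}

#' Write a detection-fit summary as JSON
#'
#' @param fit a `detection_fit`.
#' @param path output path.
#' @export
write_detection_fit <- function(fit, path) {
  out <- list(spec = unclass(fit$spec), params = fit$par,
              vcov = fit$vcov, f0_per_m = fit$f0_per_m, se_f0 = fit$se_f0,
              esw_m = fit$esw_m, loglik = fit$loglik, aic = fit$aic,
              n_used = fit$n_used, covariate_levels = fit$levels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
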