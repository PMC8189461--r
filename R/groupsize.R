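# Size-bias-corrected expected group size.
#
# Larger groups are easier to see far from the trackline, so the sample mean
# group size overestimates the population mean.  The standard remedy
# regresses log group size on the estimated detection probability g(x) and
# predicts at g = 1 (the trackline), backtransforming with the usual
# half-variance lognormal adjustment.  The regression is only used when its
# slope is significant at alpha = 0.15 (the conventional gate); otherwise
# the arithmetic mean is returned.

#' Expected group size with size-bias correction
#'
#' @param sightings data frame with columns `group_size` and
#'   `perpendicular_distance_m` (and `beaufort` when the fit has covariates).
#' @param fit a `detection_fit` used to evaluate `g(x)` per sighting.
#' @param alpha significance level for the slope gate (default 0.15).
#' @return a `group_size_estimate` with `e_s`, `se_e_s`, `method`.
#' @export
expected_group_size <- function(sightings, fit, alpha = 0.15) {
  s <- sightings$group_size
  n <- length(s)
  if (n < 5L)
    sc_abort("need at least 5 sightings to estimate group size",
             "sc_insufficient_data")
  if (any(s < 1))
    sc_abort("group sizes must be >= 1", "sc_invalid_argument")
  x <- sightings$perpendicular_distance_m
  has_cov <- length(fit$spec$covariates) > 0L
  g <- vapply(seq_len(n), function(i)
    detection_g(fit, x[i],
                covariate_value = if (has_cov) sightings$beaufort[i] else NULL),
    numeric(1))

  arithmetic <- function(reason = NULL) {
    if (!is.null(reason)) sc_warn(reason)
    structure(list(e_s = mean(s), se_e_s = stats::sd(s) / sqrt(n),
                   method = "arithmetic_mean"),
              class = "group_size_estimate")
  }
  if (var(g) < 1e-12)
    return(arithmetic("degenerate regressor (all detection probabilities equal); using arithmetic mean"))
  if (var(log(s)) < 1e-12) {
    # constant sizes: regression undefined, mean is exact
    return(structure(list(e_s = s[1L], se_e_s = 0, method = "arithmetic_mean"),
                     class = "group_size_estimate"))
  }
  fm <- lm(log(s) ~ g)
  p_slope <- summary(fm)$coefficients["g", "Pr(>|t|)"]
  if (!is.finite(p_slope) || p_slope >= alpha) return(arithmetic())
  s2 <- summary(fm)$sigma^2
  X1 <- c(1, 1)  # prediction at g = 1
  mu_log <- drop(X1 %*% coef(fm))
  var_lin <- drop(t(X1) %*% vcov(fm) %*% X1)
  e_s <- exp(mu_log + s2 / 2)
  # group sizes are >= 1, so the expected size cannot drop below 1
  e_s <- max(e_s, 1)
  structure(list(e_s = e_s, se_e_s = e_s * sqrt(var_lin),
                 method = "size_bias_regression"),
            class = "group_size_estimate")
}

#' @export
print.group_size_estimate <- function(x, ...) {
  cat(sprintf("E(s) = %.3f (SE %.3f), method = %s\n",
              x$e_s, x$se_e_s, x$method))
  invisible(x)
}
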