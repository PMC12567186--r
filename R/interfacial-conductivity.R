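# Maxwell-Wagner-Sillars interfacial polarization and dc-conductivity
# analysis.
#
# In a heterogeneous dielectric (conductive amorphous matrix with poorly
# conducting crystalline inclusions), free charge accumulating at the
# internal interfaces produces a slow relaxation whose time constant depends
# on both phases' permittivities and conductivities:
#   tau_MWS = eps0 (eps2' + A phi (eps1' - eps2')) /
#             (sigma2 + A phi (sigma1 - sigma2)),
# with A the inclusion depolarization factor (1/3 for spheres) and phi its
# volume fraction.  When sigma1 << sigma2 the time is inversely proportional
# to the matrix conductivity, so the interfacial relaxation frequency and
# the fitted dc conductivity are proportional (slope 1 in log-log).

#' Maxwell-Wagner-Sillars relaxation time
#'
#' @param eps1,eps2 Real (relaxed) permittivities of the inclusion and the
#'   matrix at the interfacial-polarization frequency, `>= 1`.
#' @param sigma1,sigma2 Conductivities of inclusion and matrix in S/m,
#'   `>= 0`.
#' @param A Depolarization factor of the inclusion, in (0, 1]; 1/3 for
#'   spherical inclusions.
#' @param phi Inclusion volume fraction, in [0, 1).
#' @return Relaxation time in seconds (vectorised).  A non-positive
#'   denominator (a configuration that does not relax) yields `NA` with a
#'   warning.
#' @examples
#' mws_relaxation_time(eps1 = 3, eps2 = 10, sigma1 = 0, sigma2 = 1e-8,
#'                     A = 1/3, phi = 0.3)
#' @export
mws_relaxation_time <- function(eps1, eps2, sigma1, sigma2, A = 1 / 3, phi = 0) {
  if (any(eps1 < 1) || any(eps2 < 1)) abort("Permittivities must be >= 1.")
  if (any(sigma1 < 0) || any(sigma2 < 0)) abort("Conductivities must be >= 0.")
  if (any(A <= 0) || any(A > 1)) abort("`A` must be in (0, 1].")
  if (any(phi < 0) || any(phi >= 1)) abort("`phi` must be in [0, 1).")
  num <- .eps0 * (eps2 + A * phi * (eps1 - eps2))
  den <- sigma2 + A * phi * (sigma1 - sigma2)
  bad <- den <= 0
  if (any(bad)) {
    warn("Non-positive denominator: non-relaxing configuration(s) set to NA.")
  }
  ifelse(bad, NA_real_, num / den)
}

#' @rdname mws_relaxation_time
#' @export
mws_frequency <- function(eps1, eps2, sigma1, sigma2, A = 1 / 3, phi = 0) {
  1 / (2 * pi * mws_relaxation_time(eps1, eps2, sigma1, sigma2, A, phi))
}

#' Correlation between dc conductivity and the slow-process frequency
#'
#' Least-squares slope of `log10 f0_slow` versus `log10 sigma0` over
#' temperatures present in both series.  Proportionality of relaxation
#' frequency and conductivity (slope 1) is the signature of interfacial
#' polarization controlled by the matrix conductivity (`sigma1 << sigma2`
#' in the MWS time).
#'
#' @param cond_series Data frame with `temperature_K` and `sigma0` (S/m).
#' @param slow_points Data frame with `temperature_K` and `f0_Hz`.
#' @param temp_tol Temperatures closer than this (K) are considered matched.
#' @return An object of class `sigma_correlation`: `slope`, `intercept`,
#'   `conf_low`/`conf_high` (95% CI on the slope), `n_points`, `r_squared`.
#' @export
sigma_slow_correlation <- function(cond_series, slow_points, temp_tol = 0.01) {
  cond_series <- as_tibble(cond_series)
  slow_points <- as_tibble(slow_points)
  stopifnot(all(c("temperature_K", "sigma0") %in% names(cond_series)),
            all(c("temperature_K", "f0_Hz") %in% names(slow_points)))
  key <- function(T_K) round(T_K / temp_tol) * temp_tol
  joined <- dplyr::inner_join(
    dplyr::mutate(cond_series, .k = key(.data$temperature_K)),
    dplyr::mutate(slow_points, .k = key(.data$temperature_K)),
    by = ".k", suffix = c("", ".slow")
  )
  joined <- joined[joined$sigma0 > 0 & joined$f0_Hz > 0, ]
  if (nrow(joined) < 3L) {
    abort("Need at least 3 matched temperatures for the correlation.")
  }
  fit <- lm(log10(f0_Hz) ~ log10(sigma0), data = joined)
  ci <- suppressMessages(confint(fit, level = 0.95))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         conf_low = ci[2, 1], conf_high = ci[2, 2],
         n_points = nrow(joined),
         r_squared = summary(fit)$r.squared, lm = fit),
    class = "sigma_correlation"
  )
}

#' @export
print.sigma_correlation <- function(x, ...) {
  cat(sprintf(
    "<sigma_correlation>  slope = %.3f [%.3f, %.3f], intercept = %.3f  (%d points, R2 = %.4f)\n",
    x$slope, x$conf_low, x$conf_high, x$intercept, x$n_points, x$r_squared))
  invisible(x)
}

#' @rdname sigma_slow_correlation
#' @param x A `sigma_correlation`.
#' @param ... Unused.
#' @export
glance.sigma_correlation <- function(x, ...) {
  tibble(slope = x$slope, conf_low = x$conf_low, conf_high = x$conf_high,
         intercept = x$intercept, n_points = x$n_points,
         r_squared = x$r_squared)
}

#' Two-regime Arrhenius analysis of dc conductivity
#'
#' Fits separate Arrhenius laws to `log10 sigma0` versus `1/T` below and
#' above a breakpoint temperature.  In hydrated polysaccharide films the
#' low-temperature regime (hopping, fractional conductivity exponent) shows
#' a moderate activation energy and the regime above the glass transition a
#' much steeper one.  `breakpoint = NULL` scans the interior temperature
#' grid (at least `min_points` per side) and picks the split minimising the
#' total residual sum of squares.
#'
#' @param series Data frame with `temperature_K` and `sigma0` (S/m) columns.
#' @param breakpoint Breakpoint temperature in K, or `NULL` for the
#'   automatic scan.
#' @param min_points Minimum points per regime.
#' @return An object of class `conductivity_regimes`: `breakpoint_K` and two
#'   regime summaries (`low`, `high`) each with `Ea_kJ_mol`,
#'   `log10_sigma_inf`, `n_points`, `rms`.
#' @export
fit_conductivity_regimes <- function(series, breakpoint = NULL,
                                     min_points = 3L) {
  series <- as_tibble(series)
  stopifnot(all(c("temperature_K", "sigma0") %in% names(series)))
  series <- series[series$sigma0 > 0, ]
  series <- dplyr::arrange(series, .data$temperature_K)
  n <- nrow(series)
  if (n < 2L * min_points) {
    abort(sprintf("Need at least %d points (%d per regime).",
                  2L * min_points, min_points))
  }
  y <- log10(series$sigma0)
  T_K <- series$temperature_K

  seg <- function(idx) {
    ln <- .arrhenius_line(T_K[idx], y[idx])
    list(Ea_kJ_mol = -ln$slope * .ln10 * .gas_R / 1000,
         log10_sigma_inf = ln$intercept,
         n_points = length(idx), rms = ln$rms,
         rss = sum(stats::residuals(ln$lm)^2))
  }

  if (is.null(breakpoint)) {
    cuts <- seq(min_points, n - min_points)
    rss <- vapply(cuts, function(k) {
      seg(1:k)$rss + seg((k + 1):n)$rss
    }, numeric(1))
    k <- cuts[which.min(rss)]
    breakpoint <- (T_K[k] + T_K[k + 1]) / 2
  } else {
    k <- sum(T_K < breakpoint)
    if (k < min_points || n - k < min_points) {
      abort("Too few points on one side of the supplied breakpoint.")
    }
  }
  low <- seg(1:k)
  high <- seg((k + 1):n)
  structure(
    list(breakpoint_K = breakpoint, low = low, high = high,
         total_rss = low$rss + high$rss),
    class = "conductivity_regimes"
  )
}

#' @export
print.conductivity_regimes <- function(x, ...) {
  cat(sprintf(
    "<conductivity_regimes>  break at %.1f K\n  below: Ea = %.3g kJ/mol (%d pts)\n  above: Ea = %.3g kJ/mol (%d pts)\n",
    x$breakpoint_K, x$low$Ea_kJ_mol, x$low$n_points,
    x$high$Ea_kJ_mol, x$high$n_points))
  invisible(x)
}

#' @rdname fit_conductivity_regimes
#' @param x A `conductivity_regimes`.
#' @param ... Unused.
#' @export
tidy.conductivity_regimes <- function(x, ...) {
  tibble(
    regime = c("low", "high"),
    Ea_kJ_mol = c(x$low$Ea_kJ_mol, x$high$Ea_kJ_mol),
    log10_sigma_inf = c(x$low$log10_sigma_inf, x$high$log10_sigma_inf),
    n_points = c(x$low$n_points, x$high$n_points),
    rms = c(x$low$rms, x$high$rms),
    breakpoint_K = x$breakpoint_K
  )
}

#' Extract a conductivity series from isotherm fits
#'
#' Collects the fitted `(sigma0, n)` per temperature from a [fit_dataset()]
#' result or list of [fit_isotherm()] results.
#'
#' @param results A `bds_fit_set` or list of `isotherm_fit` objects.
#' @return A tibble with `temperature_K`, `sigma0`, `n`.
#' @export
conductivity_series <- function(results) {
  if (inherits(results, "bds_fit_set")) results <- results$fits
  rows <- lapply(results, function(r) {
    if (is.null(r$model$conductivity)) return(NULL)
    tibble(temperature_K = r$temperature_K,
           sigma0 = r$model$conductivity$sigma0,
           n = r$model$conductivity$n)
  })
  dplyr::bind_rows(rows)
}
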