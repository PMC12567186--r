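# Relaxation maps and temperature laws.
#
# A relaxation map collects, per labelled process, the fitted relaxation
# frequencies across temperature; plotted as log10 f0 versus 1000/T, an
# Arrhenius-activated process is a straight line (slope ~ activation energy)
# while a structural relaxation follows the super-Arrhenius VFT law
#   f(T) = f_inf exp(-B / (T - T0)),
# whose Vogel temperature T0 is the finite-temperature divergence of the
# relaxation time.  The dielectric glass-transition convention is the
# temperature where the relaxation time reaches 100 s, i.e.
# f = 1/(2 pi 100) Hz (log10 f = -2.8 to the usual rounding), giving
#   Tg = T0 + B / (ln10 (2 + log10(2 pi f_inf)))
# and the dynamic fragility
#   m = B Tg / (ln10 (Tg - T0)^2)
#     = C (1 + ln10 C T0 / B),  C = 2 + log10(2 pi f_inf).
# The conventional "2.3" prefactor of these formulas is implemented as ln10:
# recomputing published fragilities from their own VFT parameters matches
# only with the exact value.

#' Assemble a relaxation map from isotherm fits
#'
#' Collects `(temperature, f0)` per process label from a list of
#' [fit_isotherm()] results or a [fit_dataset()] result, skipping entries
#' flagged unresolved.  Entries whose `f0` was pinned by Arrhenius
#' extrapolation keep provenance `"fixed:arrhenius"` so that downstream
#' temperature-law fits can exclude them (no circular fitting).
#'
#' @param results A `bds_fit_set` or list of `isotherm_fit` objects.
#' @return A tibble of class `relaxation_map` with columns `process_label`,
#'   `temperature_K`, `f0_Hz`, `log10_f0`, `inv1000_over_T`, `provenance`,
#'   and `in_window` (whether the fitted relaxation frequency lies inside
#'   the measured frequency window; law fits use in-window entries only).
#' @export
build_relaxation_map <- function(results) {
  if (inherits(results, "bds_fit_set")) results <- results$fits
  stopifnot(is.list(results))
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "isotherm_fit"))
    if (!length(r$model$processes)) return(NULL)
    f0_src <- r$params$source[r$params$term == "f0"]
    names(f0_src) <- r$params$label[r$params$term == "f0"]
    lbl <- vapply(r$model$processes, `[[`, character(1), "label")
    keep <- !(lbl %in% r$unresolved)
    if (!any(keep)) return(NULL)
    f0 <- vapply(r$model$processes, `[[`, numeric(1), "f0")[keep]
    fwin <- r$freq_window %||% c(-Inf, Inf)
    tibble(
      process_label = lbl[keep],
      temperature_K = r$temperature_K,
      f0_Hz = f0,
      provenance = ifelse(f0_src[lbl[keep]] == "fixed:arrhenius",
                          "fixed:arrhenius", "fitted"),
      in_window = f0 >= fwin[1] & f0 <= fwin[2]
    )
  })
  map <- dplyr::bind_rows(rows)
  if (nrow(map)) {
    map$log10_f0 <- log10(map$f0_Hz)
    map$inv1000_over_T <- 1000 / map$temperature_K
  } else {
    map$log10_f0 <- numeric(0)
    map$inv1000_over_T <- numeric(0)
    map$in_window <- logical(0)
  }
  class(map) <- c("relaxation_map", class(tibble()))
  map
}

# internal: straight-line fit of y on 1/T
.arrhenius_line <- function(T_K, y) {
  fit <- lm(y ~ I(1 / T_K))
  res <- stats::residuals(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       rms = sqrt(mean(res^2)), lm = fit)
}

#' Fit an Arrhenius temperature law
#'
#' Ordinary least squares of `log10 f0` on `1/T`:
#' `log10 f = log10 f_inf - Ea / (ln10 R T)`, so the activation energy is
#' `Ea = -slope * ln10 * R` (kJ/mol, `R = 8.314462618 J/(mol K)`) and the
#' intercept is `log10 f_inf`.
#'
#' @param data A data frame with columns `temperature_K` and `f0_Hz` (a
#'   [build_relaxation_map()] group, for example).  Entries with provenance
#'   `"fixed:arrhenius"` are dropped automatically if a `provenance` column
#'   is present.
#' @return An object of class `arrhenius_fit` with `log10_f_inf`,
#'   `Ea_kJ_mol`, `n_points` and the rms residual in `log10 f`.
#' @export
fit_arrhenius <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("temperature_K", "f0_Hz") %in% names(data)))
  if ("provenance" %in% names(data)) {
    data <- data[data$provenance != "fixed:arrhenius", ]
  }
  if (nrow(data) < 2L) abort("Need at least 2 points for an Arrhenius fit.")
  if (any(data$temperature_K <= 0)) abort("Temperatures must be positive (K).")
  if (any(data$f0_Hz <= 0)) abort("Frequencies must be positive (Hz).")
  ln <- .arrhenius_line(data$temperature_K, log10(data$f0_Hz))
  structure(
    list(log10_f_inf = ln$intercept,
         Ea_kJ_mol = -ln$slope * .ln10 * .gas_R / 1000,
         n_points = nrow(data), rms = ln$rms, lm = ln$lm),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit>  log10 f_inf = %.4g, Ea = %.4g kJ/mol  (%d points, rms %.3g)\n",
    x$log10_f_inf, x$Ea_kJ_mol, x$n_points, x$rms))
  invisible(x)
}

#' @rdname fit_arrhenius
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(term = c("log10_f_inf", "Ea_kJ_mol"),
         estimate = c(x$log10_f_inf, x$Ea_kJ_mol))
}

#' @rdname fit_arrhenius
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(log10_f_inf = x$log10_f_inf, Ea_kJ_mol = x$Ea_kJ_mol,
         n_points = x$n_points, rms_log10f = x$rms)
}

#' Fit a Vogel-Fulcher-Tammann temperature law
#'
#' Nonlinear least squares of `log10 f0` against
#' `log10 f_inf - B / (ln10 (T - T0))`.  The Vogel temperature `T0` is
#' profiled on a deterministic grid (given `T0`, the law is linear in the
#' remaining parameters), and the best profile point is polished by bounded
#' Levenberg-Marquardt; the procedure is deterministic.  `f_inf` can be fixed
#' (e.g. to the secondary relaxation's value when the structural process
#' merges with it at high temperature).
#'
#' @param data A data frame with columns `temperature_K` and `f0_Hz`; a
#'   `provenance` column, if present, drops `"fixed:arrhenius"` rows.
#' @param fixed_log10_f_inf Optional fixed value of `log10 f_inf`.
#' @param seed Unused (the profiled fit is deterministic); kept for interface
#'   stability.
#' @return An object of class `vft_fit` with `log10_f_inf`, `B` (K), `T0`
#'   (K), the derived `tg_C` and `fragility_m`, `n_points`, the rms residual
#'   in `log10 f`, and a `flagged` field that is `TRUE` when the fitted
#'   asymptote falls inside the data range (unreliable fit).
#' @seealso [tg_from_vft()], [fragility_from_vft()]
#' @export
fit_vft <- function(data, fixed_log10_f_inf = NULL, seed = 1L) {
  data <- as_tibble(data)
  stopifnot(all(c("temperature_K", "f0_Hz") %in% names(data)))
  if ("provenance" %in% names(data)) {
    data <- data[data$provenance != "fixed:arrhenius", ]
  }
  need <- if (is.null(fixed_log10_f_inf)) 3L else 2L
  if (nrow(data) < need) {
    abort(sprintf("Need at least %d points for a VFT fit.", need))
  }
  T_K <- data$temperature_K
  y <- log10(data$f0_Hz)
  Tmin <- min(T_K)

  # profile T0: linear LS in (log10 f_inf, B) at fixed T0
  profile_rss <- function(T0) {
    x <- 1 / (.ln10 * (T_K - T0))
    if (is.null(fixed_log10_f_inf)) {
      fit <- lm(y ~ x)
      c(rss = sum(stats::residuals(fit)^2),
        lf = unname(coef(fit)[1]), B = -unname(coef(fit)[2]))
    } else {
      fit <- lm(I(y - fixed_log10_f_inf) ~ x - 1)
      c(rss = sum(stats::residuals(fit)^2),
        lf = fixed_log10_f_inf, B = -unname(coef(fit)[1]))
    }
  }
  T0_grid <- seq(1, Tmin - 2, length.out = 60)
  prof <- vapply(T0_grid, profile_rss, numeric(3))
  best_i <- which.min(prof["rss", ])
  start <- c(lf = prof["lf", best_i], B = max(prof["B", best_i], 1),
             T0 = T0_grid[best_i])

  free_lf <- is.null(fixed_log10_f_inf)
  resid_fun <- function(p) {
    lf <- if (free_lf) p[1] else fixed_log10_f_inf
    B <- p[[if (free_lf) 2 else 1]]
    T0 <- p[[if (free_lf) 3 else 2]]
    (lf - B / (.ln10 * (T_K - T0))) - y
  }
  par0 <- if (free_lf) unname(start) else unname(start[2:3])
  lower <- if (free_lf) c(-5, 1e-3, 0) else c(1e-3, 0)
  upper <- if (free_lf) c(30, 1e6, Tmin - 0.5) else c(1e6, Tmin - 0.5)
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(par0, lower), upper), lower = lower, upper = upper,
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  p <- fit$par
  lf <- if (free_lf) p[1] else fixed_log10_f_inf
  B <- p[[if (free_lf) 2 else 1]]
  T0 <- p[[if (free_lf) 3 else 2]]

  flagged <- (T0 >= Tmin - 0.5 - 1e-6)
  if (flagged) {
    warn(sprintf(
      "VFT asymptote T0 = %.2f K is not below the data range (min T = %.2f K); fit flagged.",
      T0, Tmin))
  }

  out <- structure(
    list(log10_f_inf = lf, B = B, T0 = T0,
         fixed_f_inf = !free_lf, n_points = nrow(data),
         rms = sqrt(fit$deviance / nrow(data)), flagged = flagged),
    class = "vft_fit"
  )
  out$tg_C <- tryCatch(tg_from_vft(out), error = function(e) NA_real_)
  out$fragility_m <- tryCatch(fragility_from_vft(out),
                              error = function(e) NA_real_)
  out
}

#' VFT parameter triple
#'
#' Convenience constructor for a `vft_fit`-like object from known parameters
#' (for worked examples and published-value comparisons).
#'
#' @param log10_f_inf Decadic log of the infinite-temperature frequency (Hz).
#' @param B VFT activation parameter (K), `> 0`.
#' @param T0 Vogel temperature (K), `>= 0`.
#' @return An object of class `vft_fit`.
#' @export
vft_params <- function(log10_f_inf, B, T0) {
  .check_number(log10_f_inf, "log10_f_inf")
  .check_number(B, "B", lower = 0, open_lower = TRUE)
  .check_number(T0, "T0", lower = 0)
  out <- structure(
    list(log10_f_inf = log10_f_inf, B = B, T0 = T0,
         fixed_f_inf = FALSE, n_points = NA_integer_, rms = NA_real_,
         flagged = FALSE),
    class = "vft_fit"
  )
  out$tg_C <- tg_from_vft(out)
  out$fragility_m <- fragility_from_vft(out)
  out
}

#' Evaluate a VFT law
#'
#' @param fit A `vft_fit` (or [vft_params()]).
#' @param T_K Temperatures in kelvin.
#' @return Frequencies in Hz (`NA` at or below `T0`).
#' @export
vft_frequency <- function(fit, T_K) {
  stopifnot(inherits(fit, "vft_fit"))
  ifelse(T_K > fit$T0,
         10^(fit$log10_f_inf - fit$B / (.ln10 * (T_K - fit$T0))),
         NA_real_)
}

#' @export
print.vft_fit <- function(x, ...) {
  cat(sprintf(
    "<vft_fit>  log10 f_inf = %.4g%s, B = %.5g K, T0 = %.5g K\n           Tg = %.1f C, m = %.1f%s\n",
    x$log10_f_inf, if (x$fixed_f_inf) " (fixed)" else "", x$B, x$T0,
    x$tg_C, x$fragility_m, if (x$flagged) "  [FLAGGED]" else ""))
  invisible(x)
}

#' @rdname fit_vft
#' @param x A `vft_fit`.
#' @param ... Unused.
#' @export
tidy.vft_fit <- function(x, ...) {
  tibble(term = c("log10_f_inf", "B", "T0"),
         estimate = c(x$log10_f_inf, x$B, x$T0),
         fixed = c(x$fixed_f_inf, FALSE, FALSE))
}

#' @rdname fit_vft
#' @export
glance.vft_fit <- function(x, ...) {
  tibble(log10_f_inf = x$log10_f_inf, B = x$B, T0 = x$T0,
         tg_C = x$tg_C, fragility_m = x$fragility_m,
         n_points = x$n_points, rms_log10f = x$rms, flagged = x$flagged)
}

# C = 2 + log10(2 pi f_inf), the decadic decade count between f_inf and the
# conventional glass-transition frequency 1/(2 pi 100) Hz.
.vft_C <- function(log10_f_inf) 2 + log10(2 * pi) + log10_f_inf

.as_vft <- function(fit, B, T0) {
  if (inherits(fit, "vft_fit")) return(fit)
  if (is.numeric(fit) && !is.null(B) && !is.null(T0)) {
    return(list(log10_f_inf = fit, B = B, T0 = T0))
  }
  abort("Supply a vft_fit or (log10_f_inf, B, T0) numbers.")
}

#' Glass-transition temperature from VFT parameters
#'
#' The dielectric convention places Tg at the temperature where the
#' relaxation frequency reaches `1/(2 pi 100)` Hz (relaxation time 100 s):
#' \deqn{T_g = T_0 + \frac{B}{\ln 10\,(2 + \log_{10}(2\pi f_\infty))}.}
#' This equals the exact numeric root of the VFT law at that frequency (to
#' well below 1e-9 K); the conventional prefactor "2.3" is implemented as
#' `ln 10`.
#'
#' @param fit A `vft_fit`, or the numeric `log10_f_inf` with `B` and `T0`
#'   supplied.
#' @param B,T0 VFT parameters when `fit` is numeric.
#' @return Tg in degrees Celsius.
#' @examples
#' tg_from_vft(10.03, B = 2529, T0 = 144.5)  # about -43.0 C
#' @export
tg_from_vft <- function(fit, B = NULL, T0 = NULL) {
  v <- .as_vft(fit, B, T0)
  C <- .vft_C(v$log10_f_inf)
  if (C <= 0) {
    abort("2 + log10(2 pi f_inf) <= 0: glass-transition frequency above f_inf.",
          class = "bdsfit_undefined_tg")
  }
  celsius(v$T0 + v$B / (.ln10 * C))
}

#' Dynamic fragility index from VFT parameters
#'
#' The steepness of the relaxation-time slowdown at the glass transition,
#' \deqn{m = \left.\frac{d\,\log_{10}\tau}{d\,(T_g/T)}\right|_{T_g}
#'   = \frac{B\,T_g}{\ln 10\,(T_g - T_0)^2}
#'   = C\left(1 + \frac{\ln 10\, C\, T_0}{B}\right),\quad
#'   C = 2 + \log_{10}(2\pi f_\infty).}
#' The two algebraic forms agree identically; `T0 = 0` gives the
#' Arrhenius-limit minimum `m = C`.  Low `m` (near-Arrhenius) indicates a
#' strong glass former; high `m` a fragile one.
#'
#' @inheritParams tg_from_vft
#' @return The dimensionless fragility index.
#' @examples
#' fragility_from_vft(10.03, B = 2529, T0 = 144.5)  # about 34.5
#' @export
fragility_from_vft <- function(fit, B = NULL, T0 = NULL) {
  v <- .as_vft(fit, B, T0)
  C <- .vft_C(v$log10_f_inf)
  if (C <= 0) {
    abort("2 + log10(2 pi f_inf) <= 0: fragility undefined.",
          class = "bdsfit_undefined_tg")
  }
  C * (1 + .ln10 * C * v$T0 / v$B)
}

#' Dielectric Tg from the log f0 = -2.8 crossing
#'
#' The relaxation-map reading of the glass transition: the temperature where
#' a process's `log10 f0` crosses -2.8 (the rounded decadic log of
#' `1/(2 pi 100)` Hz).  For a `vft_fit` the crossing is closed-form; for a
#' data-frame group it is interpolated linearly in `log10 f0` versus `1/T`
#' (exact for an Arrhenius process) between the bracketing points.
#'
#' @param x A `vft_fit`, or a data frame with `temperature_K` and `f0_Hz`
#'   (or `log10_f0`) columns.
#' @param level The crossing level in `log10 f0` (default -2.8).
#' @param guard For `vft_fit` input, the crossing must fall in
#'   `(T0 + 1 K, Inf)`; for data input, within the data span (no
#'   extrapolation).  A miss returns `NA` with a warning.
#' @return Crossing temperature in degrees Celsius (`NA` if no crossing).
#' @export
dielectric_tg_crossing <- function(x, level = -2.8, guard = TRUE) {
  if (inherits(x, "vft_fit")) {
    denom <- x$log10_f_inf - level
    if (denom <= 0) {
      warn("VFT law never reaches the crossing level; no Tg crossing.")
      return(NA_real_)
    }
    T_cross <- x$T0 + x$B / (.ln10 * denom)
    if (guard && T_cross <= x$T0 + 1) {
      warn("Crossing falls within 1 K of the Vogel asymptote; flagged.")
      return(NA_real_)
    }
    return(celsius(T_cross))
  }
  data <- as_tibble(x)
  stopifnot("temperature_K" %in% names(data))
  if (!"log10_f0" %in% names(data)) {
    stopifnot("f0_Hz" %in% names(data))
    data$log10_f0 <- log10(data$f0_Hz)
  }
  data <- dplyr::arrange(data, .data$temperature_K)
  y <- data$log10_f0 - level
  s <- which(y[-1] * y[-length(y)] <= 0)
  if (!length(s)) {
    warn("Group does not cross the level within its temperature span.")
    return(NA_real_)
  }
  i <- s[1]
  if (y[i] == 0) return(celsius(data$temperature_K[i]))
  x1 <- 1 / data$temperature_K[i]; x2 <- 1 / data$temperature_K[i + 1]
  w <- y[i] / (y[i] - y[i + 1])
  celsius(1 / (x1 + w * (x2 - x1)))
}

#' Fit temperature laws to every process of a relaxation map
#'
#' Groups a [build_relaxation_map()] by process label, drops
#' `"fixed:arrhenius"` entries, and fits the declared law per label
#' (Arrhenius by default), returning a summary table in the layout of
#' published relaxation-parameter tables.
#'
#' @param map A `relaxation_map`.
#' @param laws Named character vector label -> `"arrhenius"` or `"vft"`;
#'   unnamed labels default to `"arrhenius"`.
#' @param fixed_log10_f_inf Optional named numeric vector of fixed
#'   `log10 f_inf` values per label (VFT fits only).
#' @param min_points Minimum free map points required per label.
#' @param trim If `TRUE` (default), one round of outlier exclusion is applied
#'   per label: points whose residual in `log10 f0` exceeds 3 robust standard
#'   deviations (MAD-based) of the first fit are dropped and the law is
#'   refitted once.  Map entries near a window edge or an unresolved crossing
#'   otherwise leak large errors into the law parameters.
#' @return A tibble of class `law_summary` with one row per process:
#'   `process_label`, `law`, `log10_f_inf`, `B`, `T0`, `Ea_kJ_mol`, `tg_C`,
#'   `fragility_m`, `n_points`, `rms_log10f`, `flagged`; fit objects in the
#'   `fit` list-column.
#' @export
fit_relaxation_laws <- function(map, laws = NULL, fixed_log10_f_inf = NULL,
                                min_points = 3L, trim = TRUE) {
  stopifnot(is.data.frame(map))
  labels <- unique(map$process_label)
  rows <- list()

  law_resid <- function(law, ft, pts) {
    pred <- if (law == "vft") {
      ft$log10_f_inf - ft$B / (.ln10 * (pts$temperature_K - ft$T0))
    } else {
      ft$log10_f_inf -
        ft$Ea_kJ_mol * 1000 / (.ln10 * .gas_R * pts$temperature_K)
    }
    log10(pts$f0_Hz) - pred
  }
  fit_once <- function(law, pts, ffix) {
    if (law == "vft") fit_vft(pts, fixed_log10_f_inf = ffix)
    else fit_arrhenius(pts)
  }

  for (lbl in labels) {
    pts <- map[map$process_label == lbl & map$provenance != "fixed:arrhenius", ]
    # temperature laws are fitted only where the relaxation peak lies inside
    # the measured window; an extrapolated peak position is not a measurement
    if ("in_window" %in% names(pts)) pts <- pts[pts$in_window, ]
    if (nrow(pts) < min_points) {
      warn(sprintf("Process '%s': only %d free points; skipped.", lbl, nrow(pts)))
      next
    }
    law <- unname((laws %||% character(0))[lbl])
    if (is.na(law %||% NA_character_)) law <- "arrhenius"
    ffix <- unname((fixed_log10_f_inf %||% numeric(0))[lbl])
    if (is.na(ffix %||% NA_real_)) ffix <- NULL

    ft <- fit_once(law, pts, ffix)
    if (trim) {
      for (round in 1:3) {
        if (nrow(pts) < min_points + 2L) break
        res <- law_resid(law, ft, pts)
        keep <- abs(res) <= 3 * max(stats::mad(res), 1e-6)
        if (sum(keep) < min_points || all(keep)) break
        pts <- pts[keep, ]
        ft <- fit_once(law, pts, ffix)
      }
    }

    if (law == "vft") {
      rows[[lbl]] <- tibble(
        process_label = lbl, law = "vft",
        log10_f_inf = ft$log10_f_inf, B = ft$B, T0 = ft$T0,
        Ea_kJ_mol = NA_real_, tg_C = ft$tg_C, fragility_m = ft$fragility_m,
        n_points = ft$n_points, rms_log10f = ft$rms, flagged = ft$flagged,
        fit = list(ft)
      )
    } else {
      rows[[lbl]] <- tibble(
        process_label = lbl, law = "arrhenius",
        log10_f_inf = ft$log10_f_inf, B = NA_real_, T0 = NA_real_,
        Ea_kJ_mol = ft$Ea_kJ_mol, tg_C = NA_real_, fragility_m = NA_real_,
        n_points = ft$n_points, rms_log10f = ft$rms, flagged = FALSE,
        fit = list(ft)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("law_summary", class(tibble()))
  out
}
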