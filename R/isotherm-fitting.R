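# Per-isotherm least-squares fitting of dielectric spectra.
#
# The fitting protocol mirrors standard practice for conductive, thinning
# films: the unrelaxed permittivity eps_inf is read off the coldest spectrum
# at the highest frequency; the fast process is fitted at low temperatures
# (with b = 1 and the conductivity term included); its Arrhenius
# extrapolation then pins its relaxation frequency in higher-temperature fits
# where slower processes appear; the refined representation is the global
# loss tangent tan delta = eps''/eps', which is invariant to sample-thickness
# drift, while a plain eps'' fit is also available.
#
# Optimisation: bounded Levenberg-Marquardt (minpack.lm::nls.lm) on
# unweighted residuals in the linear scale of the fitted quantity, evaluated
# at the measured frequency points (log-uniform grids by construction).
# delta_eps, f0 and sigma0 are optimised in log10; a, b and n in natural
# scale.  Multi-start from a seeded jittered set; lowest residual norm wins.

#' Default parameter bounds for isotherm fits
#'
#' @return A named list of `c(lower, upper)` bounds: `delta_eps` in
#'   (1e-4, 1e4), `f0` in (1e-6, 1e9) Hz, `a` and `b` in (0.05, 1],
#'   `sigma0` in (1e-20, 1e2) S/m, `n` in (0.05, 1].
#' @export
bds_bounds <- function() {
  list(
    delta_eps = c(1e-4, 1e4),
    f0 = c(1e-6, 1e9),
    a = c(0.05, 1),
    b = c(0.05, 1),
    sigma0 = c(1e-20, 1e2),
    n = c(0.05, 1)
  )
}

#' Specification of one process in a fit
#'
#' Initial values, fixed/free flags and provenance for one HN process of a
#' [fit_config()].  By convention `b` is held fixed at 1 unless `free_b` is
#' set.  A process whose `f0` comes from an Arrhenius extrapolation is fixed
#' with `free_f0 = FALSE` and `f0_source = "fixed:arrhenius"`.
#'
#' @param label Process tag.
#' @param delta_eps,f0,a,b Initial values; `f0 = NULL` requests peak-picking
#'   initialisation from the data.
#' @param free_delta,free_f0,free_a,free_b Which parameters are optimised.
#' @param f0_source Provenance string for `f0` (e.g. `"init"`,
#'   `"fixed:arrhenius"`, `"fixed:user"`).
#' @return An object of class `process_spec`.
#' @export
process_spec <- function(label, delta_eps = 1, f0 = NULL, a = 0.5, b = 1,
                         free_delta = TRUE, free_f0 = TRUE, free_a = TRUE,
                         free_b = FALSE, f0_source = "init") {
  structure(
    list(label = label, delta_eps = delta_eps, f0 = f0, a = a, b = b,
         free_delta = free_delta, free_f0 = free_f0, free_a = free_a,
         free_b = free_b, f0_source = f0_source),
    class = "process_spec"
  )
}

#' Configuration of a single-isotherm fit
#'
#' @param processes List of [process_spec()] objects (at least one process or
#'   the conductivity term must be enabled).
#' @param include_conductivity Include the [cond_term()] contribution.
#' @param sigma0,n Initial conductivity values (`n = NULL` requests a guess
#'   from the low-frequency tan-delta plateau).
#' @param eps_inf Fixed unrelaxed permittivity; `NULL` estimates it from the
#'   spectrum's own highest-frequency eps' (for datasets use
#'   [estimate_eps_inf()] and pass the value).
#' @param representation `"tan_delta"` (global Eq.-style loss-tangent fit) or
#'   `"eps_imag"` (plain loss fit).
#' @param weighting `"none"`: unweighted residuals in the linear scale of the
#'   fitted quantity; `"relative"`: residuals divided by the measured value,
#'   the maximum-likelihood choice when measurement noise is multiplicative
#'   (the usual regime of broadband dielectric data, and the noise model of
#'   the synthetic generator).
#' @param n_starts Number of optimisation starts (1 nominal + jittered).
#' @param jitter_sd Log10-scale jitter applied to starts 2..n_starts.
#' @param seed Seed for the jittered starts (fits are deterministic given it).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param bounds Parameter bounds, see [bds_bounds()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(processes, include_conductivity = TRUE,
                       sigma0 = 1e-12, n = NULL, eps_inf = NULL,
                       representation = c("tan_delta", "eps_imag"),
                       weighting = c("none", "relative"),
                       n_starts = 5, jitter_sd = 0.3, seed = 1L,
                       max_iter = 200, bounds = bds_bounds()) {
  representation <- match.arg(representation)
  weighting <- match.arg(weighting)
  if (inherits(processes, "process_spec")) processes <- list(processes)
  stopifnot(all(vapply(processes, inherits, logical(1), "process_spec")))
  if (!length(processes) && !include_conductivity) {
    abort("At least one process or the conductivity term must be enabled.")
  }
  labels <- vapply(processes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("Process labels must be unique.")
  structure(
    list(processes = processes, include_conductivity = include_conductivity,
         sigma0 = sigma0, n = n, eps_inf = eps_inf,
         representation = representation, weighting = weighting,
         n_starts = n_starts,
         jitter_sd = jitter_sd, seed = as.integer(seed),
         max_iter = max_iter, bounds = bounds),
    class = "fit_config"
  )
}

#' Unrelaxed permittivity from a dataset
#'
#' Reads eps_inf off the measured eps' at the lowest temperature of the
#' dataset and its highest frequency, where all relaxations have decayed.
#'
#' @param spectra A `bds_spectra` tibble.
#' @return A single permittivity value.
#' @export
estimate_eps_inf <- function(spectra) {
  spectra <- as_bds_spectra(spectra)
  if (!nrow(spectra)) abort("Empty dataset.")
  cold <- spectra[spectra$temperature_K == min(spectra$temperature_K), ]
  cold$eps_real[which.max(cold$frequency_Hz)]
}

# parameter packing ----------------------------------------------------------

# A parameter table row: term, label, init (natural scale), free, lower,
# upper, log (TRUE -> optimise log10).
.param_table <- function(config, f0_inits, n_init) {
  rows <- list()
  b <- config$bounds
  for (i in seq_along(config$processes)) {
    p <- config$processes[[i]]
    f0 <- p$f0 %||% f0_inits[[p$label]]
    rows[[length(rows) + 1L]] <- tibble(
      term = c("delta_eps", "f0", "a", "b"),
      label = p$label,
      init = c(p$delta_eps, f0, p$a, p$b),
      free = c(p$free_delta, p$free_f0, p$free_a, p$free_b),
      lower = c(b$delta_eps[1], b$f0[1], b$a[1], b$b[1]),
      upper = c(b$delta_eps[2], b$f0[2], b$a[2], b$b[2]),
      log = c(TRUE, TRUE, FALSE, FALSE),
      source = c("init", p$f0_source, "init", if (p$free_b) "init" else "convention:b=1")
    )
  }
  if (config$include_conductivity) {
    rows[[length(rows) + 1L]] <- tibble(
      term = c("sigma0", "n"),
      label = "conductivity",
      init = c(config$sigma0, config$n %||% n_init),
      free = c(TRUE, TRUE),
      lower = c(b$sigma0[1], b$n[1]),
      upper = c(b$sigma0[2], b$n[2]),
      log = c(TRUE, FALSE),
      source = "init"
    )
  }
  tbl <- dplyr::bind_rows(rows)
  tbl$init <- pmin(pmax(tbl$init, tbl$lower), tbl$upper)
  tbl
}

.pack <- function(values, tbl) ifelse(tbl$log, log10(values), values)
.unpack <- function(packed, tbl) ifelse(tbl$log, 10^packed, packed)

.model_from_values <- function(values, tbl, eps_inf, config) {
  procs <- list()
  for (p in config$processes) {
    idx <- tbl$label == p$label
    v <- setNames(values[idx], tbl$term[idx])
    procs <- c(procs, list(hn_process(v[["delta_eps"]], v[["f0"]],
                                      v[["a"]], v[["b"]], label = p$label)))
  }
  cond <- NULL
  if (config$include_conductivity) {
    idx <- tbl$label == "conductivity"
    v <- setNames(values[idx], tbl$term[idx])
    cond <- cond_term(v[["sigma0"]], v[["n"]])
  }
  dielectric_model(eps_inf, procs, cond)
}

# peak-picking initialisation ------------------------------------------------

# Local maxima of the smoothed log-representation curve give f0 guesses for
# processes without an explicit initial value; the low-frequency plateau of
# tan delta gives the conductivity-exponent guess via n = (2/pi) atan(plateau).
.pick_peaks <- function(f, y, n_needed) {
  if (n_needed == 0L) return(numeric(0))
  ly <- log10(pmax(y, 1e-12))
  k <- min(5L, length(ly))
  sm <- stats::filter(ly, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- ly[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  is_peak <- rep(FALSE, n)
  for (i in seq(3, n - 2)) {
    if (sm[i] >= sm[i - 1] && sm[i] >= sm[i + 1] &&
        sm[i] > sm[i - 2] && sm[i] > sm[i + 2]) is_peak[i] <- TRUE
  }
  peaks <- f[is_peak]
  if (length(peaks) < n_needed) {
    fill <- 10^seq(log10(min(f)) + 0.5, log10(max(f)) - 0.5,
                   length.out = n_needed - length(peaks))
    peaks <- sort(c(peaks, fill))
  }
  sort(peaks)[seq_len(n_needed)]
}

.guess_n <- function(spectrum) {
  td <- spectrum$tan_delta[order(spectrum$frequency_Hz)][1:min(3, nrow(spectrum))]
  plateau <- stats::median(td)
  min(max(2 / pi * atan(max(plateau, 1e-6)), 0.1), 0.95)
}

# ---------------------------------------------------------------------------

#' Fit one isothermal spectrum
#'
#' Minimises the unweighted sum of squared residuals between the composite
#' model and the data in the chosen representation (`tan_delta`: the global
#' loss-tangent function; `eps_imag`: the summed loss contributions), over
#' the free parameters only.  Fixed parameters (`b = 1` convention,
#' Arrhenius-pinned `f0`, fixed `eps_inf`) never move.  The best of the
#' seeded multi-start set is returned; the fit is deterministic for a given
#' seed.  Non-convergence of every start yields a result flagged
#' `converged = FALSE` (never a silent failure), and parameters pinned at a
#' bound are flagged in the parameter table.
#'
#' @param spectrum A single-temperature `bds_spectra` tibble.
#' @param config A [fit_config()].
#' @return An object of class `isotherm_fit`: the fitted
#'   [dielectric_model()], a parameter tibble (value, free flag, provenance,
#'   standard error when estimable, at-bound flag), the residual norm, the
#'   representation used, convergence information and per-process
#'   `unresolved` flags (dielectric strength below 1e-3 or relaxation
#'   frequency more than two decades outside the measured window).
#' @export
fit_isotherm <- function(spectrum, config) {
  stopifnot(inherits(config, "fit_config"))
  spectrum <- as_bds_spectra(spectrum)
  if (dplyr::n_distinct(spectrum$temperature_K) != 1L) {
    abort("`spectrum` must contain a single temperature; see split_isotherms().")
  }
  T_K <- spectrum$temperature_K[1]
  f <- spectrum$frequency_Hz
  ydata <- if (config$representation == "tan_delta") spectrum$tan_delta
           else spectrum$eps_imag

  eps_inf <- config$eps_inf %||%
    spectrum$eps_real[which.max(spectrum$frequency_Hz)]

  need_pick <- vapply(config$processes,
                      function(p) is.null(p$f0), logical(1))
  picked <- .pick_peaks(f, ydata, sum(need_pick))
  f0_inits <- list()
  j <- 0L
  for (p in config$processes) {
    if (is.null(p$f0)) { j <- j + 1L; f0_inits[[p$label]] <- picked[j] }
  }
  tbl <- .param_table(config, f0_inits, .guess_n(spectrum))

  n_free <- sum(tbl$free)
  if (nrow(spectrum) < 5L * max(n_free, 1L)) {
    warn(sprintf("Only %d points for %d free parameters (T = %.2f K).",
                 nrow(spectrum), n_free, T_K))
  }

  wts <- if ((config$weighting %||% "none") == "relative") {
    1 / pmax(abs(ydata), max(abs(ydata)) * 1e-9)
  } else {
    rep(1, length(ydata))
  }
  resid_fun <- function(par_free) {
    packed <- .pack(tbl$init, tbl)
    packed[tbl$free] <- par_free
    values <- .unpack(packed, tbl)
    m <- try(.model_from_values(values, tbl, eps_inf, config), silent = TRUE)
    if (inherits(m, "try-error")) return(rep(1e3, length(ydata)))
    e <- composite_eps(m, f)
    if (config$representation == "tan_delta") {
      er <- Re(e)
      if (any(er <= 0)) return(rep(1e3, length(ydata)))
      ((-Im(e) / er) - ydata) * wts
    } else {
      ((-Im(e)) - ydata) * wts
    }
  }

  lower <- .pack(tbl$lower, tbl)[tbl$free]
  upper <- .pack(tbl$upper, tbl)[tbl$free]
  start0 <- .pack(tbl$init, tbl)[tbl$free]

  starts <- list(start0)
  if (config$n_starts > 1L && n_free > 0L) {
    jit <- withr::with_seed(config$seed, {
      lapply(seq_len(config$n_starts - 1L), function(k) {
        s <- start0 + rnorm(n_free, 0, config$jitter_sd)
        pmin(pmax(s, lower), upper)
      })
    })
    starts <- c(starts, jit)
  }
  # Overlapping like-structured HN terms make the objective nearly invariant
  # under exchanging two processes' parameter blocks, creating permutation
  # local minima that random jitter rarely escapes.  Add one start per pair
  # of exchangeable (fully free, same b) processes whose initial relaxation
  # frequencies lie close enough to be confusable (within 2.5 decades), with
  # their (delta_eps, f0, a) blocks swapped.  Distant pairs are excluded:
  # seeding a process on top of another's well-separated peak only invites
  # degenerate peak-splitting solutions.
  ex <- which(vapply(config$processes, function(p) {
    p$free_delta && p$free_f0 && p$free_a
  }, logical(1)))
  ex_b <- vapply(ex, function(i) config$processes[[i]]$b, numeric(1))
  ex_lf0 <- vapply(ex, function(i) {
    log10(config$processes[[i]]$f0 %||% f0_inits[[config$processes[[i]]$label]])
  }, numeric(1))
  if (length(ex) >= 2L && n_free > 0L) {
    free_idx <- which(tbl$free)
    pos_of <- function(lbl) match(
      paste(lbl, c("delta_eps", "f0", "a")),
      paste(tbl$label, tbl$term)[free_idx])
    pairs <- utils::combn(seq_along(ex), 2L, simplify = FALSE)
    for (pr in pairs) {
      if (ex_b[pr[1]] != ex_b[pr[2]]) next
      if (abs(ex_lf0[pr[1]] - ex_lf0[pr[2]]) > 2.5) next
      i1 <- pos_of(config$processes[[ex[pr[1]]]]$label)
      i2 <- pos_of(config$processes[[ex[pr[2]]]]$label)
      ok <- !is.na(i1) & !is.na(i2)
      if (!any(ok)) next
      s <- start0
      s[c(i1[ok], i2[ok])] <- s[c(i2[ok], i1[ok])]
      starts <- c(starts, list(s))
    }
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iter, ftol = 1e-12, ptol = 1e-12)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort(sprintf("All optimisation starts failed at T = %.2f K.", T_K))
  }

  packed <- .pack(tbl$init, tbl)
  packed[tbl$free] <- best$par
  values <- .unpack(packed, tbl)
  model <- .model_from_values(values, tbl, eps_inf, config)

  # standard errors (delta method for log10-scale parameters)
  se_packed <- rep(NA_real_, n_free)
  dof <- length(ydata) - n_free
  if (dof > 0) {
    se_try <- try(sqrt(diag(solve(best$hessian)) * best$deviance / dof),
                  silent = TRUE)
    if (!inherits(se_try, "try-error") && all(is.finite(se_try))) {
      se_packed <- se_try
    }
  }
  se <- rep(NA_real_, nrow(tbl))
  se[tbl$free] <- se_packed
  se <- ifelse(tbl$log & !is.na(se), values * .ln10 * se, se)

  at_bound <- rep(FALSE, nrow(tbl))
  at_bound[tbl$free] <- (abs(best$par - lower) < 1e-8) |
    (abs(best$par - upper) < 1e-8)
  # a/b/n = 1 (Debye, ohmic) and sigma0 at its floor (no conduction) are
  # meaningful boundary values; only other pinned parameters are suspicious.
  natural <- (tbl$term %in% c("a", "b", "n") & abs(values - 1) < 1e-8) |
    tbl$term == "sigma0"
  if (any(at_bound & !natural)) {
    warn(sprintf("Parameter(s) pinned at a bound at T = %.2f K: %s.",
                 T_K, paste(tbl$term[at_bound & !natural], collapse = ", ")))
  }

  params <- tibble(
    term = c(tbl$term, "eps_inf"),
    label = c(tbl$label, "global"),
    value = c(values, eps_inf),
    free = c(tbl$free, FALSE),
    source = c(tbl$source,
               if (is.null(config$eps_inf)) "estimated:spectrum" else "fixed:dataset"),
    std_error = c(se, NA_real_),
    at_bound = c(at_bound, FALSE)
  )

  # A process is unresolved when its strength collapses, its frequency leaves
  # the measured window by more than two decades, or it cannot be
  # discriminated from a neighbouring process: within a third of a decade of
  # any stronger process, or within half a decade of one at least twice as
  # strong (a weak term under a dominant peak has no independent position).
  fwin <- range(f)
  de_all <- vapply(model$processes, `[[`, numeric(1), "delta_eps")
  lf_all <- log10(vapply(model$processes, `[[`, numeric(1), "f0"))
  unresolved <- vapply(seq_along(model$processes), function(i) {
    p <- model$processes[[i]]
    d <- abs(lf_all[i] - lf_all[-i])
    shadow <- length(lf_all) > 1L &&
      (any(d < 0.3 & de_all[i] < de_all[-i]) ||
         any(d < 0.5 & 2 * de_all[i] <= de_all[-i]))
    p$delta_eps < 1e-3 || p$f0 < fwin[1] * 1e-2 || p$f0 > fwin[2] * 1e2 ||
      shadow
  }, logical(1))
  unresolved <- vapply(model$processes, `[[`, character(1), "label")[unresolved]

  converged <- best$info %in% 1:4
  if (!converged) {
    warn(sprintf("No start converged at T = %.2f K (info = %d: %s).",
                 T_K, best$info, best$message))
  }

  structure(
    list(temperature_K = T_K, model = model, params = params,
         residual_norm = sqrt(best$deviance), deviance = best$deviance,
         representation = config$representation, converged = converged,
         info = best$info, message = best$message,
         n_points = length(ydata), n_free = n_free,
         freq_window = fwin,
         unresolved = unresolved),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    "<isotherm_fit>  T = %.2f K (%.1f C), %s fit, %d process(es), residual norm %.3g%s\n",
    x$temperature_K, celsius(x$temperature_K), x$representation,
    length(x$model$processes), x$residual_norm,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @rdname fit_isotherm
#' @param x An `isotherm_fit`.
#' @param ... Unused.
#' @export
tidy.isotherm_fit <- function(x, ...) {
  dplyr::mutate(x$params, temperature_K = x$temperature_K, .before = 1)
}

#' @rdname fit_isotherm
#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(
    temperature_K = x$temperature_K, n_points = x$n_points,
    n_free = x$n_free, residual_norm = x$residual_norm,
    representation = x$representation, converged = x$converged,
    n_unresolved = length(x$unresolved)
  )
}

#' Arrhenius-extrapolated relaxation frequency
#'
#' Evaluates a fitted Arrhenius law (see [fit_arrhenius()]) at temperature
#' `T_K`, for use as a pinned relaxation frequency in higher-temperature fits
#' once a fast process has left the measured window.
#'
#' @param fit An `arrhenius_fit`.
#' @param T_K Temperature(s) in kelvin.
#' @return Frequency in Hz.
#' @export
fix_process_frequency <- function(fit, T_K) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  10^(fit$log10_f_inf - fit$Ea_kJ_mol * 1000 / (.ln10 * .gas_R * T_K))
}

# label tracking -------------------------------------------------------------
#
# The composite model is invariant under permutation of like-structured HN
# terms, so per-isotherm optimisation cannot by itself keep a stable identity
# for overlapping processes (their relaxation frequencies may even cross in
# temperature).  Identity is therefore maintained the way an analyst reads a
# relaxation map: (i) across consecutive isotherms, fitted processes are
# re-matched to labels by closeness of (log10 f0, log10 delta_eps, a) to the
# previous isotherm's values; (ii) after the full series, whole tracks are
# assigned to labels by which declared temperature law (Arrhenius vs VFT)
# fits each track best.

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

.track_distance <- function(proc, w) {
  if (is.null(w)) return(9)
  ((log10(proc$f0) - log10(w$f0)) / 0.5)^2 +
    ((log10(proc$delta_eps) - log10(w$delta_eps)) / 0.3)^2 +
    ((proc$a - w$a) / 0.1)^2
}

# relabel the processes of an isotherm_fit according to `mapping`
# (named character vector old label -> new label)
.relabel_fit <- function(r, mapping) {
  ren <- function(x) ifelse(x %in% names(mapping), mapping[x], x)
  r$model$processes <- lapply(r$model$processes, function(p) {
    p$label <- unname(ren(p$label)); p
  })
  r$params$label <- unname(ren(r$params$label))
  r$unresolved <- unname(ren(r$unresolved))
  r
}

# best permutation of exchangeable process labels against warm-start state
.match_labels <- function(r, specs, warm) {
  ex <- which(vapply(specs, function(s) {
    s$free_f0 && s$free_delta && s$free_a
  }, logical(1)))
  if (length(ex) < 2L) return(r)
  labels <- vapply(specs[ex], `[[`, character(1), "label")
  procs <- r$model$processes[ex]
  b_vals <- vapply(procs, `[[`, numeric(1), "b")
  for (bv in unique(b_vals)) {
    idx <- which(b_vals == bv)
    if (length(idx) < 2L) next
    perms <- .permutations(length(idx))
    cost <- vapply(perms, function(p) {
      sum(vapply(seq_along(idx), function(i) {
        .track_distance(procs[[idx[i]]], warm[[labels[idx[p[i]]]]])
      }, numeric(1)))
    }, numeric(1))
    best <- perms[[which.min(cost)]]
    if (!identical(best, seq_along(idx))) {
      mapping <- setNames(labels[idx[best]], labels[idx])
      mapping <- mapping[mapping != names(mapping)]
      r <- .relabel_fit(r, mapping)
    }
  }
  r
}

# end-of-series assignment of tracks to labels by declared temperature law,
# with a declared slowness ordering (slowest label first) breaking ties
# between labels sharing the same law
.disambiguate_tracks <- function(fits, map_laws, order = NULL,
                                 min_overlap = 3L) {
  if (is.null(map_laws)) return(fits)
  map <- build_relaxation_map(fits)
  map <- map[map$provenance == "fitted" & map$in_window, ]
  labels <- intersect(names(map_laws), unique(map$process_label))
  if (length(labels) < 2L) return(fits)
  temps <- lapply(labels, function(l) map$temperature_K[map$process_label == l])
  names(temps) <- labels

  # connected components of labels whose tracks overlap in temperature
  overlap <- function(a, b) length(intersect(temps[[a]], temps[[b]]))
  comp <- as.list(labels)
  repeat {
    merged <- FALSE
    for (i in seq_along(comp)) {
      for (j in seq_along(comp)) {
        if (j <= i) next
        if (any(outer(comp[[i]], comp[[j]], Vectorize(overlap)) >= min_overlap)) {
          comp[[i]] <- c(comp[[i]], comp[[j]]); comp[[j]] <- NULL
          merged <- TRUE; break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  # Robust assignment cost: fit the law on a trimmed point set, then sum
  # capped squared residuals over all points.  Stray map entries (window
  # edges, unresolved crossings) then contribute a bounded, law-independent
  # offset, and the assignment is decided by how the clean points follow the
  # law (an Arrhenius line fitted to a curved structural track misfits
  # systematically; the reverse does not).
  law_rss <- function(law, pts) {
    n_min <- if (law == "vft") 4L else 3L
    if (nrow(pts) < n_min) return(Inf)
    resid_of <- function(ft, pp) {
      pred <- if (inherits(ft, "vft_fit")) {
        ft$log10_f_inf - ft$B / (.ln10 * (pp$temperature_K - ft$T0))
      } else {
        ft$log10_f_inf -
          ft$Ea_kJ_mol * 1000 / (.ln10 * .gas_R * pp$temperature_K)
      }
      log10(pp$f0_Hz) - pred
    }
    fit1 <- function(pp) tryCatch(
      suppressWarnings(if (law == "vft") fit_vft(pp) else fit_arrhenius(pp)),
      error = function(e) NULL)
    ft <- fit1(pts)
    if (is.null(ft)) return(Inf)
    res <- resid_of(ft, pts)
    keep <- abs(res) <= 3 * max(stats::mad(res), 1e-6)
    if (sum(keep) >= n_min && any(!keep)) {
      ft2 <- fit1(pts[keep, ])
      if (!is.null(ft2)) ft <- ft2
    }
    sum(pmin(resid_of(ft, pts)^2, 0.25))
  }

  # order violations of an assignment: for each declared-slower pair of
  # labels, compare their assigned tracks' log10 f0 over shared temperatures
  order_violations <- function(grp, tracks, p) {
    if (is.null(order)) return(0L)
    pos <- match(grp, order)
    v <- 0L
    for (i in seq_along(grp)) {
      for (j in seq_along(grp)) {
        if (i == j || is.na(pos[i]) || is.na(pos[j]) || pos[i] >= pos[j]) next
        ti <- tracks[[p[i]]]; tj <- tracks[[p[j]]]
        shared <- intersect(ti$temperature_K, tj$temperature_K)
        if (length(shared) < 2L) next
        di <- ti$log10_f0[match(shared, ti$temperature_K)]
        dj <- tj$log10_f0[match(shared, tj$temperature_K)]
        if (stats::median(di - dj) > 0) v <- v + 1L  # slower label is faster
      }
    }
    v
  }

  for (grp in comp) {
    if (length(grp) < 2L) next
    distinct_laws <- length(unique(map_laws[grp])) >= 2L
    if (!distinct_laws && is.null(order)) next
    tracks <- lapply(grp, function(l) map[map$process_label == l, ])
    perms <- .permutations(length(grp))
    cost <- vapply(perms, function(p) {
      sum(vapply(seq_along(grp), function(i) {
        law_rss(unname(map_laws[grp[i]]), tracks[[p[i]]])
      }, numeric(1)))
    }, numeric(1))
    if (all(!is.finite(cost))) next
    # near-ties on the law criterion are decided by the declared slowness
    # ordering, then by preferring the identity assignment
    near <- which(cost <= min(cost[is.finite(cost)]) + 0.05)
    viol <- vapply(perms[near], function(p) order_violations(grp, tracks, p),
                   integer(1))
    near <- near[viol == min(viol)]
    ident <- which(vapply(perms, identical, logical(1), seq_along(grp)))
    best <- if (ident %in% near) ident else near[1]
    p <- perms[[best]]
    if (!identical(p, seq_along(grp))) {
      # label grp[i] takes the track currently labelled grp[p[i]]
      mapping <- setNames(grp, grp[p])
      mapping <- mapping[mapping != names(mapping)]
      fits <- lapply(fits, .relabel_fit, mapping = mapping)
    }
  }
  fits
}

# lost-process re-seeding -----------------------------------------------------
#
# A process can come out of an isotherm fit "lost": its strength pinned at a
# bound, flagged unresolved, or parked on top of another process as a
# lower-strength shadow, while its real spectral signature sits unfitted
# elsewhere in the window.  Re-seed such a process at the frequency where the
# model-without-it underfits the data most, refit, and keep the refit only if
# it improves the deviance.

.lost_labels <- function(r, specs) {
  free_lbl <- vapply(specs[vapply(specs, `[[`, logical(1), "free_f0")],
                     `[[`, character(1), "label")
  procs <- r$model$processes
  lbl <- vapply(procs, `[[`, character(1), "label")
  de <- vapply(procs, `[[`, numeric(1), "delta_eps")
  lf <- log10(vapply(procs, `[[`, numeric(1), "f0"))
  lost <- logical(length(procs))
  for (i in seq_along(procs)) {
    if (!(lbl[i] %in% free_lbl)) next
    at_bnd <- any(r$params$at_bound[r$params$label == lbl[i] &
                                      r$params$term %in% c("delta_eps", "f0")])
    shadow <- any(abs(lf[i] - lf[-i]) < 0.3 & de[i] < de[-i])
    lost[i] <- at_bnd || shadow || lbl[i] %in% r$unresolved
  }
  lbl[lost]
}

.reseed_once <- function(iso, r, specs, config, lbl) {
  ydata <- if (config$representation == "tan_delta") iso$tan_delta
           else iso$eps_imag
  f <- iso$frequency_Hz
  wts <- if ((config$weighting %||% "none") == "relative") {
    1 / pmax(abs(ydata), max(abs(ydata)) * 1e-9)
  } else {
    rep(1, length(ydata))
  }
  keep <- vapply(r$model$processes, function(p) p$label != lbl, logical(1))
  m0 <- dielectric_model(r$model$eps_inf, r$model$processes[keep],
                         r$model$conductivity)
  e <- composite_eps(m0, f)
  pred <- if (config$representation == "tan_delta") -Im(e) / Re(e) else -Im(e)
  res <- (ydata - pred) * wts
  k <- min(5L, length(res))
  sm <- as.numeric(stats::filter(res, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- res[is.na(sm)]
  full_rms <- r$residual_norm / sqrt(length(ydata))
  if (max(sm) < 3 * full_rms) return(NULL)
  i_new <- which.max(sm)
  er <- iso$eps_real[i_new]
  miss <- sm[i_new] / wts[i_new]   # underfit in the data's own scale
  delta_new <- if (config$representation == "tan_delta") {
    max(2 * miss * er, 0.1)
  } else {
    max(2 * miss, 0.1)
  }
  specs2 <- lapply(specs, function(s) {
    if (s$label == lbl) {
      s$f0 <- f[i_new]
      s$delta_eps <- min(delta_new, 1e3)
      s$a <- 0.6
    } else {
      # warm-start the others from the current fit
      p <- r$model$processes[[which(vapply(r$model$processes, `[[`,
                                           character(1), "label") == s$label)]]
      if (s$free_delta) s$delta_eps <- p$delta_eps
      if (s$free_f0) s$f0 <- p$f0
      if (s$free_a) s$a <- p$a
    }
    s
  })
  config2 <- config
  config2$processes <- specs2
  config2$n_starts <- 2L
  if (!is.null(r$model$conductivity)) {
    config2$sigma0 <- r$model$conductivity$sigma0
    config2$n <- r$model$conductivity$n
  }
  r2 <- fit_isotherm(iso, config2)
  if (r2$deviance < r$deviance) r2 else NULL
}

# dataset-level fitting -------------------------------------------------------

#' Fit plan for a temperature series
#'
#' Declares which labelled processes are active in which temperature range
#' (the analyst's by-inspection choice of process count), when each process's
#' relaxation frequency is pinned by Arrhenius extrapolation, and the
#' representation and temperature laws used downstream.
#'
#' @param activity A tibble with columns `label`, `t_on_K` (first temperature
#'   the process is included), `t_fix_K` (temperature from which its `f0` is
#'   pinned to the Arrhenius extrapolation of its lower-temperature fits;
#'   `Inf` = never), `t_off_K` (temperature above which it is dropped;
#'   `Inf` = never), and optionally `delta_init`, `a_init`, `b`.
#' @param include_conductivity Include the conductivity term at every
#'   temperature.
#' @param representation `"tan_delta"` or `"eps_imag"`.
#' @param map_laws Named character vector label -> `"arrhenius"`/`"vft"`,
#'   the temperature law to fit to each process's relaxation map.
#' @param order Optional character vector of labels from slowest to fastest
#'   process: the analyst's interpretive ordering (e.g. electrode
#'   polarization is the slowest apparent relaxation), used to resolve
#'   track-label assignment ties between processes that share a law.
#' @param eps_inf Fixed unrelaxed permittivity, or `NULL` to estimate it from
#'   the dataset via [estimate_eps_inf()].
#' @param n_starts,jitter_sd Multi-start settings passed to [fit_config()].
#' @return An object of class `bds_fit_plan`.
#' @seealso [derive_plan()], [fit_dataset()]
#' @export
fit_plan <- function(activity, include_conductivity = TRUE,
                     representation = c("tan_delta", "eps_imag"),
                     weighting = c("none", "relative"),
                     map_laws = NULL, order = NULL, eps_inf = NULL,
                     n_starts = 5, jitter_sd = 0.3) {
  representation <- match.arg(representation)
  weighting <- match.arg(weighting)
  activity <- as_tibble(activity)
  stopifnot(all(c("label", "t_on_K", "t_fix_K", "t_off_K") %in% names(activity)))
  if (!"delta_init" %in% names(activity)) activity$delta_init <- 1
  if (!"a_init" %in% names(activity)) activity$a_init <- 0.5
  if (!"b" %in% names(activity)) activity$b <- 1
  structure(
    list(activity = activity, include_conductivity = include_conductivity,
         representation = representation, weighting = weighting,
         map_laws = map_laws, order = order,
         eps_inf = eps_inf, n_starts = n_starts, jitter_sd = jitter_sd),
    class = "bds_fit_plan"
  )
}

#' Derive a fit plan from a synthetic protocol
#'
#' Automates the by-inspection windowing step for synthetic studies: a
#' process is included once its generating law's relaxation frequency
#' approaches the measured window from below (`f0 >= f_entry`), pinned by
#' Arrhenius extrapolation once it leaves above the window top
#' (`f0 > f_fix`), and dropped once it is far above it (`f0 > f_drop`, two
#' decades beyond the top by default, matching the unresolved-flag rule of
#' [fit_isotherm()]).  Map entries from pinned temperatures carry
#' `"fixed:arrhenius"` provenance and are excluded from later law fits.  Initial strengths and shapes
#' are deliberately generic (`delta_eps = 1`, `a = 0.5`), not the generating
#' values, so parameter recovery remains a genuine optimisation result.
#'
#' @param protocol A [synthetic_protocol()].
#' @param f_entry,f_fix,f_drop Window-entry, pin and drop thresholds in Hz.
#' @inheritParams fit_plan
#' @return A [fit_plan()].
#' @export
derive_plan <- function(protocol, f_entry = 0.05, f_fix = 1e6, f_drop = 1e8,
                        representation = "tan_delta", weighting = "relative",
                        n_starts = 5, jitter_sd = 0.3) {
  stopifnot(inherits(protocol, "synthetic_protocol"))
  temps <- protocol_temperatures(protocol)
  first_at <- function(cond) if (any(cond, na.rm = TRUE)) temps[which(cond)[1]] else Inf
  rows <- lapply(protocol$processes, function(pl) {
    f0 <- law_frequency(pl, temps)
    tibble(
      label = pl$label,
      t_on_K = first_at(!is.na(f0) & f0 >= f_entry),
      t_fix_K = first_at(!is.na(f0) & f0 > f_fix),
      t_off_K = first_at(!is.na(f0) & f0 > f_drop)
    )
  })
  activity <- dplyr::bind_rows(rows)
  activity$t_off_K <- ifelse(is.infinite(activity$t_off_K), Inf,
                             activity$t_off_K - 1e-9)
  map_laws <- setNames(
    vapply(protocol$processes, `[[`, character(1), "law"),
    vapply(protocol$processes, `[[`, character(1), "label")
  )
  # declared slowness ordering (slowest first) at the top of the measured
  # range: breaks label-assignment ties between processes sharing a law
  f_top <- vapply(protocol$processes, law_frequency, numeric(1),
                  T_K = max(temps))
  order <- names(map_laws)[base::order(f_top)]
  fit_plan(activity,
           include_conductivity = !is.null(protocol$conductivity),
           representation = representation, weighting = weighting,
           map_laws = map_laws, order = order,
           n_starts = n_starts, jitter_sd = jitter_sd)
}

#' Fit a full temperature series
#'
#' Executes the staged protocol over all isotherms in ascending temperature
#' order: eps_inf estimation, low-temperature fits of the processes active
#' there, Arrhenius pre-fit of each process that leaves the window and pinning
#' of its extrapolated frequency in subsequent fits, with warm-started
#' initial values carried from the previous isotherm (newly entering
#' processes start at the low-frequency window edge).  Every result carries
#' full per-parameter provenance.
#'
#' @param spectra A `bds_spectra` tibble (see [read_spectra()],
#'   [generate_dataset()]).
#' @param plan A [fit_plan()] or [derive_plan()] result.
#' @param seed Base seed; each isotherm's multi-start uses `seed + index`.
#' @return An object of class `bds_fit_set`: list of `isotherm_fit`s plus the
#'   eps_inf used and the plan.
#' @export
fit_dataset <- function(spectra, plan, seed = 1L, refine = TRUE) {
  stopifnot(inherits(plan, "bds_fit_plan"))
  spectra <- as_bds_spectra(spectra)
  isos <- split_isotherms(spectra)
  ord <- order(vapply(isos, function(s) s$temperature_K[1], numeric(1)))
  isos <- isos[ord]

  eps_inf <- plan$eps_inf %||% estimate_eps_inf(spectra)

  run_sweep <- function(predictor, seed_base) {
    warm <- list()       # label -> list(delta_eps, f0, a), last accepted
    warm_cond <- NULL    # list(sigma0, n)
    arr_points <- list() # label -> tibble(temperature_K, f0_Hz)
    track <- list()      # label -> tibble(T_K, lf0, lde, a)
    fits <- list()

    # reference state for label matching: the predictor when available,
    # else a short linear extrapolation of the track's log10 f0 in 1/T
    # (so tracks crossing in temperature keep their identity by trend)
    track_refs <- function(T_K) {
      refs <- list()
      lbls <- union(names(track),
                    if (is.null(predictor)) character(0) else names(predictor))
      for (lbl in lbls) {
        pr <- if (!is.null(predictor)) predictor[[lbl]](T_K) else NULL
        if (!is.null(pr)) { refs[[lbl]] <- pr; next }
        h <- track[[lbl]]
        if (is.null(h)) next
        h <- utils::tail(h, 4L)
        lf0 <- if (nrow(h) >= 2L) {
          unname(predict(lm(lf0 ~ I(1 / T_K), data = h),
                         newdata = data.frame(T_K = T_K)))
        } else h$lf0[nrow(h)]
        refs[[lbl]] <- list(f0 = 10^lf0,
                            delta_eps = 10^h$lde[nrow(h)],
                            a = h$a[nrow(h)])
      }
      refs
    }

    for (i in seq_along(isos)) {
      iso <- isos[[i]]
      T_K <- iso$temperature_K[1]
      act <- plan$activity[plan$activity$t_on_K <= T_K &
                             T_K <= plan$activity$t_off_K, ]
      if (!nrow(act) && !plan$include_conductivity) {
        warn(sprintf("No active process at T = %.2f K; isotherm skipped.", T_K))
        next
      }
      specs <- list()
      for (j in seq_len(nrow(act))) {
        lbl <- act$label[j]
        pr <- if (!is.null(predictor) && !is.null(predictor[[lbl]])) {
          predictor[[lbl]](T_K)
        } else NULL
        w <- pr %||% warm[[lbl]]
        pin <- T_K >= act$t_fix_K[j]
        arr <- NULL
        if (pin && is.null(pr)) {
          pts <- arr_points[[lbl]]
          if (!is.null(pts) && nrow(pts) >= 2L) {
            arr <- fit_arrhenius(pts)
          } else {
            warn(sprintf(
              "Cannot pin '%s' at T = %.2f K (<2 lower-T points); kept free.",
              lbl, T_K))
            pin <- FALSE
          }
        }
          f0_init <- if (pin) {
          # refined passes pin at the declared-law extrapolation when the
          # label's law is available, else at the Arrhenius pre-fit
          if (!is.null(pr)) pr$f0 else fix_process_frequency(arr, T_K)
        } else {
          w$f0 %||% (2 * min(iso$frequency_Hz))
        }
        # once a pinned process has moved far above the window its wing is a
        # known background: freeze its strength and shape too, so it
        # contributes no degenerate freedom to the fit
        out_far <- pin && f0_init > 100 * max(iso$frequency_Hz)
        specs[[length(specs) + 1L]] <- process_spec(
          label = lbl,
          delta_eps = w$delta_eps %||% act$delta_init[j],
          f0 = f0_init,
          a = w$a %||% act$a_init[j],
          b = act$b[j],
          free_delta = !out_far,
          free_f0 = !pin,
          free_a = !pin && !isTRUE(w$fix_a),
          f0_source = if (pin) "fixed:arrhenius" else "init"
        )
      }
      config <- fit_config(
        processes = specs,
        include_conductivity = plan$include_conductivity,
        sigma0 = warm_cond$sigma0 %||% 1e-12,
        n = warm_cond$n,
        eps_inf = eps_inf,
        representation = plan$representation,
        weighting = plan$weighting %||% "none",
        n_starts = plan$n_starts, jitter_sd = plan$jitter_sd,
        seed = seed_base + i
      )
      r <- fit_isotherm(iso, config)

      refs <- track_refs(T_K)
      r <- .match_labels(r, specs, refs)
      for (attempt in 1:2) {
        lost <- .lost_labels(r, specs)
        if (!length(lost)) break
        r2 <- .reseed_once(iso, r, specs, config, lost[1])
        if (is.null(r2)) break
        r <- .match_labels(r2, specs, refs)
      }
      fits[[length(fits) + 1L]] <- r

      for (p in r$model$processes) {
        spec_j <- which(vapply(specs, `[[`, character(1), "label") == p$label)
        free_f0 <- specs[[spec_j]]$free_f0
        if (p$label %in% r$unresolved) next
        warm[[p$label]] <- list(delta_eps = p$delta_eps, f0 = p$f0, a = p$a)
        if (free_f0 && r$converged) {
          arr_points[[p$label]] <- dplyr::bind_rows(
            arr_points[[p$label]],
            tibble(temperature_K = T_K, f0_Hz = p$f0)
          )
          track[[p$label]] <- dplyr::bind_rows(
            track[[p$label]],
            tibble(T_K = T_K, lf0 = log10(p$f0),
                   lde = log10(p$delta_eps), a = p$a)
          )
        }
      }
      if (!is.null(r$model$conductivity)) {
        warm_cond <- list(sigma0 = r$model$conductivity$sigma0,
                          n = r$model$conductivity$n)
      }
    }

    .disambiguate_tracks(fits, plan$map_laws, order = plan$order)
  }

  fits <- run_sweep(NULL, as.integer(seed))
  n_refine <- if (is.logical(refine)) as.integer(refine) else
    as.integer(refine)
  for (pass in seq_len(n_refine)) {
    predictor <- .law_predictor(fits, plan)
    if (!length(predictor)) break
    fits <- run_sweep(predictor, as.integer(seed) + 10000L * pass)
  }

  structure(list(fits = fits, eps_inf = eps_inf, plan = plan),
            class = "bds_fit_set")
}

# Build per-label initial-value predictors from a first-pass fit: relaxation
# frequency from the label's fitted temperature law, strength and shape by
# interpolation of its accepted first-pass values.  Labels whose law could
# not be fitted get no predictor.
.law_predictor <- function(fits, plan) {
  map <- build_relaxation_map(fits)
  laws <- tryCatch(
    suppressWarnings(fit_relaxation_laws(map, laws = plan$map_laws)),
    error = function(e) NULL)
  if (is.null(laws) || !nrow(laws)) return(list())

  # strength/shape statistics come from the clean core of each track:
  # resolved entries whose relaxation frequency lies inside the window
  par_tbl <- dplyr::bind_rows(lapply(fits, function(r) {
    lbl <- vapply(r$model$processes, `[[`, character(1), "label")
    f0 <- vapply(r$model$processes, `[[`, numeric(1), "f0")
    fwin <- r$freq_window %||% c(-Inf, Inf)
    keep <- !(lbl %in% r$unresolved) & f0 >= fwin[1] & f0 <= fwin[2]
    if (!any(keep)) return(NULL)
    tibble(
      label = lbl[keep],
      T_K = r$temperature_K,
      delta_eps = vapply(r$model$processes, `[[`, numeric(1), "delta_eps")[keep],
      a = vapply(r$model$processes, `[[`, numeric(1), "a")[keep]
    )
  }))

  predictor <- list()
  for (k in seq_len(nrow(laws))) {
    lbl <- laws$process_label[k]
    ft <- laws$fit[[k]]
    if (inherits(ft, "vft_fit") && ft$flagged) next
    h <- par_tbl[par_tbl$label == lbl, ]
    if (nrow(h) < 2L) next
    predictor[[lbl]] <- local({
      ft_k <- ft
      de_fun <- stats::approxfun(h$T_K, h$delta_eps, rule = 2)
      # HN shape exponents are temperature-independent to good approximation;
      # when the previous pass estimated a process's width exponent stably,
      # the refinement pass pins a at its median, removing the
      # shape-versus-frequency trade that destabilises weak shoulder
      # processes.  An unstable shape estimate (wide IQR) stays free.
      a_med <- stats::median(h$a)
      a_stable <- nrow(h) >= 5L && diff(stats::quantile(h$a, c(.25, .75))) <= 0.15
      f0_fun <- if (inherits(ft_k, "vft_fit")) {
        function(T_K) vft_frequency(ft_k, T_K)
      } else {
        function(T_K) fix_process_frequency(ft_k, T_K)
      }
      a_fun <- stats::approxfun(h$T_K, h$a, rule = 2)
      function(T_K) {
        f0 <- f0_fun(T_K)
        if (is.na(f0) || f0 <= 0) return(NULL)
        if (a_stable) {
          list(delta_eps = de_fun(T_K), f0 = f0, a = a_med, fix_a = TRUE)
        } else {
          list(delta_eps = de_fun(T_K), f0 = f0, a = a_fun(T_K))
        }
      }
    })
  }
  predictor
}

#' @export
print.bds_fit_set <- function(x, ...) {
  ok <- vapply(x$fits, `[[`, logical(1), "converged")
  cat(sprintf("<bds_fit_set>  %d isotherms (%d converged), eps_inf = %.4g\n",
              length(x$fits), sum(ok), x$eps_inf))
  invisible(x)
}

#' @rdname fit_dataset
#' @param x A `bds_fit_set`.
#' @param ... Unused.
#' @export
tidy.bds_fit_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, tidy))
}

#' @rdname fit_dataset
#' @export
glance.bds_fit_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, glance))
}
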