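# Global law-constrained refinement.
#
# The staged per-isotherm protocol treats every isotherm independently, so
# each relaxation frequency carries the single-isotherm statistical
# uncertainty — appreciable for a weak process overlapping a stronger one.
# Since each process's relaxation frequency follows a smooth temperature law
# (Arrhenius or VFT) and its HN shape is temperature independent, the
# statistically efficient estimator fits those laws against all isotherms
# simultaneously.  This stage takes the staged results as its starting point
# and refines, per labelled process, the law parameters, one dielectric
# strength and one width exponent, by least squares on the stacked
# loss-tangent (or loss) residuals of the entire temperature series.  The
# conductivity parameters stay at their per-isotherm estimates: they shape
# only the low-frequency upturn and are well determined where they matter.

#' Global temperature-law fit across all isotherms
#'
#' Refines the temperature law of every labelled process against the full
#' spectra table at once.  Parameters per process: the law parameters
#' (`log10_f_inf`, `Ea` or `B`, `T0`), one dielectric strength and one width
#' exponent (`b` stays at the plan's fixed value); the unrelaxed permittivity
#' and the per-isotherm conductivity parameters are held at the staged
#' estimates.  Initial values come from a [fit_dataset()] result; the fit is
#' a single bounded Levenberg-Marquardt run and is deterministic.
#'
#' @param spectra The `bds_spectra` tibble the staged fit was run on.
#' @param fits A `bds_fit_set` from [fit_dataset()].
#' @param plan The [fit_plan()] used (declares each label's law and `b`).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `bds_global_fit`: a `laws` tibble (one row per
#'   process: law type, parameters, derived `tg_C` and `fragility_m` for VFT
#'   laws, `Ea_kJ_mol` for Arrhenius laws, plus the refined `delta_eps` and
#'   `a`), the stacked-residual deviance, and a `predict_f0` function
#'   (label, temperature) for the refined laws.
#' @seealso [fit_dataset()], [fit_relaxation_laws()]
#' @export
fit_global_laws <- function(spectra, fits, plan, max_iter = 150) {
  stopifnot(inherits(fits, "bds_fit_set"), inherits(plan, "bds_fit_plan"))
  spectra <- as_bds_spectra(spectra)
  isos <- split_isotherms(spectra)
  ord <- order(vapply(isos, function(s) s$temperature_K[1], numeric(1)))
  isos <- isos[ord]
  temps <- vapply(isos, function(s) s$temperature_K[1], numeric(1))

  representation <- plan$representation
  relative <- (plan$weighting %||% "none") == "relative"
  eps_inf <- fits$eps_inf

  map <- build_relaxation_map(fits)
  laws0 <- suppressWarnings(fit_relaxation_laws(map, laws = plan$map_laws))
  if (!nrow(laws0)) abort("No process law could be initialised from the staged fits.")

  # strength/shape starting values: clean-core medians per label
  par_tbl <- dplyr::bind_rows(lapply(fits$fits, function(r) {
    lbl <- vapply(r$model$processes, `[[`, character(1), "label")
    f0 <- vapply(r$model$processes, `[[`, numeric(1), "f0")
    fwin <- r$freq_window %||% c(-Inf, Inf)
    keep <- !(lbl %in% r$unresolved) & f0 >= fwin[1] & f0 <= fwin[2]
    if (!any(keep)) return(NULL)
    tibble(label = lbl[keep],
           delta_eps = vapply(r$model$processes, `[[`, numeric(1),
                              "delta_eps")[keep],
           a = vapply(r$model$processes, `[[`, numeric(1), "a")[keep])
  }))

  # per-isotherm conductivity starting values (co-estimated below: fixing
  # them would push their errors into the law parameters)
  conds0 <- lapply(fits$fits, function(r) r$model$conductivity)
  names(conds0) <- as.character(vapply(fits$fits, `[[`, numeric(1),
                                       "temperature_K"))
  with_cond <- plan$include_conductivity && length(conds0) > 0

  b_of <- setNames(plan$activity$b, plan$activity$label)

  # every planned process with any accepted entries must enter the global
  # model; a label whose trimmed law fit was unavailable falls back to an
  # untrimmed fit of its raw map points
  map_free <- map[map$provenance != "fixed:arrhenius" & map$in_window, ]
  law_of <- setNames(plan$map_laws[plan$activity$label], plan$activity$label)
  law_of[is.na(law_of)] <- "arrhenius"

  init_law <- function(lbl) {
    k <- which(laws0$process_label == lbl)
    if (length(k)) return(laws0[k, ])
    pts <- map_free[map_free$process_label == lbl, ]
    n_min <- if (law_of[[lbl]] == "vft") 3L else 2L
    if (nrow(pts) < n_min) return(NULL)
    ft <- tryCatch(suppressWarnings(
      if (law_of[[lbl]] == "vft") fit_vft(pts) else fit_arrhenius(pts)),
      error = function(e) NULL)
    if (is.null(ft)) return(NULL)
    if (inherits(ft, "vft_fit")) {
      tibble(process_label = lbl, law = "vft", log10_f_inf = ft$log10_f_inf,
             B = ft$B, T0 = ft$T0, Ea_kJ_mol = NA_real_)
    } else {
      tibble(process_label = lbl, law = "arrhenius",
             log10_f_inf = ft$log10_f_inf, B = NA_real_, T0 = NA_real_,
             Ea_kJ_mol = ft$Ea_kJ_mol)
    }
  }

  # parameter vector layout ---------------------------------------------
  specs <- list()
  add <- function(name, init, lower, upper) {
    specs[[length(specs) + 1L]] <<- list(name = name, init = init,
                                         lower = lower, upper = upper)
  }
  labels <- character(0)
  for (lbl in plan$activity$label) {
    h <- par_tbl[par_tbl$label == lbl, ]
    lw <- init_law(lbl)
    if (!nrow(h) || is.null(lw)) {
      warn(sprintf("Process '%s' has no usable staged estimates; omitted from the global fit.",
                   lbl))
      next
    }
    labels <- c(labels, lbl)
    if (lw$law == "vft") {
      add(paste0(lbl, ".lf"), lw$log10_f_inf, -5, 30)
      add(paste0(lbl, ".B"), max(lw$B, 10), 1, 1e5)
      add(paste0(lbl, ".T0"), min(max(lw$T0, 1), max(temps) - 60),
          0, max(temps) - 50)
    } else {
      add(paste0(lbl, ".lf"), lw$log10_f_inf, -5, 30)
      add(paste0(lbl, ".Ea"), max(lw$Ea_kJ_mol, 1), 0.5, 400)
    }
    add(paste0(lbl, ".lde"), log10(stats::median(h$delta_eps)), -4, 4)
    add(paste0(lbl, ".a"), stats::median(h$a), 0.05, 1)
    law_of[[lbl]] <- lw$law
  }
  if (!length(labels)) abort("No refinable process found.")
  if (with_cond) {
    for (i in seq_along(temps)) {
      c0 <- conds0[[as.character(temps[i])]]
      add(paste0("cond", i, ".lsig"),
          log10(max(c0$sigma0 %||% 1e-14, 1e-20)), -20, 2)
      add(paste0("cond", i, ".n"), c0$n %||% 0.8, 0.05, 1)
    }
  }
  p_names <- vapply(specs, `[[`, character(1), "name")
  p_init <- vapply(specs, `[[`, numeric(1), "init")
  p_lower <- vapply(specs, `[[`, numeric(1), "lower")
  p_upper <- vapply(specs, `[[`, numeric(1), "upper")
  p_init <- pmin(pmax(p_init, p_lower), p_upper)

  f0_from <- function(par, lbl, T_K) {
    if (law_of[[lbl]] == "vft") {
      T0 <- par[[paste0(lbl, ".T0")]]
      ifelse(T_K > T0 + 1e-3,
             10^(par[[paste0(lbl, ".lf")]] -
                   par[[paste0(lbl, ".B")]] / (.ln10 * (T_K - T0))),
             NA_real_)
    } else {
      10^(par[[paste0(lbl, ".lf")]] -
            par[[paste0(lbl, ".Ea")]] * 1000 / (.ln10 * .gas_R * T_K))
    }
  }

  resid_fun <- function(p) {
    par <- as.list(setNames(p, p_names))
    out <- vector("list", length(isos))
    for (i in seq_along(isos)) {
      iso <- isos[[i]]
      T_K <- temps[i]
      f <- iso$frequency_Hz
      e <- rep(eps_inf + 0i, length(f))
      bad <- FALSE
      for (lbl in labels) {
        f0 <- f0_from(par, lbl, T_K)
        if (is.na(f0) || f0 < 1e-10) next
        de <- 10^par[[paste0(lbl, ".lde")]]
        a <- par[[paste0(lbl, ".a")]]
        e <- e + de / (1 + (1i * f / f0)^a)^(b_of[[lbl]] %||% 1)
      }
      if (with_cond) {
        sig <- 10^par[[paste0("cond", i, ".lsig")]]
        ncnd <- par[[paste0("cond", i, ".n")]]
        e <- e + sig / (.eps0 * (2i * pi * f)^ncnd)
      }
      ydata <- if (representation == "tan_delta") iso$tan_delta else iso$eps_imag
      pred <- if (representation == "tan_delta") {
        er <- Re(e)
        if (any(er <= 0)) bad <- TRUE
        -Im(e) / er
      } else {
        -Im(e)
      }
      w <- if (relative) 1 / pmax(abs(ydata), max(abs(ydata)) * 1e-9) else 1
      out[[i]] <- if (bad) rep(1e3, length(ydata)) else (pred - ydata) * w
    }
    unlist(out)
  }

  # restart the trust region from the current iterate until converged
  cur <- p_init
  n_iter <- 0L
  for (round in 1:4) {
    fit <- minpack.lm::nls.lm(
      par = cur, lower = p_lower, upper = p_upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-12, ptol = 1e-12)
    )
    cur <- fit$par
    n_iter <- n_iter + fit$niter
    if (fit$info %in% 1:4) break
  }
  par <- as.list(setNames(fit$par, p_names))

  rows <- lapply(labels, function(lbl) {
    if (law_of[[lbl]] == "vft") {
      vf <- vft_params(par[[paste0(lbl, ".lf")]], par[[paste0(lbl, ".B")]],
                       par[[paste0(lbl, ".T0")]])
      tibble(process_label = lbl, law = "vft",
             log10_f_inf = vf$log10_f_inf, B = vf$B, T0 = vf$T0,
             Ea_kJ_mol = NA_real_, tg_C = vf$tg_C,
             fragility_m = vf$fragility_m,
             delta_eps = 10^par[[paste0(lbl, ".lde")]],
             a = par[[paste0(lbl, ".a")]])
    } else {
      tibble(process_label = lbl, law = "arrhenius",
             log10_f_inf = par[[paste0(lbl, ".lf")]], B = NA_real_,
             T0 = NA_real_, Ea_kJ_mol = par[[paste0(lbl, ".Ea")]],
             tg_C = NA_real_, fragility_m = NA_real_,
             delta_eps = 10^par[[paste0(lbl, ".lde")]],
             a = par[[paste0(lbl, ".a")]])
    }
  })

  out <- structure(
    list(
      laws = dplyr::bind_rows(rows),
      deviance = fit$deviance,
      converged = fit$info %in% 1:4,
      info = fit$info,
      n_iter = n_iter,
      predict_f0 = function(label, T_K) f0_from(par, label, T_K),
      temperatures = temps
    ),
    class = "bds_global_fit"
  )
  out
}

#' @export
print.bds_global_fit <- function(x, ...) {
  cat(sprintf(
    "<bds_global_fit>  %d process laws refined jointly, deviance %.4g%s\n",
    nrow(x$laws), x$deviance,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$laws)
  invisible(x)
}

#' @rdname fit_global_laws
#' @param x A `bds_global_fit`.
#' @param ... Unused.
#' @export
tidy.bds_global_fit <- function(x, ...) x$laws

#' @rdname fit_global_laws
#' @export
glance.bds_global_fit <- function(x, ...) {
  tibble(deviance = x$deviance, converged = x$converged,
         n_processes = nrow(x$laws), n_iter = x$n_iter)
}
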