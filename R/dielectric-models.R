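# Forward models for broadband dielectric spectra: Havriliak-Negami (HN)
# relaxation terms, a fractional-exponent conductivity term, and their
# composite complex permittivity / loss tangent.
#
# Sign convention: eps*(f) = eps' - i eps'' with eps'' >= 0 the loss.  Complex
# powers use the principal branch, so i^x = exp(i pi x / 2); with that choice
# the a = b = 1 HN term reduces exactly to the Debye form delta_eps/(1 + i f/f0).

#' Havriliak-Negami relaxation process
#'
#' One empirical relaxation term
#' \deqn{\Delta\varepsilon / \left(1 + (i f/f_0)^a\right)^b}
#' with dielectric strength \eqn{\Delta\varepsilon}, relaxation frequency
#' \eqn{f_0} (Hz), width exponent \eqn{a} and symmetry exponent \eqn{b}.
#' `a = b = 1` is the Debye case; `b = 1` the symmetric Cole-Cole case.
#'
#' @param delta_eps Dielectric strength \eqn{\Delta\varepsilon > 0}
#'   (dimensionless).
#' @param f0 Relaxation frequency in Hz, `> 0`.
#' @param a Width exponent, `0 < a <= 1`.
#' @param b Symmetry exponent, `0 < b <= 1` (default 1).
#' @param label Free-text process tag, e.g. `"beta"`, `"alpha_a"`,
#'   `"alpha_c"`, `"slow"`, `"EP"`.
#' @return An object of class `hn_process`.
#' @seealso [hn_term()], [hn_loss_peak_frequency()], [dielectric_model()]
#' @examples
#' p <- hn_process(delta_eps = 2, f0 = 100, a = 0.8, label = "beta")
#' hn_term(p, c(1, 100, 1e4))
#' @export
hn_process <- function(delta_eps, f0, a = 1, b = 1, label = "process") {
  .check_number(delta_eps, "delta_eps", lower = 0, open_lower = TRUE)
  .check_number(f0, "f0", lower = 0, open_lower = TRUE)
  .check_number(a, "a", lower = 0, upper = 1, open_lower = TRUE)
  .check_number(b, "b", lower = 0, upper = 1, open_lower = TRUE)
  structure(
    list(delta_eps = delta_eps, f0 = f0, a = a, b = b,
         label = as.character(label)),
    class = "hn_process"
  )
}

#' @export
print.hn_process <- function(x, ...) {
  cat(sprintf(
    "<hn_process '%s'>  delta_eps = %.4g, f0 = %.4g Hz, a = %.3g, b = %.3g\n",
    x$label, x$delta_eps, x$f0, x$a, x$b
  ))
  invisible(x)
}

#' Fractional-exponent conductivity term
#'
#' Contribution of charge transport to the complex permittivity,
#' \deqn{\varepsilon_c(f) = \sigma_0 / \left(\varepsilon_0 (i\,2\pi f)^n\right),}
#' the standard description of ac conductivity in disordered solids.
#' `n = 1` is ohmic (pure dc) transport with no real-part contribution;
#' fractional `n` (typically 0.3-0.4 in the hopping regime) contributes to
#' both components, and makes the low-frequency loss tangent saturate at
#' `tan(n pi / 2)` (see [tan_delta_plateau()]).
#'
#' @param sigma0 dc conductivity \eqn{\sigma_0 \ge 0} in S/m.
#' @param n Conductivity exponent, `0 < n <= 1`.
#' @return An object of class `cond_term`.
#' @seealso [conductivity_term()], [tan_delta_plateau()]
#' @export
cond_term <- function(sigma0, n) {
  .check_number(sigma0, "sigma0", lower = 0)
  .check_number(n, "n", lower = 0, upper = 1, open_lower = TRUE)
  structure(list(sigma0 = sigma0, n = n), class = "cond_term")
}

#' @export
print.cond_term <- function(x, ...) {
  cat(sprintf("<cond_term>  sigma0 = %.4g S/m, n = %.3g\n", x$sigma0, x$n))
  invisible(x)
}

#' Composite dielectric model
#'
#' Unrelaxed permittivity \eqn{\varepsilon_\infty} plus a set of HN processes
#' and an optional conductivity term:
#' \deqn{\varepsilon^*(f) = \varepsilon_\infty + \sum_j \Delta\varepsilon_{HN,j}(f)
#'   + \varepsilon_c(f).}
#'
#' @param eps_inf Unrelaxed permittivity, `>= 1`.
#' @param processes A list of [hn_process()] objects (labels must be unique),
#'   or a single `hn_process`.
#' @param conductivity A [cond_term()] or `NULL`.
#' @return An object of class `dielectric_model`.
#' @examples
#' m <- dielectric_model(
#'   eps_inf = 3,
#'   processes = list(hn_process(2, 10, label = "debye")),
#'   conductivity = cond_term(1e-12, 0.8)
#' )
#' tan_delta(m, 10^seq(-1, 6))
#' @export
dielectric_model <- function(eps_inf, processes = list(), conductivity = NULL) {
  .check_number(eps_inf, "eps_inf", lower = 1)
  if (inherits(processes, "hn_process")) processes <- list(processes)
  if (!is.list(processes) ||
      !all(vapply(processes, inherits, logical(1), "hn_process"))) {
    abort("`processes` must be a list of hn_process objects.")
  }
  labels <- vapply(processes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort("Process labels must be unique within one model.")
  }
  if (!is.null(conductivity) && !inherits(conductivity, "cond_term")) {
    abort("`conductivity` must be a cond_term or NULL.")
  }
  structure(
    list(eps_inf = eps_inf, processes = processes, conductivity = conductivity),
    class = "dielectric_model"
  )
}

#' @export
print.dielectric_model <- function(x, ...) {
  cat(sprintf("<dielectric_model>  eps_inf = %.4g, %d process(es)%s\n",
              x$eps_inf, length(x$processes),
              if (is.null(x$conductivity)) "" else ", with conductivity"))
  for (p in x$processes) print(p)
  if (!is.null(x$conductivity)) print(x$conductivity)
  invisible(x)
}

#' Evaluate one HN term
#'
#' Complex permittivity contribution of a single [hn_process()] at frequencies
#' `f`, using the principal branch for the complex power.  The imaginary part
#' is negative or zero under the `eps* = eps' - i eps''` convention; the loss
#' contribution is `-Im(hn_term(...)) >= 0`.
#'
#' @param process An [hn_process()].
#' @param f Frequencies in Hz, strictly positive.
#' @return Complex vector, one value per frequency.
#' @export
hn_term <- function(process, f) {
  stopifnot(inherits(process, "hn_process"))
  .check_freq(f)
  process$delta_eps / (1 + (1i * f / process$f0)^process$a)^process$b
}

#' Evaluate the conductivity term
#'
#' Complex permittivity contribution of a [cond_term()] at frequencies `f`
#' (principal branch).  Real part scales as `cos(n pi/2) f^-n`, loss as
#' `sin(n pi/2) f^-n`.
#'
#' @param cond A [cond_term()].
#' @param f Frequencies in Hz, strictly positive.
#' @return Complex vector, one value per frequency.
#' @export
conductivity_term <- function(cond, f) {
  stopifnot(inherits(cond, "cond_term"))
  .check_freq(f)
  if (cond$sigma0 == 0) return(rep(0 + 0i, length(f)))
  cond$sigma0 / (.eps0 * (2i * pi * f)^cond$n)
}

#' Composite complex permittivity
#'
#' Evaluates \eqn{\varepsilon^*(f)} of a [dielectric_model()]: the sum of
#' \eqn{\varepsilon_\infty}, all HN terms and the conductivity term.
#' Use `Re()` for \eqn{\varepsilon'} and `-Im()` for the loss
#' \eqn{\varepsilon''}.
#'
#' @param model A [dielectric_model()].
#' @param f Frequencies in Hz, strictly positive.
#' @return Complex vector, one value per frequency.
#' @seealso [model_spectrum()] for a tidy data-frame rendering.
#' @export
composite_eps <- function(model, f) {
  stopifnot(inherits(model, "dielectric_model"))
  .check_freq(f)
  out <- rep(model$eps_inf + 0i, length(f))
  for (p in model$processes) out <- out + hn_term(p, f)
  if (!is.null(model$conductivity)) {
    out <- out + conductivity_term(model$conductivity, f)
  }
  out
}

#' Loss tangent of a composite model
#'
#' \eqn{\tan\delta = \varepsilon''/\varepsilon'} of the composite model.  This
#' is not a bare sum of per-process terms: every term enters both numerator
#' and denominator, which is exactly why the representation is invariant under
#' sample-thickness drift (any factor rescaling \eqn{\varepsilon'} and
#' \eqn{\varepsilon''} jointly cancels).
#'
#' @inheritParams composite_eps
#' @return Numeric vector of loss-tangent values.
#' @export
tan_delta <- function(model, f) {
  e <- composite_eps(model, f)
  er <- Re(e)
  if (any(er <= 0)) {
    abort("Composite eps'(f) <= 0: unphysical parameter set for tan delta.",
          class = "bdsfit_unphysical")
  }
  -Im(e) / er
}

#' Tidy spectrum of a model
#'
#' Evaluates a [dielectric_model()] on a frequency grid and returns a tibble
#' with `frequency_Hz`, `eps_real`, `eps_imag` (positive loss) and
#' `tan_delta` columns.
#'
#' @inheritParams composite_eps
#' @return A tibble with one row per frequency.
#' @export
model_spectrum <- function(model, f) {
  e <- composite_eps(model, f)
  tibble(
    frequency_Hz = f,
    eps_real = Re(e),
    eps_imag = -Im(e),
    tan_delta = -Im(e) / Re(e)
  )
}

#' Loss-peak frequency of an isolated HN term
#'
#' Closed form for the frequency of the loss maximum of a single HN process,
#' \deqn{f_{max} = f_0 \left[\frac{\sin\left(\frac{a\pi}{2+2b}\right)}
#'   {\sin\left(\frac{ab\pi}{2+2b}\right)}\right]^{1/a}.}
#' For `b = 1` (Cole-Cole, and in particular Debye) the peak sits exactly at
#' `f0`.  Used for initialising fits and for reading relaxation frequencies
#' off isolated peaks.
#'
#' @param process An [hn_process()].
#' @return The peak frequency in Hz.
#' @export
hn_loss_peak_frequency <- function(process) {
  stopifnot(inherits(process, "hn_process"))
  a <- process$a; b <- process$b
  process$f0 * (sin(a * pi / (2 + 2 * b)) / sin(a * b * pi / (2 + 2 * b)))^(1 / a)
}

#' Low-frequency loss-tangent plateau of a conductivity term
#'
#' For `0 < n < 1` the loss tangent of any model containing the conductivity
#' term tends, as `f -> 0`, to the constant `tan(n pi / 2)`: both components
#' of the permittivity are asymptotically dominated by the conductivity term,
#' whose loss/real ratio is frequency independent.  For `n = 1` the real part
#' of the term vanishes and no finite plateau exists.
#'
#' @param cond A [cond_term()] with `n < 1`.
#' @return The dimensionless plateau value `tan(n pi / 2)`.
#' @export
tan_delta_plateau <- function(cond) {
  stopifnot(inherits(cond, "cond_term"))
  if (cond$n >= 1) {
    abort("n = 1: ohmic conduction, tan delta diverges at low frequency.",
          class = "bdsfit_divergent_plateau")
  }
  tan(cond$n * pi / 2)
}

# JSON (de)serialisation of model parameter sets, keyed by process label ----

#' Serialise / restore a dielectric model
#'
#' `model_to_list()` renders a [dielectric_model()] as a plain list (processes
#' keyed by label) suitable for JSON; `model_from_list()` inverts it.
#'
#' @param model A [dielectric_model()].
#' @return A named list (`model_to_list`) or a `dielectric_model`
#'   (`model_from_list`).
#' @export
model_to_list <- function(model) {
  stopifnot(inherits(model, "dielectric_model"))
  procs <- lapply(model$processes, function(p) {
    list(delta_eps = p$delta_eps, f0 = p$f0, a = p$a, b = p$b)
  })
  names(procs) <- vapply(model$processes, `[[`, character(1), "label")
  list(
    eps_inf = model$eps_inf,
    processes = procs,
    conductivity = if (is.null(model$conductivity)) NULL else
      list(sigma0 = model$conductivity$sigma0, n = model$conductivity$n)
  )
}

#' @rdname model_to_list
#' @param x A list as produced by `model_to_list()`.
#' @export
model_from_list <- function(x) {
  procs <- purrr::imap(x$processes, function(p, lbl) {
    hn_process(p$delta_eps, p$f0, p$a, p$b, label = lbl)
  })
  cond <- if (is.null(x$conductivity)) NULL else
    cond_term(x$conductivity$sigma0, x$conductivity$n)
  dielectric_model(x$eps_inf, unname(procs), cond)
}
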