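# Synthetic broadband dielectric spectra with known ground truth.
#
# The generator emulates the statistical structure of temperature-stepped BDS
# measurements on semicrystalline biopolymer films: a 0.1 Hz - 1 MHz log grid,
# 5 K or 10 K temperature steps from about -100 C upward, up to four
# simultaneous HN relaxations following Arrhenius or VFT temperature laws, a
# fractional-exponent conductivity term with a two-regime dc law, independent
# multiplicative lognormal measurement noise on eps' and eps'', and a
# temperature-dependent thickness-drift factor g(T) that rescales apparent
# eps' and eps'' equally (so tan delta is exactly invariant to it).

#' Temperature law of a synthetic relaxation process
#'
#' Describes one relaxation process of the generator: its relaxation-frequency
#' law (`"arrhenius"`: `log10 f0 = log10_f_inf - Ea/(ln10 R T)`, `Ea` in
#' kJ/mol; or `"vft"`: `log10 f0 = log10_f_inf - B/(ln10 (T - T0))`), its
#' dielectric strength (optionally linear in temperature) and fixed HN shape
#' exponents.
#'
#' @param label Process tag (e.g. `"beta"`, `"alpha_a"`, `"slow"`, `"EP"`).
#' @param law `"arrhenius"` or `"vft"`.
#' @param log10_f_inf Decadic log of the infinite-temperature frequency (Hz).
#' @param Ea Activation energy in kJ/mol (Arrhenius law).
#' @param B,T0 VFT activation parameter (K) and Vogel temperature (K).
#' @param delta_eps Dielectric strength at the reference temperature.
#' @param delta_eps_slope Linear temperature coefficient of the strength
#'   (per K, default 0 = constant).
#' @param a,b HN shape exponents (constant in temperature).
#' @return An object of class `process_law`.
#' @seealso [law_frequency()], [synthetic_protocol()]
#' @export
process_law <- function(label, law = c("arrhenius", "vft"), log10_f_inf,
                        Ea = NULL, B = NULL, T0 = NULL,
                        delta_eps = 1, delta_eps_slope = 0, a = 1, b = 1) {
  law <- match.arg(law)
  .check_number(log10_f_inf, "log10_f_inf")
  if (law == "arrhenius") {
    .check_number(Ea, "Ea", lower = 0)
  } else {
    .check_number(B, "B", lower = 0, open_lower = TRUE)
    .check_number(T0, "T0", lower = 0)
  }
  .check_number(delta_eps, "delta_eps", lower = 0, open_lower = TRUE)
  .check_number(a, "a", lower = 0, upper = 1, open_lower = TRUE)
  .check_number(b, "b", lower = 0, upper = 1, open_lower = TRUE)
  structure(
    list(label = label, law = law, log10_f_inf = log10_f_inf,
         Ea = Ea, B = B, T0 = T0, delta_eps = delta_eps,
         delta_eps_slope = delta_eps_slope, a = a, b = b),
    class = "process_law"
  )
}

#' Evaluate a process law
#'
#' `law_frequency()` returns the relaxation frequency f0(T) in Hz (NA below
#' the Vogel temperature, where the process is frozen);
#' `law_strength()` returns the dielectric strength at T.
#'
#' @param law A [process_law()].
#' @param T_K Temperatures in kelvin (vectorised).
#' @return Numeric vector.
#' @export
law_frequency <- function(law, T_K) {
  stopifnot(inherits(law, "process_law"))
  if (law$law == "arrhenius") {
    10^(law$log10_f_inf - law$Ea * 1000 / (.ln10 * .gas_R * T_K))
  } else {
    ifelse(T_K > law$T0 + 1e-6,
           10^(law$log10_f_inf - law$B / (.ln10 * (T_K - law$T0))),
           NA_real_)
  }
}

#' @rdname law_frequency
#' @export
law_strength <- function(law, T_K) {
  stopifnot(inherits(law, "process_law"))
  pmax(law$delta_eps + law$delta_eps_slope * (T_K - 273.15), 1e-6)
}

#' Two-regime dc-conductivity law
#'
#' dc conductivity with two Arrhenius regimes in log10 sigma0 versus 1/T,
#' continuous at the breakpoint `T_break_K` (typically near the glass
#' transition), and a conductivity exponent stepping from a fractional
#' hopping value below the breakpoint to a near-ohmic value above it.
#'
#' @param log10_sigma_break log10 of sigma0 (S/m) at the breakpoint.
#' @param T_break_K Breakpoint temperature in K.
#' @param Ea_low,Ea_high Activation energies (kJ/mol) below/above the break.
#' @param n_low,n_high Conductivity exponents below/above the break.
#' @return An object of class `conductivity_law`.
#' @export
conductivity_law <- function(log10_sigma_break, T_break_K,
                             Ea_low = 20, Ea_high = 70,
                             n_low = 0.35, n_high = 0.95) {
  .check_number(T_break_K, "T_break_K", lower = 0, open_lower = TRUE)
  .check_number(Ea_low, "Ea_low", lower = 0)
  .check_number(Ea_high, "Ea_high", lower = 0)
  .check_number(n_low, "n_low", lower = 0, upper = 1, open_lower = TRUE)
  .check_number(n_high, "n_high", lower = 0, upper = 1, open_lower = TRUE)
  structure(
    list(log10_sigma_break = log10_sigma_break, T_break_K = T_break_K,
         Ea_low = Ea_low, Ea_high = Ea_high, n_low = n_low, n_high = n_high),
    class = "conductivity_law"
  )
}

#' @rdname conductivity_law
#' @param law A `conductivity_law`.
#' @param T_K Temperatures in kelvin (vectorised).
#' @export
law_sigma0 <- function(law, T_K) {
  stopifnot(inherits(law, "conductivity_law"))
  Ea <- ifelse(T_K < law$T_break_K, law$Ea_low, law$Ea_high) * 1000
  10^(law$log10_sigma_break - Ea / (.ln10 * .gas_R) *
        (1 / T_K - 1 / law$T_break_K))
}

#' @rdname conductivity_law
#' @export
law_n <- function(law, T_K) {
  stopifnot(inherits(law, "conductivity_law"))
  ifelse(T_K < law$T_break_K, law$n_low, law$n_high)
}

#' Synthetic measurement protocol
#'
#' Full description of a synthetic BDS run: temperature and frequency grids,
#' process laws, conductivity law, unrelaxed permittivity, multiplicative
#' noise level, thickness-drift factor and seed.  The drift `g(T)` ramps
#' linearly from `drift[1]` at the coldest to `drift[2]` at the hottest
#' temperature and multiplies apparent eps' and eps'' equally, mimicking the
#' film thinning observed across a heating run (a 51 um -> 32 um thinning
#' corresponds to `drift = c(1, 51/32)`).
#'
#' @param processes List of [process_law()] objects.
#' @param conductivity A [conductivity_law()] or `NULL`.
#' @param eps_inf Unrelaxed permittivity.
#' @param temp_range_C Length-2 numeric, first and last temperature in C.
#' @param temp_step_C Temperature step, 5 or 10 C.
#' @param freq_range_Hz Length-2 numeric frequency span in Hz.
#' @param points_per_decade Frequency grid density (default 10, giving the
#'   71-point 0.1 Hz-1 MHz grid).
#' @param noise_sd Standard deviation of the multiplicative lognormal noise
#'   applied independently per point to eps' and eps'' (default 0.01 = 1%).
#' @param drift Length-2 numeric: thickness-drift factor at the coldest and
#'   hottest temperature (linearly interpolated in T).
#' @param sample_id Sample tag stored with the spectra.
#' @param anneal_label Free-text annealing descriptor kept as metadata.
#' @param seed Default RNG seed for [generate_dataset()].
#' @return An object of class `synthetic_protocol`.
#' @export
synthetic_protocol <- function(processes, conductivity = NULL, eps_inf = 3,
                               temp_range_C = c(-100, 160), temp_step_C = 10,
                               freq_range_Hz = c(0.1, 1e6),
                               points_per_decade = 10,
                               noise_sd = 0.01, drift = c(1, 1),
                               sample_id = "synthetic",
                               anneal_label = "no ann.", seed = 1L) {
  if (inherits(processes, "process_law")) processes <- list(processes)
  stopifnot(all(vapply(processes, inherits, logical(1), "process_law")))
  labels <- vapply(processes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("Process labels must be unique.")
  if (!is.null(conductivity)) stopifnot(inherits(conductivity, "conductivity_law"))
  .check_number(eps_inf, "eps_inf", lower = 1)
  .check_number(temp_step_C, "temp_step_C", lower = 0, open_lower = TRUE)
  .check_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(temp_range_C) == 2, length(freq_range_Hz) == 2,
            length(drift) == 2, all(drift > 0))
  structure(
    list(processes = processes, conductivity = conductivity,
         eps_inf = eps_inf, temp_range_C = temp_range_C,
         temp_step_C = temp_step_C, freq_range_Hz = freq_range_Hz,
         points_per_decade = points_per_decade, noise_sd = noise_sd,
         drift = drift, sample_id = sample_id, anneal_label = anneal_label,
         seed = as.integer(seed)),
    class = "synthetic_protocol"
  )
}

#' Grids of a synthetic protocol
#'
#' @param protocol A [synthetic_protocol()].
#' @return `protocol_temperatures()`: kelvin grid; `protocol_frequencies()`:
#'   Hz grid, log-uniform.
#' @export
protocol_temperatures <- function(protocol) {
  kelvin(seq(protocol$temp_range_C[1], protocol$temp_range_C[2],
             by = protocol$temp_step_C))
}

#' @rdname protocol_temperatures
#' @export
protocol_frequencies <- function(protocol) {
  lo <- log10(protocol$freq_range_Hz[1])
  hi <- log10(protocol$freq_range_Hz[2])
  10^seq(lo, hi, by = 1 / protocol$points_per_decade)
}

#' Composite model implied by a protocol at one temperature
#'
#' Evaluates every process law at `T_K` and assembles the exact
#' [dielectric_model()] the generator uses there.  Processes whose law
#' frequency is undefined (below the Vogel temperature) or below 1e-12 Hz are
#' omitted (frozen: they contribute nothing measurable in the window).
#'
#' @param protocol A [synthetic_protocol()].
#' @param T_K Temperature in kelvin.
#' @return A [dielectric_model()].
#' @export
protocol_model <- function(protocol, T_K) {
  procs <- list()
  for (pl in protocol$processes) {
    f0 <- law_frequency(pl, T_K)
    if (is.na(f0) || f0 < 1e-12) next
    procs <- c(procs, list(hn_process(law_strength(pl, T_K), f0,
                                      a = pl$a, b = pl$b, label = pl$label)))
  }
  cond <- if (is.null(protocol$conductivity)) NULL else
    cond_term(law_sigma0(protocol$conductivity, T_K),
              law_n(protocol$conductivity, T_K))
  dielectric_model(protocol$eps_inf, procs, cond)
}

.drift_factor <- function(protocol, T_K) {
  Tg <- kelvin(protocol$temp_range_C)
  if (diff(Tg) == 0) return(rep(protocol$drift[1], length(T_K)))
  w <- (T_K - Tg[1]) / (Tg[2] - Tg[1])
  protocol$drift[1] + w * (protocol$drift[2] - protocol$drift[1])
}

#' Generate a synthetic BDS dataset
#'
#' For each temperature of the protocol grid, evaluates the composite model
#' on the frequency grid, applies the thickness-drift factor `g(T)` to eps'
#' and eps'' jointly, then applies independent multiplicative lognormal noise
#' to each component; `tan_delta` is recomputed from the noisy components.
#' Deterministic for a given seed.
#'
#' @param protocol A [synthetic_protocol()].
#' @param seed RNG seed; defaults to the protocol's own seed.
#' @return A list of class `bds_synthetic` with elements
#'   \describe{
#'     \item{spectra}{a `bds_spectra` tibble of the noisy apparent spectra,}
#'     \item{truth}{a tibble of the exact generating per-temperature,
#'       per-process parameters (`delta_eps`, `f0_Hz`, `a`, `b`),}
#'     \item{conditions}{a per-temperature tibble of `eps_inf`, `sigma0`,
#'       `n` and the drift factor `g`,}
#'     \item{protocol}{the protocol used.}
#'   }
#' @export
generate_dataset <- function(protocol, seed = NULL) {
  stopifnot(inherits(protocol, "synthetic_protocol"))
  seed <- as.integer(seed %||% protocol$seed)
  temps <- protocol_temperatures(protocol)
  freqs <- protocol_frequencies(protocol)

  build <- function() {
    rows <- vector("list", length(temps))
    truth <- vector("list", length(temps))
    conds <- vector("list", length(temps))
    for (i in seq_along(temps)) {
      T_K <- temps[i]
      m <- protocol_model(protocol, T_K)
      sp <- model_spectrum(m, freqs)
      g <- .drift_factor(protocol, T_K)
      er <- sp$eps_real * g
      ei <- sp$eps_imag * g
      if (protocol$noise_sd > 0) {
        er <- er * exp(rnorm(length(er), 0, protocol$noise_sd))
        ei <- ei * exp(rnorm(length(ei), 0, protocol$noise_sd))
      }
      rows[[i]] <- tibble(
        sample_id = protocol$sample_id, ramp = 1L, temperature_K = T_K,
        frequency_Hz = freqs, eps_real = er, eps_imag = ei,
        tan_delta = ei / er
      )
      truth[[i]] <- if (length(m$processes)) tibble(
        temperature_K = T_K,
        process_label = vapply(m$processes, `[[`, character(1), "label"),
        delta_eps = vapply(m$processes, `[[`, numeric(1), "delta_eps"),
        f0_Hz = vapply(m$processes, `[[`, numeric(1), "f0"),
        a = vapply(m$processes, `[[`, numeric(1), "a"),
        b = vapply(m$processes, `[[`, numeric(1), "b")
      ) else NULL
      conds[[i]] <- tibble(
        temperature_K = T_K, eps_inf = protocol$eps_inf,
        sigma0 = if (is.null(m$conductivity)) NA_real_ else m$conductivity$sigma0,
        n = if (is.null(m$conductivity)) NA_real_ else m$conductivity$n,
        g = g
      )
    }
    list(
      spectra = as_bds_spectra(dplyr::bind_rows(rows)),
      truth = dplyr::bind_rows(truth),
      conditions = dplyr::bind_rows(conds),
      protocol = protocol
    )
  }
  out <- withr::with_seed(seed, build())
  class(out) <- "bds_synthetic"
  out
}

#' @export
print.bds_synthetic <- function(x, ...) {
  cat(sprintf(
    "<bds_synthetic>  %d isotherms x %d frequencies, %d process law(s)%s\n",
    dplyr::n_distinct(x$spectra$temperature_K),
    dplyr::n_distinct(x$spectra$frequency_Hz),
    length(x$protocol$processes),
    if (is.null(x$protocol$conductivity)) "" else ", conductivity"
  ))
  invisible(x)
}

# presets -------------------------------------------------------------------

#' Shipped synthetic presets
#'
#' Fully specified protocols emulating solution-cast chitosan films measured
#' over -100 to 160 C.  Temperature-law parameters (log10 f_inf, Ea or B/T0)
#' for the neutralized (`A90_*`) and non-neutralized (`A0_*`) presets are the
#' published Arrhenius/VFT parameters for those samples and annealing states;
#' dielectric strengths, shape exponents, eps_inf, conductivity magnitudes
#' and noise levels are this package's own realistic choices (the sources do
#' not print them) and are documented in the methods vignette.
#'
#' Available names: `"A90_no_annealing"`, `"A90_Ta100"`, `"A90_Ta140"`,
#' `"A0_no_annealing"`, `"debye_single"`, `"two_regime_conductivity"`.
#'
#' @param name Preset name.
#' @return A [synthetic_protocol()].
#' @examples
#' prot <- bds_preset("debye_single")
#' gen <- generate_dataset(prot, seed = 1)
#' @export
bds_preset <- function(name) {
  cond_neutral <- conductivity_law(-14, 230, 20, 70, 0.35, 0.95)
  cond_acid <- conductivity_law(-13, 230, 20, 70, 0.35, 0.95)
  switch(
    name,
    A90_no_annealing = synthetic_protocol(
      processes = list(
        process_law("beta", "vft", 16.40, B = 5324, T0 = 25.93,
                    delta_eps = 1.0, a = 0.35),
        process_law("alpha_a", "vft", 10.03, B = 2529, T0 = 144.5,
                    delta_eps = 2.0, a = 0.6),
        process_law("slow", "arrhenius", 14.02, Ea = 68.91,
                    delta_eps = 8, a = 0.8),
        process_law("EP", "arrhenius", 2.60, Ea = 20.96,
                    delta_eps = 50, a = 1)
      ),
      conductivity = cond_neutral, sample_id = "A90",
      anneal_label = "no ann."
    ),
    A90_Ta100 = synthetic_protocol(
      processes = list(
        process_law("beta", "vft", 12.90, B = 3168, T0 = 70.75,
                    delta_eps = 1.0, a = 0.35),
        process_law("alpha_a", "vft", 8.44, B = 4185, T0 = 86.0,
                    delta_eps = 2.0, a = 0.6),
        process_law("alpha_c", "arrhenius", 12.74, Ea = 51.66,
                    delta_eps = 1.5, a = 0.5),
        process_law("slow", "arrhenius", 11.68, Ea = 67.50,
                    delta_eps = 8, a = 0.8),
        process_law("EP", "arrhenius", -0.2, Ea = 5.46,
                    delta_eps = 50, a = 1)
      ),
      conductivity = cond_neutral, sample_id = "A90", anneal_label = "100 C"
    ),
    A90_Ta140 = synthetic_protocol(
      processes = list(
        process_law("beta", "vft", 12.0, B = 3160, T0 = 45.78,
                    delta_eps = 1.0, a = 0.35),
        process_law("alpha_a", "vft", 6.03, B = 933.7, T0 = 306.4,
                    delta_eps = 2.0, a = 0.6),
        process_law("alpha_c", "arrhenius", 12.7, Ea = 58.14,
                    delta_eps = 1.5, a = 0.5),
        process_law("slow", "arrhenius", 12.83, Ea = 88.94,
                    delta_eps = 8, a = 0.8),
        process_law("EP", "arrhenius", 0.599, Ea = 12.77,
                    delta_eps = 50, a = 1)
      ),
      conductivity = cond_neutral, sample_id = "A90", anneal_label = "140 C"
    ),
    A0_no_annealing = synthetic_protocol(
      processes = list(
        process_law("beta_f", "arrhenius", 9.04, Ea = 11.01,
                    delta_eps = 0.8, a = 0.35),
        process_law("beta", "arrhenius", 13.5, Ea = 48.54,
                    delta_eps = 1.0, a = 0.4),
        process_law("alpha_a", "vft", 7.72, B = 2340.8, T0 = 144.7,
                    delta_eps = 2.0, a = 0.6),
        process_law("alpha_c", "arrhenius", 18.66, Ea = 85.48,
                    delta_eps = 1.5, a = 0.5),
        process_law("slow", "arrhenius", 5.70, Ea = 29.93,
                    delta_eps = 8, a = 0.8),
        process_law("EP", "arrhenius", 7.73, Ea = 50.29,
                    delta_eps = 50, a = 1)
      ),
      conductivity = cond_acid, sample_id = "A0", anneal_label = "no ann."
    ),
    debye_single = synthetic_protocol(
      processes = list(
        process_law("debye", "arrhenius", 8, Ea = 30, delta_eps = 2,
                    a = 1, b = 1)
      ),
      conductivity = NULL, eps_inf = 3,
      temp_range_C = c(-80, 40), temp_step_C = 10, noise_sd = 0,
      sample_id = "debye"
    ),
    two_regime_conductivity = synthetic_protocol(
      processes = list(
        process_law("slow", "arrhenius", 14.02, Ea = 68.91,
                    delta_eps = 8, a = 0.8)
      ),
      conductivity = conductivity_law(-12, 230, 20, 70, 0.35, 0.95),
      temp_range_C = c(-90, 160), temp_step_C = 10,
      sample_id = "sigma2reg"
    ),
    abort(sprintf("Unknown preset '%s'.", name))
  )
}
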