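test_that("eps_inf is read at the coldest temperature and highest frequency", {
  toy <- tibble::tibble(
    temperature_C = rep(c(-100, -50), each = 3),
    frequency_Hz = rep(c(1, 100, 1e6), 2),
    eps_real = c(4.1, 3.6, 3.2, 6.0, 5.1, 4.4),
    eps_imag = 0.1
  )
  expect_equal(estimate_eps_inf(as_bds_spectra(toy)), 3.2)
  expect_equal(estimate_eps_inf(as_bds_spectra(toy[4:6, ])), 4.4)
  expect_error(estimate_eps_inf(as_bds_spectra(toy[0, ])), "Empty")

  # generator ground truth: coldest spectrum far below all process activity
  prot <- synthetic_protocol(
    list(process_law("slow", "arrhenius", 8, Ea = 60, delta_eps = 3, a = 0.8)),
    conductivity = NULL, eps_inf = 4.0, temp_range_C = c(-100, 0),
    noise_sd = 0.01, sample_id = "einf"
  )
  gen <- generate_dataset(prot, seed = 5)
  expect_equal(estimate_eps_inf(gen$spectra), 4.0, tolerance = 0.02)
})

test_that("a noiseless single-Debye tan delta spectrum is recovered to 0.1%", {
  prot <- synthetic_protocol(
    list(process_law("d", "arrhenius", 8, Ea = 30, delta_eps = 2, a = 1)),
    conductivity = NULL, eps_inf = 3, temp_range_C = c(-40, -40),
    noise_sd = 0, sample_id = "debye"
  )
  gen <- generate_dataset(prot, seed = 1)
  iso <- split_isotherms(gen$spectra)[[1]]
  truth <- gen$truth
  cfg <- fit_config(list(process_spec("d", a = 0.8)),
                    include_conductivity = FALSE,
                    representation = "tan_delta", seed = 3)
  r <- quiet(fit_isotherm(iso, cfg))
  expect_true(r$converged)
  expect_equal(delta_of(r), truth$delta_eps, tolerance = 1e-3)
  expect_equal(f0_of(r), truth$f0_Hz, tolerance = 1e-3)
  expect_equal(a_of(r), 1, tolerance = 1e-3)
})

test_that("a noiseless two-process + conductivity spectrum is recovered to 1%", {
  gen <- generate_dataset(two_process_protocol(), seed = 2)
  iso <- split_isotherms(gen$spectra)[[3]]
  truth <- dplyr::filter(gen$truth, temperature_K == iso$temperature_K[1])
  r <- quiet(fit_isotherm(iso, two_process_config()))
  expect_equal(delta_of(r), truth$delta_eps, tolerance = 0.01)
  expect_equal(log10(f0_of(r)), log10(truth$f0_Hz), tolerance = 0.01)
  expect_equal(a_of(r), truth$a, tolerance = 0.01)
})

test_that("thickness drift leaves tan-delta fits unchanged and scales eps'' strengths by g(T)", {
  g0 <- generate_dataset(two_process_protocol(drift = c(1, 1)), seed = 1)
  g1 <- generate_dataset(two_process_protocol(drift = c(1, 51 / 32)), seed = 1)
  for (k in c(3, 4)) {
    iso0 <- split_isotherms(g0$spectra)[[k]]
    iso1 <- split_isotherms(g1$spectra)[[k]]
    g_T <- g1$conditions$g[k]

    r0 <- quiet(fit_isotherm(iso0, two_process_config("tan_delta")))
    r1 <- quiet(fit_isotherm(iso1, two_process_config("tan_delta")))
    expect_equal(delta_of(r1), delta_of(r0), tolerance = 1e-4)
    expect_equal(f0_of(r1), f0_of(r0), tolerance = 1e-4)

    e0 <- quiet(fit_isotherm(iso0, two_process_config("eps_imag")))
    e1 <- quiet(fit_isotherm(iso1, two_process_config("eps_imag")))
    expect_equal(delta_of(e1) / delta_of(e0), rep(g_T, 2), tolerance = 1e-3)
    expect_equal(f0_of(e1), f0_of(e0), tolerance = 1e-3)
  }
})

test_that("fits are deterministic given the seed and honour fixed parameters", {
  gen <- generate_dataset(two_process_protocol(noise_sd = 0.01), seed = 6)
  iso <- split_isotherms(gen$spectra)[[3]]
  r1 <- quiet(fit_isotherm(iso, two_process_config(seed = 11)))
  r2 <- quiet(fit_isotherm(iso, two_process_config(seed = 11)))
  expect_identical(tidy(r1)$value, tidy(r2)$value)

  pinned <- fit_config(
    list(process_spec("fast", delta_eps = 1, f0 = 1234, a = 0.6,
                      free_f0 = FALSE, f0_source = "fixed:arrhenius"),
         process_spec("slow", delta_eps = 1, f0 = 10, a = 0.6)),
    eps_inf = 3, weighting = "relative", seed = 1
  )
  r <- quiet(fit_isotherm(iso, pinned))
  expect_equal(r$model$processes[[1]]$f0, 1234)       # never moved
  expect_equal(r$model$processes[[1]]$b, 1)           # convention b = 1
  prm <- tidy(r)
  expect_equal(prm$source[prm$label == "fast" & prm$term == "f0"],
               "fixed:arrhenius")
  expect_false(prm$free[prm$label == "fast" & prm$term == "f0"])
})

test_that("Arrhenius extrapolation pins frequencies at stated values", {
  flat <- structure(list(log10_f_inf = 12, Ea_kJ_mol = 0, n_points = 2,
                         rms = 0), class = "arrhenius_fit")
  expect_equal(fix_process_frequency(flat, c(150, 300)), c(1e12, 1e12))

  # published secondary-process parameters: log f_inf = 9.04, Ea = 11.01 kJ/mol
  a0 <- structure(list(log10_f_inf = 9.04, Ea_kJ_mol = 11.01, n_points = 5,
                       rms = 0), class = "arrhenius_fit")
  expect_equal(
    fix_process_frequency(a0, 173.15),
    10^(9.04 - 11.01e3 / (log(10) * GAS_R * 173.15)),
    tolerance = 1e-12
  )

  # a two-point fit interpolates exactly at its anchors
  pts <- tibble::tibble(temperature_K = c(200, 250), f0_Hz = c(1e2, 1e4))
  ft <- fit_arrhenius(pts)
  expect_equal(fix_process_frequency(ft, 200), 1e2, tolerance = 1e-9)
  expect_equal(fix_process_frequency(ft, 250), 1e4, tolerance = 1e-9)
})

test_that("dataset fitting recovers a two-process series with pinning provenance", {
  prot <- synthetic_protocol(
    processes = list(
      process_law("fast", "arrhenius", 13, Ea = 40, delta_eps = 2, a = 0.5),
      process_law("slow", "arrhenius", 12.5, Ea = 65, delta_eps = 5, a = 0.8)
    ),
    conductivity = conductivity_law(-13, 230, 20, 70, 0.35, 0.95),
    eps_inf = 3, temp_range_C = c(-80, 60), temp_step_C = 10,
    noise_sd = 0.01, sample_id = "series"
  )
  gen <- generate_dataset(prot, seed = 8)
  plan <- derive_plan(prot)
  fits <- quiet(fit_dataset(gen$spectra, plan, seed = 8))
  map <- build_relaxation_map(fits)

  # the fast process leaves the window at high T: pinned entries are present
  # and excluded from the law fits
  expect_true(any(map$provenance == "fixed:arrhenius" &
                    map$process_label == "fast"))
  cmp <- dplyr::inner_join(
    dplyr::filter(map, provenance == "fitted", in_window),
    gen$truth, by = c("process_label", "temperature_K")
  )
  err <- abs(cmp$log10_f0 - log10(cmp$f0_Hz.y))
  expect_true(all(tapply(err, cmp$process_label, stats::median) <= 0.1))

  laws <- quiet(fit_relaxation_laws(map, laws = plan$map_laws))
  expect_equal(laws$Ea_kJ_mol[laws$process_label == "fast"], 40,
               tolerance = 0.05)
  expect_equal(laws$Ea_kJ_mol[laws$process_label == "slow"], 65,
               tolerance = 0.05)
})

test_that("warnings flag parameter-starved and non-convergent situations", {
  toy <- as_bds_spectra(tibble::tibble(
    temperature_C = -40, frequency_Hz = 10^seq(0, 3, length.out = 8),
    eps_real = 3 + 1 / (1 + (10^seq(0, 3, length.out = 8) / 30)^2),
    eps_imag = 0.3
  ))
  cfg <- fit_config(list(process_spec("p", a = 0.5)),
                    include_conductivity = TRUE, seed = 1, n_starts = 1)
  expect_warning(fit_isotherm(toy, cfg), "free parameters")
})
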