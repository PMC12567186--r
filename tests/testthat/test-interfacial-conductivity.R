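test_that("MWS time reduces to the Maxwell time of the pure matrix", {
  # phi = 0: tau = eps0 eps2 / sigma2
  expect_equal(mws_relaxation_time(eps1 = 3, eps2 = 5, sigma1 = 0,
                                   sigma2 = 1e-9, phi = 0),
               EPS0 * 5 / 1e-9, tolerance = 1e-12)
  expect_equal(EPS0 * 5 / 1e-9, 4.43e-2, tolerance = 1e-3)

  # homogeneous limit: independent of A and phi
  taus <- vapply(c(0, 0.2, 0.5, 0.9), function(phi) {
    mws_relaxation_time(eps1 = 4, eps2 = 4, sigma1 = 2e-9, sigma2 = 2e-9,
                        A = 0.7, phi = phi)
  }, numeric(1))
  expect_equal(taus, rep(EPS0 * 4 / 2e-9, 4), tolerance = 1e-12)

  # direct substitution: A = 1/3, phi = 0.3, eps 3/10, sigma 0/1e-8
  tau <- mws_relaxation_time(eps1 = 3, eps2 = 10, sigma1 = 0, sigma2 = 1e-8,
                             A = 1 / 3, phi = 0.3)
  expect_equal(tau, EPS0 * (10 + 0.1 * (3 - 10)) / (1e-8 + 0.1 * (0 - 1e-8)),
               tolerance = 1e-12)
  expect_equal(tau, EPS0 * 9.3 / 9e-9, tolerance = 1e-12)
  expect_equal(tau, 9.15e-3, tolerance = 1e-3)

  expect_equal(mws_frequency(eps1 = 3, eps2 = 10, sigma1 = 0, sigma2 = 1e-8,
                             A = 1 / 3, phi = 0.3),
               1 / (2 * pi * tau), tolerance = 1e-12)
})

test_that("MWS time is monotone in matrix conductivity and scales homogeneously", {
  withr::with_seed(31, {
    for (i in 1:50) {
      e1 <- runif(1, 1, 10); e2 <- runif(1, 1, 10)
      A <- runif(1, 0.1, 1); phi <- runif(1, 0, 0.6)
      s2 <- 10^seq(-12, -6, length.out = 10)
      s1 <- s2[1] * runif(1)   # sigma1 <= sigma2 throughout
      taus <- mws_relaxation_time(e1, e2, s1, s2, A, phi)
      expect_true(all(diff(taus) < 0))
      # scaling both conductivities by k scales tau by 1/k
      k <- runif(1, 2, 50)
      expect_equal(mws_relaxation_time(e1, e2, k * s1, k * s2[3], A, phi),
                   taus[3] / k, tolerance = 1e-12)
    }
  })
  expect_warning(
    out <- mws_relaxation_time(eps1 = 2, eps2 = 2, sigma1 = 0, sigma2 = 0),
    "Non-positive")
  expect_true(is.na(out))
  expect_error(mws_relaxation_time(0.5, 2, 0, 1e-9), "Permittivities")
  expect_error(mws_relaxation_time(2, 2, 0, 1e-9, A = 0), "`A`")
  expect_error(mws_relaxation_time(2, 2, 0, 1e-9, phi = 1), "`phi`")
})

test_that("conductivity / slow-frequency correlation recovers the expected slopes", {
  T_K <- seq(280, 420, by = 10)
  sigma0 <- 10^(-12 + 5 * (T_K - 280) / 140)

  # constructed proportionality: f0 = sigma0 / (2 pi eps0 eps_eff)
  slow1 <- tibble::tibble(temperature_K = T_K,
                          f0_Hz = sigma0 / (2 * pi * EPS0 * 8))
  r1 <- quiet(sigma_slow_correlation(
    tibble::tibble(temperature_K = T_K, sigma0 = sigma0), slow1))
  expect_equal(r1$slope, 1, tolerance = 1e-9)

  # frequency independent of conductivity: slope 0
  slow0 <- tibble::tibble(temperature_K = T_K, f0_Hz = 50)
  r0 <- quiet(sigma_slow_correlation(
    tibble::tibble(temperature_K = T_K, sigma0 = sigma0), slow0))
  expect_equal(r0$slope, 0, tolerance = 1e-9)

  # interfacial-time generator with sigma1 = sigma2/2 and A phi = 0.3:
  # still slope 1, intercept shifted relative to the sigma1 = 0 case
  f_mws <- mws_frequency(eps1 = 3, eps2 = 8, sigma1 = sigma0 / 2,
                         sigma2 = sigma0, A = 1, phi = 0.3)
  r2 <- quiet(sigma_slow_correlation(
    tibble::tibble(temperature_K = T_K, sigma0 = sigma0),
    tibble::tibble(temperature_K = T_K, f0_Hz = f_mws)))
  expect_equal(r2$slope, 1, tolerance = 1e-9)
  f_ref <- mws_frequency(eps1 = 3, eps2 = 8, sigma1 = 0,
                         sigma2 = sigma0, A = 1, phi = 0.3)
  r3 <- quiet(sigma_slow_correlation(
    tibble::tibble(temperature_K = T_K, sigma0 = sigma0),
    tibble::tibble(temperature_K = T_K, f0_Hz = f_ref)))
  expect_gt(r2$intercept, r3$intercept)

  expect_error(
    sigma_slow_correlation(
      tibble::tibble(temperature_K = T_K[1:2], sigma0 = sigma0[1:2]),
      slow1[1:2, ]),
    "at least 3")
})

test_that("two-segment Arrhenius analysis recovers both conductivity regimes", {
  cl <- conductivity_law(-12, 230, 20, 70, 0.35, 0.95)
  T_K <- seq(180, 330, by = 10)
  series <- tibble::tibble(temperature_K = T_K, sigma0 = law_sigma0(cl, T_K))

  fit <- fit_conductivity_regimes(series)
  expect_equal(fit$low$Ea_kJ_mol, 20, tolerance = 0.05 * 20)
  expect_equal(fit$high$Ea_kJ_mol, 70, tolerance = 0.05 * 70)
  expect_lt(abs(fit$breakpoint_K - 230), 10 + 1e-9)  # within one step

  # the conductivity-exponent step sits at the same breakpoint
  n_T <- law_n(cl, T_K)
  step_at <- (max(T_K[n_T == 0.35]) + min(T_K[n_T == 0.95])) / 2
  expect_lt(abs(fit$breakpoint_K - step_at), 10 + 1e-9)

  # single-regime series: both segments agree
  single <- tibble::tibble(
    temperature_K = T_K,
    sigma0 = 10^(-2 - 30e3 / (log(10) * GAS_R * T_K))
  )
  fs <- fit_conductivity_regimes(single)
  expect_equal(fs$low$Ea_kJ_mol, fs$high$Ea_kJ_mol, tolerance = 0.01 * 30)
  expect_equal(fs$low$Ea_kJ_mol, 30, tolerance = 1e-6)

  expect_error(fit_conductivity_regimes(series[1:4, ]), "at least")
  td <- tidy(fit)
  expect_equal(td$regime, c("low", "high"))
})

test_that("conductivity series extraction mirrors fitted isotherm models", {
  gen <- generate_dataset(two_process_protocol(noise_sd = 0.01), seed = 3)
  plan <- derive_plan(two_process_protocol())
  fits <- quiet(fit_dataset(gen$spectra, plan, seed = 3, refine = FALSE))
  cs <- conductivity_series(fits)
  expect_equal(nrow(cs), length(fits$fits))
  expect_true(all(cs$sigma0 >= 0))
  expect_true(all(cs$n > 0 & cs$n <= 1))
})
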