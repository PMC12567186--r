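test_that("Arrhenius fits follow the two-point closed form", {
  pts <- tibble::tibble(temperature_K = c(200, 250), f0_Hz = c(1e2, 1e4))
  ft <- fit_arrhenius(pts)
  # closed form: Ea = R ln(f2/f1) / (1/T1 - 1/T2)
  ea_oracle <- GAS_R * log(1e4 / 1e2) / (1 / 200 - 1 / 250) / 1000
  expect_equal(ea_oracle, 38.2895, tolerance = 1e-4)
  expect_equal(ft$Ea_kJ_mol, ea_oracle, tolerance = 1e-9)
  expect_equal(ft$rms, 0, tolerance = 1e-12)

  flat <- tibble::tibble(temperature_K = c(180, 220, 260), f0_Hz = 500)
  expect_equal(fit_arrhenius(flat)$Ea_kJ_mol, 0, tolerance = 1e-9)

  expect_error(fit_arrhenius(pts[1, ]), "at least 2")
})

test_that("Arrhenius fits recover published generator parameters exactly without noise", {
  # secondary-relaxation row used as generating truth: log f_inf 13.5, Ea 48.54
  T_K <- seq(150, 220, by = 10)
  f0 <- 10^(13.5 - 48.54e3 / (log(10) * GAS_R * T_K))
  ft <- fit_arrhenius(tibble::tibble(temperature_K = T_K, f0_Hz = f0))
  expect_equal(ft$log10_f_inf, 13.5, tolerance = 1e-9)
  expect_equal(ft$Ea_kJ_mol, 48.54, tolerance = 1e-9)
})

test_that("VFT fits recover generating triples, free and fixed f_inf", {
  vft_f <- function(lf, B, T0, T_K) 10^(lf - B / (log(10) * (T_K - T0)))
  T_K <- seq(250, 430, by = 10)
  pts <- tibble::tibble(temperature_K = T_K,
                        f0_Hz = vft_f(10.03, 2529, 144.5, T_K))
  ft <- quiet(fit_vft(pts))
  expect_equal(ft$log10_f_inf, 10.03, tolerance = 1e-4)
  expect_equal(ft$B, 2529, tolerance = 1e-3)
  expect_equal(ft$T0, 144.5, tolerance = 1e-3)
  expect_false(ft$flagged)

  ftf <- quiet(fit_vft(pts, fixed_log10_f_inf = 10.03))
  expect_equal(ftf$B, 2529, tolerance = 1e-6)
  expect_equal(ftf$T0, 144.5, tolerance = 1e-6)
  expect_true(ftf$fixed_f_inf)

  expect_error(fit_vft(pts[1:2, ]), "at least 3")
})

test_that("VFT estimates are unbiased under 1% log-noise over 50 seeds", {
  vft_f <- function(T_K) 10^(10.03 - 2529 / (log(10) * (T_K - 144.5)))
  T_K <- seq(250, 430, by = 10)
  est <- t(vapply(1:50, function(s) {
    withr::with_seed(s, {
      noisy <- vft_f(T_K) * 10^rnorm(length(T_K), 0, 0.01)
      ft <- quiet(fit_vft(tibble::tibble(temperature_K = T_K, f0_Hz = noisy)))
      c(ft$log10_f_inf, ft$B, ft$T0, ft$tg_C)
    })
  }, numeric(4)))
  med <- apply(est, 2, stats::median)
  mc_se <- apply(est, 2, stats::mad) / sqrt(50) * 3
  expect_lt(abs(med[1] - 10.03), max(mc_se[1], 0.02))
  expect_lt(abs(med[2] - 2529), max(mc_se[2], 15))
  expect_lt(abs(med[3] - 144.5), max(mc_se[3], 1))
  expect_lt(abs(med[4] - (-43.03)), max(mc_se[4], 0.3))
})

test_that("a VFT asymptote inside the data range is flagged", {
  # generating Vogel temperature 0.2 K below the coldest point: the fitted
  # asymptote collides with the data range
  T_K <- seq(255, 305, by = 10)
  f0 <- 10^(8 - 20 / (log(10) * (T_K - 254.8)))
  expect_warning(
    ft <- fit_vft(tibble::tibble(temperature_K = T_K, f0_Hz = f0)),
    "flagged")
  expect_true(ft$flagged)
})

test_that("Tg from VFT parameters matches published values and the numeric root", {
  expect_equal(tg_from_vft(10.03, B = 2529, T0 = 144.5), -43.0, tolerance = 0.2)
  expect_equal(tg_from_vft(6.03, B = 933.7, T0 = 306.4), 79.2, tolerance = 0.2)
  expect_equal(tg_from_vft(12.90, B = 3168, T0 = 70.75), -114.7, tolerance = 0.2)

  # constructed identity: T0 = 0 and B chosen so that Tg = 300 K exactly
  lf <- 9
  B300 <- log(10) * (2 + log10(2 * pi * 10^lf)) * 300
  expect_equal(tg_from_vft(lf, B = B300, T0 = 0), 300 - 273.15,
               tolerance = 1e-9)

  # Tg solves f_VFT(Tg) = 1/(2 pi 100) Hz
  fit <- vft_params(10.03, 2529, 144.5)
  tg_K <- kelvin(tg_from_vft(fit))
  root <- uniroot(function(T_K) {
    log10(vft_frequency(fit, T_K)) - log10(1 / (2 * pi * 100))
  }, c(fit$T0 + 1, 500), tol = 1e-12)$root
  expect_equal(tg_K, root, tolerance = 1e-9)

  expect_error(tg_from_vft(-12, B = 100, T0 = 100),
               class = "bdsfit_undefined_tg")
})

test_that("fragility matches published values and both algebraic forms agree", {
  expect_equal(fragility_from_vft(10.03, B = 2529, T0 = 144.5), 34.5,
               tolerance = 0.01 * 34.5)
  expect_equal(fragility_from_vft(4.76, B = 228.8, T0 = 396.9), 235.7,
               tolerance = 0.01 * 235.7)

  # T0 = 0 gives the Arrhenius-limit minimum m = 2 + log10(2 pi f_inf)
  expect_equal(fragility_from_vft(8, B = 1500, T0 = 0),
               2 + log10(2 * pi * 1e8), tolerance = 1e-12)

  withr::with_seed(21, {
    for (i in 1:1000) {
      lf <- runif(1, 2, 16)
      B <- runif(1, 100, 8000)
      T0 <- runif(1, 1, 400)
      C <- 2 + log10(2 * pi * 10^lf)
      m1 <- C * (1 + log(10) * C * T0 / B)
      tg_K <- T0 + B / (log(10) * C)
      m2 <- B * tg_K / (log(10) * (tg_K - T0)^2)
      expect_equal(m1, m2, tolerance = 1e-9)
      expect_equal(fragility_from_vft(lf, B = B, T0 = T0), m1,
                   tolerance = 1e-12)
      # and Tg equals the numeric root of the VFT law at 1/(2 pi 100) Hz
      fit <- vft_params(lf, B, T0)
      root <- uniroot(function(T_K) {
        (lf - B / (log(10) * (T_K - T0))) - log10(1 / (2 * pi * 100))
      }, c(T0 + 1e-6, T0 + B * 10), tol = 1e-13)$root
      expect_equal(kelvin(tg_from_vft(fit)), root, tolerance = 1e-9)
    }
  })
})

test_that("Tg and fragility are monotone in the VFT parameters", {
  T0s <- seq(50, 350, by = 50)
  tg_T0 <- vapply(T0s, function(T0) tg_from_vft(9, B = 2000, T0 = T0),
                  numeric(1))
  m_T0 <- vapply(T0s, function(T0) fragility_from_vft(9, B = 2000, T0 = T0),
                 numeric(1))
  expect_true(all(diff(tg_T0) > 0))
  expect_true(all(diff(m_T0) > 0))
  Bs <- seq(500, 5000, by = 500)
  tg_B <- vapply(Bs, function(B) tg_from_vft(9, B = B, T0 = 150), numeric(1))
  expect_true(all(diff(tg_B) > 0))
})

test_that("the log f0 = -2.8 crossing agrees with the VFT Tg and interpolates Arrhenius maps", {
  fit <- vft_params(10.03, 2529, 144.5)
  expect_equal(dielectric_tg_crossing(fit), tg_from_vft(fit), tolerance = 0.5)

  # Arrhenius group: interpolation in log f0 versus 1/T is exact
  T_K <- c(220, 240, 260, 280)
  lf0 <- 7 - 2300 / T_K  # crosses -2.8 between grid points
  pts <- tibble::tibble(temperature_K = T_K, f0_Hz = 10^lf0)
  T_cross <- 2300 / (7 + 2.8)
  expect_equal(dielectric_tg_crossing(pts), celsius(T_cross),
               tolerance = 1e-9)

  fast <- tibble::tibble(temperature_K = T_K, f0_Hz = 10^(2 + T_K / 100))
  expect_warning(out <- dielectric_tg_crossing(fast), "cross")
  expect_true(is.na(out))
})

test_that("relaxation maps group per label and keep pinning provenance out of refits", {
  mk_fit <- function(T_K, f0s, src) {
    procs <- list(hn_process(1, f0s[1], 0.5, 1, "a"),
                  hn_process(2, f0s[2], 0.8, 1, "b"))
    structure(list(
      temperature_K = T_K,
      model = dielectric_model(3, procs),
      params = tibble::tibble(
        term = rep(c("delta_eps", "f0", "a", "b"), 2),
        label = rep(c("a", "b"), each = 4),
        value = 1, free = TRUE,
        source = c("init", src[1], "init", "convention:b=1",
                   "init", src[2], "init", "convention:b=1"),
        std_error = NA_real_, at_bound = FALSE
      ),
      residual_norm = 0, deviance = 0, representation = "tan_delta",
      converged = TRUE, info = 1, message = "", n_points = 71, n_free = 6,
      freq_window = c(0.1, 1e6), unresolved = character(0)
    ), class = "isotherm_fit")
  }
  fits <- list(
    mk_fit(200, c(10, 1), c("init", "init")),
    mk_fit(210, c(100, 5), c("init", "init")),
    mk_fit(220, c(1000, 20), c("fixed:arrhenius", "init"))
  )
  map <- build_relaxation_map(fits)
  expect_equal(nrow(map), 6)
  expect_equal(sort(unique(map$process_label)), c("a", "b"))
  expect_equal(sum(map$provenance == "fixed:arrhenius"), 1)

  # pinned entries never feed the law refit of the same process
  pts_a <- map[map$process_label == "a", ]
  ft <- fit_arrhenius(pts_a)
  expect_equal(ft$n_points, 2)
})
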