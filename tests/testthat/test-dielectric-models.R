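test_that("HN term reproduces Debye limits and the static/unrelaxed limits", {
  debye <- hn_process(1, 1, 1, 1, label = "d")
  expect_equal(hn_term(debye, 1), 0.5 - 0.5i, tolerance = 1e-12)

  p <- hn_process(7, 10, 0.7, 0.6, label = "x")
  expect_equal(hn_term(p, 1e-9), 7 + 0i, tolerance = 1e-5)
  expect_equal(abs(hn_term(p, 1e12)), 0, tolerance = 1e-3)

  # a = b = 1 equals the Debye form to machine precision at arbitrary f
  f <- 10^seq(-2, 6, by = 0.5)
  p1 <- hn_process(3.2, 250, 1, 1, label = "d2")
  expect_equal(hn_term(p1, f), 3.2 / (1 + 1i * f / 250), tolerance = 1e-14)

  expect_error(hn_term(debye, 0), "positive")
  expect_error(hn_term(debye, -5), "positive")
})

test_that("HN term matches the direct complex-arithmetic value for a Cole-Cole case", {
  # independent evaluation: 2 / (1 + e^{i 0.4 pi}) at f = f0, a = 0.8, b = 1
  oracle <- 2 / (1 + exp(1i * 0.4 * pi))
  p <- hn_process(2, 100, 0.8, 1, label = "cc")
  expect_equal(hn_term(p, 100), oracle, tolerance = 1e-12)
  expect_equal(Re(oracle), 1, tolerance = 1e-12)
  expect_equal(-Im(oracle), 0.726543, tolerance = 1e-6)
})

test_that("conductivity term has the principal-branch real/loss split", {
  ohmic <- cond_term(2 * pi * EPS0, 1)
  expect_equal(conductivity_term(ohmic, 1), 0 - 1i, tolerance = 1e-12)

  expect_equal(conductivity_term(cond_term(0, 0.5), c(1, 10, 100)),
               rep(0 + 0i, 3))

  half <- cond_term(EPS0, 0.5)
  expect_equal(conductivity_term(half, 1 / (2 * pi)),
               cos(pi / 4) - 1i * sin(pi / 4), tolerance = 1e-12)

  # both components scale as f^-n
  ct <- cond_term(1e-10, 0.7)
  v <- conductivity_term(ct, c(1, 10))
  expect_equal(Re(v[1]) / Re(v[2]), 10^0.7, tolerance = 1e-12)
  expect_equal(Im(v[1]) / Im(v[2]), 10^0.7, tolerance = 1e-12)
  expect_error(conductivity_term(ct, 0), "positive")
})

test_that("composite model sums terms and honours the static limit", {
  m <- dielectric_model(3, list(hn_process(2, 10, label = "d")))
  e0 <- composite_eps(m, 1e-9)
  expect_equal(Re(e0), 5, tolerance = 1e-9)
  expect_equal(-Im(e0), 0, tolerance = 1e-9)

  m2 <- dielectric_model(3, conductivity = cond_term(1e-10, 1))
  expect_equal(Re(composite_eps(m2, 10^seq(-1, 6))), rep(3, 8),
               tolerance = 1e-12)

  # additivity by construction
  p1 <- hn_process(1, 1e3, 0.5, 1, "beta")
  p2 <- hn_process(4, 5, 0.8, 1, "alpha_c")
  ct <- cond_term(3e-12, 0.6)
  m3 <- dielectric_model(4, list(p1, p2), ct)
  f <- c(0.5, 30, 2e4)
  expect_equal(composite_eps(m3, f),
               4 + hn_term(p1, f) + hn_term(p2, f) + conductivity_term(ct, f),
               tolerance = 1e-14)
})

test_that("loss is non-negative for random valid parameter sets", {
  withr::with_seed(11, {
    for (i in 1:50) {
      m <- dielectric_model(
        1 + runif(1, 0, 5),
        list(hn_process(10^runif(1, -2, 2), 10^runif(1, -3, 6),
                        runif(1, 0.1, 1), runif(1, 0.1, 1), "p")),
        cond_term(10^runif(1, -16, -8), runif(1, 0.1, 1))
      )
      f <- 10^seq(-2, 7, length.out = 40)
      expect_true(all(-Im(composite_eps(m, f)) >= -1e-12))
    }
  })
})

test_that("tan delta is the pointwise loss/storage ratio and errors when unphysical", {
  m <- dielectric_model(4, list(hn_process(1e-9, 10, label = "null")))
  expect_equal(tan_delta(m, 10^seq(-1, 5)), rep(0, 7), tolerance = 1e-8)

  m2 <- dielectric_model(3, list(hn_process(2, 100, 0.7, 0.9, "p")),
                         cond_term(1e-11, 0.4))
  f <- 10^seq(-1, 6, by = 0.25)
  e <- composite_eps(m2, f)
  expect_equal(tan_delta(m2, f), -Im(e) / Re(e), tolerance = 1e-14)

  spec <- model_spectrum(m2, f)
  expect_equal(spec$tan_delta, spec$eps_imag / spec$eps_real, tolerance = 1e-14)
})

test_that("low-frequency tan delta plateau equals tan(n pi / 2)", {
  expect_equal(tan_delta_plateau(cond_term(1e-12, 0.5)), 1, tolerance = 1e-12)
  expect_equal(tan_delta_plateau(cond_term(1e-12, 0.9)), tan(0.45 * pi),
               tolerance = 1e-12)
  expect_equal(tan(0.45 * pi), 6.3138, tolerance = 1e-4)
  expect_error(tan_delta_plateau(cond_term(1e-12, 1)),
               class = "bdsfit_divergent_plateau")

  # a full composite model reaches the plateau far below every process
  for (n in c(0.3, 0.5, 0.9)) {
    m <- dielectric_model(3, list(hn_process(2, 100, 0.8, 1, "p")),
                          cond_term(1e-8, n))
    f_low <- 1e-6 * 100
    expect_equal(tan_delta(m, f_low), tan(n * pi / 2), tolerance = 0.01)
  }
})

test_that("loss-peak closed form matches a brute-force grid argmax", {
  # Debye and symmetric Cole-Cole peak exactly at f0
  expect_equal(hn_loss_peak_frequency(hn_process(1, 42, 1, 1, "d")), 42)
  expect_equal(hn_loss_peak_frequency(hn_process(1, 42, 0.5, 1, "cc")), 42)

  grid_argmax <- function(p) {
    f <- 10^seq(log10(p$f0) - 4, log10(p$f0) + 4, length.out = 2e5)
    f[which.max(-Im(hn_term(p, f)))]
  }
  p <- hn_process(1, 1e3, 0.8, 0.4, "hn")
  expect_equal(hn_loss_peak_frequency(p), grid_argmax(p), tolerance = 1e-3)

  # For broad shape exponents the loss maximum is extremely flat, so the
  # argmax position itself is ill-conditioned; the defining property is that
  # no grid point exceeds the loss at the closed-form frequency beyond the
  # grid's numerical resolution.
  withr::with_seed(7, {
    for (i in 1:100) {
      p <- hn_process(1, 10^runif(1, -2, 5),
                      runif(1, 0.15, 1), runif(1, 0.15, 1), "r")
      f <- 10^seq(log10(p$f0) - 4, log10(p$f0) + 4, length.out = 2e5)
      max_grid <- max(-Im(hn_term(p, f)))
      at_closed <- -Im(hn_term(p, hn_loss_peak_frequency(p)))
      expect_gte(at_closed, max_grid * (1 - 1e-9))
    }
  })
})

test_that("model serialisation round-trips through plain lists", {
  m <- dielectric_model(
    3.5,
    list(hn_process(1.2, 3e3, 0.45, 1, "beta"),
         hn_process(8, 0.8, 0.8, 0.6, "slow")),
    cond_term(2.5e-12, 0.37)
  )
  m2 <- model_from_list(model_to_list(m))
  f <- 10^seq(-1, 6, by = 0.5)
  expect_equal(composite_eps(m2, f), composite_eps(m, f), tolerance = 1e-15)
  expect_equal(vapply(m2$processes, `[[`, character(1), "label"),
               c("beta", "slow"))
})

test_that("constructors validate their domains", {
  expect_error(hn_process(-1, 10), "delta_eps")
  expect_error(hn_process(1, 10, a = 1.2), "`a`")
  expect_error(hn_process(1, 10, b = 0), "`b`")
  expect_error(cond_term(-1e-12, 0.5), "sigma0")
  expect_error(cond_term(1e-12, 1.4), "`n`")
  expect_error(dielectric_model(0.5), "eps_inf")
  expect_error(
    dielectric_model(3, list(hn_process(1, 1, label = "x"),
                             hn_process(1, 2, label = "x"))),
    "unique")
})
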