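test_that("long-table reader parses comments, sorts frequencies, computes tan delta", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# toy two-temperature table",
    "temperature_C,frequency_Hz,eps_real,eps_imag",
    "-40,100,5.0,0.5",
    "-40,1,6.0,1.2",
    "-40,10,5.5,0.9",
    "-20,1,7.0,2.0",
    "-20,10,6.2,1.1",
    "-20,100,5.8,0.6"
  ), path)
  ds <- read_spectra(path)
  expect_s3_class(ds, "bds_spectra")
  expect_equal(nrow(ds), 6)
  expect_equal(sort(unique(ds$temperature_K)), kelvin(c(-40, -20)))
  isos <- split_isotherms(ds)
  expect_length(isos, 2)
  expect_equal(isos[[1]]$frequency_Hz, c(1, 10, 100))  # sorted on load
  expect_equal(ds$tan_delta, ds$eps_imag / ds$eps_real)
})

test_that("tab-delimited input and the per-temperature dialect are accepted", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "temperature_C\tfrequency_Hz\teps_real\teps_imag",
    "-40\t1\t6.0\t1.2",
    "-40\t10\t5.5\t0.9"
  ), tab)
  expect_equal(nrow(read_spectra(tab)), 2)

  dirpath <- withr::local_tempdir()
  writeLines(c("temperature_C,frequency_Hz,eps_real,eps_imag",
               "-40,1,6.0,1.2", "-40,10,5.5,0.9"),
             file.path(dirpath, "T1.csv"))
  writeLines(c("temperature_C,frequency_Hz,eps_real,eps_imag",
               "-20,1,7.0,2.0", "-20,10,6.2,1.1"),
             file.path(dirpath, "T2.csv"))
  ds <- read_spectra(dirpath, dialect = "per-temperature")
  expect_equal(dplyr::n_distinct(ds$temperature_K), 2)
})

test_that("malformed tables fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature_C,frequency_Hz,eps_real",
               "-40,1,6.0"), path)
  expect_error(read_spectra(path), "eps_imag")

  dup <- tibble::tibble(temperature_C = c(-40, -40), frequency_Hz = c(1, 1),
                        eps_real = c(6, 6), eps_imag = c(1, 1))
  expect_error(as_bds_spectra(dup), "Duplicate.*row 2")

  bad <- tibble::tibble(temperature_C = -40, frequency_Hz = 1,
                        eps_real = -2, eps_imag = 1)
  expect_error(as_bds_spectra(bad), "eps_real")
  expect_error(read_spectra(withr::local_tempfile()), "not found")
})

test_that("write/read round trip is lossless at double precision", {
  gen <- generate_dataset(two_process_protocol(noise_sd = 0.01), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(gen$spectra, path)
  back <- read_spectra(path)
  for (col in c("temperature_K", "frequency_Hz", "eps_real", "eps_imag")) {
    expect_equal(back[[col]], gen$spectra[[col]], tolerance = 1e-12)
  }
})

test_that("fit reports round-trip parameter values exactly", {
  expect_silent(write_fit_report(list(), p0 <- withr::local_tempfile()))
  expect_length(read_fit_report(p0)$results, 0)

  gen <- generate_dataset(bds_preset("debye_single"), seed = 1)
  iso <- split_isotherms(gen$spectra)[[4]]
  cfg <- fit_config(list(process_spec("debye", a = 1)),
                    include_conductivity = FALSE, seed = 1)
  r <- quiet(fit_isotherm(iso, cfg))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(list(r), path)
  doc <- read_fit_report(path)
  expect_length(doc$results, 1)
  entry <- doc$results[[1]]
  expect_length(entry$processes, 1)
  expect_equal(entry$processes$debye$f0, r$model$processes[[1]]$f0,
               tolerance = 1e-12)
  expect_equal(entry$processes$debye$delta_eps,
               r$model$processes[[1]]$delta_eps, tolerance = 1e-12)
  expect_equal(entry$eps_inf, r$model$eps_inf, tolerance = 1e-12)
})

test_that("relaxation-map export carries the 1000/T and log10 f0 columns", {
  map <- tibble::tibble(
    process_label = c("beta", "beta"),
    temperature_K = c(200, 250),
    f0_Hz = c(1e2, 1e4),
    provenance = "fitted"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_relaxation_map(map, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$inv1000_over_T, 1000 / c(200, 250))
  expect_equal(back$log10_f0, c(2, 4))
  expect_named(back, c("process_label", "temperature_K", "inv1000_over_T",
                       "log10_f0", "provenance"))
})
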