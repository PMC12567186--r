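# Reading/writing isothermal spectra, fit reports and relaxation maps in
# plain delimited-text and JSON formats.
#
# The canonical in-memory form of a spectra dataset is a long tibble of class
# "bds_spectra": one row per (temperature, frequency) point, with columns
#   sample_id, ramp, temperature_K, frequency_Hz, eps_real, eps_imag, tan_delta
# sorted by temperature then frequency.  Temperatures are kelvin internally;
# the on-disk long-table dialect carries temperature_C (matching the axis
# conventions of dielectric-relaxation figures), converted on load/save with
# the exact offset 273.15.

.spectra_cols <- c("sample_id", "ramp", "temperature_K", "frequency_Hz",
                   "eps_real", "eps_imag", "tan_delta")

#' Validate and normalise a spectra table
#'
#' Coerces a long data frame of isothermal spectra to the canonical
#' `bds_spectra` tibble: adds `sample_id`/`ramp` defaults, converts a
#' `temperature_C` column to `temperature_K`, computes `tan_delta` as
#' eps''/eps' when absent, sorts frequencies ascending within each isotherm,
#' and checks the invariants (positive eps', non-negative eps'', no duplicate
#' (temperature, frequency) pair within a ramp).
#'
#' @param x A data frame with at least `frequency_Hz`, `eps_real`, `eps_imag`
#'   and one of `temperature_K`/`temperature_C`.
#' @param sample_id Default sample id used if the table has no `sample_id`
#'   column.
#' @return A `bds_spectra` tibble.
#' @export
as_bds_spectra <- function(x, sample_id = "sample") {
  x <- as_tibble(x)
  if (!"temperature_K" %in% names(x)) {
    if (!"temperature_C" %in% names(x)) {
      abort("Need a `temperature_K` or `temperature_C` column.")
    }
    x$temperature_K <- kelvin(x$temperature_C)
  }
  x$temperature_C <- NULL
  required <- c("temperature_K", "frequency_Hz", "eps_real", "eps_imag")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  for (col in required) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))))[1]
      abort(sprintf("Non-numeric value in column `%s` (row %d).", col,
                    if (is.na(bad)) 1L else bad))
    }
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- sample_id
  if (!"ramp" %in% names(x)) x$ramp <- 1L
  if (!"tan_delta" %in% names(x)) x$tan_delta <- x$eps_imag / x$eps_real

  dup <- duplicated(x[c("ramp", "temperature_K", "frequency_Hz")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "Duplicate (temperature, frequency) pair at row %d: T = %g K, f = %g Hz (ramp %s).",
      i, x$temperature_K[i], x$frequency_Hz[i], x$ramp[i]
    ))
  }
  if (any(x$eps_real <= 0)) {
    abort(sprintf("eps_real must be > 0 everywhere (row %d violates).",
                  which(x$eps_real <= 0)[1]))
  }
  if (any(x$eps_imag < 0)) {
    abort(sprintf("eps_imag must be >= 0 everywhere (row %d violates).",
                  which(x$eps_imag < 0)[1]))
  }
  if (any(x$frequency_Hz <= 0)) {
    abort(sprintf("frequency_Hz must be > 0 (row %d violates).",
                  which(x$frequency_Hz <= 0)[1]))
  }
  x <- dplyr::arrange(x, .data$ramp, .data$temperature_K, .data$frequency_Hz)
  x <- x[, c(.spectra_cols, setdiff(names(x), .spectra_cols))]
  class(x) <- c("bds_spectra", class(tibble()))
  x
}

#' Read isothermal spectra from delimited text
#'
#' Long-table dialect: one file with header columns `temperature_C`,
#' `frequency_Hz`, `eps_real`, `eps_imag` (comma- or tab-delimited, `#`
#' comment lines ignored; optional `tan_delta`, `ramp`, `sample_id` columns).
#' Per-temperature dialect: `path` is a directory whose delimited files each
#' hold one or more isotherms in the same column layout.
#'
#' @param path File (long-table) or directory (per-temperature) path.
#' @param dialect `"long-table"` or `"per-temperature"`.
#' @param sample_id Default sample id if the table has none.
#' @return A `bds_spectra` tibble (see [as_bds_spectra()]), frequencies sorted
#'   ascending within each isotherm, `tan_delta` computed if not present.
#' @export
read_spectra <- function(path, dialect = c("long-table", "per-temperature"),
                         sample_id = "sample") {
  dialect <- match.arg(dialect)
  read_one <- function(p) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
    first <- readLines(p, n = 50L, warn = FALSE)
    first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))][1]
    delim <- if (grepl("\t", first)) "\t" else ","
    readr::read_delim(p, delim = delim, comment = "#", show_col_types = FALSE,
                      trim_ws = TRUE, progress = FALSE)
  }
  tbl <- if (dialect == "long-table") {
    read_one(path)
  } else {
    if (!dir.exists(path)) abort(sprintf("Directory not found: %s", path))
    files <- sort(list.files(path, pattern = "\\.(csv|tsv|txt)$",
                             full.names = TRUE))
    if (!length(files)) abort(sprintf("No delimited files in %s", path))
    dplyr::bind_rows(lapply(files, read_one))
  }
  as_bds_spectra(tbl, sample_id = sample_id)
}

#' Write isothermal spectra as a long delimited table
#'
#' Emits the long-table dialect read by [read_spectra()]: columns
#' `temperature_C`, `frequency_Hz`, `eps_real`, `eps_imag`, `tan_delta`,
#' `ramp`, `sample_id`.  Values are written with shortest round-trip
#' precision, so a write/read cycle is lossless at double precision.
#'
#' @param x A `bds_spectra` tibble (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  x <- as_bds_spectra(x)
  out <- tibble(
    sample_id = x$sample_id,
    ramp = x$ramp,
    temperature_C = celsius(x$temperature_K),
    frequency_Hz = x$frequency_Hz,
    eps_real = x$eps_real,
    eps_imag = x$eps_imag,
    tan_delta = x$tan_delta
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a spectra table into isotherms
#'
#' @param x A `bds_spectra` tibble.
#' @return A list of single-temperature tibbles, ordered by ramp then
#'   temperature.
#' @export
split_isotherms <- function(x) {
  x <- as_bds_spectra(x)
  key <- interaction(x$ramp, x$temperature_K, drop = TRUE, lex.order = TRUE)
  unname(split(x, key))
}

# fit reports ---------------------------------------------------------------

.report_schema <- "bdsfit-fit-report/1"

#' Write a JSON fit report
#'
#' Serialises a list of per-isotherm fit results (see [fit_isotherm()]) to a
#' schema-versioned JSON document: per temperature, per process label the
#' `(delta_eps, f0, a, b)` values and which of them were held fixed, plus
#' `eps_inf`, the conductivity `(sigma0, n)`, the residual norm and the fitted
#' representation.
#'
#' @param results A list of `isotherm_fit` objects (possibly empty), or a
#'   `bds_fit_set` from [fit_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(results, path) {
  if (inherits(results, "bds_fit_set")) results <- results$fits
  stopifnot(is.list(results))
  entry <- function(r) {
    stopifnot(inherits(r, "isotherm_fit"))
    m <- r$model
    procs <- lapply(m$processes, function(p) {
      fixed <- r$params$term[r$params$label %in% p$label & !r$params$free]
      list(delta_eps = p$delta_eps, f0 = p$f0, a = p$a, b = p$b,
           fixed = as.list(fixed))
    })
    names(procs) <- vapply(m$processes, `[[`, character(1), "label")
    list(
      temperature_K = r$temperature_K,
      representation = r$representation,
      eps_inf = m$eps_inf,
      sigma0 = if (is.null(m$conductivity)) NULL else m$conductivity$sigma0,
      n = if (is.null(m$conductivity)) NULL else m$conductivity$n,
      residual_norm = r$residual_norm,
      converged = r$converged,
      unresolved = as.list(r$unresolved),
      processes = procs
    )
  }
  doc <- list(schema = .report_schema, results = lapply(results, entry))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path Path to a file written by [write_fit_report()].
#' @return A list with `schema` and `results` (list of per-isotherm entries).
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, .report_schema)) {
    abort(sprintf("Unrecognised fit-report schema: %s", doc$schema %||% "<none>"))
  }
  doc
}

#' Write a relaxation map as CSV
#'
#' Columns `process_label`, `temperature_K`, `inv1000_over_T`, `log10_f0`
#' (plus `provenance`), the layout used for relaxation plots of
#' log10 f0 versus 1000/T.
#'
#' @param map A `relaxation_map` tibble from [build_relaxation_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_relaxation_map <- function(map, path) {
  stopifnot(is.data.frame(map))
  out <- tibble(
    process_label = map$process_label,
    temperature_K = map$temperature_K,
    inv1000_over_T = 1000 / map$temperature_K,
    log10_f0 = log10(map$f0_Hz),
    provenance = map$provenance
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
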