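#' Default measurement frequency grid
#'
#' Thirteen logarithmically spaced frequencies spanning 1.00 to 49.00 kHz,
#' the band explored by the tetrapolar spectroscopy instrument.
#'
#' @param n Number of points (default 13).
#' @param fmin,fmax Band edges in Hz.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function(n = 13, fmin = 1000, fmax = 49000) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Impedance spectrum container
#'
#' Frequencies with complex impedance, or magnitude-only data as delivered by
#' the instrument.
#'
#' @param frequency_hz Strictly increasing frequencies in Hz.
#' @param z Complex impedances in Ohm, or a numeric vector of magnitudes
#'   (then `magnitude_only` is set).
#' @param metadata Optional named list (subject id, provenance, ...).
#' @return An object of class `"impedance_spectrum"` with fields
#'   `frequency_hz`, `z` (complex or NULL), `magnitude` and `phase_deg`
#'   (NULL when magnitude-only).
#' @export
impedance_spectrum <- function(frequency_hz, z, metadata = list()) {
  if (!is.numeric(frequency_hz) || any(!is.finite(frequency_hz)) ||
      any(frequency_hz <= 0))
    stop_validation("frequencies must be positive and finite")
  if (is.unsorted(frequency_hz, strictly = TRUE))
    stop_validation("frequencies must be strictly increasing")
  if (length(z) != length(frequency_hz))
    stop_validation("'z' and 'frequency_hz' must have equal length")
  if (is.complex(z)) {
    mag <- Mod(z); phase <- Arg(z) * 180 / pi
  } else if (is.numeric(z)) {
    mag <- as.numeric(z); z <- NULL; phase <- NULL
  } else stop_validation("'z' must be complex or numeric")
  if (any(!is.finite(mag)) || any(mag <= 0))
    stop_validation("|Z| must be positive and finite")
  structure(list(frequency_hz = as.numeric(frequency_hz), z = z,
                 magnitude = mag, phase_deg = phase, metadata = metadata),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies in [%.4g, %.4g] Hz%s\n",
              length(x$frequency_hz), min(x$frequency_hz), max(x$frequency_hz),
              if (is.null(x$z)) " (magnitude only)" else ""))
  cat(sprintf("  |Z| in [%.4g, %.4g] Ohm\n", min(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  df <- data.frame(frequency_hz = x$frequency_hz, z_abs_ohm = x$magnitude)
  if (!is.null(x$phase_deg)) df$z_phase_deg <- x$phase_deg
  df
}

#' Read an impedance spectrum from CSV
#'
#' Expects columns `frequency_hz`, `z_abs_ohm` and optionally `z_phase_deg`;
#' lines starting with `#` are collected as metadata. Frequencies must be
#' strictly increasing.
#'
#' @param path CSV file path.
#' @return An [impedance_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))
  lines <- readLines(path)
  is_meta <- startsWith(trimws(lines), "#")
  meta <- sub("^\\s*#\\s*", "", lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2)
    stop_validation(sprintf("%s: no data rows found", path))
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop_validation(sprintf("%s: parse failure: %s",
                                                path, conditionMessage(e))))
  need <- c("frequency_hz", "z_abs_ohm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_validation(sprintf("%s: missing column(s) %s", path,
                            paste(missing, collapse = ", ")))
  for (col in intersect(c(need, "z_phase_deg"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop_validation(sprintf("%s: non-numeric value in column '%s' at data row %d",
                              path, col, bad))
    }
    df[[col]] <- v
  }
  f <- df$frequency_hz
  if (anyDuplicated(f) || is.unsorted(f, strictly = TRUE)) {
    bad <- which(diff(f) <= 0)[1] + 1L
    stop_validation(sprintf(
      "%s: frequencies must be strictly increasing (violated at data row %d, frequency %g Hz)",
      path, bad, f[bad]))
  }
  z <- if ("z_phase_deg" %in% names(df))
    complex(modulus = df$z_abs_ohm, argument = df$z_phase_deg * pi / 180)
  else df$z_abs_ohm
  impedance_spectrum(f, z, metadata = list(header = meta, path = path))
}

#' Write an impedance spectrum to CSV
#'
#' Emits `#`-prefixed metadata lines followed by `frequency_hz`, `z_abs_ohm`
#' and (for complex spectra) `z_phase_deg`; the output is accepted verbatim by
#' [read_spectrum_csv()].
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path Output file path.
#' @param metadata Character vector of metadata lines (written as comments).
#' @export
write_spectrum_csv <- function(spectrum, path, metadata = character()) {
  if (!inherits(spectrum, "impedance_spectrum"))
    stop_validation("'spectrum' must be an impedance_spectrum")
  df <- as.data.frame(spectrum)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in metadata) writeLines(paste0("# ", m), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
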