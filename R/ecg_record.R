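#' Multi-lead ECG record
#'
#' An `ecg_record` holds a multi-lead voltage time series: a numeric matrix
#' with one row per time sample and one column per lead (millivolts), the
#' sampling rate in Hz, and an ordered set of unique lead names. Time is
#' sample-indexed from zero; no timestamps are stored.
#'
#' @param voltages numeric matrix, one row per sample, one column per lead
#'   (mV). A plain vector is treated as a single lead.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param lead_names character vector of unique lead labels, one per column.
#'   Names matching the six frontal-plane leads (I, II, III, aVR, aVL, aVF)
#'   are normalized to their canonical capitalization.
#' @return An object of class `ecg_record` with fields `voltages`,
#'   `sample_rate_hz`, `lead_names` and `n_samples`.
#' @examples
#' r <- ecg_record(cbind(sin(1:100), cos(1:100)), 257, c("I", "II"))
#' r$n_samples
#' @export
ecg_record <- function(voltages, sample_rate_hz, lead_names) {
  if (is.vector(voltages)) voltages <- matrix(voltages, ncol = 1L)
  if (!is.matrix(voltages) || !is.numeric(voltages))
    stop("`voltages` must be a numeric matrix (samples x leads)")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a single positive number")
  lead_names <- canonical_lead_names(as.character(lead_names))
  if (length(lead_names) != ncol(voltages))
    stop(sprintf("%d lead names for %d voltage columns",
                 length(lead_names), ncol(voltages)))
  if (anyDuplicated(lead_names))
    stop("lead names must be unique")
  if (nrow(voltages) < 1L)
    stop("record must contain at least one sample")
  if (!all(is.finite(voltages)))
    stop("voltages must be finite")
  colnames(voltages) <- lead_names
  structure(
    list(voltages = voltages,
         sample_rate_hz = as.numeric(sample_rate_hz),
         lead_names = lead_names,
         n_samples = nrow(voltages)),
    class = "ecg_record")
}

# Canonical capitalization for the six frontal-plane limb leads; the
# literature mixes case ("avF", "AVF"), so matching is case-insensitive.
canonical_lead_names <- function(x) {
  canon <- c("I", "II", "III", "aVR", "aVL", "aVF")
  idx <- match(tolower(x), tolower(canon))
  ifelse(is.na(idx), x, canon[idx])
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d leads (%s), %d samples @ %g Hz (%.2f s)\n",
              length(x$lead_names), paste(x$lead_names, collapse = ", "),
              x$n_samples, x$sample_rate_hz,
              x$n_samples / x$sample_rate_hz))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, leads = x$lead_names, ...) {
  leads <- canonical_lead_names(leads)
  t <- seq(0, by = 1 / x$sample_rate_hz, length.out = x$n_samples)
  old <- graphics::par(mfrow = c(length(leads), 1L),
                       mar = c(2, 4, 0.5, 0.5))
  on.exit(graphics::par(old))
  for (l in leads) {
    graphics::plot(t, x$voltages[, l], type = "l", xlab = "time (s)",
                   ylab = paste0(l, " (mV)"), ...)
  }
  invisible(x)
}

#' Duration of an ECG record in seconds
#' @param record an [ecg_record()].
#' @return duration in seconds (`n_samples / sample_rate_hz`).
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  record$n_samples / record$sample_rate_hz
}

#' Select and reorder ECG leads
#'
#' Returns a record whose columns are exactly the requested leads in the
#' requested order. Matching is case-insensitive for the six frontal-plane
#' lead names, so `"avF"` selects lead aVF.
#'
#' @param record an [ecg_record()].
#' @param wanted character vector of lead labels, in the desired order.
#' @return An `ecg_record` with the requested leads; sampling rate unchanged.
#' @examples
#' r <- ecg_record(matrix(rnorm(30), ncol = 3), 257, c("I", "II", "III"))
#' select_leads(r, c("III", "I"))$lead_names
#' @export
select_leads <- function(record, wanted) {
  stopifnot(inherits(record, "ecg_record"))
  wanted <- canonical_lead_names(as.character(wanted))
  idx <- match(tolower(wanted), tolower(record$lead_names))
  if (anyNA(idx)) {
    stop(sprintf("lead(s) not found: %s; available leads: %s",
                 paste(wanted[is.na(idx)], collapse = ", "),
                 paste(record$lead_names, collapse = ", ")))
  }
  ecg_record(record$voltages[, idx, drop = FALSE],
             record$sample_rate_hz, record$lead_names[idx])
}

#' Read an ECG record from a delimited text file
#'
#' Reads a comma-separated file with a mandatory header row of lead names
#' and one numeric column per lead ("." decimal). Trailing blank lines are
#' tolerated; ragged or non-numeric rows are an error.
#'
#' @param path path to the CSV file.
#' @param sample_rate_hz sampling rate in Hz (not stored in the file).
#' @return An [ecg_record()] with columns in file order.
#' @export
read_delimited <- function(path, sample_rate_hz) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # tolerate trailing blank lines only
  while (length(lines) > 0L && grepl("^\\s*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L)
    stop(sprintf("format error in %s: need a header row and at least one data row", path))
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(fields[[1L]])
  ncols <- length(header)
  n <- length(lines) - 1L
  v <- matrix(NA_real_, nrow = n, ncol = ncols)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncols)
      stop(sprintf("format error in %s: row %d has %d fields, expected %d",
                   path, i + 1L, length(row), ncols))
    num <- suppressWarnings(as.numeric(row))
    if (anyNA(num))
      stop(sprintf("format error in %s: non-numeric value '%s' in row %d",
                   path, trimws(row[which(is.na(num))[1L]]), i + 1L))
    v[i, ] <- num
  }
  ecg_record(v, sample_rate_hz, header)
}

#' Write an ECG record to disk
#'
#' Writes either a comma-separated text file (header row of lead names,
#' full double precision) or a WFDB header/signal pair (16-bit integer
#' storage; voltages are quantized by the ADC gain, 1/2000 mV by default).
#'
#' @param record an [ecg_record()].
#' @param path output path. For `format = "wfdb"` this is the record path
#'   without extension (`path.hea` and `path.dat` are written).
#' @param format `"delimited"` (CSV) or `"wfdb"`.
#' @param gain WFDB ADC gain in units per mV (quantization step `1/gain` mV).
#' @return Invisibly, the path(s) written.
#' @export
write_record <- function(record, path, format = c("delimited", "wfdb"),
                         gain = 2000) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  if (record$n_samples < 1L)
    stop("refusing to write a record with no samples")
  if (format == "delimited") {
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error"))
      stop(sprintf("cannot write to %s", path))
    on.exit(close(con))
    writeLines(paste(record$lead_names, collapse = ","), con)
    lines <- apply(record$voltages, 1L, function(row)
      paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ","))
    writeLines(lines, con)
    invisible(path)
  } else {
    write_wfdb(record, path, gain = gain)
  }
}
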