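#' Read a WFDB record
#'
#' Reads a PhysioNet WFDB record: the `.hea` header plus its signal file(s).
#' Supported storage format is 16 (16-bit two's-complement little-endian,
#' samples interleaved across signals), which covers records written by
#' [write_record()] and many PhysioNet holdings. Digital values are
#' converted to physical units with each signal's gain and baseline; every
#' signal must declare millivolt units (`mV`), otherwise the record is
#' rejected rather than silently assuming a scale.
#'
#' @param record_path path to the record, with or without the `.hea`
#'   extension.
#' @return An [ecg_record()] with all leads present in the header, in
#'   header order, voltages in mV.
#' @export
read_wfdb <- function(record_path) {
  hea <- if (grepl("\\.hea$", record_path)) record_path
         else paste0(record_path, ".hea")
  if (!file.exists(hea))
    stop(sprintf("WFDB format error: header file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L)
    stop(sprintf("WFDB format error in %s: missing record or signal lines", hea))
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec) < 4L)
    stop(sprintf("WFDB format error in %s: record line needs 'name nsig fs nsamples'", hea))
  nsig <- as.integer(rec[2L])
  fs <- as.numeric(rec[3L])
  nsamp <- as.integer(rec[4L])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp) || nsig < 1L || fs <= 0 || nsamp < 1L)
    stop(sprintf("WFDB format error in %s: bad record line '%s'", hea, lines[[1L]]))
  sig_lines <- lines[1L + seq_len(nsig)]
  if (anyNA(sig_lines))
    stop(sprintf("WFDB format error in %s: %d signal lines declared, fewer found",
                 hea, nsig))
  sig <- lapply(sig_lines, parse_wfdb_signal_line, hea = hea)
  dat_files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(dat_files) != 1L)
    stop(sprintf("WFDB format error in %s: all signals must share one signal file", hea))
  if (!all(vapply(sig, `[[`, "", "format") == "16"))
    stop(sprintf("WFDB format error in %s: only storage format 16 is supported", hea))
  units <- vapply(sig, `[[`, "", "units")
  if (any(units == ""))
    stop(sprintf("WFDB format error in %s: signal(s) without units metadata; refusing to guess a voltage scale", hea))
  if (!all(tolower(units) == "mv"))
    stop(sprintf("WFDB format error in %s: unsupported units '%s' (only mV)",
                 hea, paste(unique(units[tolower(units) != "mv"]), collapse = ", ")))
  dat <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat))
    stop(sprintf("WFDB I/O error: signal file not found: %s", dat))
  raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp)
    stop(sprintf("WFDB I/O error: %s holds %d samples, header declares %d",
                 dat, length(raw), nsig * nsamp))
  digital <- matrix(raw, nrow = nsamp, ncol = nsig, byrow = TRUE)
  gain <- vapply(sig, `[[`, 0, "gain")
  baseline <- vapply(sig, `[[`, 0, "baseline")
  physical <- sweep(sweep(digital, 2L, baseline, "-"), 2L, gain, "/")
  ecg_record(physical, fs, vapply(sig, `[[`, "", "description"))
}

# One WFDB signal line: file format[xN] gain(baseline)/units adcres adczero
# initval checksum blocksize description. Gain defaults (200) are rejected
# upstream only if units are missing; an explicit gain is required here.
parse_wfdb_signal_line <- function(line, hea) {
  tok <- strsplit(trimws(line), "\\s+")[[1L]]
  if (length(tok) < 3L)
    stop(sprintf("WFDB format error in %s: bad signal line '%s'", hea, line))
  gain_spec <- tok[3L]
  m <- regmatches(gain_spec,
                  regexec("^(-?[0-9.]+)(\\(([-0-9]+)\\))?(/(.*))?$", gain_spec))[[1L]]
  if (length(m) == 0L || m[2L] == "")
    stop(sprintf("WFDB format error in %s: cannot parse gain spec '%s'", hea, gain_spec))
  gain <- as.numeric(m[2L])
  if (!is.finite(gain) || gain <= 0)
    stop(sprintf("WFDB format error in %s: non-positive gain in '%s'", hea, gain_spec))
  baseline <- if (m[4L] != "") as.numeric(m[4L]) else 0
  units <- if (length(m) >= 6L) m[6L] else ""
  desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
  list(file = tok[1L], format = sub("x[0-9]+$", "", tok[2L]),
       gain = gain, baseline = baseline, units = units, description = desc)
}

# Writer counterpart of read_wfdb: format 16, one .dat, gain/baseline per
# signal, units mV. Quantization step is 1/gain mV.
write_wfdb <- function(record, record_path, gain = 2000) {
  base <- sub("\\.hea$", "", record_path)
  name <- basename(base)
  nsig <- length(record$lead_names)
  digital <- round(record$voltages * gain)
  if (any(abs(digital) > 32767))
    stop(sprintf("voltages exceed the 16-bit range at gain %g; reduce the gain", gain))
  storage.mode(digital) <- "integer"
  checksum <- vapply(seq_len(nsig), function(j) {
    s <- sum(as.numeric(digital[, j])) %% 65536
    as.integer(if (s > 32767) s - 65536 else s)
  }, 0L)
  hea <- c(sprintf("%s %d %g %d", name, nsig, record$sample_rate_hz,
                   record$n_samples),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
                   name, gain, digital[1L, ], checksum, record$lead_names))
  hea_path <- paste0(base, ".hea")
  dat_path <- paste0(base, ".dat")
  ok <- try(writeLines(hea, hea_path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write to %s", hea_path))
  con <- file(dat_path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(digital)), con, size = 2L, endian = "little")
  invisible(c(hea_path, dat_path))
}
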