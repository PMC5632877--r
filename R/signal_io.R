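#' Construct a single-channel EEG recording
#'
#' The basic container used throughout the package: a uniformly sampled
#' single-channel amplitude series in microvolts, the sampling rate, a channel
#' label, and the offset of the first sample relative to session start.
#'
#' @param samples Numeric vector of amplitudes in microvolts. Must be finite.
#' @param fs Sampling rate in Hz (positive scalar). The study device sampled a
#'   single prefrontal (~Fpz) electrode at 512 Hz; any positive rate is
#'   accepted.
#' @param channel_label Channel name, default `"EEG"`.
#' @param t0 Start time of the first sample in seconds, default 0.
#' @return An object of class `eeg_recording`: a list with elements `samples`,
#'   `fs`, `channel_label`, `t0`.
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 2 * seq(0, 10, by = 1 / 256)), fs = 256)
#' duration_s(rec)
#' @export
eeg_recording <- function(samples, fs, channel_label = "EEG", t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(samples) < 1L)
    stop("recording must contain at least one sample", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_label = as.character(channel_label), t0 = as.numeric(t0)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              x$channel_label, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$fs
}

#' Read an EEG recording from EDF or CSV
#'
#' CSV files must have two columns, time in seconds and amplitude in
#' microvolts (header optional); the sampling rate is inferred from the median
#' time step and the timebase must be uniform to within 1% of that step.
#' EDF (European Data Format) files are read with a minimal built-in parser;
#' the sampling rate and channel labels come from the header.
#'
#' @param path Path to a `.edf` or `.csv` file.
#' @param channel Channel selector for EDF files: an index or a label.
#'   Defaults to the first channel. Ignored for CSV.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path, channel = channel)
  } else {
    read_recording_csv(path)
  }
}

read_recording_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*,", first)
  df <- read.csv(path, header = has_header,
                 col.names = c("time_s", "amplitude_uV"))
  if (nrow(df) < 2L) stop("CSV recording needs at least 2 rows", call. = FALSE)
  dt <- diff(df$time_s)
  med <- median(dt)
  if (med <= 0) stop("CSV timebase is not increasing", call. = FALSE)
  if (max(abs(dt - med)) > 0.01 * med)
    stop("CSV timebase is not uniform (deviation exceeds 1% of the median step)",
         call. = FALSE)
  eeg_recording(df$amplitude_uV, fs = 1 / med, t0 = df$time_s[1L])
}

#' Write an EEG recording to a two-column CSV
#'
#' Columns `time_s, amplitude_uV`; the inverse of the CSV branch of
#' [read_recording()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  t <- rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
  write.csv(data.frame(time_s = t, amplitude_uV = rec$samples),
            path, row.names = FALSE)
  invisible(path)
}

# Minimal EDF reader: fixed 256-byte header, 256 bytes per signal, data
# records of little-endian int16 scaled by the physical/digital ranges.
read_edf <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_txt(8)                          # version
  hdr_txt(80); hdr_txt(80)            # patient, recording id
  hdr_txt(8); hdr_txt(8)              # start date, time
  hdr_txt(8)                          # header byte count
  hdr_txt(44)                         # reserved
  n_records <- as.integer(hdr_txt(8))
  rec_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                     # transducer, physical dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                             # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)                             # reserved
  ch <- if (is.null(channel)) 1L
        else if (is.character(channel)) match(channel, labels)
        else as.integer(channel)
  if (is.na(ch) || ch < 1L || ch > ns)
    stop("requested channel not present in EDF file", call. = FALSE)
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- readBin(con, "integer", n = nsamp[s], size = 2L,
                   signed = TRUE, endian = "little")
      if (s == ch) out[[r]] <- x
    }
  }
  dig <- unlist(out)
  gain <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
  phys <- (dig - dmin[ch]) * gain + pmin[ch]
  eeg_recording(phys, fs = nsamp[ch] / rec_dur, channel_label = labels[ch])
}

# Minimal single-channel EDF writer; used to exercise the reader in tests.
write_edf <- function(rec, path, label = rec$channel_label) {
  n <- length(rec$samples)
  rec_dur <- 1
  nsamp <- as.integer(round(rec$fs * rec_dur))
  n_records <- ceiling(n / nsamp)
  x <- c(rec$samples, rep(0, n_records * nsamp - n))
  pmin <- min(x) - 1e-6; pmax <- max(x) + 1e-6
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
  pad <- function(s, w) formatC(substr(s, 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s, width) writeBin(charToRaw(pad(s, width)), con)
  w("0", 8); w("synthetic", 80); w("synthetic", 80)
  w("01.01.26", 8); w("00.00.00", 8)
  w(as.character(256L + 256L), 8); w("", 44)
  w(as.character(n_records), 8); w(as.character(rec_dur), 8); w("1", 4)
  w(label, 16); w("", 80); w("uV", 8)
  w(sprintf("%.4f", pmin), 8); w(sprintf("%.4f", pmax), 8)
  w(as.character(dmin), 8); w(as.character(dmax), 8)
  w("", 80); w(as.character(nsamp), 8); w("", 32)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Construct a matching template
#'
#' A 1500 ms waveform used for sliding-window matching, min-max normalized so
#' that its most negative deflection maps to -1 and its most positive to +1.
#'
#' @param values Numeric waveform; length must equal `round(1.5 * fs)`.
#' @param fs Sampling rate in Hz the template is expressed at.
#' @param normalize If `TRUE` (default), min-max normalize `values` to
#'   `[-1, 1]`; if `FALSE`, `values` must already satisfy the invariant.
#' @return An object of class `bei_template`: list with `values`, `fs`,
#'   `duration_ms = 1500`.
#' @export
bei_template <- function(values, fs, normalize = TRUE) {
  values <- as.numeric(values)
  n_expected <- round(1.5 * fs)
  if (length(values) != n_expected)
    stop(sprintf("template length %d does not match 1500 ms at %g Hz (%d samples)",
                 length(values), fs, n_expected), call. = FALSE)
  if (normalize) values <- normalize_unit_range(values)
  if (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9)
    stop("template values must lie within [-1, 1]", call. = FALSE)
  structure(list(values = values, fs = as.numeric(fs), duration_ms = 1500),
            class = "bei_template")
}

#' @export
print.bei_template <- function(x, ...) {
  cat(sprintf("<bei_template> 1500 ms @ %g Hz (%d samples), range [%.3f, %.3f]\n",
              x$fs, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Load a matching template from a single-column CSV
#'
#' The file holds one waveform value per line (header optional) and is assumed
#' to span exactly 1500 ms at its native rate.  The waveform is delta-band
#' filtered, resampled to `target_fs` with a polyphase (linear-phase)
#' resampler, and min-max normalized to `[-1, 1]`.
#'
#' @param path Path to the template CSV.
#' @param target_fs Sampling rate in Hz the template will be matched at.
#' @return A [bei_template()].
#' @export
load_template <- function(path, target_fs = 512) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(first)))
  v <- read.csv(path, header = has_header, col.names = "value")$value
  if (length(v) < 4L) stop("template waveform too short", call. = FALSE)
  if (max(v) - min(v) <= 0)
    stop("constant template waveform: zero-range normalization undefined",
         call. = FALSE)
  native_fs <- length(v) / 1.5
  v <- delta_filter(v, native_fs)
  n_target <- round(1.5 * target_fs)
  if (n_target != length(v))
    v <- signal::resample(v, p = n_target, q = length(v))
  v <- v[seq_len(n_target)]
  if (max(v) - min(v) <= 0)
    stop("template waveform is constant after filtering", call. = FALSE)
  bei_template(v, fs = target_fs, normalize = TRUE)
}

#' Packaged synthetic ERP-surrogate template
#'
#' The original attention-related averaged ERP template is proprietary and not
#' distributable, so the package ships a synthetic surrogate: a 2 Hz
#' (mid-delta) oscillation spanning 1500 ms, tapered with a Tukey(0.5) window
#' and min-max normalized.  It lies inside the 1-4 Hz analysis band and its
#' rectified-amplitude variation stays below the noise-rejection threshold, so
#' clean embedded instances of it are matchable.  All downstream computation
#' is template-agnostic: supply your own via [load_template()].
#'
#' @param fs Sampling rate in Hz, default 512.
#' @return A [bei_template()].
#' @examples
#' tpl <- synthetic_erp_template(256)
#' range(tpl$values)
#' @export
synthetic_erp_template <- function(fs = 512) {
  n <- round(1.5 * fs)
  t <- (seq_len(n) - 1L) / fs
  bei_template(sin(2 * pi * 2 * t) * tukey_window(n, 0.5), fs = fs)
}

tukey_window <- function(n, a) {
  w <- rep(1, n)
  m <- floor(a * (n - 1) / 2)
  i <- 0:m
  edge <- 0.5 * (1 + cos(pi * (2 * i / (a * (n - 1)) - 1)))
  w[i + 1L] <- edge
  w[n - i] <- edge
  w
}

#' Path to the packaged synthetic template CSV
#' @return File path inside the installed package.
#' @export
default_template_path <- function() {
  system.file("extdata", "delta_erp_template_synthetic.csv",
              package = "braindex", mustWork = TRUE)
}
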