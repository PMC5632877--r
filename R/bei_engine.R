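#' Engine configuration
#'
#' All analysis constants of the engagement-index engine.  Defaults are the
#' published operating point of the device: 1-4 Hz delta band, 10 s segments
#' aggregated over the preceding 60 s, a 1500 ms matching window, a mean
#' absolute distance threshold of 0.5, an amplitude-variation noise threshold
#' of 1, at most one rejected window per segment, at least three valid
#' segments per minute, and a 10 s emission cadence.
#'
#' @param delta_band Passband in Hz, length 2.
#' @param segment_s Segment length in seconds.
#' @param window_s Aggregation window in seconds; must be an integer multiple
#'   of `segment_s`.
#' @param template_ms Matching window length in milliseconds.
#' @param match_threshold Mean absolute distance below which a window counts
#'   as a match (normalized units).
#' @param noise_ratio_threshold Windows whose rectified-amplitude coefficient
#'   of variation exceeds this are rejected as noisy.
#' @param max_rejected_windows_per_segment A segment with strictly more
#'   non-overlapping rejected windows than this is invalidated.
#' @param min_valid_segments_per_minute Minimum valid segments required to
#'   emit a minute-level value.
#' @param cadence_s Emission cadence in seconds.
#' @param opposite_mode How the distance to the polarity-inverted template is
#'   used: `"ignore"` (default; it is logged but classification uses only the
#'   template distance) or `"opposite_counts_as_nomatch"` (a window counts as
#'   a no-match only when it is within threshold of the inverted template;
#'   windows far from both are left uncounted).
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(delta_band = c(1, 4),
                          segment_s = 10,
                          window_s = 60,
                          template_ms = 1500,
                          match_threshold = 0.5,
                          noise_ratio_threshold = 1,
                          max_rejected_windows_per_segment = 1,
                          min_valid_segments_per_minute = 3,
                          cadence_s = 10,
                          opposite_mode = c("ignore", "opposite_counts_as_nomatch")) {
  opposite_mode <- match.arg(opposite_mode)
  stopifnot(length(delta_band) == 2L, all(delta_band > 0),
            delta_band[1] < delta_band[2],
            segment_s > 0, window_s > 0, template_ms > 0,
            match_threshold > 0, noise_ratio_threshold > 0,
            max_rejected_windows_per_segment >= 0,
            min_valid_segments_per_minute >= 1, cadence_s > 0)
  if (abs(window_s / segment_s - round(window_s / segment_s)) > 1e-9)
    stop("`window_s` must be an integer multiple of `segment_s`", call. = FALSE)
  structure(list(
    delta_band = delta_band, segment_s = segment_s, window_s = window_s,
    template_ms = template_ms, match_threshold = match_threshold,
    noise_ratio_threshold = noise_ratio_threshold,
    max_rejected_windows_per_segment = max_rejected_windows_per_segment,
    min_valid_segments_per_minute = min_valid_segments_per_minute,
    cadence_s = cadence_s, opposite_mode = opposite_mode
  ), class = "engine_config")
}

# Zero-phase delta-band filter on a bare numeric vector.  4th-order
# Butterworth bandpass run forward-backward; the input is mirror-padded
# (up to 2 s each side) so the segment's own edges, not zeros, feed the
# filter warm-up.  Padding uses only the segment itself, which keeps
# segment results independent of surrounding context (a requirement for
# bitwise batch/streaming equivalence).
delta_filter <- function(x, fs, band = c(1, 4)) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  p <- min(length(x) - 1L, round(2 * fs))
  xp <- c(rev(x[seq_len(p) + 1L]), x, rev(x[length(x) - seq_len(p)]))
  y <- signal::filtfilt(bf, xp)
  y[(p + 1L):(p + length(x))]
}

#' Delta-band filter a recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth bandpass over
#' the configured delta band.  Zero phase preserves the temporal alignment of
#' waveform features, which matters for template matching.
#'
#' @param rec An [eeg_recording()].
#' @param cfg An [engine_config()].
#' @return A filtered [eeg_recording()] of identical length and rate.
#' @export
bandpass_delta <- function(rec, cfg = engine_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * cfg$delta_band[2])
    stop("sampling rate too low for the analysis band", call. = FALSE)
  if (duration_s(rec) < 3)
    stop("recording shorter than the filter warm-up length (3 s)", call. = FALSE)
  out <- rec
  out$samples <- delta_filter(rec$samples, rec$fs, cfg$delta_band)
  out
}

#' Min-max normalize a segment to [-1, 1]
#'
#' Affine map sending the most negative deflection to -1 and the most positive
#' to +1.
#'
#' @param x Numeric vector of length >= 2 with positive range.
#' @return Normalized numeric vector.
#' @export
normalize_unit_range <- function(x) {
  if (length(x) < 2L) stop("segment too short to normalize", call. = FALSE)
  r <- range(x)
  if (r[2] - r[1] <= 0)
    stop(structure(class = c("braindex_degenerate_segment", "error", "condition"),
                   list(message = "degenerate segment: zero amplitude range",
                        call = NULL)))
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

#' Distances between a window and the template
#'
#' Mean absolute sample-wise distance from the window to the template and to
#' the polarity-inverted ("opposite") template.
#'
#' @param window Normalized numeric vector, same length as the template.
#' @param template A [bei_template()].
#' @return Named numeric vector `c(d_template =, d_opposite =)`.
#' @export
window_distance <- function(window, template) {
  stopifnot(inherits(template, "bei_template"))
  if (length(window) != length(template$values))
    stop("window length does not match template length", call. = FALSE)
  c(d_template = mean(abs(window - template$values)),
    d_opposite = mean(abs(window + template$values)))
}

#' Noise ratio of a filtered window
#'
#' Coefficient of variation of the rectified delta-band amplitude,
#' `sd(|w|) / mean(|w|)`.  Steady oscillatory activity keeps the ratio well
#' below 1 while transient high-amplitude bursts (eye blinks and other
#' frontal artifacts) push it above 1.  An all-zero window is flagged noisy.
#'
#' @param window Filtered (unnormalized) amplitude vector.
#' @return The ratio; `Inf` for an all-zero window.
#' @export
noise_ratio <- function(window) {
  a <- abs(window)
  m <- mean(a)
  if (m <= 0) return(Inf)
  sd(a) / m
}

segment_result <- function(start_s, matches = 0L, nomatches = 0L,
                           rejected_windows = 0L, valid = FALSE,
                           bei = NA_real_, d_opposite_min = NA_real_) {
  tibble(start_s = start_s, matches = as.integer(matches),
         nomatches = as.integer(nomatches),
         rejected_windows = as.integer(rejected_windows),
         valid = valid, bei = bei, d_opposite_min = d_opposite_min)
}

#' Scan one 10-second segment for template matches
#'
#' Implements the per-segment pipeline: delta-band zero-phase filtering,
#' min-max normalization to `[-1, 1]`, then a sliding 1500 ms window at
#' one-sample stride.  Each window is first screened by [noise_ratio()];
#' noisy windows are excluded from classification, and non-overlapping noisy
#' windows are tallied — strictly more than
#' `max_rejected_windows_per_segment` of them invalidates the whole segment.
#' Clean windows are classified as a match when the mean absolute distance to
#' the template is below `match_threshold`, else as a no-match; within each
#' class, an event is only counted if its window does not overlap the most
#' recently counted event of that class (greedy left-to-right deduplication).
#' The segment index is `matches / nomatches` clamped to at most 1, with 1
#' when there are matches but no no-matches and 0 when there are no matches;
#' a segment with no counted events at all is invalid.
#'
#' @param segment An [eeg_recording()] of exactly `segment_s` seconds.
#' @param template A [bei_template()] at the recording's sampling rate.
#' @param cfg An [engine_config()].
#' @return A one-row tibble: `start_s`, `matches`, `nomatches`,
#'   `rejected_windows`, `valid`, `bei`, `d_opposite_min`.
#' @export
scan_segment <- function(segment, template, cfg = engine_config()) {
  stopifnot(inherits(segment, "eeg_recording"), inherits(template, "bei_template"))
  fs <- segment$fs
  if (abs(template$fs - fs) > 1e-9)
    stop("template sampling rate does not match the recording", call. = FALSE)
  n <- length(segment$samples)
  if (abs(n - round(cfg$segment_s * fs)) > 1L)
    stop(sprintf("segment must be %g s at %g Hz", cfg$segment_s, fs), call. = FALSE)

  f <- delta_filter(segment$samples, fs, cfg$delta_band)
  norm <- tryCatch(normalize_unit_range(f),
                   braindex_degenerate_segment = function(e) NULL)
  if (is.null(norm))
    return(segment_result(segment$t0, rejected_windows = 1L, valid = FALSE))

  tpl <- template$values
  T_ <- length(tpl)
  P <- n - T_ + 1L
  if (P < 1L) stop("segment shorter than the template", call. = FALSE)

  # rolling rectified-amplitude statistics of the filtered signal
  a <- abs(f)
  ca <- c(0, cumsum(a)); ca2 <- c(0, cumsum(a * a))
  pos <- seq_len(P)
  s1 <- ca[pos + T_] - ca[pos]
  s2 <- ca2[pos + T_] - ca2[pos]
  mu <- s1 / T_
  va <- pmax(0, (s2 - s1 * s1 / T_) / (T_ - 1))
  ratio <- ifelse(mu > 0, sqrt(va) / mu, Inf)
  noisy <- ratio > cfg$noise_ratio_threshold

  # distances for every window position, in blocks to bound memory
  d_tpl <- numeric(P); d_opp <- numeric(P)
  block <- 2048L
  for (b0 in seq(1L, P, by = block)) {
    b1 <- min(b0 + block - 1L, P)
    idx <- outer(seq_len(T_) - 1L, b0:b1, "+")
    W <- matrix(norm[idx], nrow = T_)
    d_tpl[b0:b1] <- colMeans(abs(W - tpl))
    d_opp[b0:b1] <- colMeans(abs(W + tpl))
  }

  opp_mode <- identical(cfg$opposite_mode, "opposite_counts_as_nomatch")
  matches <- 0L; nomatches <- 0L; rejected <- 0L
  last_end <- c(match = 0L, nomatch = 0L)  # last counted sample index per class
  last_rej_end <- 0L
  for (p in pos) {
    if (noisy[p]) {
      if (p > last_rej_end) {
        rejected <- rejected + 1L
        last_rej_end <- p + T_ - 1L
      }
      next
    }
    is_match <- d_tpl[p] < cfg$match_threshold
    if (!is_match && opp_mode && d_opp[p] >= cfg$match_threshold) next
    cls <- if (is_match) "match" else "nomatch"
    if (p > last_end[[cls]]) {
      if (is_match) matches <- matches + 1L else nomatches <- nomatches + 1L
      last_end[[cls]] <- p + T_ - 1L
    }
  }

  valid <- rejected <= cfg$max_rejected_windows_per_segment &&
    (matches + nomatches) > 0L
  bei <- if (!valid) NA_real_
         else if (matches == 0L) 0
         else if (nomatches == 0L) 1
         else min(1, matches / nomatches)
  segment_result(segment$t0, matches, nomatches, rejected, valid, bei,
                 d_opposite_min = suppressWarnings(min(d_opp[!noisy], Inf)))
}

#' Minute-level index from six segment results
#'
#' Median of the valid segments' indices over one analysis minute; missing
#' (`NA`) unless at least `min_valid_segments_per_minute` segments are valid.
#'
#' @param segments A tibble of exactly `window_s / segment_s` rows as produced
#'   by [scan_segment()].
#' @param cfg An [engine_config()].
#' @return A single numeric value in `[0, 1]`, or `NA`.
#' @export
minute_bei <- function(segments, cfg = engine_config()) {
  k <- round(cfg$window_s / cfg$segment_s)
  if (nrow(segments) != k)
    stop(sprintf("expected %d segment results, got %d", k, nrow(segments)),
         call. = FALSE)
  v <- segments$bei[segments$valid]
  if (length(v) < cfg$min_valid_segments_per_minute) return(NA_real_)
  median(v)
}

bei_trace <- function(times_s, values, n_valid, segments, cfg) {
  structure(list(times_s = times_s, values = values, n_valid = n_valid,
                 segments = segments, cadence_s = cfg$cadence_s),
            class = "bei_trace")
}

#' @export
print.bei_trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<bei_trace> %d emissions every %g s, %d missing\n",
              n, x$cadence_s, sum(is.na(x$values))))
  if (n) cat(sprintf("  t = %g..%g s, mean BEI %.3f\n",
                     min(x$times_s), max(x$times_s),
                     mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.bei_trace <- function(x, ...) {
  data.frame(time_s = x$times_s, bei = x$values,
             n_valid_segments = x$n_valid)
}

#' Compute the full engagement-index trace of a recording
#'
#' Splits the recording into consecutive 10 s segments aligned to a grid
#' anchored at `t0`, scans each segment once, and emits one value every
#' `cadence_s` seconds starting at `t = window_s`: the minute-level median
#' over the six most recent segments.  Consecutive emissions therefore share
#' 50 s of analyzed signal.  Minutes with fewer than the minimum number of
#' valid segments are emitted as `NA` gaps, never interpolated.
#'
#' @param rec An [eeg_recording()] of at least `window_s` seconds.
#' @param template A [bei_template()] at the recording's sampling rate.
#' @param cfg An [engine_config()].
#' @return A `bei_trace`: emission times (end of each 60 s analysis window,
#'   seconds from recording start), values (`NA` = missing), per-emission
#'   valid-segment counts, and the full segment log.
#' @examples
#' tpl <- synthetic_erp_template(128)
#' rec <- gen_background(synth_spec(duration_s = 120, fs = 128), seed = 1)
#' stream_bei(rec, tpl)
#' @export
stream_bei <- function(rec, template, cfg = engine_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  st <- bei_stream(template, cfg, fs = rec$fs, t0 = rec$t0)
  st$feed(rec$samples)
  tr <- st$trace()
  if (length(tr$values) == 0L)
    warning("recording shorter than one full analysis window: empty trace",
            call. = FALSE)
  tr
}

#' Incremental (chunked/streaming) engagement-index computation
#'
#' Returns a stateful stream object emulating live acquisition: feed raw
#' samples in chunks of any size; complete 10 s segments are scanned as soon
#' as they fill, each exactly once, and emissions appear as soon as six
#' segments are available.  Because every segment is processed from its own
#' samples only, the resulting trace is bitwise identical to [stream_bei()]
#' on the concatenated signal, regardless of chunking.
#'
#' @param template A [bei_template()].
#' @param cfg An [engine_config()].
#' @param fs Sampling rate of the incoming samples in Hz.
#' @param t0 Session-relative time of the first sample, seconds.
#' @return A list with functions `feed(samples)` (returns, invisibly, the
#'   values emitted by that chunk) and `trace()` (the `bei_trace` so far).
#' @export
bei_stream <- function(template, cfg = engine_config(), fs = 512, t0 = 0) {
  stopifnot(inherits(template, "bei_template"))
  if (abs(template$fs - fs) > 1e-9)
    stop("template sampling rate does not match `fs`", call. = FALSE)
  seg_len <- round(cfg$segment_s * fs)
  k <- round(cfg$window_s / cfg$segment_s)
  buffer <- numeric(0)
  seg_rows <- list()
  times <- numeric(0); values <- numeric(0); nvalid <- integer(0)

  feed <- function(samples) {
    buffer <<- c(buffer, as.numeric(samples))
    emitted <- numeric(0)
    while (length(buffer) >= seg_len) {
      i <- length(seg_rows) + 1L
      seg <- eeg_recording(buffer[seq_len(seg_len)], fs = fs,
                           t0 = t0 + (i - 1L) * cfg$segment_s)
      buffer <<- buffer[-seq_len(seg_len)]
      seg_rows[[i]] <<- scan_segment(seg, template, cfg)
      if (i >= k) {
        recent <- do.call(rbind, seg_rows[(i - k + 1L):i])
        v <- minute_bei(recent, cfg)
        times <<- c(times, t0 + i * cfg$segment_s)
        values <<- c(values, v)
        nvalid <<- c(nvalid, sum(recent$valid))
        emitted <- c(emitted, v)
      }
    }
    invisible(emitted)
  }
  trace <- function() {
    segments <- if (length(seg_rows)) do.call(rbind, seg_rows)
                else segment_result(numeric(0))[0, ]
    bei_trace(times, values, nvalid, segments, cfg)
  }
  list(feed = feed, trace = trace)
}

#' Write / read a trace as CSV
#'
#' Columns `time_s, bei, n_valid_segments`; missing values are written as
#' empty cells.
#'
#' @param trace A `bei_trace`.
#' @param path Output path.
#' @return `path` invisibly ([write_trace()]); a `bei_trace` without segment
#'   log ([read_trace()]).
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  cad <- if (nrow(df) > 1L) median(diff(df$time_s)) else 10
  bei_trace(df$time_s, as.numeric(df$bei),
            as.integer(df$n_valid_segments),
            segment_result(numeric(0))[0, ],
            engine_config(cadence_s = cad))
}
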