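with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Specification of a synthetic EEG recording
#'
#' Parameters of the generator that stands in for clinical recordings:
#' band-limited 1/f ("pink-like") background at a target RMS, template
#' occurrences embedded at a Poisson rate, and blink-like transients.
#' Defaults describe a plausible frontal single-electrode setup: 512 Hz
#' sampling, 10 uV broadband RMS with a 1/f spectrum over 0.5-45 Hz, two
#' clear 25 uV template occurrences per 10 s segment, and two 150 uV blink
#' transients per minute.
#'
#' @param duration_s Recording length in seconds (>= 60 for engine tests).
#' @param fs Sampling rate in Hz.
#' @param rms_uV Background RMS amplitude in microvolts.
#' @param pink_exponent Spectral exponent a of the 1/f^a background.
#' @param band Frequency support of the background in Hz.
#' @param embed_rate Expected template occurrences per 10 s segment.
#' @param embed_amplitude_uV Peak amplitude of embedded templates.
#' @param artifact_rate_per_min Blink-like transients per minute.
#' @param artifact_amplitude_uV Peak amplitude of the transients.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 300, fs = 512, rms_uV = 10,
                       pink_exponent = 1, band = c(0.5, 45),
                       embed_rate = 2, embed_amplitude_uV = 25,
                       artifact_rate_per_min = 2,
                       artifact_amplitude_uV = 150) {
  stopifnot(duration_s > 0, fs > 0, rms_uV >= 0, embed_rate >= 0,
            embed_amplitude_uV >= 0, artifact_rate_per_min >= 0,
            artifact_amplitude_uV >= 0)
  structure(list(duration_s = duration_s, fs = fs, rms_uV = rms_uV,
                 pink_exponent = pink_exponent, band = band,
                 embed_rate = embed_rate,
                 embed_amplitude_uV = embed_amplitude_uV,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amplitude_uV = artifact_amplitude_uV),
            class = "synth_spec")
}

#' Generate band-limited 1/f background EEG
#'
#' White Gaussian noise is shaped in the frequency domain by `f^(-a/2)` gain
#' inside the spec's band (zero outside, including DC) and rescaled to the
#' target RMS.  Bit-reproducible given the seed.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer RNG seed (`NULL` = use current RNG state).
#' @return An [eeg_recording()].
#' @export
gen_background <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$duration_s * spec$fs)
  x <- with_opt_seed(seed, rnorm(n))
  if (spec$rms_uV == 0) return(eeg_recording(numeric(n) + 0 * x, spec$fs))
  f <- c(0, seq_len(n - 1)) * spec$fs / n
  f <- pmin(f, spec$fs - f)                     # two-sided frequency axis
  gain <- ifelse(f >= spec$band[1] & f <= spec$band[2],
                 f^(-spec$pink_exponent / 2), 0)
  y <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
  y <- y * spec$rms_uV / sqrt(mean(y^2))
  eeg_recording(y, spec$fs, channel_label = "synthetic Fpz")
}

poisson_times <- function(rate_per_s, duration_s, width_s, seed,
                          non_overlap = TRUE) {
  with_opt_seed(seed, {
    k <- rpois(1, rate_per_s * duration_s)
    t <- sort(runif(k, 0, max(0, duration_s - width_s)))
    if (non_overlap && length(t) > 1) {
      keep <- t[1]
      for (ti in t[-1]) if (ti >= keep[length(keep)] + width_s)
        keep <- c(keep, ti)
      t <- keep
    }
    t
  })
}

#' Embed template occurrences into a recording
#'
#' Adds scaled copies of the template at Poisson-distributed, non-overlapping
#' onset times and returns the ground truth.  Errors when the requested rate
#' would occupy more than 80% of the signal, making non-overlap infeasible.
#'
#' @param rec An [eeg_recording()].
#' @param template A [bei_template()] at the recording's rate.
#' @param rate Expected occurrences per 10 s.
#' @param amplitude_uV Peak amplitude of each embedded copy.
#' @param seed Integer RNG seed (`NULL` = current RNG state).
#' @return A list: `recording` (with templates added), `onset_s` (ground
#'   truth onset times in seconds).
#' @export
embed_templates <- function(rec, template, rate, amplitude_uV, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(template, "bei_template"))
  if (abs(template$fs - rec$fs) > 1e-9)
    stop("template sampling rate does not match the recording", call. = FALSE)
  if (rate * 1.5 / 10 > 0.8)
    stop("embedding rate too high for non-overlapping occurrences",
         call. = FALSE)
  dur <- duration_s(rec)
  if (rate == 0 || amplitude_uV == 0)
    return(list(recording = rec, onset_s = numeric(0)))
  t <- poisson_times(rate / 10, dur, 1.5, seed)
  x <- rec$samples
  tv <- amplitude_uV * template$values
  for (ti in t) {
    i0 <- round(ti * rec$fs) + 1L
    idx <- i0:(i0 + length(tv) - 1L)
    x[idx] <- x[idx] + tv
  }
  out <- rec
  out$samples <- x
  list(recording = out, onset_s = t)
}

#' Inject blink-like artifacts
#'
#' Adds high-amplitude, low-frequency biphasic transients (one 2 Hz cycle
#' over 0.5 s, Hann-tapered) at Poisson times, emulating eye blinks picked up
#' by a forehead electrode.
#'
#' @param rec An [eeg_recording()].
#' @param rate_per_min Expected transients per minute.
#' @param amplitude_uV Peak amplitude of each transient.
#' @param seed Integer RNG seed (`NULL` = current RNG state).
#' @return A list: `recording`, `onset_s`.
#' @export
inject_artifacts <- function(rec, rate_per_min, amplitude_uV, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rate_per_min == 0 || amplitude_uV == 0)
    return(list(recording = rec, onset_s = numeric(0)))
  dur <- duration_s(rec)
  t <- poisson_times(rate_per_min / 60, dur, 0.5, seed, non_overlap = FALSE)
  np <- round(0.5 * rec$fs)
  tp <- (seq_len(np) - 1L) / rec$fs
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(np) - 1L) / (np - 1L)))
  pulse <- amplitude_uV * sin(2 * pi * 2 * tp) * hann
  x <- rec$samples
  for (ti in t) {
    i0 <- round(ti * rec$fs) + 1L
    idx <- i0:min(i0 + np - 1L, length(x))
    x[idx] <- x[idx] + pulse[seq_along(idx)]
  }
  out <- rec
  out$samples <- x
  list(recording = out, onset_s = t)
}

#' Generate a complete synthetic recording
#'
#' Convenience wrapper: background + embedded templates + artifacts, with
#' independent sub-seeds derived from `seed`.
#'
#' @param spec A [synth_spec()].
#' @param template A [bei_template()] at the spec's rate.
#' @param seed Integer RNG seed.
#' @return A list: `recording`, `template_onset_s`, `artifact_onset_s`.
#' @export
gen_recording <- function(spec, template, seed = NULL) {
  bg <- gen_background(spec, seed = seed)
  em <- embed_templates(bg, template, spec$embed_rate,
                        spec$embed_amplitude_uV,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  ar <- inject_artifacts(em$recording, spec$artifact_rate_per_min,
                         spec$artifact_amplitude_uV,
                         seed = if (is.null(seed)) NULL else seed + 2L)
  list(recording = ar$recording, template_onset_s = em$onset_s,
       artifact_onset_s = ar$onset_s)
}

#' Generate a paired-session rating dataset
#'
#' Emulates the inputs of the statistics stage: two sessions per patient, one
#' per condition, each scored by two independent raters on the `[-3, +3]`
#' Likert scale.  Per patient, two latent session-engagement levels are drawn
#' uniformly on `[0.2, 0.8]`; the expected Likert change of a session is
#' `0.5 + engagement_link * (latent - 0.5)` (a monotone link, zero slope =
#' no association), to which independent Gaussian rater noise is added before
#' rounding and clipping to integers.  The condition with the larger latent
#' level is recorded as the patient's higher-engagement condition; first
#' conditions alternate, mirroring the study's alternate allocation.
#'
#' @param n_patients Number of patients (>= 2).
#' @param engagement_link Slope of the latent-to-score link; 0 = null.
#' @param rater_noise_sd SD of each rater's independent noise.
#' @param seed Integer RNG seed.
#' @return A list of tibbles: `scores` (`patient_id`, `condition`, `rater1`,
#'   `rater2`), `pairing` (`patient_id`, `higher_bei_condition`,
#'   `first_condition`), `truth` (latent levels per session).
#' @export
gen_session_dataset <- function(n_patients, engagement_link = 1.5,
                                rater_noise_sd = 0.7, seed = NULL) {
  stopifnot(n_patients >= 2)
  with_opt_seed(seed, {
    conds <- c("feedback", "no_feedback")
    ids <- sprintf("p%03d", seq_len(n_patients))
    e_fb <- runif(n_patients, 0.2, 0.8)
    e_nofb <- runif(n_patients, 0.2, 0.8)
    clip_round <- function(mu) {
      as.integer(pmax(-3, pmin(3, round(mu + rnorm(length(mu),
                                                   sd = rater_noise_sd)))))
    }
    mu_fb <- 0.5 + engagement_link * (e_fb - 0.5)
    mu_nofb <- 0.5 + engagement_link * (e_nofb - 0.5)
    scores <- tibble(
      patient_id = rep(ids, each = 2),
      condition = rep(conds, n_patients),
      rater1 = as.vector(rbind(clip_round(mu_fb), clip_round(mu_nofb))),
      rater2 = as.vector(rbind(clip_round(mu_fb), clip_round(mu_nofb)))
    )
    pairing <- tibble(
      patient_id = ids,
      higher_bei_condition = ifelse(e_fb >= e_nofb, "feedback", "no_feedback"),
      first_condition = conds[(seq_len(n_patients) - 1L) %% 2L + 1L]
    )
    truth <- tibble(patient_id = ids, latent_feedback = e_fb,
                    latent_no_feedback = e_nofb)
    list(scores = scores, pairing = pairing, truth = truth)
  })
}
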