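trace_values <- function(x) {
  if (inherits(x, "bei_trace")) x$values else as.numeric(x)
}

#' Session-level engagement index for a pair of sessions
#'
#' Pools every non-missing engagement value from both of a patient's sessions,
#' computes the pooled mean and standard deviation, and grades each session by
#' the fraction of its values lying strictly above `mean + 1 SD`.  The session
#' with the larger fraction is labelled the higher-engagement session; equal
#' fractions are reported as a tie.
#'
#' @param trace_a,trace_b `bei_trace` objects or numeric vectors of the two
#'   sessions' values (`NA` = missing).
#' @param labels Length-2 character vector naming the sessions.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list of class `session_bei_result`: `pooled_mean`, `pooled_sd`,
#'   `threshold`, `fractions` (named length-2), `higher_session` (a label or
#'   `"tie"`), `n` (values per session).
#' @examples
#' session_bei(c(0.1, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.1))
#' @export
session_bei <- function(trace_a, trace_b, labels = c("A", "B"),
                        sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  a <- trace_values(trace_a); a <- a[!is.na(a)]
  b <- trace_values(trace_b); b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("a session has no non-missing values", call. = FALSE)
  pooled <- c(a, b)
  if (length(pooled) < 2L)
    stop("need at least 2 non-missing values across the two sessions",
         call. = FALSE)
  m <- mean(pooled)
  s <- sd(pooled)
  if (sd_type == "population")
    s <- s * sqrt((length(pooled) - 1) / length(pooled))
  thr <- m + s
  fr <- c(mean(a > thr), mean(b > thr))
  names(fr) <- labels
  higher <- if (fr[1] > fr[2]) labels[1]
            else if (fr[2] > fr[1]) labels[2]
            else "tie"
  structure(list(pooled_mean = m, pooled_sd = s, threshold = thr,
                 fractions = fr, higher_session = higher,
                 n = c(length(a), length(b))),
            class = "session_bei_result")
}

#' @export
print.session_bei_result <- function(x, ...) {
  cat(sprintf("<session_bei_result> pooled mean %.4f, SD %.4f, threshold %.4f\n",
              x$pooled_mean, x$pooled_sd, x$threshold))
  cat(sprintf("  fraction above threshold: %s = %.3f (n=%d), %s = %.3f (n=%d)\n",
              names(x$fractions)[1], x$fractions[1], x$n[1],
              names(x$fractions)[2], x$fractions[2], x$n[2]))
  cat("  higher session:", x$higher_session, "\n")
  invisible(x)
}

#' Therapist feedback advisory ladder
#'
#' Replays (or receives live) the 10 s engagement emissions of a session and
#' flags sustained drops.  The patient's baseline is the running mean of all
#' values observed outside drop episodes; a drop episode begins when the
#' current value falls more than `drop_frac` (default 10%) below that
#' baseline and ends at the first recovered value.  Each emission below
#' threshold attests that the preceding `cadence_s` seconds were low, so once
#' the accumulated low time reaches `trigger_s` (default 30 s) the first
#' advisory fires, with one escalation step per further `escalation_s` of
#' persistence:
#' `encourage` -> difficulty change (`intensify` when the exercise looks too
#' easy, `reduce_intensity` when too hard) -> `rest_or_passive`.  Recovery
#' resets the ladder; the baseline is frozen while a drop lasts so that a
#' sustained drop cannot erode its own trigger threshold.  Missing values are
#' skipped: they neither extend nor reset a drop.
#'
#' @param values Numeric vector of emissions (`NA` = missing) or a
#'   `bei_trace`.
#' @param times_s Emission times; defaults to the trace's, else a
#'   `cadence_s` grid.
#' @param cadence_s Emission cadence in seconds, default 10.
#' @param drop_frac Relative decrease that arms a drop, default 0.10
#'   (strictly more than 10% below baseline).
#' @param trigger_s Sustained low time before the first advisory, default 30.
#' @param escalation_s Additional persistence per ladder stage, default 30.
#' @param performance_hint `"too_easy"` or `"too_hard"`: which difficulty
#'   change the second stage suggests.
#' @return A tibble of advisory events: `time_s`, `stage`, `action`,
#'   `triggering_drop` (relative decrease vs baseline), `baseline`.
#' @examples
#' feedback_advisor(c(rep(0.5, 6), rep(0.4, 4)))
#' @export
feedback_advisor <- function(values, times_s = NULL, cadence_s = 10,
                             drop_frac = 0.10, trigger_s = 30,
                             escalation_s = 30,
                             performance_hint = c("too_easy", "too_hard")) {
  performance_hint <- match.arg(performance_hint)
  if (inherits(values, "bei_trace")) {
    if (is.null(times_s)) times_s <- values$times_s
    cadence_s <- values$cadence_s
    values <- values$values
  }
  if (is.null(times_s)) times_s <- seq_along(values) * cadence_s
  stopifnot(length(times_s) == length(values))
  ladder <- c("encourage",
              if (performance_hint == "too_easy") "intensify" else "reduce_intensity",
              "rest_or_passive")
  base_sum <- 0; base_n <- 0L
  low_s <- 0; stage <- 0L
  ev_t <- numeric(0); ev_stage <- integer(0); ev_drop <- numeric(0)
  ev_base <- numeric(0)
  for (i in seq_along(values)) {
    v <- values[i]
    if (is.na(v)) next
    if (base_n == 0L) {
      base_sum <- v; base_n <- 1L
      next
    }
    baseline <- base_sum / base_n
    if (v < (1 - drop_frac) * baseline) {
      low_s <- low_s + cadence_s
      want <- if (low_s >= trigger_s)
        1L + min(2L, (low_s - trigger_s) %/% escalation_s) else 0L
      while (stage < want) {
        stage <- stage + 1L
        ev_t <- c(ev_t, times_s[i])
        ev_stage <- c(ev_stage, stage)
        ev_drop <- c(ev_drop, 1 - v / baseline)
        ev_base <- c(ev_base, baseline)
      }
    } else {
      low_s <- 0; stage <- 0L
      base_sum <- base_sum + v; base_n <- base_n + 1L
    }
  }
  tibble(time_s = ev_t, stage = ev_stage, action = ladder[ev_stage],
         triggering_drop = ev_drop, baseline = ev_base)
}

#' Summarize a trace over labelled exercise blocks
#'
#' For each block: the first and last non-missing value acquired inside the
#' block and the block mean.  Blocks sharing a label (e.g. two repetitions of
#' the same difficulty level) are then averaged per label.
#'
#' @param trace A `bei_trace` (or numeric vector plus `times_s` via a trace).
#' @param blocks A data frame with columns `label`, `start_s`, `end_s`.
#' @return A list of two tibbles: `$blocks` (per block `label`, `start_s`,
#'   `end_s`, `n`, `start_bei`, `end_bei`, `mean_bei`) and `$labels` (per
#'   label averages of the same quantities over its blocks).
#' @export
summarize_blocks <- function(trace, blocks) {
  stopifnot(inherits(trace, "bei_trace"),
            all(c("label", "start_s", "end_s") %in% names(blocks)))
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    sel <- trace$times_s >= blocks$start_s[i] & trace$times_s <= blocks$end_s[i]
    v <- trace$values[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning(sprintf("block '%s' [%g, %g] contains no non-missing values",
                      blocks$label[i], blocks$start_s[i], blocks$end_s[i]),
              call. = FALSE)
      return(tibble(label = blocks$label[i], start_s = blocks$start_s[i],
                    end_s = blocks$end_s[i], n = 0L, start_bei = NA_real_,
                    end_bei = NA_real_, mean_bei = NA_real_))
    }
    tibble(label = blocks$label[i], start_s = blocks$start_s[i],
           end_s = blocks$end_s[i], n = length(v),
           start_bei = v[1L], end_bei = v[length(v)], mean_bei = mean(v))
  })
  per_block <- do.call(rbind, rows)
  labs <- unique(per_block$label)
  per_label <- do.call(rbind, lapply(labs, function(l) {
    d <- per_block[per_block$label == l & per_block$n > 0L, ]
    tibble(label = l, n_blocks = nrow(d),
           start_bei = mean(d$start_bei), end_bei = mean(d$end_bei),
           mean_bei = mean(d$mean_bei))
  }))
  list(blocks = per_block, labels = per_label)
}
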