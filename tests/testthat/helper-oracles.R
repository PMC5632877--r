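# Independent reference implementations used to cross-check the engine and
# the signed-rank test.  These deliberately use naive enumeration and explicit
# interval bookkeeping rather than the package's vectorized/greedy code paths.

# Brute-force segment scan: every window position examined one by one; the
# deduplication rule is applied by keeping a list of all counted event
# intervals per class and testing overlap against each of them.
oracle_scan_segment <- function(segment, template, cfg = engine_config()) {
  f <- braindex:::delta_filter(segment$samples, segment$fs, cfg$delta_band)
  r <- range(f)
  if (r[2] - r[1] <= 0)
    return(list(matches = 0L, nomatches = 0L, rejected = 1L,
                valid = FALSE, bei = NA_real_))
  x <- 2 * (f - r[1]) / (r[2] - r[1]) - 1
  tpl <- template$values
  Tn <- length(tpl)
  counted <- list(match = list(), nomatch = list(), rejected = list())
  overlaps_any <- function(lst, s, e)
    any(vapply(lst, function(iv) s <= iv[2] && e >= iv[1], logical(1)))
  matches <- nomatches <- rejected <- 0L
  opp_mode <- identical(cfg$opposite_mode, "opposite_counts_as_nomatch")
  for (p in seq_len(length(x) - Tn + 1L)) {
    s <- p; e <- p + Tn - 1L
    wf <- f[s:e]
    m <- mean(abs(wf))
    noisy <- if (m <= 0) TRUE else sd(abs(wf)) / m > cfg$noise_ratio_threshold
    if (noisy) {
      if (!overlaps_any(counted$rejected, s, e)) {
        rejected <- rejected + 1L
        counted$rejected[[length(counted$rejected) + 1L]] <- c(s, e)
      }
      next
    }
    w <- x[s:e]
    d <- sum(abs(w - tpl)) / Tn
    is_match <- d < cfg$match_threshold
    if (!is_match && opp_mode &&
        sum(abs(w + tpl)) / Tn >= cfg$match_threshold) next
    cls <- if (is_match) "match" else "nomatch"
    if (!overlaps_any(counted[[cls]], s, e)) {
      if (is_match) matches <- matches + 1L else nomatches <- nomatches + 1L
      counted[[cls]][[length(counted[[cls]]) + 1L]] <- c(s, e)
    }
  }
  valid <- rejected <= cfg$max_rejected_windows_per_segment &&
    (matches + nomatches) > 0L
  bei <- if (!valid) NA_real_
         else if (matches == 0L) 0
         else if (nomatches == 0L) 1
         else min(1, matches / nomatches)
  list(matches = matches, nomatches = nomatches, rejected = rejected,
       valid = valid, bei = bei)
}

# Exhaustive sign-flip null for the paired signed-rank test: all 2^n sign
# assignments of the midranks, enumerated via expand.grid + matrix product.
oracle_signflip_wilcoxon <- function(higher, lower, alternative = "greater") {
  d <- higher - lower
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wp <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (alternative == "greater") mean(Wp >= W)
       else mean(abs(Wp - mu) >= abs(W - mu))
  list(statistic = W, p = p)
}

# A recording made of back-to-back template repetitions (engagement-saturated
# signal), optionally scaled.
tiled_template_recording <- function(template, duration_s, amplitude = 40) {
  n <- round(duration_s * template$fs)
  eeg_recording(rep(amplitude * template$values, length.out = n),
                fs = template$fs)
}
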