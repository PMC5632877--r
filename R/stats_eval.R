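#' Inter-rater agreement filter
#'
#' Two blinded raters score the functional change of every session on a
#' 7-point Likert scale in `[-3, +3]`.  A patient is excluded from analysis
#' when, for any of their sessions, the two raters differ by more than 1
#' point; retained sessions carry the two raters' mean as `mean_score`.
#'
#' @param scores A data frame with columns `patient_id`, `condition`,
#'   `rater1`, `rater2` (integers in `[-3, 3]`).
#' @return A list: `$retained` (tibble with added `mean_score`), `$excluded`
#'   (tibble `patient_id`, `max_diff`).
#' @examples
#' s <- tibble::tibble(patient_id = c("p1", "p1", "p2", "p2"),
#'                     condition = rep(c("feedback", "no_feedback"), 2),
#'                     rater1 = c(2L, 1L, 2L, 0L), rater2 = c(2L, 0L, 0L, 0L))
#' rater_filter(s)
#' @export
rater_filter <- function(scores) {
  scores <- as_tibble(scores)
  need <- c("patient_id", "condition", "rater1", "rater2")
  stopifnot(all(need %in% names(scores)))
  if (nrow(scores) == 0L)
    return(list(retained = tibble(scores, mean_score = numeric(0)),
                excluded = tibble(patient_id = character(0),
                                  max_diff = integer(0))))
  r <- cbind(scores$rater1, scores$rater2)
  if (anyNA(r)) stop("missing rater score", call. = FALSE)
  if (any(r != round(r)) || any(abs(r) > 3))
    stop("rater scores must be integers in [-3, 3]", call. = FALSE)
  d <- abs(scores$rater1 - scores$rater2)
  max_d <- tapply(d, scores$patient_id, max)
  bad <- names(max_d)[max_d > 1]
  retained <- scores[!(scores$patient_id %in% bad), ]
  retained$mean_score <- (retained$rater1 + retained$rater2) / 2
  list(retained = retained,
       excluded = tibble(patient_id = bad,
                         max_diff = as.integer(max_d[bad])))
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test for the paired comparison of each patient's
#' higher-engagement session score against their lower-engagement session
#' score.  Zero differences are dropped (classic convention), absolute
#' differences are midranked, and the one-sided alternative is that
#' higher-engagement sessions score higher.  With fewer than 10 nonzero
#' differences the null distribution is enumerated exactly over all `2^n`
#' sign assignments (midranks kept, so ties are handled exactly); otherwise a
#' normal approximation with tie-corrected variance is used.  The Z statistic
#' `(W+ - mu) / sigma` is reported in both modes.
#'
#' @param higher_scores,lower_scores Equal-length numeric vectors of paired
#'   scores.
#' @param alternative `"greater"` (default: higher-engagement sessions score
#'   higher) or `"two.sided"`.
#' @param method `"auto"` (exact when n < 10), `"exact"`, or `"normal"`.
#' @return A list of class `wilcoxon_paired`: `statistic` (W+, sum of ranks
#'   of positive differences), `z`, `p`, `n` (pairs after zero removal),
#'   `method`, `alternative`, `undefined` (TRUE when all differences are
#'   zero).
#' @examples
#' wilcoxon_paired(c(2, 1.5, 1, 2, 0.5, 1), c(1, 0.5, 0, 1, -0.5, 0))
#' @export
wilcoxon_paired <- function(higher_scores, lower_scores,
                            alternative = c("greater", "two.sided"),
                            method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(higher_scores) == length(lower_scores))
  d <- higher_scores - lower_scores
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, z = NA_real_, p = NA_real_,
                          n = 0L, method = "undefined",
                          alternative = alternative, undefined = TRUE),
                     class = "wilcoxon_paired"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else NA_real_
  if (method == "auto") method <- if (n < 10) "exact" else "normal"
  if (method == "exact") {
    if (n > 24) stop("exact enumeration limited to n <= 24", call. = FALSE)
    # all 2^n sign assignments of the midranks
    Wperm <- numeric(2^n)
    for (mask in 0:(2^n - 1)) {
      Wperm[mask + 1] <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    }
    p <- if (alternative == "greater") mean(Wperm >= W)
         else mean(abs(Wperm - mu) >= abs(W - mu))
  } else {
    p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
         else 2 * pnorm(-abs(z))
  }
  structure(list(statistic = W, z = z, p = p, n = n, method = method,
                 alternative = alternative, undefined = FALSE),
            class = "wilcoxon_paired")
}

#' @export
print.wilcoxon_paired <- function(x, ...) {
  if (x$undefined) {
    cat("<wilcoxon_paired> undefined: all paired differences are zero\n")
  } else {
    cat(sprintf("<wilcoxon_paired> W+ = %g, Z = %.4f, %s p = %.5g (n = %d, %s)\n",
                x$statistic, x$z, x$alternative, x$p, x$n, x$method))
  }
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square with 1 degree of freedom, without continuity
#' correction by default (Yates available via `correct = TRUE`).  A table
#' with a zero row or column margin is reported as undefined.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return A list of class `chi_square_2x2`: `statistic`, `df`, `p`, `n`,
#'   `undefined`.
#' @examples
#' chi_square_2x2(matrix(c(10, 3, 2, 9), 2))
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- sum(table)
  if (n == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(structure(list(statistic = NA_real_, df = 1L, p = NA_real_,
                          n = n, undefined = TRUE), class = "chi_square_2x2"))
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  structure(list(statistic = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value), n = n, undefined = FALSE),
            class = "chi_square_2x2")
}

#' @export
print.chi_square_2x2 <- function(x, ...) {
  if (x$undefined)
    cat("<chi_square_2x2> undefined: zero marginal\n")
  else
    cat(sprintf("<chi_square_2x2> X2(1, %d) = %.4f, p = %.5g\n",
                x$n, x$statistic, x$p))
  invisible(x)
}

#' Effect size for a pair of proportions
#'
#' Standardized difference between two proportions: the probit (inverse
#' normal) transform `d = qnorm(p1) - qnorm(p2)` by default, or Cohen's h
#' (arcsine transform) via `method = "cohen_h"`.  Positive when `p1 > p2`.
#' Proportions of exactly 0 or 1 get the continuity adjustment `1/(2n)` when
#' the group size `n` is supplied, and are an error otherwise (the probit is
#' unbounded there).
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @param method `"probit"` (default) or `"cohen_h"`.
#' @param n Optional group size(s) (length 1 or 2) for the boundary
#'   adjustment.
#' @return The effect size (numeric scalar).
#' @examples
#' categorical_effect_size(0.72, 0.39)
#' @export
categorical_effect_size <- function(p1, p2, method = c("probit", "cohen_h"),
                                    n = NULL) {
  method <- match.arg(method)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  adjust <- function(p, ni) {
    if (p > 0 && p < 1) return(p)
    if (is.null(ni)) stop("proportion of exactly 0 or 1 needs `n` for the ",
                          "continuity adjustment", call. = FALSE)
    if (p == 0) 1 / (2 * ni) else 1 - 1 / (2 * ni)
  }
  nn <- if (is.null(n)) list(NULL, NULL) else as.list(rep(n, length.out = 2))
  p1 <- adjust(p1, nn[[1]]); p2 <- adjust(p2, nn[[2]])
  if (method == "probit") qnorm(p1) - qnorm(p2)
  else 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Cumulative threshold curve of session scores
#'
#' For each Likert threshold t in -3..+3, the fraction of sessions whose mean
#' change score is at least t.  Monotone non-increasing; the fraction at -3
#' is 1 by construction.
#'
#' @param scores Numeric vector of session mean scores.
#' @param thresholds Thresholds to evaluate, default `-3:3`.
#' @return A tibble with columns `threshold`, `fraction`.
#' @examples
#' cumulative_threshold_curve(c(1, 1, 0, 2))
#' @export
cumulative_threshold_curve <- function(scores, thresholds = -3:3) {
  stopifnot(length(scores) > 0)
  tibble(threshold = thresholds,
         fraction = vapply(thresholds, function(t) mean(scores >= t),
                           numeric(1)))
}

#' Pair each patient's session scores by engagement ranking
#'
#' Joins rater-filtered mean scores with the per-patient pairing table to
#' yield, per patient, the score of the higher-engagement session and of the
#' lower one.
#'
#' @param retained Tibble from [rater_filter()]`$retained`.
#' @param pairing Data frame with columns `patient_id`,
#'   `higher_bei_condition` (and optionally `first_condition`).
#' @return A tibble: `patient_id`, `higher_score`, `lower_score`.
#' @export
paired_session_scores <- function(retained, pairing) {
  stopifnot(all(c("patient_id", "higher_bei_condition") %in% names(pairing)))
  ids <- intersect(unique(retained$patient_id), pairing$patient_id)
  rows <- lapply(ids, function(id) {
    s <- retained[retained$patient_id == id, ]
    hc <- pairing$higher_bei_condition[pairing$patient_id == id][1]
    hi <- s$mean_score[s$condition == hc]
    lo <- s$mean_score[s$condition != hc]
    if (length(hi) != 1L || length(lo) != 1L) return(NULL)
    tibble(patient_id = id, higher_score = hi, lower_score = lo)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Full paired-session outcome analysis
#'
#' The complete statistics stage: inter-rater filtering, pairing by
#' engagement ranking, the one-sided Wilcoxon signed-rank test, cumulative
#' threshold curves for the higher- and lower-engagement groups, the probit
#' effect size of the "improved by at least `improve_threshold`" proportions,
#' and — when `first_condition` is present in the pairing — the post hoc 2x2
#' chi-square comparing sessions of patients who started with feedback
#' against those who started without, on reaching at least `max_threshold`.
#'
#' @param scores Data frame per [rater_filter()].
#' @param pairing Data frame per [paired_session_scores()].
#' @param improve_threshold Likert threshold for the effect-size proportions,
#'   default +1.
#' @param max_threshold Likert threshold for the chi-square comparison,
#'   default +2.
#' @return A list: `retained`, `excluded`, `paired`, `wilcoxon`, `curves`
#'   (list `higher`, `lower`), `proportions`, `effect_size`, `chi_square`
#'   (or `NULL`), `chi_table`.
#' @export
session_outcome_stats <- function(scores, pairing,
                                  improve_threshold = 1, max_threshold = 2) {
  rf <- rater_filter(scores)
  paired <- paired_session_scores(rf$retained, pairing)
  if (is.null(paired) || nrow(paired) == 0L)
    stop("no complete patient pairs after filtering", call. = FALSE)
  wt <- wilcoxon_paired(paired$higher_score, paired$lower_score)
  curves <- list(higher = cumulative_threshold_curve(paired$higher_score),
                 lower = cumulative_threshold_curve(paired$lower_score))
  p1 <- mean(paired$higher_score >= improve_threshold)
  p2 <- mean(paired$lower_score >= improve_threshold)
  es <- categorical_effect_size(p1, p2, n = nrow(paired))
  chi <- NULL; chi_tab <- NULL
  if ("first_condition" %in% names(pairing)) {
    m <- merge(rf$retained, pairing[, c("patient_id", "first_condition")],
               by = "patient_id")
    started_fb <- m$first_condition == "feedback"
    high <- m$mean_score >= max_threshold
    chi_tab <- matrix(c(sum(started_fb & high), sum(started_fb & !high),
                        sum(!started_fb & high), sum(!started_fb & !high)),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(first = c("feedback", "no_feedback"),
                                      change = c(">=max", "<max")))
    chi <- chi_square_2x2(chi_tab)
  }
  list(retained = rf$retained, excluded = rf$excluded, paired = paired,
       wilcoxon = wt, curves = curves,
       proportions = c(higher = p1, lower = p2), effect_size = es,
       chi_square = chi, chi_table = chi_tab)
}
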