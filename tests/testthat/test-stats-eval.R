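test_that("patients with inter-rater differences above 1 point are excluded", {
  s <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
    condition = rep(c("feedback", "no_feedback"), 3),
    rater1 = c(2L, 1L, 2L, 1L, 0L, 1L),
    rater2 = c(2L, 0L, 0L, 1L, 0L, 1L))
  out <- rater_filter(s)
  expect_setequal(unique(out$retained$patient_id), c("p1", "p3"))
  expect_equal(out$excluded$patient_id, "p2")
  expect_equal(out$excluded$max_diff, 2L)
  expect_equal(out$retained$mean_score[1:2], c(2, 0.5))

  empty <- rater_filter(s[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_error(rater_filter(transform(s, rater1 = rater1 + 4)), "integers")
})

test_that("signed-rank: all-positive unit differences give exact p = 1/64", {
  w <- wilcoxon_paired(rep(1, 6), rep(0, 6))
  expect_equal(w$method, "exact")
  expect_equal(w$p, 1 / 64)
  expect_equal(w$statistic, 21)
})

test_that("signed-rank: all-zero differences are reported undefined", {
  w <- wilcoxon_paired(c(1, 2, 3), c(1, 2, 3))
  expect_true(w$undefined)
  expect_true(is.na(w$p))
})

test_that("exact mode equals the exhaustive sign-flip oracle, ties included", {
  withr::with_seed(42, {
    for (i in 1:12) {
      n <- sample(4:10, 1)
      # half-point Likert-style differences with ties and zeros
      h <- sample(seq(-3, 3, by = 0.5), n, replace = TRUE)
      l <- sample(seq(-3, 3, by = 0.5), n, replace = TRUE)
      if (all(h == l)) h[1] <- h[1] + 1
      got <- wilcoxon_paired(h, l, method = "exact")
      ref <- oracle_signflip_wilcoxon(h, l)
      expect_equal(got$statistic, ref$statistic)
      expect_equal(got$p, ref$p, tolerance = 1e-12)
      two <- wilcoxon_paired(h, l, alternative = "two.sided", method = "exact")
      ref2 <- oracle_signflip_wilcoxon(h, l, alternative = "two.sided")
      expect_equal(two$p, ref2$p, tolerance = 1e-12)
    }
  })
})

test_that("exact mode matches wilcox.test for tie-free differences", {
  withr::with_seed(7, {
    for (i in 1:5) {
      h <- rnorm(8); l <- rnorm(8)  # continuous: no ties, no zeros
      got <- wilcoxon_paired(h, l, method = "exact")
      ref <- wilcox.test(h, l, paired = TRUE, alternative = "greater",
                         exact = TRUE)
      expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
    }
  })
})

test_that("normal approximation uses tie-corrected variance", {
  h <- c(2, 2, 1.5, 1, 1, 3, 2.5, 0.5, 2, 1, 1.5, 2)
  l <- c(1, 0, 0.5, 1.5, 0, 1, 0.5, 0, 1, 0.5, 0, 1)
  w <- wilcoxon_paired(h, l, method = "normal")
  d <- h - l; d <- d[d != 0]
  r <- rank(abs(d)); W <- sum(r[d > 0]); n <- length(d)
  ties <- table(r)
  s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  expect_equal(w$z, (W - n * (n + 1) / 4) / sqrt(s2))
  expect_equal(w$p, pnorm(w$z, lower.tail = FALSE))
})

test_that("chi-square matches the direct Pearson formula and handles margins", {
  tab <- matrix(c(10, 3, 2, 9), 2)  # [[10, 2], [3, 9]]
  got <- chi_square_2x2(tab)
  a <- 10; b <- 2; c <- 3; d <- 9; n <- a + b + c + d
  ref <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(got$statistic, ref)
  expect_equal(got$df, 1L)

  same <- chi_square_2x2(matrix(c(5, 5, 7, 7), 2))  # identical rows
  expect_equal(same$statistic, 0)

  zero <- chi_square_2x2(matrix(c(3, 5, 0, 0), 2))
  expect_true(zero$undefined)

  # invariance under transposition and simultaneous row/column swaps
  expect_equal(chi_square_2x2(t(tab))$statistic, got$statistic)
  swapped <- tab[2:1, 2:1]
  expect_equal(chi_square_2x2(swapped)$statistic, got$statistic)

  yates <- chi_square_2x2(tab, correct = TRUE)
  expect_lt(yates$statistic, got$statistic)
})

test_that("probit effect size matches normal-quantile tables and is antisymmetric", {
  expect_equal(categorical_effect_size(0.5, 0.5), 0)
  # quantile-table values: z(0.72) = 0.5828, z(0.39) = -0.2793
  expect_equal(categorical_effect_size(0.72, 0.39), 0.8622, tolerance = 1e-3)
  expect_equal(categorical_effect_size(0.39, 0.72),
               -categorical_effect_size(0.72, 0.39))
  # Cohen's h option
  expect_equal(categorical_effect_size(0.72, 0.39, method = "cohen_h"),
               2 * asin(sqrt(0.72)) - 2 * asin(sqrt(0.39)))
  # boundary proportions need n for the 1/(2n) adjustment
  expect_error(categorical_effect_size(1, 0.5), "needs `n`")
  adj <- categorical_effect_size(1, 0.5, n = 18)
  expect_equal(adj, qnorm(1 - 1 / 36))
})

test_that("cumulative threshold curves count fractions and stay monotone", {
  cv <- cumulative_threshold_curve(c(1, 1, 0, 2))
  expect_equal(cv$fraction[cv$threshold == 1], 0.75)
  expect_equal(cv$fraction[cv$threshold == -3], 1)

  single <- cumulative_threshold_curve(0)
  expect_equal(single$fraction, c(1, 1, 1, 1, 0, 0, 0))

  expect_equal(cumulative_threshold_curve(rep(3, 5))$fraction, rep(1, 7))

  withr::with_seed(1, {
    for (i in 1:10) {
      cv <- cumulative_threshold_curve(sample(-3:3, 8, replace = TRUE))
      expect_true(all(diff(cv$fraction) <= 0))
    }
  })
})

test_that("the full outcome pipeline recovers a strong engagement link", {
  ds <- gen_session_dataset(60, engagement_link = 3, rater_noise_sd = 0.4,
                            seed = 99)
  res <- session_outcome_stats(ds$scores, ds$pairing)
  expect_lt(res$wilcoxon$p, 0.01)
  expect_gt(res$effect_size, 0)
  expect_true(all(diff(res$curves$higher$fraction) <= 0))
  expect_equal(res$chi_square$n, sum(res$chi_table))
})
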