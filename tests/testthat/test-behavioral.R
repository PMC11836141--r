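make_records <- function(n = 9, immediate = 10, RnpRcp = 12, RnpRcm = 6,
                         RnmRcp = 0, RnmRcm = 2, Dp = 19, Dm = 1,
                         condition = "rest", session = 1) {
  data.frame(id = seq_len(n), condition = condition, session = session,
             immediate_correct = immediate, RnpRcp = RnpRcp,
             RnpRcm = RnpRcm, RnmRcp = RnmRcp, RnmRcm = RnmRcm,
             Dp = Dp, Dm = Dm)
}

test_that("retention and recognition scores follow their definitions", {
  rec <- make_records(n = 3)
  rec$immediate_correct <- c(12, 10, 10)
  rec$RnpRcp <- c(12, 12, 19); rec$RnmRcp <- 0
  rec$RnpRcm <- c(6, 6, 0)
  rec$Dm <- c(1, 1, 1); rec$Dp <- c(19, 19, 19)
  sc <- score_participants(rec)
  expect_equal(sc$retention, c(1.00, 1.20, 1.90))
  # hits 19/20, false alarms 1/20 -> 0.95 - 0.05 = 0.90
  expect_equal(sc$recognition[3], 0.90)
  expect_true(all(sc$recognition >= -1 & sc$recognition <= 1))

  # below-criterion participants are excluded at source, not scored
  rec$immediate_correct[2] <- 3
  rec$excluded <- rec$immediate_correct < 7
  sc2 <- score_participants(rec)
  expect_true(sc2$excluded_at_source[2])
  expect_true(is.na(sc2$retention[2]))
})

test_that("MAD flagging reproduces the hand-computed example", {
  vals <- c(1.00, 1.02, 0.98, 1.00, 2.00)
  # unscaled: median 1.00, MAD 0.02, threshold 0.06 -> only 2.00 flagged
  flags <- mad_outliers(vals, outlier_rule(multiplier = 3, scaled = FALSE))
  expect_equal(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_warning(out <- mad_outliers(rep(1, 5)), "MAD is zero")
  expect_false(any(out))
  # huge multiplier: nothing flagged
  expect_false(any(mad_outliers(vals, outlier_rule(multiplier = 1e9))))
  expect_error(mad_outliers(c(1, 2)), "at least 3")
})

test_that("exclusion uses the pooled grand median and the union rule", {
  set.seed(42)
  rec <- make_records(n = 60)
  rec$condition <- rep(c("rest", "social", "vocab"), each = 20)
  rec$RnpRcp <- pmin(20, pmax(0, round(rnorm(60, 12, 1))))
  rec$Dm <- rbinom(60, 20, 0.05)
  rec$RnpRcp[1] <- 1   # retention outlier
  rec$Dm[2] <- 20      # recognition outlier
  sc <- exclude_outliers(score_participants(rec))
  expect_true(sc$excluded_outlier[1])
  expect_true(sc$excluded_outlier[2])
  # permuting condition labels cannot change the flags (grand median)
  rec2 <- rec; rec2$condition <- rev(rec$condition)
  sc2 <- exclude_outliers(score_participants(rec2))
  expect_identical(sc$excluded_outlier, sc2$excluded_outlier)
  # union rule flags at least as many as either score alone
  expect_gte(sum(sc$excluded_outlier),
             max(sum(sc$flag_retention), sum(sc$flag_recognition)))
})

test_that("one-way ANOVA matches the hand-worked oracle", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  an <- oneway_anova(vals, grp)
  # by hand: SSB = 6, SSW = 6, MSB = 3, MSW = 1
  expect_equal(an$f, 3)
  expect_equal(an$df1, 2L); expect_equal(an$df2, 6L)
  expect_equal(an$p, pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(an$eta_squared, 0.5)
  expect_equal(an$eta_squared + (1 - an$eta_squared), 1, tolerance = 1e-12)

  an0 <- oneway_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(an0$f, 0)
  expect_equal(an0$eta_squared, 0)
  expect_error(oneway_anova(rep(1, 9), rep(c("a", "b", "c"), each = 3)),
               "degenerate")
})

test_that("planned contrasts use pooled error and honor direction", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  ct <- planned_contrast(vals, grp, c(a = 1, c = -1), tail = "one")
  # hypothesis a > c but observed c > a: p beyond 0.5, never reflected
  expect_lt(ct$t, 0)
  expect_gt(ct$p, 0.5)
  ct2 <- planned_contrast(vals, grp, c(c = 1, a = -1), tail = "one")
  expect_equal(ct2$p, 1 - ct$p)
  # equal means: t = 0, one-tailed p = 0.5
  ct0 <- planned_contrast(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                          c(a = 1, b = -1), tail = "one")
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 0.5)
  expect_error(planned_contrast(vals, grp, c(a = 1, b = 1)), "sum to 0")
})

test_that("two-group contrast t squares to the ANOVA F", {
  set.seed(7)
  for (i in 1:50) {
    vals <- rnorm(24, rep(c(0, .6), each = 12))
    grp <- rep(c("a", "b"), each = 12)
    an <- oneway_anova(vals, grp)
    ct <- planned_contrast(vals, grp, c(a = 1, b = -1))
    expect_equal(ct$t^2, an$f, tolerance = 1e-10)
    expect_equal(ct$p, an$p, tolerance = 1e-10)
  }
})

test_that("contrast Cohen's d is calibrated on simulated shifts", {
  set.seed(88)
  d_hat <- replicate(400, {
    vals <- c(rnorm(50, 0.5), rnorm(50, 0), rnorm(50, 0))
    planned_contrast(vals, rep(c("a", "b", "c"), each = 50),
                     c(a = 1, b = -1))$cohens_d
  })
  expect_lt(abs(mean(d_hat) - 0.5), 3 * sd(d_hat) / sqrt(400) + 0.01)
})

test_that("power analysis reproduces the design's a-priori N", {
  res <- required_sample_size(k = 3, f = 0.25, alpha = 0.05, power = 0.80)
  expect_equal(res$N, 159L)
  expect_equal(res$n, 53L)
  expect_gte(res$power, 0.80)
  # the next smaller balanced design falls short
  expect_lt(anova_power(159 - 3, k = 3, f = 0.25), 0.80)
  # 10% oversampling
  ov <- oversampled_n(53, 0.10, 3)
  expect_equal(ov$n, 59L)
  expect_equal(ov$N, 177L)
  expect_equal(oversampled_n(53, 0, 3)$N, 159L)
  expect_equal(oversampled_n(10, 0.10, 3)$n, 11L)
})

test_that("power is monotone in N, f and alpha", {
  Ns <- seq(30, 300, 30)
  p_by_N <- anova_power(Ns, k = 3, f = 0.25)
  expect_true(all(diff(p_by_N) > 0))
  fs <- c(.1, .2, .3, .4)
  p_by_f <- vapply(fs, function(f) anova_power(150, 3, f), 1)
  expect_true(all(diff(p_by_f) > 0))
  expect_lt(anova_power(150, 3, .25, alpha = 0.01),
            anova_power(150, 3, .25, alpha = 0.05))
  # larger effect needs fewer participants
  expect_lt(required_sample_size(3, 0.4)$N, required_sample_size(3, 0.25)$N)
})
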