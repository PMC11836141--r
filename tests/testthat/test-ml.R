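test_that("saturated fit on expected frequencies recovers the generating vector", {
  th <- c(s = .85, r1 = .92, g = .35, r2 = .66)
  cts <- expected_frequencies(sr_model, th,
                              c(target = 1000, distractor = 1000))
  fit <- fit_ml(sr_model, cts, restarts = 2, seed = 3)
  expect_true(fit$converged)
  expect_lt(fit$g_squared, 1e-6)
  expect_equal(fit$estimates[names(th), 1], th, tolerance = 1e-6)
  expect_true(is.na(fit$p_value))  # df = 0: not testable
})

test_that("closed-form inversion equals the optimizer on random interior data", {
  set.seed(99)
  for (i in 1:100) {
    cts <- draw_counts(random_interior_theta())
    inv <- tryCatch(invert_saturated(cts), error = function(e) NULL)
    if (is.null(inv) || any(inv > 0.995)) next  # near-boundary draw
    fit <- fit_ml(sr_model, cts, restarts = 1)
    expect_equal(fit$estimates[names(inv), 1], inv, tolerance = 1e-5)
  }
})

test_that("inversion round-trips exactly and rejects chance performance", {
  th <- c(s = .9, r1 = .95, g = .4, r2 = .7)
  cts <- expected_frequencies(sr_model, th, c(target = 1, distractor = 1))
  expect_equal(invert_saturated(cts), th, tolerance = 1e-12)
  # hit rate equal to false-alarm rate: memory at chance, not invertible
  flat <- list(target = c("Rn+Rc+" = 10, "Rn+Rc-" = 10, "Rn-Rc+" = 10,
                          "Rn-Rc-" = 10),
               distractor = c("D+" = 10, "D-" = 10))
  expect_error(invert_saturated(flat), "hit rate")
})

test_that("boundary data give a flagged boundary solution", {
  cts <- list(target = c("Rn+Rc+" = 20, "Rn+Rc-" = 0, "Rn-Rc+" = 0,
                         "Rn-Rc-" = 0),
              distractor = c("D+" = 20, "D-" = 0))
  fit <- fit_ml(sr_model, cts, restarts = 2, seed = 5)
  expect_true(fit$boundary)
  expect_equal(unname(fit$estimates[c("s", "r1", "r2"), 1]), rep(1, 3),
               tolerance = 1e-4)
  # g carries no information here: flat likelihood, interval unavailable
  expect_true(is.null(fit$vcov) || is.na(fit$se[["g"]]) ||
                fit$se[["g"]] > 10)
})

test_that("likelihood at the optimum dominates random interior vectors", {
  set.seed(17)
  cts <- draw_counts(c(s = .8, r1 = .9, g = .4, r2 = .6))
  fit <- fit_ml(sr_model, cts, restarts = 3, seed = 2)
  pz <- fit$parameterization
  for (i in 1:100) {
    ll <- srmpt:::loglik_free(pz, fit$counts, runif(pz$n_free, .01, .99))
    expect_lte(ll, fit$loglik + 1e-8)
  }
})

test_that("goodness_of_fit converts G2 to tail probabilities", {
  # anchor: G2 = 11.34 on 2 df has p = 0.003 (chi-square tail)
  expect_equal(round(pchisq(11.34, 2, lower.tail = FALSE), 3), 0.003)
  th <- c(s = .85, r1 = .92, g = .35, r2 = .66)
  cts <- expected_frequencies(sr_model, th, c(target = 800, distractor = 800))
  fit <- fit_ml(sr_model, cts, restarts = 2, seed = 1)
  gof <- goodness_of_fit(fit)
  expect_lt(gof$g_squared, 1e-6)
  expect_true(is.na(gof$p_value))
})

test_that("compare_nested handles identical sets, nesting and direction", {
  set.seed(31)
  theta <- c(s = .9, r1 = .95, g = .4, r2 = .7)
  cts <- list(a = draw_counts(theta), b = draw_counts(theta))
  gen <- fit_ml(sr_model, cts, restarts = 1)
  gen2 <- fit_ml(sr_model, cts, restarts = 2, seed = 44)
  same <- compare_nested(gen, gen2)
  expect_equal(same$delta_g_squared, 0, tolerance = 1e-6)
  expect_equal(same$p_two, 1)

  res <- fit_ml(sr_model, cts, mpt_constraints(list(
    con_substitute("d", c("s", "r1")), con_equal("s", "all"))),
    restarts = 1)
  cmp <- compare_nested(gen, res, tail = "one",
                        direction = list(parameter = "s", larger = "a",
                                         smaller = "b"))
  expect_gte(cmp$delta_g_squared, -1e-6)
  expect_equal(cmp$delta_df, 1L)
  expect_equal(cmp$z, sqrt(cmp$delta_g_squared))
  # one-tailed convention: p_one = p_two/2 iff observed direction matches
  expected_p1 <- if (cmp$observed_diff >= 0) cmp$p_two / 2
                 else 1 - cmp$p_two / 2
  expect_equal(cmp$p_one, expected_p1)
  expect_error(compare_nested(res, gen), "nested")
})

test_that("restricted G2 dominates general G2 under nesting (monotonicity)", {
  set.seed(812)
  for (i in 1:100) {
    theta <- random_interior_theta()
    cts <- list(a = draw_counts(theta, 400, 400),
                b = draw_counts(theta, 400, 400))
    gen <- fit_ml(sr_model, cts, restarts = 1)
    res <- fit_ml(sr_model, cts, mpt_constraints(list(
      con_substitute("d", c("s", "r1")),
      con_equal("g", "all"))), restarts = 1)
    expect_gte(res$g_squared - gen$g_squared, -1e-6)
  }
})

test_that("Wald intervals shrink with N and cover the estimate", {
  th <- c(s = .88, r1 = .93, g = .42, r2 = .64)
  set.seed(5)
  cts_small <- draw_counts(th, 500, 500)
  cts_big <- lapply(cts_small, function(v) v * 4)  # exactly x4 information
  ci_small <- wald_ci(fit_ml(sr_model, cts_small, restarts = 1))
  ci_big <- wald_ci(fit_ml(sr_model, cts_big, restarts = 1))
  expect_true(all(ci_small$lower <= ci_small$estimate + 1e-12))
  expect_true(all(ci_small$upper >= ci_small$estimate - 1e-12))
  expect_true(all(ci_small$lower >= 0 & ci_small$upper <= 1))
  w_small <- ci_small$upper - ci_small$lower
  w_big <- ci_big$upper - ci_big$lower
  expect_equal(unname(w_big / w_small), rep(0.5, 4), tolerance = 0.02)
})

test_that("Wald 95% interval coverage is calibrated at moderate N", {
  # 400 replicates at N = 1000 per tree; binomial(400, .95) 3-sigma band
  th <- c(s = .85, r1 = .9, g = .4, r2 = .65)
  set.seed(204)
  hits <- 0L; total <- 0L
  for (i in 1:400) {
    fit <- fit_ml(sr_model, draw_counts(th, 1000, 1000), restarts = 1)
    ci <- wald_ci(fit)
    if (any(is.na(ci$lower))) next
    for (p in names(th)) {
      row <- ci[ci$parameter == p, ]
      hits <- hits + (row$lower <= th[[p]] && th[[p]] <= row$upper)
      total <- total + 1L
    }
  }
  cov <- hits / total
  se3 <- 3 * sqrt(0.95 * 0.05 / total)
  expect_gt(cov, 0.95 - se3 - 0.01)
  expect_lt(cov, 0.95 + se3 + 0.01)
})
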