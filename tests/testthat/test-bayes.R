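# module tests run with deliberately short chains; the calibration-grade
# checks live in test-acceptance.R

short_cfg <- function(seed, chains = 2L, iter = 600L, burnin = 250L)
  latent_trait_config(chains = chains, iter = iter, burnin = burnin,
                      seed = seed)

test_that("split R-hat separates mixed from divergent chains", {
  set.seed(1)
  mixed <- matrix(rnorm(4000), 1000, 4)
  tab <- convergence_check(mixed)
  expect_lt(tab$rhat, 1.02)
  expect_gt(tab$ess, 1000)
  divergent <- cbind(rnorm(1000, 0), rnorm(1000, 3))
  expect_gt(convergence_check(divergent)$rhat, 1.05)
  expect_error(convergence_check(matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("latent-trait fit recovers group-level probabilities on simulated data", {
  tp <- true_parameters(
    means = list(one = c(s = .85, r1 = .9, g = .4, r2 = .7)), sigma = 0.3)
  theta <- draw_participant_parameters(tp, "one", 50, seed = 210)
  y <- simulate_counts(theta, seed = 211)
  fit <- suppressWarnings(fit_latent_trait(y, config = short_cfg(212)))
  s <- fit$summary
  means <- s[grep("^mean_", s$quantity), ]
  # posterior means of Phi(mu_k) land near the truth; BCIs cover >= 3 of 4
  truth <- c(s = .85, r1 = .9, g = .4, r2 = .7)
  covered <- 0L
  for (p in names(truth)) {
    row <- means[means$quantity == paste0("mean_", p), ]
    expect_lt(abs(row$mean - truth[[p]]), 0.12)
    covered <- covered + (row$lower <= truth[[p]] && truth[[p]] <= row$upper)
  }
  expect_gte(covered, 3L)
  expect_true(all(c("rhat", "ess") %in% names(s)))
})

test_that("with homogeneous high-count data the posterior tracks the ML solution", {
  # every participant identical, counts scaled far beyond 20 items:
  # the group mean must concentrate on the saturated ML estimate
  th <- c(s = .8, r1 = .9, g = .35, r2 = .6)
  ef <- expected_frequencies(sr_model, th,
                             c(target = 2000, distractor = 2000), round = TRUE)
  y <- matrix(rep(c(ef$target, ef$distractor), each = 12), 12, 6,
              dimnames = list(NULL, names(category_columns())))
  fit <- suppressWarnings(fit_latent_trait(y, config = short_cfg(77)))
  means <- fit$summary[grep("^mean_", fit$summary$quantity), ]
  for (p in names(th)) {
    row <- means[means$quantity == paste0("mean_", p), ]
    expect_lt(abs(row$mean - th[[p]]), 0.03)
  }
})

test_that("posterior group means shrink from the ML estimate toward the prior", {
  # shrinkage direction: the posterior mean of Phi(mu_k) lies between the
  # prior mean (0.5) and the pooled saturated ML estimate, up to MC noise
  tp <- true_parameters(
    means = list(one = c(s = .85, r1 = .9, g = .35, r2 = .7)), sigma = 0.3)
  ok <- 0L; total <- 0L
  for (run in 1:5) {
    theta <- draw_participant_parameters(tp, "one", 50, seed = 520 + run)
    y <- simulate_counts(theta, seed = 530 + run)
    fit <- suppressWarnings(fit_latent_trait(y, config = short_cfg(540 + run)))
    lab <- category_columns()
    ml <- invert_saturated(list(
      target = stats::setNames(colSums(y[, 1:4]), lab[1:4]),
      distractor = stats::setNames(colSums(y[, 5:6]), lab[5:6])))
    means <- fit$summary[grep("^mean_", fit$summary$quantity), ]
    for (p in names(ml)) {
      post <- means$mean[means$quantity == paste0("mean_", p)]
      lo <- min(0.5, ml[[p]]) - 0.03
      hi <- max(0.5, ml[[p]]) + 0.03
      ok <- ok + (post >= lo && post <= hi)
      total <- total + 1L
    }
  }
  expect_gte(ok / total, 0.9)
})

test_that("convergence trouble is surfaced, not silent", {
  tp <- true_parameters(
    means = list(one = c(s = .85, r1 = .9, g = .4, r2 = .7)), sigma = 0.3)
  theta <- draw_participant_parameters(tp, "one", 25, seed = 4)
  y <- simulate_counts(theta, seed = 5)
  # 2 chains x 30 retained draws cannot mix
  expect_warning(
    fit <- fit_latent_trait(y, config = latent_trait_config(
      chains = 2, iter = 30, burnin = 10, seed = 6)),
    "convergence")
  expect_false(fit$convergence_ok)
})

test_that("posterior-predictive checks flag designed misfit and pass own data", {
  tp <- true_parameters(
    means = list(one = c(s = .85, r1 = .9, g = .4, r2 = .7)), sigma = 0.25)
  theta <- draw_participant_parameters(tp, "one", 50, seed = 301)
  y <- simulate_counts(theta, seed = 302)
  fit <- suppressWarnings(fit_latent_trait(y, config = short_cfg(303)))
  ppc <- posterior_predictive_check(fit, n_rep = 200, seed = 304)
  expect_true(ppc$p_t1 > 0.05 && ppc$p_t2 > 0.05)
  expect_true(ppc$satisfactory)

  # shuffle target categories across participants: means stay, structure breaks
  y_bad <- y
  set.seed(305)
  y_bad[, 1:4] <- t(apply(y[, 1:4], 1, sample))
  fit_bad <- suppressWarnings(fit_latent_trait(y_bad, config = short_cfg(306)))
  ppc_bad <- posterior_predictive_check(fit_bad, n_rep = 200, seed = 307)
  expect_lte(ppc_bad$p_t1, 0.05)
  expect_warning(posterior_predictive_check(fit, n_rep = 50, seed = 1),
                 "unstable")
})

test_that("group differences pair draws and summarize the posterior of the gap", {
  tp <- true_parameters(sigma = 0.25)
  ya <- simulate_counts(draw_participant_parameters(tp, "rest", 45, seed = 401),
                        seed = 402)
  yb <- simulate_counts(draw_participant_parameters(tp, "vocab", 45, seed = 403),
                        seed = 404)
  fa <- suppressWarnings(fit_latent_trait(ya, config = short_cfg(405)))
  fb <- suppressWarnings(fit_latent_trait(yb, config = short_cfg(406)))
  # identical posteriors: p about .5, interval straddles zero
  same <- group_difference(fa, fa, "s")
  expect_equal(same$bayes_p, 0.5, tolerance = 1e-12)
  expect_false(same$excludes_zero)
  # rest vs vocab guessing gap is large (.46 vs .27): detected
  gd <- group_difference(fa, fb, "g")
  expect_lt(gd$bayes_p, 0.05)
  expect_true(gd$excludes_zero)
  expect_error(group_difference(fa, fb, "nope"), "not monitored")
})
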