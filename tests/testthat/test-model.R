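test_that("category probabilities match the algebraic oracle and spec values", {
  th <- c(s = .91, r1 = .98, g = .46, r2 = .73)
  pr <- category_probabilities(sr_model, th, sr_cons)
  oracle <- sr_probs_oracle(.91, .98, .46, .73)
  expect_equal(pr$target, oracle$target, tolerance = 1e-14)
  expect_equal(pr$distractor, oracle$distractor, tolerance = 1e-14)
  # hand-derived anchors: P(D-) = (1 - s*r1)*g; P(Rc+) = s*r2
  expect_equal(pr$distractor[["D-"]], 0.049772, tolerance = 1e-12)
  expect_equal(pr$target[["Rn+Rc+"]] + pr$target[["Rn-Rc+"]], 0.6643,
               tolerance = 1e-12)

  # deterministic-success branch
  pr1 <- category_probabilities(sr_model, c(s = 1, r1 = 1, g = .3, r2 = 1),
                                sr_cons)
  expect_equal(pr1$target[["Rn+Rc+"]], 1)
  expect_equal(sum(pr1$target[c("Rn+Rc-", "Rn-Rc+", "Rn-Rc-")]), 0)

  expect_error(category_probabilities(sr_model, c(s = 1.2, r1 = .9, g = .3,
                                                  r2 = .5), sr_cons),
               "\\[0, 1\\]")
})

test_that("branch probabilities sum to one and stay in [0,1] under fuzzing", {
  set.seed(421)
  worst_sum <- 0
  in_range <- TRUE
  for (i in 1:1000) {
    th <- c(s = runif(1), r1 = runif(1), g = runif(1), r2 = runif(1))
    pr <- category_probabilities(sr_model, th, sr_cons)
    for (tree in pr) {
      in_range <- in_range && all(tree >= 0 & tree <= 1)
      worst_sum <- max(worst_sum, abs(sum(tree) - 1))
    }
  }
  expect_true(in_range)
  expect_lt(worst_sum, 1e-12)
})

test_that("df accounting matches the design's model versions", {
  # saturated single group: identifiable but not testable
  expect_equal(df_account(apply_constraints(sr_model, sr_cons, "g1"))$df, 0L)
  groups <- c("rest", "social", "vocab")
  # r1 shared between waking rest and social media: 11 free, df = 1
  pz1 <- apply_constraints(sr_model, mpt_constraints(list(
    con_substitute("d", c("s", "r1")),
    con_equal("r1", c("rest", "social")))), groups)
  expect_equal(df_account(pz1)$free_parameters, 11L)
  expect_equal(pz1$df, 1L)
  # g shared across all three conditions: df = 2
  pz2 <- apply_constraints(sr_model, mpt_constraints(list(
    con_substitute("d", c("s", "r1")), con_equal("g", "all"))), groups)
  expect_equal(pz2$df, 2L)
  # df equals the independent recomputation free cats - free params
  for (pz in list(pz1, pz2)) {
    acc <- df_account(pz)
    expect_equal(acc$df, acc$free_categories - acc$free_parameters)
  }
})

test_that("constraint resolution is idempotent and rejects contradictions", {
  cons <- mpt_constraints(list(con_substitute("d", c("s", "r1")),
                               con_equal("g", "all"),
                               con_fix("r1", 0.95)))
  pz_a <- apply_constraints(sr_model, cons, c("a", "b"))
  pz_b <- apply_constraints(sr_model, cons, c("a", "b"))
  expect_identical(pz_a$free_names, pz_b$free_names)
  expect_identical(pz_a$df, pz_b$df)
  th <- expand_free <- rep(0.4, pz_a$n_free)
  expect_identical(srmpt:::expand_theta(pz_a, th),
                   srmpt:::expand_theta(pz_b, th))

  expect_error(apply_constraints(sr_model, mpt_constraints(list(
    con_fix("g", 0.2), con_fix("g", 0.6))), "g1"), "contradictory")
  expect_error(apply_constraints(sr_model, mpt_constraints(list(
    con_equal("zz", "all"))), "g1"), "undeclared")
  expect_error(apply_constraints(sr_model, mpt_constraints(list(
    con_substitute("d", "s"), con_substitute("s", "d"))), "g1"), "cycle")
})

test_that("fixed and substituted parameters satisfy their constraints exactly", {
  pz <- apply_constraints(sr_model, mpt_constraints(list(
    con_substitute("d", c("s", "r1")), con_fix("g", 0.25),
    con_equal("s", "all"))), c("a", "b"))
  free <- stats::setNames(seq(0.3, 0.8, length.out = pz$n_free),
                          pz$free_names)
  th <- srmpt:::expand_theta(pz, free)
  expect_equal(th["g", ], c(a = 0.25, b = 0.25))
  expect_equal(th["d", ], th["s", ] * th["r1", ])
  expect_equal(th["s", "a"], th["s", "b"])
})

test_that("identifiability probe ranks behave as designed", {
  # d = s*r1 substitution: rank 4 everywhere, locally identifiable
  rep_ok <- check_identifiability(sr_model, sr_cons, n_probe = 5, seed = 7)
  expect_true(rep_ok$identifiable)
  expect_true(all(rep_ok$ranks == 4L))
  # d left free: 5 parameters against 4 free categories
  rep_bad <- check_identifiability(sr_model, mpt_constraints(list()),
                                   n_probe = 3, seed = 7)
  expect_false(rep_bad$identifiable)
  expect_true(all(rep_bad$ranks < rep_bad$n_free))
  # one-parameter two-category model: rank 1
  m1 <- parse_eqn(c("t A p", "t B (1-p)"))
  rep1 <- check_identifiability(m1, mpt_constraints(list()), n_probe = 3,
                                seed = 7)
  expect_true(rep1$identifiable)
  expect_equal(rep1$n_free, 1L)
})
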