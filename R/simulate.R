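#' Experiment design description
#'
#' Defaults mirror the three-condition post-encoding design: waking rest,
#' social media and vocabulary-learning groups; 20 target and 20 distractor
#' words per delayed test (plus 4 untested buffer items at study); an
#' immediate-recall learning criterion of 35% (at least 7 of 20 correct)
#' with up to three study-test cycles; and a per-group sample size of 53
#' (the a-priori power analysis, see [required_sample_size()]).
#'
#' @param conditions Condition labels.
#' @param n_per_condition Participants per condition (recycled).
#' @param targets,distractors Items per delayed test.
#' @param buffer Buffer items at study (never tested).
#' @param criterion Learning-criterion threshold (correct responses).
#' @param max_cycles Maximum study-test cycles.
#' @param sessions Number of delayed test sessions (1 or 2).
#' @param test_order `"recognition-recall"` or `"recall-recognition"`
#'   (bookkeeping only; the model is the same under both orders).
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(conditions = c("rest", "social", "vocab"),
                              n_per_condition = 53L,
                              targets = 20L, distractors = 20L, buffer = 4L,
                              criterion = 7L, max_cycles = 3L, sessions = 1L,
                              test_order = c("recognition-recall",
                                             "recall-recognition")) {
  test_order <- match.arg(test_order)
  n_per_condition <- rep_len(as.integer(n_per_condition), length(conditions))
  stopifnot(all(n_per_condition > 0), targets > 0, distractors > 0,
            criterion >= 0, max_cycles >= 1, sessions %in% 1:2)
  structure(list(conditions = conditions, n_per_condition = n_per_condition,
                 targets = as.integer(targets),
                 distractors = as.integer(distractors),
                 buffer = as.integer(buffer), criterion = as.integer(criterion),
                 max_cycles = as.integer(max_cycles),
                 sessions = as.integer(sessions), test_order = test_order),
            class = "experiment_design")
}

#' True generating parameters for the simulator
#'
#' Group-level probabilities of the storage-retrieval model per condition,
#' individual heterogeneity on the probit scale, and the immediate-encoding
#' probability `e` that drives the immediate-recall cycles (a simulator
#' construct: delayed category counts come from the MPT parameters, so
#' retention relative to immediate recall may exceed 1).
#'
#' Defaults place the condition effect on storage `s` (and mildly on `g`
#' and `r2`), at values close to published aggregated Session-1 estimates
#' for this design; heterogeneity defaults to independent probit-normal
#' deviations with standard deviation 0.3.
#'
#' @param means Named list: per condition a named vector of probabilities
#'   for `s`, `r1`, `g`, `r2`.
#' @param sigma Covariance matrix of probit-scale individual deviations
#'   (4 x 4, order `s`, `r1`, `g`, `r2`), or a scalar standard deviation.
#' @param e_mean Group-level immediate-encoding probability.
#' @param e_sd Probit-scale SD of individual encoding probabilities.
#' @param cycle_increment Probit-scale gain in `e` per additional
#'   study-test cycle.
#' @return List of class `true_parameters`.
#' @export
true_parameters <- function(
    means = list(
      rest   = c(s = 0.91, r1 = 0.98, g = 0.46, r2 = 0.73),
      social = c(s = 0.92, r1 = 0.98, g = 0.38, r2 = 0.73),
      vocab  = c(s = 0.87, r1 = 0.96, g = 0.27, r2 = 0.68)),
    sigma = 0.3, e_mean = 0.58, e_sd = 0.33, cycle_increment = 0.35) {
  K <- 4L
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == K, ncol(sigma) == K)
  } else {
    sigma <- diag(rep(sigma^2, K))
  }
  dimnames(sigma) <- list(c("s", "r1", "g", "r2"), c("s", "r1", "g", "r2"))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("sigma must be positive semi-definite", call. = FALSE)
  for (m in means)
    stopifnot(all(c("s", "r1", "g", "r2") %in% names(m)),
              all(m > 0 & m < 1))
  structure(list(means = means, sigma = sigma, e_mean = e_mean, e_sd = e_sd,
                 cycle_increment = cycle_increment),
            class = "true_parameters")
}

#' Draw per-participant MPT parameters
#'
#' Individual parameters follow the latent-trait construction
#' \eqn{\theta_{ik} = \Phi(\Phi^{-1}(\mu_k) + \delta_{ik})} with
#' \eqn{\delta_i \sim N(0, \Sigma)}.
#'
#' @param true A `true_parameters` object.
#' @param condition Condition label (selects the group means).
#' @param n Number of participants.
#' @param seed Optional integer seed.
#' @return `n x 4` matrix of probabilities (columns `s`, `r1`, `g`, `r2`).
#' @export
draw_participant_parameters <- function(true, condition, n, seed = NULL) {
  stopifnot(inherits(true, "true_parameters"))
  mu <- true$means[[condition]]
  if (is.null(mu)) stop("unknown condition: ", condition, call. = FALSE)
  local_seed(seed)
  K <- ncol(true$sigma)
  delta <- if (all(true$sigma == 0)) matrix(0, n, K)
           else MASS::mvrnorm(n, rep(0, K), true$sigma)
  delta <- matrix(delta, n, K)
  theta <- stats::pnorm(sweep(delta, 2, stats::qnorm(mu[colnames(true$sigma)]), "+"))
  colnames(theta) <- colnames(true$sigma)
  theta
}

#' Simulate delayed-test category counts for given parameters
#'
#' Target counts are multinomial over the four target categories;
#' distractor counts are multinomial over (`D+`, `D-`) with the distractor
#' detection probability tied to `s * r1`.
#'
#' @param theta Matrix of per-participant probabilities (columns `s`, `r1`,
#'   `g`, `r2`) or a single named vector.
#' @param design An `experiment_design` (supplies the item totals).
#' @param seed Optional integer seed.
#' @param model,constraints Model structure (defaults to the built-in one).
#' @return Integer matrix, one row per participant, columns
#'   `RnpRcp, RnpRcm, RnmRcp, RnmRcm, Dp, Dm`.
#' @export
simulate_counts <- function(theta, design = experiment_design(), seed = NULL,
                            model = storage_retrieval_model(),
                            constraints = default_constraints()) {
  if (is.null(dim(theta))) theta <- matrix(theta, 1L,
                                           dimnames = list(NULL, names(theta)))
  stopifnot(all(theta > 0 - 1e-12), all(theta < 1 + 1e-12))
  local_seed(seed)
  # complete substituted parameters (d = s*r1)
  full <- theta
  for (k in Filter(function(z) z$type == "substitute", constraints)) {
    v <- rep(1, nrow(theta))
    for (f in k$factors) v <- v * theta[, f]
    full <- cbind(full, v)
    colnames(full)[ncol(full)] <- k$target
  }
  probs <- category_prob_matrix(model, full)
  n <- nrow(theta)
  out <- matrix(0L, n, 6L,
                dimnames = list(NULL, names(category_columns())))
  lab <- category_columns()
  for (i in seq_len(n)) {
    tg <- stats::rmultinom(1, design$targets, probs$target[i, ])[, 1]
    ds <- stats::rmultinom(1, design$distractors, probs$distractor[i, ])[, 1]
    out[i, ] <- c(tg[lab[1:4]], ds[lab[5:6]])
  }
  out
}

#' Simulate a complete experiment
#'
#' Per participant: an encoding probability `e_i` is drawn on the probit
#' scale; immediate-recall cycles are binomial draws at `e_i` with a fixed
#' probit increment per repetition, stopping once the learning criterion is
#' reached (participants failing all cycles are flagged excluded and get no
#' delayed data); MPT parameters are drawn from the latent-trait structure
#' and delayed category counts are simulated from the model. With
#' `sessions = 2` the delayed test is re-simulated from the same
#' individual parameters (fresh distractors).
#'
#' @param design An `experiment_design`.
#' @param true A `true_parameters` object.
#' @param seed Optional integer seed; all randomness flows from it.
#' @return Data frame with columns `id`, `condition`, `session`, `cycles`,
#'   `immediate_correct`, the six category-count columns, and `excluded`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                true = true_parameters(), seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(true, "true_parameters"))
  local_seed(seed)
  n_rows <- sum(design$n_per_condition) * design$sessions
  id_v <- cyc_v <- imm_v <- integer(n_rows)
  cond_v <- character(n_rows)
  ses_v <- integer(n_rows)
  cnt_m <- matrix(NA_integer_, n_rows, 6L,
                  dimnames = list(NULL, names(category_columns())))
  excl_v <- logical(n_rows)
  row <- 0L
  id0 <- 0L
  for (ci in seq_along(design$conditions)) {
    cond <- design$conditions[ci]
    n <- design$n_per_condition[ci]
    theta <- draw_participant_parameters(true, cond, n)
    e_probit <- stats::qnorm(true$e_mean) + stats::rnorm(n, 0, true$e_sd)
    for (i in seq_len(n)) {
      id0 <- id0 + 1L
      cycles <- NA_integer_
      imm <- NA_integer_
      for (cyc in seq_len(design$max_cycles)) {
        e_cyc <- stats::pnorm(e_probit[i] + (cyc - 1L) * true$cycle_increment)
        cnt <- stats::rbinom(1L, design$targets, e_cyc)
        if (cnt >= design$criterion) { cycles <- cyc; imm <- cnt; break }
        imm <- cnt
      }
      excluded <- is.na(cycles)
      if (excluded) cycles <- design$max_cycles
      for (ses in seq_len(design$sessions)) {
        row <- row + 1L
        id_v[row] <- id0; cond_v[row] <- cond; ses_v[row] <- ses
        cyc_v[row] <- cycles; imm_v[row] <- imm; excl_v[row] <- excluded
      }
    }
    # delayed counts for this condition's included participants, one
    # vectorized call per session
    cond_rows <- which(cond_v[seq_len(row)] == cond &
                         id_v[seq_len(row)] > id0 - n)
    for (ses in seq_len(design$sessions)) {
      rws <- cond_rows[ses_v[cond_rows] == ses & !excl_v[cond_rows]]
      if (length(rws)) {
        part <- id_v[rws] - (id0 - n)
        cnt_m[rws, ] <- simulate_counts(theta[part, , drop = FALSE], design)
      }
    }
  }
  out <- data.frame(id = id_v, condition = cond_v, session = ses_v,
                    cycles = cyc_v, immediate_correct = imm_v,
                    cnt_m, excluded = excl_v, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expected category frequencies at a parameter vector
#'
#' Deterministic real-valued frequencies `totals x category probability`,
#' the standard device for round-trip checks: refitting the saturated model
#' to its own expected frequencies recovers the generating parameters.
#'
#' @param model An `mpt_model`.
#' @param theta Named parameter vector (substituted parameters may be
#'   omitted when `constraints` supplies them).
#' @param totals Named vector of per-tree totals.
#' @param constraints Constraint set used to complete `theta`.
#' @param round Round to integers (largest-remainder, totals preserved)?
#' @return Named list `tree -> named numeric vector` of frequencies.
#' @export
expected_frequencies <- function(model, theta,
                                 totals = c(target = 20, distractor = 20),
                                 constraints = default_constraints(),
                                 round = FALSE) {
  stopifnot(all(totals > 0))
  pr <- category_probabilities(model, theta, constraints)
  missing <- setdiff(names(model$trees), names(totals))
  if (length(missing))
    stop("totals missing for tree(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (tid in names(model$trees)) {
    v <- totals[[tid]] * pr[[tid]]
    if (round) v <- stats::setNames(largest_remainder_round(v), names(v))
    out[[tid]] <- v
  }
  out
}

#' Aggregate participant records into per-condition category counts
#'
#' @param records Data frame as produced by [simulate_experiment()] (or
#'   read from the participant CSV schema); excluded rows and rows with
#'   missing counts are dropped.
#' @param session Which session to aggregate.
#' @return Named list per condition of `list(target =, distractor =)`
#'   counts with canonical category labels, ready for [fit_ml()].
#' @export
aggregate_counts <- function(records, session = 1L) {
  lab <- category_columns()
  need <- c("condition", "session", names(lab))
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec <- records[records$session == session, , drop = FALSE]
  if ("excluded" %in% names(rec)) rec <- rec[!rec$excluded, , drop = FALSE]
  rec <- rec[stats::complete.cases(rec[, names(lab)]), , drop = FALSE]
  out <- list()
  for (cond in unique(rec$condition)) {
    sub <- rec[rec$condition == cond, names(lab), drop = FALSE]
    tot <- colSums(sub)
    out[[cond]] <- list(
      target = stats::setNames(tot[1:4], lab[1:4]),
      distractor = stats::setNames(tot[5:6], lab[5:6]))
  }
  out
}
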