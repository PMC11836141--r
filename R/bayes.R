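#' MCMC settings for the latent-trait model
#'
#' Priors follow the latent-trait MPT literature defaults: group means
#' \eqn{\mu_k \sim N(0, 1)} on the probit scale, and the covariance of the
#' individual deviations via a scaled inverse-Wishart: \eqn{\Sigma =
#' \Lambda Q \Lambda} with \eqn{Q \sim IW(I, K+1)} and uniform(0, 10)
#' scale factors \eqn{\lambda_k}. The sampler is Metropolis-within-Gibbs
#' with proposal scales adapted during burn-in toward acceptance rates in
#' 0.2–0.5; `Q` is drawn from its conjugate inverse-Wishart full
#' conditional.
#'
#' @param chains Number of chains (>= 2, required for R-hat).
#' @param iter Retained iterations per chain (after burn-in, before
#'   thinning).
#' @param burnin Burn-in iterations per chain.
#' @param thin Thinning interval.
#' @param seed Optional integer seed.
#' @param mu_prior_sd Prior SD of the probit-scale group means.
#' @param lambda_max Upper bound of the uniform prior on the scale factors.
#' @param adapt_interval Iterations between proposal-scale adaptations
#'   (burn-in only).
#' @return List of class `latent_trait_config`.
#' @export
latent_trait_config <- function(chains = 4L, iter = 8000L, burnin = 2000L,
                                thin = 1L, seed = NULL, mu_prior_sd = 1,
                                lambda_max = 10, adapt_interval = 50L) {
  stopifnot(chains >= 2L, iter >= 10L, burnin >= 0L, thin >= 1L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = seed, mu_prior_sd = mu_prior_sd,
                 lambda_max = lambda_max,
                 adapt_interval = as.integer(adapt_interval)),
            class = "latent_trait_config")
}

#' Hierarchical Bayesian latent-trait fit of one condition
#'
#' Individual parameters are \eqn{\theta_{ik} = \Phi(\mu_k + \delta_{ik})}
#' with \eqn{\delta_i \sim N(0, \Sigma)}; each participant's category
#' counts are product-multinomial at \eqn{\theta_i}. The group-level
#' probability \eqn{\Phi(\mu_k)} is summarized by posterior mean, median
#' and central 95% credibility interval, with split-chain R-hat and an
#' effective-sample-size estimate per monitored quantity. Any monitored
#' R-hat at or above 1.05 raises a convergence warning (surfaced, not
#' silent).
#'
#' @param records Participant data frame of a single condition (schema of
#'   [simulate_experiment()]), or a count matrix with the six canonical
#'   category columns.
#' @param model An `mpt_model` (built-in storage-retrieval model by
#'   default).
#' @param constraints Constraint set; substitutions define derived
#'   parameters (`d = s*r1`), so individual traits cover the base
#'   parameters only.
#' @param config A [latent_trait_config()].
#' @return Object of class `mpt_bayes_fit`: `summary` data frame, per-chain
#'   draws of `mu` (probit), `sigma`, and `delta`, acceptance rates, data,
#'   and a `convergence_ok` flag.
#' @export
fit_latent_trait <- function(records, model = storage_retrieval_model(),
                             constraints = default_constraints(),
                             config = latent_trait_config()) {
  stopifnot(inherits(config, "latent_trait_config"))
  y <- person_count_matrix(records)
  n <- nrow(y)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)

  subs <- Filter(function(k) k$type == "substitute", constraints)
  sub_targets <- vapply(subs, `[[`, "", "target")
  person_params <- setdiff(model$parameters, sub_targets)
  K <- length(person_params)

  tree_cols <- split_tree_columns(model)
  loglik_rows <- compile_person_loglik(model, subs, person_params, y, tree_cols)

  # starting center: pooled closed-form estimates where available
  mu_start <- rep(0, K)
  pooled <- tryCatch({
    cts <- list(
      target = stats::setNames(colSums(y[, tree_cols$target, drop = FALSE]),
                               category_columns()[tree_cols$target]),
      distractor = stats::setNames(colSums(y[, tree_cols$distractor, drop = FALSE]),
                                   category_columns()[tree_cols$distractor]))
    names(cts$target) <- category_columns()[tree_cols$target]
    names(cts$distractor) <- category_columns()[tree_cols$distractor]
    invert_saturated(cts)
  }, error = function(e) NULL)
  if (!is.null(pooled) && all(person_params %in% names(pooled)))
    mu_start <- stats::qnorm(pmin(pmax(pooled[person_params], 0.02), 0.98))

  local_seed(config$seed)
  chain_seeds <- derive_seeds(config$seed %||% sample.int(2^31 - 2, 1),
                              config$chains)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    chains[[ch]] <- run_latent_trait_chain(
      loglik_rows, n, K, person_params, mu_start, config,
      seed = chain_seeds[[ch]])
  }

  kept <- nrow(chains[[1]]$mu)
  qty <- c(paste0("mean_", person_params), paste0("sigma_", person_params))
  arr <- array(NA_real_, c(kept, config$chains, 2L * K),
               dimnames = list(NULL, NULL, qty))
  for (ch in seq_len(config$chains)) {
    arr[, ch, seq_len(K)] <- stats::pnorm(chains[[ch]]$mu)
    arr[, ch, K + seq_len(K)] <- chains[[ch]]$sigma
  }
  diag_tab <- convergence_check(arr)
  summ <- data.frame(
    quantity = qty,
    mean = apply(arr, 3, mean), median = apply(arr, 3, stats::median),
    lower = apply(arr, 3, stats::quantile, 0.025),
    upper = apply(arr, 3, stats::quantile, 0.975),
    rhat = diag_tab$rhat, ess = diag_tab$ess, row.names = NULL)
  conv_ok <- all(summ$rhat < 1.05, na.rm = TRUE)
  if (!conv_ok)
    warning("convergence warning: R-hat >= 1.05 for ",
            paste(summ$quantity[summ$rhat >= 1.05], collapse = ", "),
            call. = FALSE)

  structure(list(
    summary = summ, chains = chains, person_params = person_params,
    model = model, constraints = constraints, config = config,
    y = y, tree_cols = tree_cols, loglik_rows = loglik_rows,
    convergence_ok = conv_ok, n = n
  ), class = "mpt_bayes_fit")
}

#' @export
print.mpt_bayes_fit <- function(x, ...) {
  cat(sprintf("Latent-trait MPT fit: n = %d, %d chains x %d retained\n",
              x$n, x$config$chains, nrow(x$chains[[1]]$mu)))
  if (!x$convergence_ok) cat("  WARNING: R-hat >= 1.05 for some quantities\n")
  print(transform(x$summary, mean = round(mean, 3), median = round(median, 3),
                  lower = round(lower, 3), upper = round(upper, 3),
                  rhat = round(rhat, 3), ess = round(ess)))
  invisible(x)
}

run_latent_trait_chain <- function(loglik_rows, n, K, person_params,
                                   mu_start, config, seed) {
  local_seed(seed)
  mu <- mu_start + stats::rnorm(K, 0, 0.25)
  delta <- matrix(0, n, K)
  lambda <- rep(1, K)
  Q <- diag(K)
  Qinv <- diag(K)
  iw_df <- K + 1

  scale_delta <- rep(0.3, n)
  scale_mu <- rep(0.15, K)
  scale_lam <- rep(0.3, K)
  acc_delta <- numeric(n); acc_mu <- numeric(K); acc_lam <- numeric(K)
  n_since_adapt <- 0L

  addmu <- function(d, m) d + rep(m, each = n)
  ll <- loglik_rows(addmu(delta, mu))
  total_iter <- config$burnin + config$iter
  kept <- config$iter %/% config$thin
  out_mu <- matrix(NA_real_, kept, K, dimnames = list(NULL, person_params))
  out_sigma <- out_mu
  out_delta <- array(NA_real_, c(kept, n, K))
  ki <- 0L

  sigma_from <- function(lambda, Q) lambda * sqrt(diag(Q))

  for (it in seq_len(total_iter)) {
    # --- individual deviations: joint RW per participant, vectorized ---
    Sinv <- Qinv / tcrossprod(lambda)          # (Lambda Q Lambda)^{-1}
    prop <- delta + matrix(stats::rnorm(n * K), n, K) * scale_delta
    ll_prop <- loglik_rows(addmu(prop, mu))
    pr_old <- -0.5 * rowSums((delta %*% Sinv) * delta)
    pr_new <- -0.5 * rowSums((prop %*% Sinv) * prop)
    acc <- log(stats::runif(n)) < (ll_prop - ll + pr_new - pr_old)
    delta[acc, ] <- prop[acc, ]
    ll[acc] <- ll_prop[acc]
    acc_delta <- acc_delta + acc

    # --- group means: joint K-dimensional RW (one likelihood pass) ---
    mu_new <- mu + stats::rnorm(K, 0, scale_mu)
    ll_new <- loglik_rows(addmu(delta, mu_new))
    lr <- sum(ll_new) - sum(ll) +
      sum(stats::dnorm(mu_new, 0, config$mu_prior_sd, log = TRUE)) -
      sum(stats::dnorm(mu, 0, config$mu_prior_sd, log = TRUE))
    if (log(stats::runif(1)) < lr) {
      mu <- mu_new; ll <- ll_new; acc_mu <- acc_mu + 1
    }

    # --- funnel breaker: per-parameter translation mu_k <- mu_k + c,
    #     delta_.k <- delta_.k - c leaves the likelihood invariant, so
    #     acceptance depends on the priors only (cheap, decorrelates the
    #     group mean from the individual deviations) ---
    Sinv <- Qinv / tcrossprod(lambda)
    for (k in seq_len(K)) {
      cc <- stats::rnorm(1, 0, 0.25)
      mu_k <- mu[k] + cc
      dk_new <- delta[, k] - cc
      dpr <- -0.5 * (sum((dk_new^2 - delta[, k]^2) * Sinv[k, k]) +
                       2 * sum((dk_new - delta[, k]) *
                                 (delta[, -k, drop = FALSE] %*% Sinv[-k, k])))
      lr <- dpr + stats::dnorm(mu_k, 0, config$mu_prior_sd, log = TRUE) -
        stats::dnorm(mu[k], 0, config$mu_prior_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        mu[k] <- mu_k
        delta[, k] <- dk_new
      }
    }

    # --- Q: conjugate inverse-Wishart draw ---
    u <- delta * rep(1 / lambda, each = n)
    S <- diag(K) + crossprod(u)
    W <- stats::rWishart(1, iw_df + n, solve(S))[, , 1]
    Qinv <- W
    Q <- solve(W)

    # --- scale factors: scalar RW under uniform(0, lambda_max) prior ---
    lam_loglik <- function(lam) {
      uu <- delta * rep(1 / lam, each = n)
      -n * sum(log(lam)) - 0.5 * sum((uu %*% Qinv) * uu)
    }
    cur_lam_ll <- lam_loglik(lambda)
    for (k in seq_len(K)) {
      lk <- lambda[k] + stats::rnorm(1, 0, scale_lam[k])
      if (lk <= 0 || lk >= config$lambda_max) next
      lam_new <- lambda; lam_new[k] <- lk
      new_ll <- lam_loglik(lam_new)
      if (log(stats::runif(1)) < new_ll - cur_lam_ll) {
        lambda <- lam_new; cur_lam_ll <- new_ll
        acc_lam[k] <- acc_lam[k] + 1
      }
    }

    # --- proposal adaptation during burn-in ---
    n_since_adapt <- n_since_adapt + 1L
    if (it <= config$burnin && n_since_adapt >= config$adapt_interval) {
      tune <- function(scale, acc) {
        rate <- acc / n_since_adapt
        scale * ifelse(rate < 0.2, 0.8, ifelse(rate > 0.5, 1.25, 1))
      }
      scale_delta <- pmax(tune(scale_delta, acc_delta), 1e-3)
      scale_mu <- pmax(tune(scale_mu, acc_mu), 1e-3)
      scale_lam <- pmax(tune(scale_lam, acc_lam), 1e-3)
      acc_delta[] <- 0; acc_mu[] <- 0; acc_lam[] <- 0
      n_since_adapt <- 0L
    }

    if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
      ki <- ki + 1L
      out_mu[ki, ] <- mu
      out_sigma[ki, ] <- sigma_from(lambda, Q)
      out_delta[ki, , ] <- delta
    }
  }
  list(mu = out_mu, sigma = out_sigma, delta = out_delta,
       accept = list(delta = mean(acc_delta) / max(1, n_since_adapt),
                     mu = acc_mu / max(1, n_since_adapt)))
}

# Precompiled per-participant log-likelihood: probit-scale matrix
# eta (n x K, columns = person_params) -> length-n log-likelihood vector.
# All lookups reduced to integer column indices for speed (the sampler
# calls this several times per iteration).
compile_person_loglik <- function(model, subs, person_params, y, tree_cols) {
  n <- nrow(y)
  K <- length(person_params)
  full_names <- c(person_params, vapply(subs, `[[`, "", "target"))
  sub_idx <- lapply(subs, function(k) match(k$factors, full_names))
  trees <- lapply(names(model$trees), function(tid) {
    tr <- model$trees[[tid]]
    branches <- lapply(seq_len(nrow(tr$A)), function(j) {
      a <- rep(match(colnames(tr$A), full_names), tr$A[j, ])
      b <- rep(match(colnames(tr$C), full_names), tr$C[j, ])
      list(a = a, b = b, cat = tr$cat_idx[j])
    })
    yt <- y[, tree_cols[[tid]], drop = FALSE]
    list(branches = branches, ncat = length(tr$categories), y = yt)
  })
  nf <- length(full_names)
  function(eta) {
    theta <- stats::pnorm(eta)
    theta[theta < 1e-10] <- 1e-10
    theta[theta > 1 - 1e-10] <- 1 - 1e-10
    full <- matrix(0, n, nf)
    full[, seq_len(K)] <- theta
    for (si in seq_along(sub_idx)) {
      v <- full[, sub_idx[[si]][1]]
      for (fi in sub_idx[[si]][-1]) v <- v * full[, fi]
      full[, K + si] <- v
    }
    ll <- numeric(n)
    for (tr in trees) {
      P <- matrix(0, n, tr$ncat)
      for (br in tr$branches) {
        pr <- rep(1, n)
        for (ci in br$a) pr <- pr * full[, ci]
        for (ci in br$b) pr <- pr * (1 - full[, ci])
        P[, br$cat] <- P[, br$cat] + pr
      }
      P[P < 1e-300] <- 1e-300
      ll <- ll + rowSums(tr$y * log(P))
    }
    ll
  }
}

person_count_matrix <- function(records) {
  cols <- names(category_columns())
  if (is.matrix(records)) {
    stopifnot(all(cols %in% colnames(records)))
    y <- records[, cols, drop = FALSE]
  } else {
    missing <- setdiff(cols, names(records))
    if (length(missing))
      stop("records lack count column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    if ("excluded" %in% names(records))
      records <- records[!records$excluded, , drop = FALSE]
    if ("session" %in% names(records) &&
        length(unique(records$session)) > 1L)
      stop("records span several sessions: filter to one first", call. = FALSE)
    if ("condition" %in% names(records) &&
        length(unique(records$condition)) > 1L)
      stop("records span several conditions: fit each condition separately",
           call. = FALSE)
    y <- as.matrix(records[, cols])
  }
  storage.mode(y) <- "double"
  if (any(is.na(y)) || any(y < 0))
    stop("category counts must be nonnegative and complete", call. = FALSE)
  y
}

split_tree_columns <- function(model) {
  lab <- category_columns()
  out <- list()
  for (tid in names(model$trees)) {
    cats <- model$trees[[tid]]$categories
    cl <- names(lab)[match(cats, lab)]
    if (any(is.na(cl)))
      stop("model categories do not match the canonical column set",
           call. = FALSE)
    out[[tid]] <- cl
  }
  out
}

# ---- convergence diagnostics ------------------------------------------

#' Split-chain R-hat and effective sample size
#'
#' Computes the potential scale reduction factor on split chains (each
#' chain halved) and a crude effective-sample-size estimate from pooled
#' autocorrelations (initial positive sequence).
#'
#' @param draws Either an `mpt_bayes_fit`, or a 3-d array
#'   `iterations x chains x quantities`, or a matrix
#'   `iterations x chains` for a single quantity.
#' @return Data frame: quantity, rhat, ess.
#' @export
convergence_check <- function(draws) {
  if (inherits(draws, "mpt_bayes_fit")) {
    K <- length(draws$person_params)
    kept <- nrow(draws$chains[[1]]$mu)
    qty <- c(paste0("mean_", draws$person_params),
             paste0("sigma_", draws$person_params))
    arr <- array(NA_real_, c(kept, length(draws$chains), 2L * K),
                 dimnames = list(NULL, NULL, qty))
    for (ch in seq_along(draws$chains)) {
      arr[, ch, seq_len(K)] <- stats::pnorm(draws$chains[[ch]]$mu)
      arr[, ch, K + seq_len(K)] <- draws$chains[[ch]]$sigma
    }
    draws <- arr
  }
  if (is.matrix(draws)) {
    draws <- array(draws, c(nrow(draws), ncol(draws), 1L),
                   dimnames = list(NULL, NULL, "quantity"))
  }
  stopifnot(length(dim(draws)) == 3L)
  if (dim(draws)[2] < 2L)
    stop("R-hat requires at least 2 chains", call. = FALSE)
  nq <- dim(draws)[3]
  qn <- dimnames(draws)[[3]] %||% paste0("q", seq_len(nq))
  data.frame(
    quantity = qn,
    rhat = vapply(seq_len(nq), function(j) split_rhat(draws[, , j]), 1),
    ess = vapply(seq_len(nq), function(j) ess_estimate(draws[, , j]), 1),
    row.names = NULL)
}

split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  pieces <- do.call(cbind, lapply(seq_len(ncol(mat)), function(ch)
    cbind(mat[seq_len(half), ch], mat[(n - half + 1L):n, ch])))
  m <- ncol(pieces); nn <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_estimate <- function(mat, max_lag = 100L) {
  n <- nrow(mat); m <- ncol(mat)
  cen <- sweep(mat, 2, colMeans(mat))
  v <- mean(apply(cen, 2, stats::var))
  if (v <= 1e-300) return(n * m)
  max_lag <- min(max_lag, n - 2L)
  rho <- vapply(seq_len(max_lag), function(l) {
    mean(vapply(seq_len(m), function(ch)
      sum(cen[seq_len(n - l), ch] * cen[(l + 1):n, ch]) / (n - 1), 1)) / v
  }, 1)
  s <- 0
  for (l in seq_along(rho)) {
    if (rho[l] < 0) break
    s <- s + rho[l]
  }
  n * m / (1 + 2 * s)
}

# ---- posterior-predictive checks --------------------------------------

#' Posterior-predictive model checks (T1 / T2)
#'
#' For each of `n_rep` retained posterior draws a replicate dataset of the
#' same dimensions is simulated. T1 is a Pearson-type discrepancy between
#' observed and expected mean category frequencies,
#' \eqn{T_1 = \sum_c (\bar y_c - \bar E_c)^2 / \bar E_c}; T2 sums squared
#' standardized deviations between the observed across-participant
#' covariance matrix of category frequencies and its model-implied
#' counterpart (standardized by the geometric mean of the implied
#' variances). The posterior-predictive p-value is the fraction of
#' replicates whose statistic is at least the observed one; both p-values
#' above 0.05 are conventionally read as satisfactory fit.
#'
#' @param fit An `mpt_bayes_fit`.
#' @param n_rep Number of posterior draws used (warning below 100).
#' @param seed Optional integer seed.
#' @return List of class `mpt_ppc`: `p_t1`, `p_t2`, observed statistics,
#'   and `satisfactory` (both p > 0.05).
#' @export
posterior_predictive_check <- function(fit, n_rep = 500L, seed = NULL) {
  stopifnot(inherits(fit, "mpt_bayes_fit"))
  if (n_rep < 100L) warning("n_rep < 100: posterior-predictive p unstable")
  kept <- nrow(fit$chains[[1]]$mu)
  total <- kept * length(fit$chains)
  if (total < n_rep)
    stop("retained draws (", total, ") fewer than n_rep", call. = FALSE)
  pick <- floor(seq(1, total, length.out = n_rep))
  chain_of <- (pick - 1L) %/% kept + 1L
  idx_of <- (pick - 1L) %% kept + 1L

  y <- fit$y
  n <- nrow(y)
  tree_cols <- fit$tree_cols
  totals <- lapply(tree_cols, function(cl) sum(y[1, cl]))
  subs <- Filter(function(k) k$type == "substitute", fit$constraints)

  local_seed(seed)
  t1_obs <- t1_rep <- t2_obs <- t2_rep <- numeric(n_rep)
  S_obs <- stats::cov(y)
  for (r in seq_len(n_rep)) {
    ch <- chain_of[r]; ix <- idx_of[r]
    mu <- fit$chains[[ch]]$mu[ix, ]
    delta <- fit$chains[[ch]]$delta[ix, , ]
    theta <- stats::pnorm(sweep(matrix(delta, n), 2, mu, "+"))
    colnames(theta) <- fit$person_params
    full <- theta
    for (k in subs) {
      v <- rep(1, n)
      for (f in k$factors) v <- v * full[, f]
      full <- cbind(full, v); colnames(full)[ncol(full)] <- k$target
    }
    probs <- category_prob_matrix(fit$model, full)
    # expected counts per participant and model-implied covariance
    E <- matrix(0, n, ncol(y), dimnames = list(NULL, colnames(y)))
    Vsum <- matrix(0, ncol(y), ncol(y))
    yrep <- matrix(0, n, ncol(y), dimnames = list(NULL, colnames(y)))
    for (tid in names(tree_cols)) {
      cl <- tree_cols[[tid]]
      Np <- totals[[tid]]
      P <- probs[[tid]]
      E[, cl] <- Np * P
      ci <- match(cl, colnames(y))
      for (i in seq_len(n)) {
        p <- P[i, ]
        Vsum[ci, ci] <- Vsum[ci, ci] + Np * (diag(p) - tcrossprod(p))
        yrep[i, cl] <- stats::rmultinom(1, Np, p)[, 1]
      }
    }
    Sigma_exp <- Vsum / n + stats::cov(E)
    Ebar <- colMeans(E)
    t1_obs[r] <- sum((colMeans(y) - Ebar)^2 / pmax(Ebar, 1e-12))
    t1_rep[r] <- sum((colMeans(yrep) - Ebar)^2 / pmax(Ebar, 1e-12))
    denom <- sqrt(pmax(outer(diag(Sigma_exp), diag(Sigma_exp)), 0)) + 1e-12
    ut <- upper.tri(Sigma_exp, diag = TRUE)
    t2_obs[r] <- sum(((S_obs - Sigma_exp)[ut] / denom[ut])^2)
    t2_rep[r] <- sum(((stats::cov(yrep) - Sigma_exp)[ut] / denom[ut])^2)
  }
  p1 <- mean(t1_rep >= t1_obs)
  p2 <- mean(t2_rep >= t2_obs)
  structure(list(p_t1 = p1, p_t2 = p2,
                 t1_obs = mean(t1_obs), t2_obs = mean(t2_obs),
                 n_rep = n_rep, satisfactory = p1 > 0.05 && p2 > 0.05),
            class = "mpt_ppc")
}

#' @export
print.mpt_ppc <- function(x, ...) {
  cat(sprintf("posterior-predictive checks (%d draws): p_T1 = %.3f, p_T2 = %.3f -> %s\n",
              x$n_rep, x$p_t1, x$p_t2,
              if (x$satisfactory) "satisfactory" else "misfit"))
  invisible(x)
}

#' Posterior difference of a group-level parameter between two fits
#'
#' Pairs retained draws of \eqn{\Phi(\mu_k)} by index (after truncation to
#' a common length; the fits are independent, so index pairing is a
#' reproducible choice) and summarizes \eqn{\Delta = \theta_A - \theta_B}:
#' the one-tailed Bayesian p-value is the posterior mass below zero, and
#' the two-tailed criterion is whether the central 95% credibility
#' interval of \eqn{\Delta} excludes zero.
#'
#' @param fit_a,fit_b `mpt_bayes_fit` objects for the two conditions.
#' @param parameter Parameter name (e.g. `"s"`).
#' @param level Credibility level of the interval.
#' @return List of class `mpt_group_diff`: `bayes_p`, `lower`, `upper`,
#'   `excludes_zero`, `mean_diff`, and the paired draws.
#' @export
group_difference <- function(fit_a, fit_b, parameter, level = 0.95) {
  stopifnot(inherits(fit_a, "mpt_bayes_fit"), inherits(fit_b, "mpt_bayes_fit"))
  for (f in list(fit_a, fit_b))
    if (!parameter %in% f$person_params)
      stop("parameter '", parameter, "' not monitored in both fits",
           call. = FALSE)
  da <- unlist(lapply(fit_a$chains, function(ch)
    stats::pnorm(ch$mu[, parameter])), use.names = FALSE)
  db <- unlist(lapply(fit_b$chains, function(ch)
    stats::pnorm(ch$mu[, parameter])), use.names = FALSE)
  L <- min(length(da), length(db))
  d <- da[seq_len(L)] - db[seq_len(L)]
  qs <- stats::quantile(d, c((1 - level) / 2, (1 + level) / 2))
  structure(list(parameter = parameter,
                 bayes_p = mean(d < 0) + 0.5 * mean(d == 0),
                 mean_diff = mean(d), lower = qs[[1]], upper = qs[[2]],
                 excludes_zero = qs[[1]] > 0 || qs[[2]] < 0,
                 draws = d),
            class = "mpt_group_diff")
}

#' @export
print.mpt_group_diff <- function(x, ...) {
  cat(sprintf("Delta %s = %.3f [%.3f, %.3f], Bayesian p (mass < 0) = %.3f\n",
              x$parameter, x$mean_diff, x$lower, x$upper, x$bayes_p))
  invisible(x)
}
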