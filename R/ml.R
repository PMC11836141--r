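#' Maximum-likelihood fit of an MPT model to aggregated counts
#'
#' Maximizes the product-multinomial log-likelihood
#' \eqn{\sum_{jk} n_{jk} \log p_{jk}(\theta)} over the free parameters of a
#' (possibly multi-group, constrained) MPT model. Optimization runs on the
#' logit scale with an analytic gradient; multiple seeded restarts guard
#' against local optima. The goodness-of-fit statistic is
#' \eqn{G^2 = 2 \sum n_{jk} \log(n_{jk} / (N_k \hat p_{jk}))} with
#' \eqn{0 \log 0 = 0}.
#'
#' @param model An `mpt_model`.
#' @param counts Category counts: either a single group (named list
#'   `tree -> named numeric vector of category counts`) or a named list of
#'   such groups.
#' @param constraints An `mpt_constraint_set`; defaults to the `d = s*r1`
#'   substitution of the built-in model. Pass `mpt_constraints(list())`
#'   for none.
#' @param restarts Number of optimizer starts (first start is `start` or
#'   0.5 everywhere; the rest are seeded uniform draws).
#' @param seed Optional integer seed for the restart draws.
#' @param start Optional named vector of starting values (probability
#'   scale) for the free parameters.
#' @return An object of class `mpt_ml_fit`: estimates (parameter x group
#'   matrix), free-parameter vector with standard errors, `loglik`,
#'   `g_squared`, `df`, `p_value` (`NA` for saturated models), covariance
#'   of the free parameters from the observed information, convergence and
#'   boundary flags.
#' @examples
#' m <- storage_retrieval_model()
#' cts <- expected_frequencies(m, c(s = .91, r1 = .98, g = .46, r2 = .73),
#'                             totals = c(target = 1020, distractor = 1020))
#' fit <- fit_ml(m, cts, restarts = 2, seed = 1)
#' round(fit$estimates, 2)
#' @export
fit_ml <- function(model, counts, constraints = default_constraints(),
                   restarts = 10L, seed = NULL, start = NULL) {
  counts <- as_group_counts(model, counts)
  groups <- names(counts)
  pz <- apply_constraints(model, constraints, groups)
  if (pz$n_free == 0L) stop("no free parameters to estimate", call. = FALSE)

  negll <- function(eta) {
    free <- stats::plogis(eta)
    -loglik_free(pz, counts, free)
  }
  grad_negll <- function(eta) {
    free <- stats::plogis(eta)
    -grad_free(pz, counts, free) * free * (1 - free)
  }

  local_seed(seed)
  starts <- if (is.null(start)) {
    # two deterministic candidates: a mildly clamped moment start and the
    # raw closed-form one (exact for saturated groups, including
    # near-boundary solutions)
    list(smart_start(pz, counts, clamp = 0.05),
         smart_start(pz, counts, clamp = 1e-4))
  } else {
    list(unname(start[pz$free_names]))
  }
  if (restarts > 1L)
    for (r in seq_len(restarts - 1L))
      starts[[length(starts) + 1L]] <- stats::runif(pz$n_free, 0.05, 0.95)

  best <- NULL
  n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    eta0 <- stats::qlogis(pmin(pmax(st, 1e-6), 1 - 1e-6))
    opt <- tryCatch(
      stats::optim(eta0, negll, grad_negll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
  }
  if (is.null(best))
    stop("ML optimization failed to converge in any restart", call. = FALSE)
  # polish pass from the incumbent optimum (guards nesting monotonicity)
  polish <- tryCatch(
    stats::optim(best$par, negll, grad_negll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  free <- stats::setNames(stats::plogis(best$par), pz$free_names)
  ll <- -best$value
  # boundary snap: a logit-scale optimizer approaches 0/1 only
  # asymptotically; when the true optimum sits on the boundary, snapping
  # the near-boundary coordinates recovers it exactly
  near <- free > 1 - 1e-4 | free < 1e-4
  if (any(near)) {
    snapped <- free
    snapped[free > 1 - 1e-4] <- 1 - 1e-12
    snapped[free < 1e-4] <- 1e-12
    ll_snap <- loglik_free(pz, counts, snapped)
    if (ll_snap >= ll) {
      free <- snapped
      ll <- ll_snap
    }
  }
  ll_sat <- saturated_loglik(counts)
  g2 <- max(0, 2 * (ll_sat - ll))
  df <- pz$df
  boundary <- any(free < 1e-6 | free > 1 - 1e-6)

  H <- observed_information(pz, counts, free)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(free)) else {
    d <- diag(vc); d[d < 0] <- NA_real_
    sqrt(d)
  }
  names(se) <- pz$free_names

  structure(list(
    model = model, parameterization = pz, counts = counts,
    estimates = expand_theta(pz, free), free = free, se = se, vcov = vc,
    loglik = ll, g_squared = g2, df = df,
    p_value = if (df > 0) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_,
    converged = best$convergence == 0, boundary = boundary,
    restarts_used = n_used
  ), class = "mpt_ml_fit")
}

#' @export
print.mpt_ml_fit <- function(x, ...) {
  cat("MPT maximum-likelihood fit\n")
  cat(sprintf("  log-likelihood %.4f, G2(%d) = %.4f%s\n", x$loglik, x$df,
              x$g_squared,
              if (is.na(x$p_value)) " (saturated: not testable)"
              else sprintf(", p = %.4f", x$p_value)))
  if (x$boundary) cat("  note: boundary solution (some estimates at 0/1)\n")
  print(round(x$estimates, 4))
  invisible(x)
}

# ---- internal likelihood machinery ------------------------------------

as_group_counts <- function(model, counts) {
  tn <- names(model$trees)
  if (all(names(counts) %in% tn)) counts <- list(group1 = counts)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("groups must be named", call. = FALSE)
  for (g in names(counts)) {
    missing <- setdiff(tn, names(counts[[g]]))
    if (length(missing))
      stop("group '", g, "' lacks counts for tree(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (tid in tn) {
      cats <- model$trees[[tid]]$categories
      v <- counts[[g]][[tid]]
      bad <- setdiff(cats, names(v))
      if (length(bad))
        stop("group '", g, "', tree '", tid, "': missing category column(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      v <- v[cats]
      if (any(v < 0) || any(!is.finite(v)))
        stop("counts must be finite and nonnegative", call. = FALSE)
      if (sum(v) <= 0)
        stop("group '", g, "', tree '", tid, "': all counts are zero",
             call. = FALSE)
      counts[[g]][[tid]] <- v
    }
    counts[[g]] <- counts[[g]][tn]
  }
  counts
}

# moment-based starting values: closed-form saturated estimates per group
# where the canonical storage-retrieval structure allows it, averaged over
# the member slots of each free class; 0.5 otherwise
smart_start <- function(pz, counts, clamp = 0.05) {
  st <- rep(0.5, pz$n_free)
  per_group <- lapply(counts, function(ct)
    tryCatch(invert_saturated(ct), error = function(e) NULL))
  for (k in seq_len(pz$n_free)) {
    members <- which(pz$free_index == k)
    vals <- numeric(0)
    for (i in members) {
      p <- pz$slots$parameter[i]
      g <- pz$slots$group[i]
      est <- per_group[[g]]
      if (!is.null(est) && p %in% names(est)) vals <- c(vals, est[[p]])
    }
    if (length(vals)) st[k] <- min(max(mean(vals), clamp), 1 - clamp)
  }
  st
}

loglik_free <- function(pz, counts, free) {
  th <- expand_theta(pz, free)
  ll <- 0
  for (g in pz$groups) {
    theta <- pmin(pmax(th[, g], 1e-12), 1 - 1e-12)
    for (tid in names(pz$model$trees)) {
      tr <- pz$model$trees[[tid]]
      br <- tree_branch_probs(tr, theta)
      p <- vapply(seq_along(tr$categories),
                  function(ci) sum(br[tr$cat_idx == ci]), 1)
      n <- counts[[g]][[tid]]
      pos <- n > 0
      ll <- ll + sum(n[pos] * log(pmax(p[pos], 1e-300)))
    }
  }
  ll
}

# gradient of the log-likelihood wrt the free parameters (probability scale)
grad_free <- function(pz, counts, free) {
  th <- expand_theta(pz, free)
  pars <- pz$model$parameters
  G <- length(pz$groups)
  dth <- matrix(0, length(pars), G, dimnames = dimnames(th))
  for (gi in seq_len(G)) {
    g <- pz$groups[gi]
    theta <- pmin(pmax(th[, g], 1e-10), 1 - 1e-10)
    for (tid in names(pz$model$trees)) {
      tr <- pz$model$trees[[tid]]
      br <- tree_branch_probs(tr, theta)
      p <- vapply(seq_along(tr$categories),
                  function(ci) sum(br[tr$cat_idx == ci]), 1)
      n <- counts[[g]][[tid]]
      w <- ifelse(n > 0, n / pmax(p, 1e-300), 0)
      wb <- w[tr$cat_idx] * br
      # d branch / d theta_p = branch * (A/theta - C/(1-theta))
      M <- sweep(tr$A, 2, theta[colnames(tr$A)], "/") -
        sweep(tr$C, 2, 1 - theta[colnames(tr$C)], "/")
      dth[colnames(tr$A), gi] <- dth[colnames(tr$A), gi] + drop(crossprod(M, wb))
    }
  }
  # back-propagate product substitutions (reverse declaration order);
  # d(prod_j f_j^m_j)/d f = m_f * f^(m_f - 1) * prod_{o != f} o^m_o
  for (k in rev(pz$subs)) {
    mult <- table(k$factors)
    for (f in names(mult)) {
      dpart <- as.numeric(mult[[f]]) * th[f, ]^(mult[[f]] - 1L)
      for (o in setdiff(names(mult), f)) dpart <- dpart * th[o, ]^mult[[o]]
      dth[f, ] <- dth[f, ] + dth[k$target, ] * dpart
    }
    dth[k$target, ] <- 0
  }
  gr <- numeric(pz$n_free)
  for (i in seq_len(nrow(pz$slots))) {
    k <- pz$free_index[i]
    if (!is.na(k))
      gr[k] <- gr[k] + dth[pz$slots$parameter[i], pz$slots$group[i]]
  }
  gr
}

observed_information <- function(pz, counts, free, h = 1e-5) {
  n <- length(free)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- max(min(h, free[j] / 2, (1 - free[j]) / 2), 1e-7)
    up <- free; up[j] <- min(up[j] + hj, 1 - 1e-9)
    dn <- free; dn[j] <- max(dn[j] - hj, 1e-9)
    H[, j] <- -(grad_free(pz, counts, up) - grad_free(pz, counts, dn)) /
      (up[j] - dn[j])
  }
  (H + t(H)) / 2
}

saturated_loglik <- function(counts) {
  ll <- 0
  for (g in names(counts)) for (tid in names(counts[[g]])) {
    n <- counts[[g]][[tid]]
    N <- sum(n)
    pos <- n > 0
    ll <- ll + sum(n[pos] * log(n[pos] / N))
  }
  ll
}

# ---- fit summaries -----------------------------------------------------

#' Goodness of fit of an ML fit
#'
#' @param fit An `mpt_ml_fit`.
#' @return List with `g_squared`, `df`, `p_value` (`NA` when `df = 0`:
#'   a saturated model is identifiable but not testable).
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "mpt_ml_fit"))
  list(g_squared = fit$g_squared, df = fit$df, p_value = fit$p_value)
}

#' Nested model comparison by likelihood ratio
#'
#' Compares a general fit with a restricted fit of the same data:
#' \eqn{\Delta G^2 = G^2_{restricted} - G^2_{general}} is referred to a
#' chi-square distribution with \eqn{\Delta df} degrees of freedom. When
#' \eqn{\Delta df = 1} the signed root \eqn{z = \sqrt{\Delta G^2}} supports
#' one-tailed tests: the caller names the hypothesized larger group, and a
#' mismatch between hypothesis and observed direction yields `p > 0.5`.
#'
#' @param general,restricted `mpt_ml_fit` objects on identical counts; the
#'   restricted model's constraints must nest the general model's.
#' @param tail `"two"` (default) or `"one"`.
#' @param direction For one-tailed tests: `list(parameter =, larger =,
#'   smaller =)` naming the parameter and the hypothesized larger/smaller
#'   groups.
#' @return List of class `mpt_comparison`: `delta_g_squared`, `delta_df`,
#'   `p_two`, `z` (when `delta_df = 1`), `p_one` and `observed_diff` (for
#'   one-tailed requests).
#' @export
compare_nested <- function(general, restricted, tail = c("two", "one"),
                           direction = NULL) {
  tail <- match.arg(tail)
  stopifnot(inherits(general, "mpt_ml_fit"), inherits(restricted, "mpt_ml_fit"))
  if (!identical(general$counts, restricted$counts))
    stop("fits are not on the same data", call. = FALSE)
  if (restricted$df < general$df)
    stop("'restricted' has fewer df than 'general': models not nested as given",
         call. = FALSE)
  dg2 <- restricted$g_squared - general$g_squared
  if (dg2 < -1e-6)
    stop("restricted fit beats general fit: optimization failure", call. = FALSE)
  dg2 <- max(0, dg2)
  ddf <- restricted$df - general$df
  p_two <- if (ddf == 0) 1 else stats::pchisq(dg2, ddf, lower.tail = FALSE)
  z <- if (ddf == 1L) sqrt(dg2) else NA_real_
  out <- list(delta_g_squared = dg2, delta_df = ddf, p_two = p_two, z = z,
              tail = tail)
  if (tail == "one") {
    if (is.null(direction) ||
        !all(c("parameter", "larger", "smaller") %in% names(direction)))
      stop("one-tailed comparison needs direction = list(parameter, larger, smaller)",
           call. = FALSE)
    est <- general$estimates
    obs <- est[direction$parameter, direction$larger] -
      est[direction$parameter, direction$smaller]
    out$observed_diff <- obs
    out$p_one <- if (obs >= 0) p_two / 2 else 1 - p_two / 2
  }
  structure(out, class = "mpt_comparison")
}

#' @export
print.mpt_comparison <- function(x, ...) {
  cat(sprintf("Delta G2(%d) = %.4f, two-tailed p = %.4f\n",
              x$delta_df, x$delta_g_squared, x$p_two))
  if (!is.na(x$z)) cat(sprintf("  z = %.4f\n", x$z))
  if (!is.null(x$p_one))
    cat(sprintf("  one-tailed p = %.4f (observed diff %.4f)\n",
                x$p_one, x$observed_diff))
  invisible(x)
}

#' Wald confidence intervals on the probability scale
#'
#' `estimate +/- z * SE` from the inverse observed information, clipped to
#' `[0, 1]`. Intervals are flagged (and returned as `NA`) when the
#' information matrix was singular, and the whole table carries a boundary
#' flag when any estimate sits within `1e-6` of 0 or 1.
#'
#' @param fit An `mpt_ml_fit`.
#' @param level Coverage level (default 0.95).
#' @return Data frame: parameter, estimate, se, lower, upper.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mpt_ml_fit"), level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  est <- fit$free
  se <- fit$se
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se),
                    lower = pmax(0, unname(est - z * se)),
                    upper = pmin(1, unname(est + z * se)),
                    row.names = NULL)
  attr(out, "level") <- level
  attr(out, "boundary") <- fit$boundary
  out
}

#' Closed-form estimates for the saturated storage-retrieval model
#'
#' Algebraic inversion of the built-in model with `d = s*r1` from a single
#' group's category counts. With `h` the recognition hit rate, `fa` the
#' false-alarm rate, `c` the recall rate and `q3 = P(Rn-Rc+)`:
#' `s*r1 = h - fa`, `g = fa / (1 - (h - fa))`, `r1 = 1 - q3 / (c (1 - g))`,
#' `s = (h - fa) / r1`, `r2 = c / s`. For interior data this is exactly the
#' ML solution of the saturated model.
#'
#' @param counts Single-group counts: named list with trees `target`
#'   (categories `Rn+Rc+`, `Rn+Rc-`, `Rn-Rc+`, `Rn-Rc-`) and `distractor`
#'   (`D+`, `D-`).
#' @return Named vector `c(s, r1, g, r2)`.
#' @export
invert_saturated <- function(counts) {
  tg <- counts$target
  ds <- counts$distractor
  if (is.null(tg) || is.null(ds))
    stop("counts must contain 'target' and 'distractor' trees", call. = FALSE)
  tg <- tg[c("Rn+Rc+", "Rn+Rc-", "Rn-Rc+", "Rn-Rc-")]
  ds <- ds[c("D+", "D-")]
  if (any(is.na(tg)) || any(is.na(ds)))
    stop("counts lack canonical category labels", call. = FALSE)
  pt <- tg / sum(tg)
  pd <- ds / sum(ds)
  h <- pt[["Rn+Rc+"]] + pt[["Rn+Rc-"]]
  fa <- pd[["D-"]]
  cc <- pt[["Rn+Rc+"]] + pt[["Rn-Rc+"]]
  q3 <- pt[["Rn-Rc+"]]
  if (h <= fa)
    stop("inversion error: hit rate does not exceed false-alarm rate",
         call. = FALSE)
  sr1 <- h - fa
  g <- fa / (1 - sr1)
  if (g >= 1 - 1e-12)
    stop("inversion error: guessing probability at 1", call. = FALSE)
  if (cc <= 0)
    stop("inversion error: zero recall rate", call. = FALSE)
  r1 <- 1 - q3 / (cc * (1 - g))
  if (r1 <= 0)
    stop("inversion error: nonpositive recognition retrieval", call. = FALSE)
  s <- sr1 / r1
  r2 <- cc / s
  out <- c(s = s, r1 = r1, g = g, r2 = r2)
  if (any(out < 0 | out > 1))
    stop("inversion error: estimates outside [0, 1]", call. = FALSE)
  out
}
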