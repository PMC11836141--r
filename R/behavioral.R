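#' Behavioral scores per participant and session
#'
#' Computes the two dependent variables of the design: cued-recall
#' retention (delayed correct recall divided by the immediate correct
#' recall of the cycle in which the learning criterion was reached; values
#' above 1 are possible) and recognition performance (hit rate minus
#' false-alarm rate). Participants below the learning criterion are marked
#' `excluded_at_source` and get `NA` scores.
#'
#' @param records Participant data frame (schema of
#'   [simulate_experiment()]).
#' @param targets,distractors Item totals of the delayed test.
#' @param criterion Learning-criterion threshold.
#' @return Data frame: id, condition, session, immediate_correct,
#'   delayed_correct, retention, hit_rate, fa_rate, recognition,
#'   excluded_at_source.
#' @export
score_participants <- function(records, targets = 20L, distractors = 20L,
                               criterion = 7L) {
  lab <- names(category_columns())
  need <- c("id", "condition", "session", "immediate_correct", lab)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  src_excl <- if ("excluded" %in% names(records)) records$excluded
              else records$immediate_correct < criterion
  imm <- records$immediate_correct
  if (any(!src_excl & imm <= 0, na.rm = TRUE))
    stop("structural error: zero immediate recall for a criterion-passing participant",
         call. = FALSE)
  delayed <- records$RnpRcp + records$RnmRcp
  hits <- (records$RnpRcp + records$RnpRcm) / targets
  fa <- records$Dm / distractors
  out <- data.frame(
    id = records$id, condition = records$condition, session = records$session,
    immediate_correct = imm, delayed_correct = delayed,
    retention = delayed / imm, hit_rate = hits, fa_rate = fa,
    recognition = hits - fa, excluded_at_source = src_excl,
    stringsAsFactors = FALSE)
  out$retention[src_excl] <- NA_real_
  out$recognition[src_excl] <- NA_real_
  out
}

#' MAD-based outlier rule
#'
#' @param multiplier Flagging threshold in MAD units (default 3).
#' @param scaled Apply the 1.4826 normal-consistency constant (default
#'   `TRUE`; set `FALSE` for the raw median absolute distance)?
#' @return List of class `outlier_rule`.
#' @export
outlier_rule <- function(multiplier = 3, scaled = TRUE) {
  stopifnot(multiplier > 0)
  structure(list(multiplier = multiplier, scaled = scaled),
            class = "outlier_rule")
}

#' Flag outliers by distance from the grand median
#'
#' Flags `x` whenever `|x - median(x)| > multiplier * MAD(x)`, the median
#' taken across all conditions (grand median). A zero MAD yields no flags
#' and a warning.
#'
#' @param values Numeric vector (NAs are never flagged).
#' @param rule An [outlier_rule()].
#' @return Logical vector of flags.
#' @export
mad_outliers <- function(values, rule = outlier_rule()) {
  stopifnot(inherits(rule, "outlier_rule"))
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 values", call. = FALSE)
  med <- stats::median(values[ok])
  madv <- stats::mad(values[ok], constant = if (rule$scaled) 1.4826 else 1)
  if (madv == 0) {
    warning("MAD is zero: no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  flags <- abs(values - med) > rule$multiplier * madv
  flags[!ok] <- FALSE
  flags
}

#' Session-wise exclusion on retention and recognition scores
#'
#' Applies [mad_outliers()] separately per session to the retention and
#' recognition scores (grand median pooled over conditions); a participant
#' is excluded from a session if flagged on either score there.
#'
#' @param scores Output of [score_participants()].
#' @param rule An [outlier_rule()].
#' @return `scores` with added logical columns `flag_retention`,
#'   `flag_recognition`, `excluded_outlier`.
#' @export
exclude_outliers <- function(scores, rule = outlier_rule()) {
  scores$flag_retention <- FALSE
  scores$flag_recognition <- FALSE
  for (ses in unique(scores$session)) {
    i <- which(scores$session == ses & !scores$excluded_at_source)
    scores$flag_retention[i] <- mad_outliers(scores$retention[i], rule)
    scores$flag_recognition[i] <- mad_outliers(scores$recognition[i], rule)
  }
  scores$excluded_outlier <- scores$flag_retention | scores$flag_recognition
  scores
}

#' One-way between-participants ANOVA
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels.
#' @return List of class `anova_result`: `f`, `df1`, `df2`, `p`,
#'   `eta_squared`, `mse`, group means and sizes.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  n <- tabulate(groups)
  if (k < 2L || any(n < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_between <- sum(n * (gm - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- k - 1L
  df2 <- length(values) - k
  if (ss_within <= 0)
    stop("degenerate data: zero residual variance", call. = FALSE)
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  structure(list(f = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE),
                 eta_squared = ss_between / ss_total, mse = mse,
                 means = gm, n = n, levels = levels(groups)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4f, eta^2 = %.3f\n",
              x$df1, x$df2, x$f, x$p, x$eta_squared))
  invisible(x)
}

#' Planned contrast with pooled ANOVA error
#'
#' t-test of a weighted combination of group means using the pooled
#' mean-square error from the full k-group ANOVA (`df = N - k`). Cohen's d
#' is the difference of the two contrasted means divided by the root
#' pooled MSE. One-tailed p-values honor the stated direction: when the
#' observed contrast runs against the hypothesis, `p > 0.5`.
#'
#' @param values,groups As in [oneway_anova()].
#' @param weights Named (or level-ordered) contrast weights summing to 0.
#' @param tail `"two"` or `"one"`.
#' @return List of class `contrast_result`: estimate, t, df, p, cohens_d.
#' @export
planned_contrast <- function(values, groups, weights, tail = c("two", "one")) {
  tail <- match.arg(tail)
  an <- oneway_anova(values, groups)
  if (!is.null(names(weights))) {
    w <- stats::setNames(rep(0, length(an$levels)), an$levels)
    bad <- setdiff(names(weights), an$levels)
    if (length(bad)) stop("unknown group(s) in weights: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    w[names(weights)] <- weights
  } else {
    stopifnot(length(weights) == length(an$levels))
    w <- stats::setNames(weights, an$levels)
  }
  if (abs(sum(w)) > 1e-12)
    stop("contrast weights must sum to 0", call. = FALSE)
  est <- sum(w * an$means)
  se <- sqrt(an$mse * sum(w^2 / an$n))
  t <- est / se
  p_two <- 2 * stats::pt(abs(t), an$df2, lower.tail = FALSE)
  p <- if (tail == "two") p_two
       else stats::pt(t, an$df2, lower.tail = FALSE)  # H1: contrast > 0
  d <- est / sqrt(an$mse)
  structure(list(estimate = est, se = se, t = t, df = an$df2, p = p,
                 tail = tail, cohens_d = d, weights = w),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast = %.4f, t(%d) = %.3f, %s-tailed p = %.4f, d = %.3f\n",
              x$estimate, x$df, x$t, x$tail, x$p, x$cohens_d))
  invisible(x)
}

#' Power of the one-way ANOVA F test
#'
#' Noncentral-F power at total sample size `N`: noncentrality
#' \eqn{\lambda = f^2 N}, numerator df `k - 1`, denominator df `N - k`.
#'
#' @param N Total sample size.
#' @param k Number of groups.
#' @param f Cohen's f effect size.
#' @param alpha Significance level.
#' @return Power (numeric in `[0, 1]`, vectorized over `N`).
#' @export
anova_power <- function(N, k = 3L, f = 0.25, alpha = 0.05) {
  stopifnot(k >= 2, f > 0, alpha > 0, alpha < 1)
  crit <- stats::qf(1 - alpha, k - 1, N - k)
  1 - stats::pf(crit, k - 1, N - k, ncp = f^2 * N)
}

#' A-priori sample size for a one-way ANOVA
#'
#' Smallest total `N`, divisible by `k`, whose noncentral-F power reaches
#' the target.
#'
#' @param k Number of groups.
#' @param f Cohen's f.
#' @param alpha Significance level.
#' @param power Target power.
#' @return List: `N` (total), `n` (per group), `power` achieved.
#' @examples
#' required_sample_size(k = 3, f = 0.25)  # N = 159, n = 53
#' @export
required_sample_size <- function(k = 3L, f = 0.25, alpha = 0.05, power = 0.80) {
  stopifnot(k >= 2)
  if (f <= 0) stop("effect size f must be positive", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  N <- k * 2L
  repeat {
    pw <- anova_power(N, k, f, alpha)
    if (pw >= power) break
    N <- N + k
    if (N > 1e7) stop("required sample size exceeds 1e7", call. = FALSE)
  }
  list(N = N, n = N %/% k, power = pw)
}

#' Oversampled recruitment size
#'
#' Inflates the per-group n by a fraction (rounded up per group) to absorb
#' anticipated exclusions.
#'
#' @param n Per-group sample size.
#' @param fraction Oversampling fraction (e.g. 0.10).
#' @param k Number of groups.
#' @return List: `n` (inflated per group), `N` (total).
#' @examples
#' oversampled_n(53, 0.10, 3)  # n = 59, N = 177
#' @export
oversampled_n <- function(n, fraction = 0.10, k = 3L) {
  stopifnot(fraction >= 0, n > 0, k >= 1)
  n2 <- as.integer(ceiling(round(n * (1 + fraction), 9)))
  list(n = n2, N = n2 * as.integer(k))
}
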