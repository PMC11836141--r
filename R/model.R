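#' Constraint constructors for MPT parameterizations
#'
#' Constraints narrow an MPT model before fitting. Three kinds are
#' supported and are resolved in this order: product substitutions
#' (e.g. `d := s * r1`), fixations (a parameter pinned to a constant,
#' optionally in one group only), and equalities (the same parameter
#' shared across groups).
#'
#' @param target,factors For [con_substitute()]: the substituted parameter
#'   and the parameters whose product defines it.
#' @param parameter Parameter name.
#' @param value Fixed value in `[0, 1]`.
#' @param groups Character vector of group labels, or `"all"`.
#' @return A constraint object (list with class `mpt_constraint`).
#' @examples
#' default_constraints()  # d = s * r1
#' mpt_constraints(con_substitute("d", c("s", "r1")),
#'                 con_equal("r1", c("rest", "social")))
#' @export
con_substitute <- function(target, factors) {
  structure(list(type = "substitute", target = target, factors = factors),
            class = "mpt_constraint")
}

#' @rdname con_substitute
#' @export
con_fix <- function(parameter, value, groups = "all") {
  stopifnot(is.numeric(value), value >= 0, value <= 1)
  structure(list(type = "fix", parameter = parameter, value = value,
                 groups = groups), class = "mpt_constraint")
}

#' @rdname con_substitute
#' @export
con_equal <- function(parameter, groups = "all") {
  structure(list(type = "equal", parameter = parameter, groups = groups),
            class = "mpt_constraint")
}

#' @rdname con_substitute
#' @param ... Constraint objects.
#' @export
mpt_constraints <- function(...) {
  cons <- list(...)
  if (length(cons) == 1L && is.list(cons[[1]]) && !inherits(cons[[1]], "mpt_constraint"))
    cons <- cons[[1]]
  for (k in cons) stopifnot(inherits(k, "mpt_constraint"))
  structure(cons, class = "mpt_constraint_set")
}

#' @rdname con_substitute
#' @export
default_constraints <- function() {
  mpt_constraints(con_substitute("d", c("s", "r1")))
}

#' Resolve constraints into a fitting parameterization
#'
#' Builds the mapping from a free parameter vector to the full parameter
#' matrix (parameters x groups), together with the degrees-of-freedom
#' account: `df = free category count - free parameter count`, where the
#' free category count is `sum over trees (categories - 1)` per group.
#'
#' Substitutions are applied first (the target parameter drops out of the
#' free set), then fixations, then equalities; contradictory fixations and
#' substitution cycles are rejected.
#'
#' @param model An `mpt_model`.
#' @param constraints An `mpt_constraint_set` (or `NULL` for none).
#' @param groups Character vector of group labels.
#' @return An object of class `mpt_parameterization` with elements
#'   `free_names`, `n_free`, `df`, and internal mapping tables. Applying it
#'   twice is a no-op: the object is itself the resolved spec.
#' @export
apply_constraints <- function(model, constraints = NULL, groups = "group1") {
  stopifnot(inherits(model, "mpt_model"), length(groups) >= 1L)
  if (is.null(constraints)) constraints <- mpt_constraints(list())
  if (inherits(constraints, "mpt_constraint")) constraints <- mpt_constraints(constraints)
  pars <- model$parameters
  G <- length(groups)

  subs <- Filter(function(k) k$type == "substitute", constraints)
  fixes <- Filter(function(k) k$type == "fix", constraints)
  equals <- Filter(function(k) k$type == "equal", constraints)

  for (k in c(subs, fixes, equals)) {
    ref <- if (k$type == "substitute") c(k$target, k$factors) else k$parameter
    bad <- setdiff(ref, pars)
    if (length(bad))
      stop("constraint references undeclared parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    grp <- k$groups
    if (k$type != "substitute" && !identical(grp, "all")) {
      badg <- setdiff(grp, groups)
      if (length(badg))
        stop("constraint references unknown group(s): ",
             paste(badg, collapse = ", "), call. = FALSE)
    }
  }

  # order substitutions so that factors are never later substitution targets
  # (cycle detection by repeated sweeps)
  sub_targets <- vapply(subs, `[[`, "", "target")
  if (anyDuplicated(sub_targets))
    stop("a parameter is the target of two substitutions", call. = FALSE)
  ordered <- list(); remaining <- subs; resolved <- character(0)
  while (length(remaining)) {
    ready <- vapply(remaining, function(k)
      !any(k$factors %in% setdiff(sub_targets, resolved)), TRUE)
    if (!any(ready)) stop("substitution constraints form a cycle", call. = FALSE)
    ordered <- c(ordered, remaining[ready])
    resolved <- c(resolved, vapply(remaining[ready], `[[`, "", "target"))
    remaining <- remaining[!ready]
  }
  subs <- ordered

  base <- setdiff(pars, sub_targets)
  # slot table: one row per (base parameter, group)
  slots <- expand.grid(parameter = base, group = groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ns <- nrow(slots)
  class_id <- seq_len(ns)
  find <- function(i) { while (class_id[i] != i) i <- class_id[i]; i }

  for (k in equals) {
    grp <- if (identical(k$groups, "all")) groups else k$groups
    idx <- which(slots$parameter == k$parameter & slots$group %in% grp)
    if (k$parameter %in% sub_targets)
      stop("cannot put an equality on substituted parameter '", k$parameter,
           "'", call. = FALSE)
    if (length(idx) >= 2L)
      for (i in idx[-1]) class_id[find(i)] <- find(idx[1])
  }
  root <- vapply(seq_len(ns), find, 1L)

  fixed_value <- rep(NA_real_, ns)
  for (k in fixes) {
    grp <- if (identical(k$groups, "all")) groups else k$groups
    idx <- which(slots$parameter == k$parameter & slots$group %in% grp)
    for (i in idx) {
      r <- root[i]
      members <- which(root == r)
      prev <- fixed_value[members]
      if (any(!is.na(prev) & abs(prev - k$value) > 1e-12))
        stop("contradictory constraints: parameter '", k$parameter,
             "' fixed to two different values", call. = FALSE)
      fixed_value[members] <- k$value
    }
  }

  free_roots <- sort(unique(root[is.na(fixed_value)]))
  free_names <- vapply(free_roots, function(r) {
    members <- which(root == r)
    p <- unique(slots$parameter[members])
    g <- slots$group[members]
    if (length(g) == length(groups) && G > 1L) sprintf("%s[all]", p)
    else if (G == 1L) p
    else sprintf("%s[%s]", p, paste(g, collapse = "="))
  }, "")
  free_index <- match(root, free_roots)  # NA for fixed slots

  ncat_free <- sum(vapply(model$trees, function(t) length(t$categories) - 1L, 1L))
  df <- G * ncat_free - length(free_roots)

  structure(list(
    model = model, groups = groups, base = base, subs = subs,
    slots = slots, free_index = free_index, fixed_value = fixed_value,
    free_names = free_names, n_free = length(free_roots),
    n_free_categories = G * ncat_free, df = df,
    constraints = constraints
  ), class = "mpt_parameterization")
}

#' @export
print.mpt_parameterization <- function(x, ...) {
  cat(sprintf("MPT parameterization: %d group(s), %d free parameter(s), df = %d\n",
              length(x$groups), x$n_free, x$df))
  cat("  free:", paste(x$free_names, collapse = ", "), "\n")
  invisible(x)
}

#' Degrees-of-freedom account of a parameterization
#'
#' @param pz An `mpt_parameterization`.
#' @return List with `free_categories`, `free_parameters`, `df`.
#' @export
df_account <- function(pz) {
  stopifnot(inherits(pz, "mpt_parameterization"))
  list(free_categories = pz$n_free_categories,
       free_parameters = pz$n_free, df = pz$df)
}

# free vector (probability scale) -> full parameter matrix (params x groups)
expand_theta <- function(pz, free) {
  pars <- pz$model$parameters
  G <- length(pz$groups)
  th <- matrix(NA_real_, length(pars), G, dimnames = list(pars, pz$groups))
  vals <- ifelse(is.na(pz$free_index), pz$fixed_value, free[pz$free_index])
  for (i in seq_len(nrow(pz$slots)))
    th[pz$slots$parameter[i], pz$slots$group[i]] <- vals[i]
  for (k in pz$subs) {
    v <- rep(1, G)
    for (f in k$factors) v <- v * th[f, ]
    th[k$target, ] <- v
  }
  th
}

#' Category probabilities of an MPT model
#'
#' Computes per-tree category probabilities for a full parameter vector.
#' If the vector omits substituted parameters (e.g. `d`), supply
#' `constraints` so they can be derived.
#'
#' @param model An `mpt_model`.
#' @param theta Named numeric vector of parameter values in `[0, 1]`.
#' @param constraints Optional `mpt_constraint_set` whose substitutions are
#'   applied to complete `theta`.
#' @return Named list: per tree a named numeric vector of category
#'   probabilities (each summing to 1).
#' @examples
#' m <- storage_retrieval_model()
#' category_probabilities(m, c(s = .91, r1 = .98, g = .46, r2 = .73),
#'                        constraints = default_constraints())
#' @export
category_probabilities <- function(model, theta, constraints = NULL) {
  stopifnot(inherits(model, "mpt_model"))
  if (!is.null(constraints)) {
    if (inherits(constraints, "mpt_constraint")) constraints <- mpt_constraints(constraints)
    for (k in Filter(function(z) z$type == "substitute", constraints)) {
      if (!k$target %in% names(theta))
        theta[k$target] <- prod(theta[k$factors])
    }
  }
  missing <- setdiff(model$parameters, names(theta))
  if (length(missing))
    stop("missing parameter value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(theta < 0 | theta > 1))
    stop("parameter values must lie in [0, 1]", call. = FALSE)
  out <- list()
  for (tid in names(model$trees)) {
    tr <- model$trees[[tid]]
    br <- tree_branch_probs(tr, theta)
    p <- vapply(seq_along(tr$categories),
                function(ci) sum(br[tr$cat_idx == ci]), 1)
    out[[tid]] <- stats::setNames(p, tr$categories)
  }
  out
}

# category probabilities for a matrix of parameter vectors (rows = units);
# returns list per tree of (nrow x ncat) matrices. Used by the samplers.
category_prob_matrix <- function(model, theta_mat) {
  out <- list()
  for (tid in names(model$trees)) {
    tr <- model$trees[[tid]]
    nb <- nrow(tr$A)
    n <- nrow(theta_mat)
    P <- matrix(0, n, length(tr$categories), dimnames = list(NULL, tr$categories))
    for (j in seq_len(nb)) {
      pr <- rep(1, n)
      for (p in colnames(tr$A)) {
        if (tr$A[j, p] > 0) pr <- pr * theta_mat[, p]^tr$A[j, p]
        if (tr$C[j, p] > 0) pr <- pr * (1 - theta_mat[, p])^tr$C[j, p]
      }
      P[, tr$cat_idx[j]] <- P[, tr$cat_idx[j]] + pr
    }
    out[[tid]] <- P
  }
  out
}

#' Local identifiability report
#'
#' Evaluates the Jacobian of the free category probabilities (one category
#' dropped per tree and group) with respect to the free parameters at
#' random interior points, and reports the attained ranks. The model is
#' judged locally identifiable when the rank equals the free-parameter
#' count at every probe.
#'
#' @param model An `mpt_model`.
#' @param constraints Optional constraint set.
#' @param groups Group labels.
#' @param n_probe Number of random interior probe points.
#' @param seed Optional integer seed.
#' @return List with `ranks`, `n_free`, `identifiable`.
#' @export
check_identifiability <- function(model, constraints = default_constraints(),
                                  groups = "group1", n_probe = 5L, seed = NULL) {
  pz <- apply_constraints(model, constraints, groups)
  stopifnot(n_probe >= 1L)
  local_seed(seed)
  ranks <- integer(n_probe)
  for (b in seq_len(n_probe)) {
    free <- stats::runif(pz$n_free, 0.15, 0.85)
    J <- jacobian_free_probs(pz, free)
    ranks[b] <- qr(J)$rank
  }
  list(ranks = ranks, n_free = pz$n_free,
       identifiable = all(ranks == pz$n_free))
}

# numerical Jacobian of stacked free category probabilities wrt free params
jacobian_free_probs <- function(pz, free, h = 1e-6) {
  f <- function(fr) {
    th <- expand_theta(pz, fr)
    unlist(lapply(pz$groups, function(g) {
      pr <- category_probabilities(pz$model,
                                   stats::setNames(th[, g], rownames(th)))
      unlist(lapply(pr, function(p) p[-length(p)]))
    }), use.names = FALSE)
  }
  f0 <- f(free)
  J <- matrix(0, length(f0), length(free))
  for (j in seq_along(free)) {
    e <- free; e[j] <- e[j] + h
    d <- free; d[j] <- d[j] - h
    J[, j] <- (f(e) - f(d)) / (2 * h)
  }
  J
}
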