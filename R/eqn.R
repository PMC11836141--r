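#' Parse an EQN model description
#'
#' Reads a binary multinomial processing tree (MPT) model from the EQN
#' interchange format: one branch per line, given as whitespace-separated
#' `tree category expression`, where the expression is a `*`-product of
#' parameter names and complements written as `(1-name)`. Lines starting
#' with `#` are comments; an optional first non-comment line holding a
#' single integer (the branch count, MultiTree convention) is accepted and
#' ignored.
#'
#' On load the model is checked for structural completeness: at a fixed
#' grid of interior parameter vectors the branch probabilities of every
#' tree must sum to 1 within `1e-10`.
#'
#' @param text Character scalar (whole file) or character vector of lines.
#' @return An object of class `mpt_model` with elements `parameters`
#'   (character vector) and `trees` (named list; each tree has
#'   `categories` and branch matrices used internally).
#' @seealso [read_eqn()], [write_eqn()], [storage_retrieval_model()]
#' @examples
#' m <- parse_eqn(c("1 A p", "1 B (1-p)"))
#' category_probabilities(m, c(p = 0.3))
#' @export
parse_eqn <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  raw <- text
  stripped <- sub("#.*$", "", raw)
  keep <- which(trimws(stripped) != "")
  lines <- trimws(stripped[keep])
  if (length(lines) == 0L) stop("EQN input contains no branch lines", call. = FALSE)
  # optional branch-count header: a single integer token on the first line
  if (grepl("^[0-9]+$", lines[[1]])) {
    keep <- keep[-1]
    lines <- lines[-1]
  }
  branches <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "[ \t]+")[[1]]
    if (length(tok) < 3L) {
      stop(sprintf("EQN parse error at line %d: expected 'tree category expression'",
                   keep[i]), call. = FALSE)
    }
    expr <- paste(tok[-(1:2)], collapse = "")
    terms <- strsplit(expr, "*", fixed = TRUE)[[1]]
    a <- character(0)  # plain parameter factors
    b <- character(0)  # complement factors
    for (tm in terms) {
      if (grepl("^\\(1-[A-Za-z][A-Za-z0-9_.]*\\)$", tm)) {
        b <- c(b, sub("^\\(1-", "", sub("\\)$", "", tm)))
      } else if (grepl("^[A-Za-z][A-Za-z0-9_.]*$", tm)) {
        a <- c(a, tm)
      } else {
        stop(sprintf("EQN parse error at line %d: cannot parse term '%s'",
                     keep[i], tm), call. = FALSE)
      }
    }
    branches[[i]] <- list(tree = tok[1], category = tok[2], a = a, b = b)
  }
  parameters <- unique(unlist(lapply(branches, function(x) c(x$a, x$b))))
  tree_ids <- unique(vapply(branches, `[[`, "", "tree"))
  trees <- list()
  for (tid in tree_ids) {
    br <- branches[vapply(branches, function(x) x$tree == tid, TRUE)]
    cats <- unique(vapply(br, `[[`, "", "category"))
    nb <- length(br)
    A <- matrix(0L, nb, length(parameters), dimnames = list(NULL, parameters))
    C <- A
    cat_idx <- integer(nb)
    for (j in seq_len(nb)) {
      for (p in br[[j]]$a) A[j, p] <- A[j, p] + 1L
      for (p in br[[j]]$b) C[j, p] <- C[j, p] + 1L
      cat_idx[j] <- match(br[[j]]$category, cats)
    }
    trees[[tid]] <- list(categories = cats, A = A, C = C, cat_idx = cat_idx)
  }
  model <- structure(list(parameters = parameters, trees = trees),
                     class = "mpt_model")
  validate_completeness(model)
  model
}

#' @rdname parse_eqn
#' @param path Path to an EQN file (UTF-8).
#' @export
read_eqn <- function(path) parse_eqn(readLines(path, encoding = "UTF-8"))

#' Write a model back to EQN format
#'
#' @param model An `mpt_model`.
#' @param path Output file path; if `NULL` the lines are returned invisibly.
#' @param header Emit the leading branch-count line?
#' @return The character vector of lines, invisibly.
#' @export
write_eqn <- function(model, path = NULL, header = TRUE) {
  stopifnot(inherits(model, "mpt_model"))
  out <- character(0)
  for (tid in names(model$trees)) {
    tr <- model$trees[[tid]]
    for (j in seq_len(nrow(tr$A))) {
      terms <- character(0)
      for (p in model$parameters) {
        terms <- c(terms, rep(p, tr$A[j, p]), rep(sprintf("(1-%s)", p), tr$C[j, p]))
      }
      out <- c(out, paste(tid, tr$categories[tr$cat_idx[j]],
                          paste(terms, collapse = "*")))
    }
  }
  if (header) out <- c(as.character(length(out)), out)
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

# deterministic interior probe points (no global RNG use)
probe_vectors <- function(np, n = 20L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  sapply(seq_len(np), function(j) {
    x <- (seq_len(n) * sqrt(primes[(j - 1L) %% length(primes) + 1L])) %% 1
    0.05 + 0.9 * x
  })
}

validate_completeness <- function(model, tol = 1e-10) {
  pts <- probe_vectors(length(model$parameters))
  for (i in seq_len(nrow(pts))) {
    theta <- stats::setNames(pts[i, ], model$parameters)
    for (tid in names(model$trees)) {
      pr <- tree_branch_probs(model$trees[[tid]], theta)
      if (abs(sum(pr) - 1) > tol) {
        stop(sprintf(
          "structural error: branches of tree '%s' sum to %.12f (not 1) at a probe point",
          tid, sum(pr)), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

tree_branch_probs <- function(tree, theta) {
  th <- theta[colnames(tree$A)]
  pr <- rep(1, nrow(tree$A))
  for (j in seq_along(th)) {
    aj <- tree$A[, j]; cj <- tree$C[, j]
    if (any(aj > 0)) pr <- pr * th[[j]]^aj
    if (any(cj > 0)) pr <- pr * (1 - th[[j]])^cj
  }
  pr
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("MPT model:", length(x$parameters), "parameters (",
      paste(x$parameters, collapse = ", "), ")\n")
  for (tid in names(x$trees)) {
    tr <- x$trees[[tid]]
    cat(sprintf("  tree '%s': %d branches -> %d categories (%s)\n", tid,
                nrow(tr$A), length(tr$categories),
                paste(tr$categories, collapse = ", ")))
  }
  invisible(x)
}

#' The built-in storage-retrieval MPT model
#'
#' Returns the recognition-plus-cued-recall storage-retrieval model for
#' paired-associate memory. A target word is stored with probability `s`;
#' a stored target is retrieved during recognition with probability `r1`
#' and during cued recall with probability `r2`; when recognition retrieval
#' is unavailable the participant guesses "old" with probability `g`.
#' A distractor is detected with probability `d`; an undetected distractor
#' draws the same "old" guessing process. Target responses fall into the
#' four categories `Rn+Rc+`, `Rn+Rc-`, `Rn-Rc+`, `Rn-Rc-`; distractor
#' responses into `D+` (correct rejection) and `D-` (false alarm).
#'
#' The model is identifiable once `d` is tied to `s * r1` (see
#' [con_substitute()] and [default_constraints()]), giving four free
#' parameters against four non-redundant category frequencies.
#'
#' @return An `mpt_model` with trees `target` and `distractor`.
#' @export
storage_retrieval_model <- function() {
  read_eqn(system.file("extdata", "storage_retrieval.eqn", package = "srmpt",
                       mustWork = TRUE))
}

#' Canonical category labels and CSV column names
#'
#' Mapping between the canonical category labels of the built-in model and
#' the column names used in participant tables.
#' @return Named character vector: names are CSV columns, values category labels.
#' @export
category_columns <- function() {
  c(RnpRcp = "Rn+Rc+", RnpRcm = "Rn+Rc-", RnmRcp = "Rn-Rc+",
    RnmRcm = "Rn-Rc-", Dp = "D+", Dm = "D-")
}
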