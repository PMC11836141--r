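# Seed the RNG for the calling frame and restore the previous state when
# that frame exits. A NULL seed leaves the RNG untouched.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  a <- 1103515245; c <- 12345; m <- 2^31
  s <- as.numeric(seed) %% m
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (a * s + c) %% m
    out[i] <- s
  }
  as.list(as.integer(out %% (2^31 - 1)))
}

# round real-valued frequencies to integers preserving the total
# (largest-remainder method)
largest_remainder_round <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- x - fl
  k <- total - sum(fl)
  if (k > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(k)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
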