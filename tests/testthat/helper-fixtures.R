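# shared fixtures: built once per test run
sr_model <- storage_retrieval_model()
sr_cons <- default_constraints()

# spec formulas of the storage-retrieval trees, written independently of
# the package's branch enumeration; the oracle for category probabilities
sr_probs_oracle <- function(s, r1, g, r2) {
  d <- s * r1
  target <- c(
    "Rn+Rc+" = s * r1 * r2 + s * (1 - r1) * g * r2,
    "Rn+Rc-" = s * r1 * (1 - r2) + s * (1 - r1) * g * (1 - r2) + (1 - s) * g,
    "Rn-Rc+" = s * (1 - r1) * (1 - g) * r2,
    "Rn-Rc-" = s * (1 - r1) * (1 - g) * (1 - r2) + (1 - s) * (1 - g))
  distractor <- c("D+" = d + (1 - d) * (1 - g), "D-" = (1 - d) * g)
  list(target = target, distractor = distractor)
}

# multinomial draws at a parameter vector, as fit_ml-ready counts
draw_counts <- function(theta, n_target = 1020, n_distractor = 1020) {
  pr <- category_probabilities(sr_model, theta, sr_cons)
  list(target = stats::setNames(
         stats::rmultinom(1, n_target, pr$target)[, 1], names(pr$target)),
       distractor = stats::setNames(
         stats::rmultinom(1, n_distractor, pr$distractor)[, 1],
         names(pr$distractor)))
}

random_interior_theta <- function() {
  c(s = stats::runif(1, .55, .95), r1 = stats::runif(1, .7, .97),
    g = stats::runif(1, .15, .6), r2 = stats::runif(1, .4, .9))
}
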