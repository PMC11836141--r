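#' Published aggregated parameter estimates for the three-condition design
#'
#' Group-level ML estimates of the storage-retrieval model (parameters
#' `s`, `r1`, `g`, `r2`), per experiment and condition, together with the
#' analysed per-group sample size and the observed mean false-alarm rate.
#' These serve as anchor points for validation round trips (expected
#' frequencies generated at the estimates must refit to the same values)
#' and as realistic defaults for the simulator.
#'
#' @param experiment 1 (recognition-then-recall) or 2
#'   (recall-then-recognition).
#' @return Data frame: experiment, session, condition, n, s, r1, g, r2,
#'   fa_observed.
#' @export
reference_estimates <- function(experiment = NULL) {
  df <- utils::read.csv(system.file("extdata", "reference_estimates.csv",
                                    package = "srmpt", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  if (!is.null(experiment)) df <- df[df$experiment %in% experiment, ]
  df
}
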