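#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: where the data come from
#' (a participant CSV or on-the-fly simulation), the experiment design and
#' generating parameters, the outlier rule, the model and its baseline
#' constraint set, the hypothesis list, optional MCMC settings, seeds and
#' the output directory.
#'
#' @param input Path to a participant CSV (schema of
#'   [simulate_experiment()]) or `NULL` to simulate.
#' @param design,true Simulation settings (used when `input` is `NULL`).
#' @param outlier An [outlier_rule()].
#' @param model An `mpt_model`.
#' @param baseline_equalities List of `con_equal()` constraints defining
#'   the baseline (testable) model on top of the `d = s*r1` substitution.
#'   Default: recognition retrieval equal between waking rest and social
#'   media, the df = 1 baseline of the design.
#' @param hypotheses List of `list(parameter =, larger =, smaller =,
#'   tail = "one"|"two")` entries, each tested by adding an equality
#'   between the two named conditions to the saturated model.
#' @param bayes `NULL` (skip the hierarchical stage) or a
#'   [latent_trait_config()].
#' @param session Session to analyse.
#' @param alpha Significance level used throughout.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param out_dir Output directory for stage artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, design = experiment_design(),
                            true = true_parameters(),
                            outlier = outlier_rule(),
                            model = storage_retrieval_model(),
                            baseline_equalities = list(
                              con_equal("r1", c("rest", "social"))),
                            hypotheses = list(
                              list(parameter = "s", larger = "rest",
                                   smaller = "social", tail = "one"),
                              list(parameter = "s", larger = "rest",
                                   smaller = "vocab", tail = "one"),
                              list(parameter = "s", larger = "social",
                                   smaller = "vocab", tail = "two")),
                            bayes = NULL, session = 1L, alpha = 0.05,
                            seed = 1L, out_dir = tempfile("srmpt_run_")) {
  for (h in hypotheses)
    stopifnot(all(c("parameter", "larger", "smaller") %in% names(h)))
  structure(list(input = input, design = design, true = true,
                 outlier = outlier, model = model,
                 baseline_equalities = baseline_equalities,
                 hypotheses = hypotheses, bayes = bayes,
                 session = as.integer(session), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir,
                 schema_version = "1.0"),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain data (read or simulate), behavioral scoring
#' and MAD-based exclusion, ANOVA with planned contrasts, aggregated ML
#' MPT fitting with nested comparisons, and (optionally) hierarchical
#' Bayesian fits with posterior-predictive checks and group differences.
#' Every stage persists a CSV/JSON artifact under `config$out_dir`; the
#' consolidated report repeats the stage values verbatim (no
#' recomputation). Identical configs and seeds give byte-identical
#' reports.
#'
#' @param config A [pipeline_config()].
#' @return The consolidated report (list of class `analysis_report`),
#'   invisibly also written to `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  wjson <- function(x, file) jsonlite::write_json(
    x, file.path(config$out_dir, file), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")

  # --- stage 1: data ----------------------------------------------------
  if (is.null(config$input)) {
    records <- simulate_experiment(config$design, config$true,
                                   seed = seeds[[1]])
    truth <- list(means = config$true$means,
                  sigma = config$true$sigma, seed = seeds[[1]])
  } else {
    records <- read_participants_csv(config$input)
    truth <- NULL
  }
  utils::write.csv(records, file.path(config$out_dir, "data.csv"),
                   row.names = FALSE)
  if (!is.null(truth)) wjson(truth, "truth.json")

  # --- stage 2: scoring and exclusion ----------------------------------
  scores <- score_participants(records,
                               targets = config$design$targets,
                               distractors = config$design$distractors,
                               criterion = config$design$criterion)
  scores <- exclude_outliers(scores, config$outlier)
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)
  excl <- list(
    criterion_failures = sum(scores$excluded_at_source & scores$session == 1L),
    outliers_by_session = as.list(tapply(
      scores$excluded_outlier & !scores$excluded_at_source, scores$session, sum)))
  wjson(excl, "exclusions.json")

  keep <- !scores$excluded_at_source & !scores$excluded_outlier &
    scores$session == config$session
  sc <- scores[keep, , drop = FALSE]

  # --- stage 3: behavioral stats ---------------------------------------
  behavioral <- list(alpha = config$alpha)
  for (dv in c("retention", "recognition")) {
    an <- oneway_anova(sc[[dv]], sc$condition)
    behavioral[[dv]] <- list(f = an$f, df1 = an$df1, df2 = an$df2, p = an$p,
                             eta_squared = an$eta_squared,
                             means = as.list(an$means))
    contrasts <- list()
    for (h in config$hypotheses) {
      if (!all(c(h$larger, h$smaller) %in% sc$condition)) next
      w <- stats::setNames(c(1, -1), c(h$larger, h$smaller))
      ct <- planned_contrast(sc[[dv]], sc$condition, w,
                             tail = h$tail %||% "two")
      contrasts[[paste(h$larger, "vs", h$smaller)]] <-
        list(t = ct$t, df = ct$df, p = ct$p, tail = ct$tail,
             cohens_d = ct$cohens_d)
    }
    behavioral[[paste0(dv, "_contrasts")]] <- contrasts
  }
  wjson(behavioral, "behavioral.json")

  # --- stage 4: aggregated ML MPT --------------------------------------
  ids_keep <- sc$id
  rec_ml <- records[records$id %in% ids_keep &
                      records$session == config$session, , drop = FALSE]
  counts <- aggregate_counts(rec_ml, session = config$session)
  base_cons <- mpt_constraints(c(list(con_substitute("d", c("s", "r1"))),
                                 config$baseline_equalities))
  sat_cons <- default_constraints()
  fit_base <- fit_ml(config$model, counts, base_cons, restarts = 5L,
                     seed = seeds[[2]])
  fit_sat <- fit_ml(config$model, counts, sat_cons, restarts = 5L,
                    seed = seeds[[2]])
  ml <- list(
    baseline = c(goodness_of_fit(fit_base),
                 list(estimates = estimates_list(fit_base))),
    saturated = list(estimates = estimates_list(fit_sat)))
  tests <- list()
  for (h in config$hypotheses) {
    if (!all(c(h$larger, h$smaller) %in% names(counts))) next
    res_cons <- mpt_constraints(c(
      list(con_substitute("d", c("s", "r1")),
           con_equal(h$parameter, c(h$larger, h$smaller)))))
    fit_res <- fit_ml(config$model, counts, res_cons, restarts = 5L,
                      seed = seeds[[2]])
    cmp <- compare_nested(fit_sat, fit_res,
                          tail = h$tail %||% "two",
                          direction = if ((h$tail %||% "two") == "one")
                            h[c("parameter", "larger", "smaller")] else NULL)
    tests[[paste(h$parameter, h$larger, "vs", h$smaller)]] <- list(
      parameter = h$parameter, larger = h$larger, smaller = h$smaller,
      delta_g_squared = cmp$delta_g_squared, delta_df = cmp$delta_df,
      z = cmp$z, p_two = cmp$p_two, p_one = cmp$p_one %||% NULL,
      tail = h$tail %||% "two",
      significant = ((if ((h$tail %||% "two") == "one") cmp$p_one
                      else cmp$p_two) < config$alpha))
  }
  ml$comparisons <- tests
  wjson(ml, "ml.json")

  # --- stage 5: hierarchical Bayes (optional) --------------------------
  bayes <- NULL
  if (!is.null(config$bayes)) {
    bseeds <- derive_seeds(seeds[[3]], length(counts))
    fits <- list()
    bayes <- list()
    for (ci in seq_along(names(counts))) {
      cond <- names(counts)[ci]
      cfg <- config$bayes
      cfg$seed <- bseeds[[ci]]
      rec_c <- rec_ml[rec_ml$condition == cond, , drop = FALSE]
      f <- fit_latent_trait(rec_c, config$model, sat_cons, cfg)
      ppc <- posterior_predictive_check(
        f, n_rep = min(500L, nrow(f$chains[[1]]$mu) * length(f$chains)),
        seed = bseeds[[ci]])
      fits[[cond]] <- f
      bayes[[cond]] <- list(summary = f$summary,
                            convergence_ok = f$convergence_ok,
                            p_t1 = ppc$p_t1, p_t2 = ppc$p_t2,
                            satisfactory = ppc$satisfactory)
    }
    diffs <- list()
    for (h in config$hypotheses) {
      if (!all(c(h$larger, h$smaller) %in% names(fits))) next
      gd <- group_difference(fits[[h$larger]], fits[[h$smaller]],
                             h$parameter)
      diffs[[paste(h$parameter, h$larger, "vs", h$smaller)]] <- list(
        parameter = h$parameter, mean_diff = gd$mean_diff,
        bayes_p = gd$bayes_p, lower = gd$lower, upper = gd$upper,
        excludes_zero = gd$excludes_zero)
    }
    bayes$differences <- diffs
    wjson(bayes, "bayes.json")
  }

  report <- list(schema_version = config$schema_version,
                 seed = config$seed, alpha = config$alpha,
                 n_analysed = nrow(sc),
                 exclusions = excl, behavioral = behavioral, ml = ml,
                 bayes = bayes)
  wjson(report, "report.json")
  class(report) <- "analysis_report"
  invisible(report)
}

estimates_list <- function(fit) {
  est <- fit$estimates
  out <- list()
  for (g in colnames(est)) out[[g]] <- as.list(est[, g])
  out
}

#' Read a participant CSV
#'
#' Validates the canonical participant schema and reports missing columns
#' by name.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_participants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "condition", "session", "immediate_correct",
            names(category_columns()))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("input CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}
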