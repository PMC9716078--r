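#' Pipeline configuration
#'
#' Bundles every stage-level parameter of the end-to-end analysis:
#' simulate (or read) reports, extract the cohort, screen for
#' disproportionality signals, summarize onset times, fit co-medication
#' adjusted odds ratios, and build/validate the death-risk model. Unknown
#' keys are rejected, and a config round-trips through JSON identically.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param input_dir directory of quarterly-extract files to read; `NULL`
#'   (default) simulates input with `sim`.
#' @param dialect input dialect, `"faers_ascii"` or `"csv"`.
#' @param seed root seed; per-stage seeds are derived from it.
#' @param stages named logical toggles: `simulate`, `extract`, `screen`,
#'   `tto`, `combos`, `deathmodel`.
#' @param sim named list of [sim_config()] overrides (e.g. `n_reports`,
#'   `injected_ror`).
#' @param combos list with `classes` and `adjusters` for
#'   [combo_risk_table()].
#' @param death list with `n_boot`, `bins`, and `candidates` for the
#'   death-model stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            dialect = "faers_ascii",
                            seed = 17L,
                            stages = list(simulate = TRUE, extract = TRUE,
                                          screen = TRUE, tto = TRUE,
                                          combos = TRUE, deathmodel = TRUE),
                            sim = list(n_reports = 20000L),
                            combos = list(
                              classes = c("dpp4i", "glp1ra", "metformin",
                                          "insulin", "glinide", "acei",
                                          "ppi", "statin"),
                              adjusters = c("sex", "age_group", "year")
                            ),
                            death = list(
                              n_boot = 200L, bins = 10L,
                              candidates = c("statin", "heart_failure",
                                             "sglt2i", "sex")
                            )) {
  known_stages <- c("simulate", "extract", "screen", "tto", "combos",
                    "deathmodel")
  bad <- setdiff(names(stages), known_stages)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown stage(s): %s.", paste(bad, collapse = ", ")),
                 class = "pvsignal_config_error")
  }
  full_stages <- stats::setNames(as.list(rep(TRUE, length(known_stages))),
                                 known_stages)
  full_stages[names(stages)] <- stages
  structure(
    list(out_dir = out_dir, input_dir = input_dir, dialect = dialect,
         seed = as.integer(seed), stages = full_stages, sim = sim,
         combos = combos, death = death),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out_dir", "input_dir", "dialect", "seed", "stages", "sim",
             "combos", "death")
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s.",
                         paste(bad, collapse = ", ")),
                 class = "pvsignal_config_error")
  }
  do.call(pipeline_config, x[intersect(known, names(x))])
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order, writing every intermediate as a
#' file under `config$out_dir` and a manifest (`manifest.json`) recording
#' the seed, stage toggles, and row counts at each filter step, so the
#' attrition chain is auditable. All randomness flows from the root seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    rlang::abort("`config` must be built with pipeline_config().",
                 class = "pvsignal_config_error")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max - 1, 8))
  manifest <- list(seed = config$seed, stages = config$stages,
                   counts = list())
  results <- list()
  dictionary <- event_dictionary()

  # --- input: simulate or read ---
  if (isTRUE(config$stages$simulate)) {
    sim_args <- config$sim
    sim_args$seed <- stage_seeds[1]
    sim <- simulate_reports(do.call(sim_config, sim_args))
    sim_dir <- file.path(out, "simulated")
    write_faers_ascii(sim, sim_dir)
    reports <- sim$reports
    results$sim <- sim
    manifest$counts$n_simulated <- n_reports(reports)
  } else {
    if (is.null(config$input_dir)) {
      rlang::abort("either enable the simulate stage or set input_dir.",
                   class = "pvsignal_config_error")
    }
    reports <- parse_quarter(config$input_dir, dialect = config$dialect)
    manifest$counts$n_parsed <- n_reports(reports)
    manifest$counts$n_skipped_rows <- attr(reports, "n_skipped")
  }

  reports <- deduplicate(reports)
  manifest$counts$n_deduplicated <- n_reports(reports)

  # --- extract ---
  if (isTRUE(config$stages$extract)) {
    cohort <- extract_cohort(reports, dictionary,
                             require_demographics = TRUE)
    readr::write_csv(cohort, file.path(out, "cohort.csv"), progress = FALSE)
    attrition <- attr(cohort, "attrition")
    manifest$counts <- c(manifest$counts, as.list(attrition))
    if (nrow(cohort) > 0) {
      summ <- summarize_cohort(cohort)
      readr::write_csv(summ$counts, file.path(out, "cohort_summary.csv"),
                       progress = FALSE)
      jsonlite::write_json(summ$age, file.path(out, "cohort_age.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    results$cohort <- cohort
  } else {
    cohort <- NULL
  }

  # --- screen ---
  if (isTRUE(config$stages$screen)) {
    signals <- screen_all(reports, dictionary)
    readr::write_csv(signals, file.path(out, "signals.csv"),
                     progress = FALSE)
    jsonlite::write_json(signals, file.path(out, "signals.json"),
                         auto_unbox = TRUE, digits = NA)
    results$signals <- signals
    manifest$counts$n_signal_rows <- nrow(signals)
  }

  # --- tto ---
  if (isTRUE(config$stages$tto) && !is.null(cohort)) {
    evaluable <- cohort$onset_days[cohort$ap & !is.na(cohort$onset_days)]
    if (length(evaluable) > 0) {
      tto <- summarize_tto(evaluable)
      jsonlite::write_json(unclass(tto), file.path(out, "tto.json"),
                           auto_unbox = TRUE, digits = NA)
      results$tto <- tto
      manifest$counts$n_tto_evaluable <- tto$n_evaluable
    }
  }

  # --- combos ---
  if (isTRUE(config$stages$combos) && !is.null(cohort) &&
      nrow(cohort) > 0) {
    combos <- tryCatch(
      combo_risk_table(cohort, classes = config$combos$classes,
                       adjusters = config$combos$adjusters),
      error = function(e) NULL
    )
    if (!is.null(combos)) {
      readr::write_csv(combos, file.path(out, "combos.csv"),
                       progress = FALSE)
      results$combos <- combos
    }
  }

  # --- deathmodel ---
  if (isTRUE(config$stages$deathmodel) && !is.null(cohort)) {
    ap_cohort <- cohort[cohort$ap & cohort$n_sglt2i_types < 2, ,
                        drop = FALSE]
    manifest$counts$n_death_model <- nrow(ap_cohort)
    dm <- tryCatch(
      run_death_model(ap_cohort, config$death, seed = stage_seeds[2],
                      out = out),
      error = function(e) {
        rlang::inform(paste("death-model stage skipped:",
                            conditionMessage(e)))
        NULL
      }
    )
    results$death_model <- dm
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

run_death_model <- function(ap_cohort, death_cfg, seed, out) {
  # Sparse drug-type strata cannot support their own dummy coefficient in a
  # 1:1 split; merge levels with fewer than 10 reports into the largest one.
  counts <- table(ap_cohort$sglt2i)
  rare <- names(counts)[counts < 10]
  if (length(rare) > 0) {
    ap_cohort$sglt2i[ap_cohort$sglt2i %in% rare] <-
      names(which.max(counts))
  }
  halves <- split_cohort(ap_cohort, seed = seed)
  screen <- univariate_screen(halves$train, death_cfg$candidates)
  fit <- multivariate_fit(halves$train, attr(screen, "retained"))
  readr::write_csv(fit$tidy, file.path(out, "death_coefficients.csv"),
                   progress = FALSE)
  nom <- build_nomogram(fit, halves$train)
  jsonlite::write_json(
    list(table = nom$table, intercept = nom$intercept, base_lp = nom$base_lp,
         lp_per_point = nom$lp_per_point),
    file.path(out, "nomogram.json"), auto_unbox = TRUE, digits = NA
  )
  p_train <- predict(fit, halves$train)
  p_valid <- predict(fit, halves$valid)
  auc <- c(train = roc_auc(p_train, halves$train$death),
           valid = roc_auc(p_valid, halves$valid$death))
  cal <- bootstrap_calibration(fit, halves$train,
                               n_boot = death_cfg$n_boot,
                               bins = death_cfg$bins, seed = seed + 1)
  dca <- decision_curve(p_train, halves$train$death)
  readr::write_csv(cal$curve, file.path(out, "calibration.csv"),
                   progress = FALSE)
  readr::write_csv(dca, file.path(out, "decision_curve.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(auc_train = auc[["train"]], auc_valid = auc[["valid"]],
         calibration_mae_train = cal$mae, n_boot = cal$n_boot),
    file.path(out, "death_validation.json"), auto_unbox = TRUE, digits = NA
  )
  list(screen = screen, fit = fit, nomogram = nom, auc = auc,
       calibration = cal, decision_curve = dca)
}
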