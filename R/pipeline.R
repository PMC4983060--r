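#' Default pipeline run configuration
#'
#' A fully populated, human-editable configuration for [run_pipeline()],
#' round-trippable through YAML with [read_run_config()] /
#' [write_run_config()]. Top-level sections: `stages` (which stages run),
#' `sim` (arguments to [sim_config()]), `panel` (biospecimen panel size),
#' `cv` (folds, repetitions, seed), `exposure` (coefficient source,
#' quartile source, cumulative vs simple update) and `analysis` (outcomes,
#' subgroups, trend coding).
#'
#' @param ... Name-value overrides merged into the default list (nested
#'   lists are merged element-wise).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    stages = list(simulate = TRUE, derive = TRUE, score = TRUE, analyze = TRUE),
    sim = list(n_subjects = 20000L, n_cycles = 10L, seed = 20260920L),
    panel = list(n_panel = 2856L),
    cv = list(k = 5L, reps = 100L, seed = 20260920L),
    exposure = list(coefficients = "published", quartile_source = "person_time",
                    update = "cumulative"),
    analysis = list(outcomes = c("all", "ER+", "ER-"),
                    subgroups = character(0), trend = TRUE))
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_run_config()` returns a `run_config` list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- do.call(default_run_config, cfg)
  # YAML has no zero-length vector literal; normalise list-typed fields
  cfg$analysis$outcomes <- as.character(unlist(cfg$analysis$outcomes))
  cfg$analysis$subgroups <- as.character(unlist(cfg$analysis$subgroups))
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable short hash of the configuration, stamped into every output header.
config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1, 12)
}

# Delimited-text writer with a provenance header: comment lines carrying the
# config hash, the stage seed and the package version, then a CSV body.
# Missing items are written as empty fields; read back with
# `read.csv(comment.char = "#")`.
write_stage_table <- function(df, path, hash, seed, stage) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# vitdpredict %s | stage=%s | config=%s | seed=%s",
                     as.character(utils::packageVersion("vitdpredict")),
                     stage, hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full simulate-derive-score-analyze pipeline
#'
#' Orchestrates the package's stages on a synthetic cohort, with every
#' stage's inputs, outputs and seeds logged and all tables written as
#' delimited text under `out_dir`:
#'
#' 1. **simulate** — covariate histories ([generate_covariate_histories()]),
#'    item missingness ([apply_missingness()]), and the calibrated
#'    biospecimen panel ([sample_biospecimen_panel()]).
#' 2. **derive** — repeated k-fold cross-validation ([repeated_cv()]) and
#'    the full-panel prediction model ([fit_prediction_model()]).
#' 3. **score** — carry-forward, per-cycle scores, cumulative-average
#'    exposure and quartiles ([score_cohort()]); then outcomes are drawn
#'    from the exposure-dependent hazard ([simulate_outcomes()]).
#' 4. **analyze** — person-period expansion ([expand_person_periods()]) and
#'    the stratified proportional-hazards analyses ([fit_cox()],
#'    [trend_test()], [subtype_analysis()], [subgroup_analysis()]).
#'
#' A stage failure halts the run with the failing stage named; tables
#' already written are retained. A plain-text `report.txt` juxtaposes the
#' cross-validation performance and the quartile IRR tables; it contains no
#' timestamps, so two runs with the same configuration produce identical
#' reports.
#'
#' @param config A [default_run_config()] list.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with the in-memory stage results and `paths`
#'   to the written files.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("vitd_run_"), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "at")
  on.exit(close(log_con))
  log_msg <- function(...) {
    line <- sprintf(...)
    writeLines(paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), line), log_con)
    if (!quiet) message(line)
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      log_msg("stage '%s' FAILED: %s", name, conditionMessage(e))
      stop("pipeline halted in stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  paths <- list(log = log_path)
  scfg <- do.call(sim_config, config$sim)
  write_run_config(config, file.path(out_dir, "config.yml"))
  log_msg("run %s starting (config %s)", out_dir, hash)

  if (isTRUE(config$stages$simulate)) {
    run_stage("simulate", {
      log_msg("simulate: n=%d cycles=%d seed=%d", scfg$n_subjects,
              scfg$n_cycles, scfg$seed)
      cohort <- generate_covariate_histories(scfg)
      cohort <- apply_missingness(cohort, scfg)
      panel <- sample_biospecimen_panel(cohort, vitd_coefficients(),
                                        n_panel = config$panel$n_panel,
                                        config = scfg)
      cal <- attr(panel, "calibration")
      log_msg("simulate: panel n=%d sigma=%.2f delta=%.2f lambda=%.3f R2=%.3f",
              nrow(panel), cal$sigma, cal$delta, cal$lambda, cal$achieved_r2)
      paths$cohort <- write_stage_table(cohort,
        file.path(out_dir, "cohort.csv"), hash, scfg$seed, "simulate")
      paths$panel <- write_stage_table(panel,
        file.path(out_dir, "panel.csv"), hash, scfg$seed, "simulate")
      res$cohort <- cohort; res$panel <- panel
    })
  }

  if (isTRUE(config$stages$derive)) {
    run_stage("derive", {
      log_msg("derive: %dx%d-fold CV, seed=%d", config$cv$reps, config$cv$k,
              config$cv$seed)
      cv <- repeated_cv(res$panel, k = config$cv$k, reps = config$cv$reps,
                        seed = config$cv$seed)
      model <- fit_prediction_model(res$panel)
      log_msg("derive: mean r=%.3f (SD %.3f), adj R2=%.3f", cv$mean_r,
              cv$sd_r, model$adj_r2)
      paths$cv <- write_stage_table(tidy(cv),
        file.path(out_dir, "cv_folds.csv"), hash, config$cv$seed, "derive")
      paths$model <- write_stage_table(model$report,
        file.path(out_dir, "model_coefficients.csv"), hash,
        config$cv$seed, "derive")
      res$cv <- cv; res$model <- model
    })
  }

  if (isTRUE(config$stages$score)) {
    run_stage("score", {
      coeffs <- if (identical(config$exposure$coefficients, "fitted") &&
                    !is.null(res$model)) res$model$coef_set
                else vitd_coefficients()
      log_msg("score: %s coefficients, %s update, %s quartiles",
              attr(coeffs, "provenance"), config$exposure$update,
              config$exposure$quartile_source)
      expo <- score_cohort(res$cohort, coeffs,
                           exposure = config$exposure$update,
                           quartile_source = config$exposure$quartile_source)
      outcomes <- simulate_outcomes(carry_forward(res$cohort), expo, scfg)
      log_msg("score: %d usable subject-cycles; %d events",
              nrow(expo), sum(outcomes$event))
      paths$exposure <- write_stage_table(expo,
        file.path(out_dir, "exposure.csv"), hash, scfg$seed, "score")
      paths$outcomes <- write_stage_table(outcomes,
        file.path(out_dir, "outcomes.csv"), hash, scfg$seed, "score")
      res$exposure <- expo; res$outcomes <- outcomes
    })
  }

  if (isTRUE(config$stages$analyze)) {
    run_stage("analyze", {
      pp <- expand_person_periods(carry_forward(res$cohort), res$outcomes,
                                  res$exposure)
      log_msg("analyze: %d person-periods, %.0f person-years",
              nrow(pp), sum(pp$time))
      fits <- list()
      for (oc in config$analysis$outcomes) {
        if (sum(pp[[cox_event_column(oc)]]) == 0) next
        mv <- fit_cox(pp, outcome = oc)
        crude <- fit_cox(pp, outcome = oc, covariates = NULL)
        tr <- if (isTRUE(config$analysis$trend)) trend_test(pp, outcome = oc)
              else NULL
        fits[[oc]] <- list(mv = mv, crude = crude, trend = tr)
      }
      subgroups <- lapply(stats::setNames(config$analysis$subgroups,
                                          config$analysis$subgroups),
                          function(s) subgroup_analysis(pp, s))
      res$person_periods <- pp
      res$analysis <- fits
      res$subgroups <- subgroups
      irr_tbl <- purrr::map_dfr(names(fits), function(oc) {
        b <- fits[[oc]]$mv$by_quartile
        b$outcome <- oc
        b$trend_p <- if (!is.null(fits[[oc]]$trend))
          fits[[oc]]$trend$p_value else NA_real_
        b
      })
      paths$irr <- write_stage_table(irr_tbl,
        file.path(out_dir, "irr_by_quartile.csv"), hash, scfg$seed, "analyze")
      paths$report <- file.path(out_dir, "report.txt")
      writeLines(pipeline_report(config, hash, res), paths$report)
      log_msg("analyze: report written to %s", paths$report)
    })
  }
  log_msg("run complete")
  invisible(c(res, list(paths = paths, config = config)))
}

# Plain-text summary juxtaposing CV performance and the IRR tables in the
# conventional layout (quartile, cases, person-years, IRR, CI, p-trend).
pipeline_report <- function(config, hash, res) {
  out <- c(sprintf("Predicted 25(OH)D pipeline report (config %s)", hash), "")
  if (!is.null(res$cv)) {
    out <- c(out, "Cross-validated prediction performance",
             sprintf("  mean test-fold r:  %.3f (SD of repetition means %.3f)",
                     res$cv$mean_r, res$cv$sd_r),
             sprintf("  mean test-fold R2: %.3f", res$cv$mean_r2),
             sprintf("  same quartile:     %.1f%%", 100 * res$cv$same_quartile),
             sprintf("  same or adjacent:  %.1f%%",
                     100 * res$cv$same_or_adjacent), "")
  }
  if (!is.null(res$model)) {
    out <- c(out, sprintf("Prediction model (full panel): adjusted R2 = %.3f",
                          res$model$adj_r2), "")
  }
  for (oc in names(res$analysis)) {
    f <- res$analysis[[oc]]
    out <- c(out, sprintf("Outcome: %s  (events %d, person-years %.0f)%s",
                          oc, f$mv$n_event, sum(f$mv$by_quartile$person_years),
                          if (!is.null(f$trend))
                            sprintf("  P trend = %.3g", f$trend$p_value)
                          else ""))
    b <- f$mv$by_quartile
    crude_irr <- f$crude$by_quartile$irr
    for (i in seq_len(nrow(b))) {
      out <- c(out, sprintf(
        "  Q%d  cases %4d  py %9.0f  age/period IRR %5.2f  MV IRR %5.2f (%s)",
        b$quartile[i], b$events[i], b$person_years[i], crude_irr[i], b$irr[i],
        if (is.na(b$conf_low[i])) "ref"
        else sprintf("%.2f-%.2f", b$conf_low[i], b$conf_high[i])))
    }
    out <- c(out, "")
  }
  out
}
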