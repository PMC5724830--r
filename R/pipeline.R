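# Sequential pipeline: simulate -> score -> homa -> regress -> mediate -------

#' Pipeline run configuration
#'
#' Bundles every stage configuration under one seed.  In `"synthetic"` mode
#' the cohort and sessions are generated; in `"data"` mode supply
#' `inputs$sessions` (path to a session-log TSV or a named list of logs) and
#' `inputs$cohort` (path to a cohort CSV or a data frame).  The analysis
#' order mirrors the study logic: behavioural metrics, then metabolic
#' predictors of behaviour, neural predictors of behaviour, metabolic
#' predictors of activation, then mediation.  If the cohort carries a logical
#' `fmri_included` column, ROI regressions and the mediation stage are
#' restricted to that subgroup (a stand-in for head-motion exclusion, which
#' needs images the pipeline never sees).
#'
#' @param mode `"synthetic"` or `"data"`.
#' @param seed Integer seed governing the whole run.
#' @param cohort,params,task,staircase Stage configs (see [cohort_config()],
#'   [race_params()], [task_config()], [staircase_config()]).
#' @param score List: `method` (cSSD estimator) and optional extra arguments.
#' @param regress List: `outcomes`, `predictors`, `covariates` for the
#'   metabolic-to-behaviour screen (ROI screens are derived from it).
#' @param mediate List: `x`, `m`, `y`, `covariates`, `n_boot`, `ci_level`,
#'   `ci_type`.
#' @param inputs List with `sessions` and `cohort` for `"data"` mode.
#' @param stages Character vector of stages to run, in order.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "data"),
                            seed = 1L,
                            cohort = cohort_config(seed = seed),
                            params = race_params(),
                            task = task_config(),
                            staircase = staircase_config(),
                            score = list(method = "interpolate"),
                            regress = list(outcomes = c("cssd", "mgrt", "ssrt"),
                                           predictors = c("bmi", "homa_ir"),
                                           covariates = c("age", "sex", "metformin_mg")),
                            mediate = list(x = "homa_ir",
                                           m = "con_se_gt_ss_r_putamen",
                                           y = "mgrt",
                                           covariates = c("age", "sex", "metformin_mg"),
                                           n_boot = 5000, ci_level = 0.95,
                                           ci_type = "percentile"),
                            inputs = list(sessions = NULL, cohort = NULL),
                            stages = c("simulate", "score", "homa", "regress", "mediate")) {
  mode <- match.arg(mode)
  chk_num(seed, "seed")
  structure(list(mode = mode, seed = as.integer(seed), cohort = cohort,
                 params = params, task = task, staircase = staircase,
                 score = score, regress = regress, mediate = mediate,
                 inputs = inputs, stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of [pipeline_config()];
#' nested sections (`cohort`, `params`, `task`, `staircase`, `score`,
#' `regress`, `mediate`) override field-wise.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config(seed = raw$seed %||% 1L)
  ctor <- list(cohort = cohort_config, params = race_params,
               task = task_config, staircase = staircase_config)
  args <- list()
  for (nm in c("mode", "seed", "stages"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  for (nm in names(ctor)) {
    if (!is.null(raw[[nm]])) {
      merged <- modifyList(unclass(base[[nm]]), raw[[nm]])
      if (nm == "cohort" && is.null(raw[[nm]]$seed))
        merged$seed <- args$seed %||% base$seed
      args[[nm]] <- do.call(ctor[[nm]], merged[names(formals(ctor[[nm]]))[
        names(formals(ctor[[nm]])) %in% names(merged)]])
    }
  }
  for (nm in c("score", "regress", "mediate", "inputs"))
    if (!is.null(raw[[nm]])) args[[nm]] <- modifyList(base[[nm]], raw[[nm]])
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(errorCondition(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = c("sst_stage_error", "error", "condition")))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — simulate, score, homa, regress,
#' mediate — writing every intermediate table (and `report.json`) to
#' `out_dir` when given, and returns a machine-readable report together with
#' the tables.  A failing stage aborts with the stage name and cause
#' (condition class `sst_stage_error`); tables written before the failure are
#' retained.  Reports from identical configurations are identical except for
#' the timestamp.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param seed Optional override of the config seed (also reseeds the
#'   synthetic cohort).
#' @return List with `report` (per-stage row counts, exclusions with reasons,
#'   regression and mediation results, config hash, package version) and
#'   `tables` (cohort, behavioral, analysis, screens, mediation object).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$cohort$seed <- as.integer(seed)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, fname, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, fname))
  }
  hash_input <- config[c("mode", "seed", "cohort", "params", "task",
                         "staircase", "score", "regress", "mediate", "stages")]
  report <- list(package = "sstmediate",
                 version = as.character(packageVersion("sstmediate")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = config$seed,
                 config_hash = rlang::hash(hash_input),
                 stages = config$stages)
  tables <- list()
  sessions <- NULL
  cohort <- NULL

  if ("simulate" %in% config$stages) {
    if (config$mode != "synthetic")
      stop_validation("stage 'simulate' requires synthetic mode")
    sim <- run_stage("simulate",
      simulate_cohort(config$cohort, config$params, config$task,
                      config$staircase, sessions = "full"))
    cohort <- sim$cohort
    sessions <- sim$sessions
    emit(do.call(rbind, c(sim$sessions, list(make.row.names = FALSE))),
         "sessions.tsv", write_session_log)
    emit(cohort, "cohort.csv", write_cohort_table)
    report$n_simulated <- nrow(cohort)
  } else {
    cohort <- run_stage("inputs", {
      x <- config$inputs$cohort
      if (is.null(x)) stop_validation("no cohort input supplied")
      if (is.character(x)) read_cohort_table(x) else x
    })
    if (!is.null(config$inputs$sessions)) {
      x <- config$inputs$sessions
      sessions <- if (is.character(x)) read_session_log(x, split = TRUE) else x
    }
    report$n_simulated <- nrow(cohort)
  }
  tables$cohort <- cohort

  analysis <- cohort
  if ("score" %in% config$stages) {
    if (is.null(sessions))
      stop_validation("stage 'score' requires session logs")
    behav <- run_stage("score", do.call(score_cohort,
      c(list(sessions = sessions), config$score)))
    emit(behav, "behavioral.csv", write_cohort_table)
    tables$behavioral <- behav
    analysis <- merge(cohort, behav, by = "participant_id", sort = TRUE)
    report$n_scored <- nrow(behav)
    report$n_included <- sum(behav$included)
    excl <- behav[!behav$included,
                  c("participant_id", "exclusion_reasons"), drop = FALSE]
    report$exclusions <- if (nrow(excl)) excl else NULL
    analysis <- analysis[analysis$included, , drop = FALSE]
  }

  if ("homa" %in% config$stages) {
    analysis <- run_stage("homa", add_homa_ir(analysis))
  }
  emit(analysis, "analysis.csv", write_cohort_table)
  tables$analysis <- analysis

  # fMRI subgroup stand-in: optional boolean column applied as a filter to
  # ROI-level regressions and mediation.
  fmri <- analysis
  if ("fmri_included" %in% names(analysis)) {
    fmri <- analysis[as.logical(analysis$fmri_included) %in% TRUE, , drop = FALSE]
    report$n_fmri <- nrow(fmri)
  }

  roi_cols <- grep("^con_", names(analysis), value = TRUE)
  if ("regress" %in% config$stages) {
    rg <- config$regress
    screens <- run_stage("regress", {
      out <- list()
      oc <- intersect(rg$outcomes, names(analysis))
      out$metabolic_behavior <- screen_predictors(
        analysis, oc, rg$predictors, rg$covariates)
      if (length(roi_cols)) {
        out$neural_behavior <- screen_predictors(
          fmri, intersect(rg$outcomes, names(fmri)), roi_cols, rg$covariates)
        out$metabolic_neural <- screen_predictors(
          fmri, roi_cols, rg$predictors, rg$covariates)
      }
      out
    })
    all_screens <- do.call(rbind, c(lapply(names(screens), function(nm) {
      s <- screens[[nm]]; if (nrow(s)) s$screen <- nm else s$screen <- character(0); s
    }), list(make.row.names = FALSE)))
    emit(all_screens, "regressions.csv", write_cohort_table)
    tables$screens <- screens
    report$regressions <- all_screens
  }

  if ("mediate" %in% config$stages) {
    mc <- config$mediate
    med <- run_stage("mediate", mediate(
      fmri, x = mc$x, m = mc$m, y = mc$y,
      covariates = mc$covariates %||% character(),
      n_boot = mc$n_boot %||% 5000, ci_level = mc$ci_level %||% 0.95,
      seed = config$seed + 104729L,
      ci_type = mc$ci_type %||% "percentile"))
    tables$mediation <- med
    report$mediation <- list(
      x = med$x, m = med$m, y = med$y, n = med$n,
      a = med$a, b = med$b, c = med$c, c_prime = med$c_prime,
      indirect = med$indirect, indirect_ci = med$indirect_ci,
      kappa2 = med$kappa2, kappa2_ci = med$kappa2_ci,
      evidence = med$evidence, narrative = med$narrative)
  }

  if (!is.null(out_dir)) {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE, na = "null")
    writeLines(json, file.path(out_dir, "report.json"))
  }
  list(report = report, tables = tables)
}
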