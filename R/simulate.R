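# Trial- and session-level simulation under the independent race ------------

# Pure race kernel: classifies one trial given already-sampled latencies.
# Outcomes follow the GS/GE/SS/SE scheme: go success, go error (premature,
# late, or absent), stop success, stop error.  Ties go to the stop process.
race_outcome <- function(is_stop, go_rt, stop_rt, ssd, max_rt,
                         omitted = FALSE, premature = FALSE, pre_rt = NA_real_) {
  if (is_stop) {
    if (!omitted && go_rt < ssd + stop_rt && go_rt <= max_rt)
      return(list(responded = 1L, rt = go_rt, outcome = "SE"))
    return(list(responded = 0L, rt = NA_real_, outcome = "SS"))
  }
  if (premature) return(list(responded = 1L, rt = pre_rt, outcome = "GE"))
  if (omitted)   return(list(responded = 0L, rt = NA_real_, outcome = "GE"))
  list(responded = 1L, rt = go_rt,
       outcome = if (go_rt <= max_rt) "GS" else "GE")
}

#' Simulate a single SST trial
#'
#' Draws one trial from the independent race model: the go finishing time is
#' ex-Gaussian, the stop latency Gaussian truncated at zero, and on a stop
#' trial a response is emitted iff the go process beats `ssd + stopRT`.
#' Premature responses (go trials only) are recorded with a negative RT,
#' i.e. measured from the go cue backwards into the fore-period.
#'
#' @param params A [race_params()] object.
#' @param is_stop Logical: stop trial?
#' @param ssd Stop-signal delay in ms; required non-negative on stop trials.
#' @param task A [task_config()] object (supplies `max_rt` and the fore-period
#'   range).
#' @return One-row data frame with columns `trial_type`, `foreperiod_ms`,
#'   `ssd_ms`, `responded`, `rt_ms`, `outcome`.
#' @export
simulate_trial <- function(params, is_stop, ssd = NA_real_, task = task_config()) {
  stopifnot(inherits(params, "race_params"), inherits(task, "task_config"))
  if (is_stop && (is.na(ssd) || ssd < 0))
    stop_validation("ssd must be a non-negative delay on stop trials")
  fp <- runif(1, task$foreperiod_min, task$foreperiod_max)
  go_rt <- rexgauss(1, params$mu_go, params$sigma_go, params$tau_go)
  stop_rt <- rtruncnorm0(1, params$mu_stop, params$sigma_stop)
  omitted <- runif(1) < params$p_go_omission
  premature <- !is_stop && runif(1) < params$p_premature
  res <- race_outcome(is_stop, go_rt, stop_rt, ssd, task$max_rt,
                      omitted, premature, pre_rt = -runif(1, 0, fp))
  data.frame(trial_type = if (is_stop) "stop" else "go",
             foreperiod_ms = fp,
             ssd_ms = if (is_stop) ssd else NA_real_,
             responded = res$responded, rt_ms = res$rt, outcome = res$outcome,
             stringsAsFactors = FALSE)
}

#' Simulate a full SST session
#'
#' Generates `n_runs` runs of pseudo-randomly ordered go and stop trials.  By
#' default the stop-signal delay follows a one-up/one-down staircase (up after
#' a stop success, down after a stop error, clamped); alternatively a fixed
#' `ssd_schedule` can be supplied, whose values are cycled over stop trials
#' (no tracking).  The staircase state carries across runs.
#'
#' @param params A [race_params()] object.
#' @param task A [task_config()] object.
#' @param staircase A [staircase_config()] object.
#' @param seed Optional integer; when given the session is bit-reproducible.
#' @param participant_id Identifier written to every row.
#' @param ssd_schedule Optional numeric vector of fixed SSDs (ms), cycled over
#'   stop trials instead of the staircase.
#' @return A session log: data frame with one row per trial and columns
#'   `participant_id`, `run`, `trial_index`, `trial_type`, `foreperiod_ms`,
#'   `ssd_ms` (NA on go trials), `responded`, `rt_ms` (NA when no response),
#'   `outcome` (GS/GE/SS/SE).
#' @export
simulate_session <- function(params, task = task_config(),
                             staircase = staircase_config(), seed = NULL,
                             participant_id = "P001", ssd_schedule = NULL) {
  stopifnot(inherits(params, "race_params"), inherits(task, "task_config"),
            inherits(staircase, "staircase_config"))
  if (!is.null(ssd_schedule)) {
    if (!is.numeric(ssd_schedule) || !length(ssd_schedule) || any(ssd_schedule < 0))
      stop_validation("ssd_schedule must be a non-empty vector of non-negative delays")
  }
  if (!is.null(seed)) set.seed(seed)

  n_run <- task$n_go_per_run + task$n_stop_per_run
  n_total <- task$n_runs * n_run
  trial_type <- unlist(lapply(seq_len(task$n_runs), function(r)
    sample(rep(c("go", "stop"), c(task$n_go_per_run, task$n_stop_per_run)))))
  fp <- runif(n_total, task$foreperiod_min, task$foreperiod_max)
  go_rt <- rexgauss(n_total, params$mu_go, params$sigma_go, params$tau_go)
  stop_rt <- rtruncnorm0(n_total, params$mu_stop, params$sigma_stop)
  omitted <- runif(n_total) < params$p_go_omission
  premature <- runif(n_total) < params$p_premature
  pre_rt <- -runif(n_total, 0, fp)

  ssd <- rep(NA_real_, n_total)
  responded <- integer(n_total)
  rt <- rep(NA_real_, n_total)
  outcome <- character(n_total)
  ssd_cur <- staircase$initial_ssd
  k_stop <- 0L
  for (i in seq_len(n_total)) {
    is_stop <- trial_type[i] == "stop"
    if (is_stop) {
      k_stop <- k_stop + 1L
      ssd_i <- if (is.null(ssd_schedule)) ssd_cur
               else ssd_schedule[((k_stop - 1L) %% length(ssd_schedule)) + 1L]
      ssd[i] <- ssd_i
    } else ssd_i <- NA_real_
    res <- race_outcome(is_stop, go_rt[i], stop_rt[i], ssd_i, task$max_rt,
                        omitted[i], !is_stop && premature[i], pre_rt[i])
    responded[i] <- res$responded
    rt[i] <- res$rt
    outcome[i] <- res$outcome
    if (is_stop && is.null(ssd_schedule)) {
      ssd_cur <- ssd_cur + if (res$outcome == "SS") staircase$step else -staircase$step
      ssd_cur <- min(max(ssd_cur, staircase$ssd_min), staircase$ssd_max)
    }
  }
  data.frame(participant_id = participant_id,
             run = rep(seq_len(task$n_runs), each = n_run),
             trial_index = rep(seq_len(n_run), times = task$n_runs),
             trial_type = trial_type, foreperiod_ms = fp, ssd_ms = ssd,
             responded = responded, rt_ms = rt, outcome = outcome,
             stringsAsFactors = FALSE)
}

# Per-participant stream seed derived from (cohort seed, index); bounded well
# below 2^31 and collision-free within a cohort.
participant_seed <- function(seed, i) {
  ((seed %% 20011) * 100003 + i) %% 2147483647
}

#' Simulate a participant cohort with a configurable mediation structure
#'
#' Draws metabolic and demographic covariates per participant, builds the ROI
#' activation contrast as `path_a * HOMA-IR + noise`, sets each participant's
#' expected median go RT to
#' `mgrt_baseline + path_b * M + path_c_prime * HOMA-IR + noise`, and (in
#' `sessions = "full"` mode) shifts that participant's go-process mean so the
#' session's expected mGRT matches, then simulates the full trial log.  In
#' `sessions = "none"` mode no trial logs are generated and the latent
#' expected mGRT is written to the cohort table as `mgrt` — useful for
#' large simulation studies of the downstream statistics.
#'
#' Each participant uses an RNG stream seeded from
#' `(cohort seed, participant index)`, so cohorts are reproducible
#' participant-wise.
#'
#' @param cohort A [cohort_config()] object.
#' @param params_base A [race_params()] object used as the cohort-level base;
#'   only `mu_go` is shifted per participant.
#' @param task A [task_config()] object.
#' @param staircase A [staircase_config()] object.
#' @param sessions `"full"` (simulate trial logs) or `"none"` (cohort table
#'   only, latent `mgrt` column included).
#' @return A list with `cohort` (data frame: `participant_id`,
#'   `glucose_mgdl`, `insulin_uUml`, `bmi`, `age`, `sex`, `metformin_mg`, the
#'   ROI contrast column, and `mgrt` in `"none"` mode) and `sessions` (named
#'   list of session logs, or `NULL`).
#' @export
simulate_cohort <- function(cohort = cohort_config(),
                            params_base = race_params(),
                            task = task_config(),
                            staircase = staircase_config(),
                            sessions = c("full", "none")) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(params_base, "race_params"))
  sessions <- match.arg(sessions)
  n <- cohort$n_participants
  base_median <- exg_median(params_base$mu_go, params_base$sigma_go, params_base$tau_go)

  ids <- sprintf("P%03d", seq_len(n))
  glucose <- insulin <- bmi <- age <- m_val <- mgrt_lat <- numeric(n)
  sex <- metf <- integer(n)
  logs <- if (sessions == "full") vector("list", n) else NULL

  for (i in seq_len(n)) {
    set.seed(participant_seed(cohort$seed, i))
    homa_i <- rlnorm(1, cohort$homa_meanlog, cohort$homa_sdlog)
    bmi[i] <- rnorm(1, cohort$bmi_mean, cohort$bmi_sd)
    age[i] <- round(min(max(rnorm(1, cohort$age_mean, cohort$age_sd),
                            cohort$age_range[1]), cohort$age_range[2]))
    sex[i] <- rbinom(1, 1, cohort$p_male)
    metf[i] <- cohort$metformin_levels[sample.int(length(cohort$metformin_levels), 1)]
    glucose[i] <- max(cohort$glucose_min, rnorm(1, cohort$glucose_mean, cohort$glucose_sd))
    insulin[i] <- homa_i * 405 / glucose[i]
    m_val[i] <- cohort$path_a * homa_i + rnorm(1, 0, cohort$noise_sd_m)
    mgrt_lat[i] <- cohort$mgrt_baseline + cohort$path_b * m_val[i] +
      cohort$path_c_prime * homa_i + rnorm(1, 0, cohort$noise_sd_y)
    if (sessions == "full") {
      params_i <- params_base
      # mu_go is a location parameter of the go distribution, so shifting it
      # moves the median (hence the expected mGRT) one-for-one.
      params_i$mu_go <- max(params_base$mu_go + (mgrt_lat[i] - base_median), 150)
      logs[[i]] <- simulate_session(params_i, task, staircase,
                                    participant_id = ids[i])
    }
  }
  tab <- data.frame(participant_id = ids, glucose_mgdl = glucose,
                    insulin_uUml = insulin, bmi = bmi, age = age, sex = sex,
                    metformin_mg = metf, stringsAsFactors = FALSE)
  tab[[cohort$roi_name]] <- m_val
  if (sessions == "none") tab$mgrt <- mgrt_lat
  if (!is.null(logs)) names(logs) <- ids
  list(cohort = tab, sessions = logs)
}
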