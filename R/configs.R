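#' Race-model parameters for one participant
#'
#' Parameters of the independent horse-race model used to simulate stop-signal
#' task (SST) trials.  Go-process finishing times are ex-Gaussian (the standard
#' response-time model: a Gaussian stage of mean `mu_go` and SD `sigma_go` plus
#' an exponential tail of mean `tau_go`); the stop process is Gaussian,
#' truncated at zero.  On a stop trial with stop-signal delay `ssd`, a response
#' is emitted iff the sampled go time beats `ssd + stopRT`.
#'
#' Defaults are tuned so that a default cohort's median go RT, critical SSD and
#' SSRT land near 605, 310 and 295 ms, typical values for obese adults with
#' type 2 diabetes performing the task.
#'
#' @param mu_go,sigma_go,tau_go Ex-Gaussian go-process parameters (ms).
#'   `sigma_go` must be positive, `tau_go` non-negative.
#' @param mu_stop,sigma_stop Stop-process mean and SD (ms); the stop latency is
#'   Gaussian truncated at 0.
#' @param p_go_omission Probability that the go process never finishes
#'   (omission; a go error on go trials, a trivially successful stop on stop
#'   trials).
#' @param p_premature Probability of a premature response on a go trial
#'   (response during the fore-period, recorded with a negative RT and scored
#'   as a go error).
#' @return An object of class `race_params`.
#' @examples
#' race_params(mu_go = 450, sigma_go = 60, tau_go = 100, mu_stop = 200, sigma_stop = 30)
#' @export
race_params <- function(mu_go = 535, sigma_go = 60, tau_go = 100,
                        mu_stop = 290, sigma_stop = 30,
                        p_go_omission = 0.02, p_premature = 0.01) {
  chk_num(mu_go, "mu_go")
  chk_num(sigma_go, "sigma_go", lower = 0, strict = TRUE)
  chk_num(tau_go, "tau_go", lower = 0)
  chk_num(mu_stop, "mu_stop")
  chk_num(sigma_stop, "sigma_stop", lower = 0)
  chk_num(p_go_omission, "p_go_omission", 0, 1)
  chk_num(p_premature, "p_premature", 0, 1)
  structure(list(mu_go = mu_go, sigma_go = sigma_go, tau_go = tau_go,
                 mu_stop = mu_stop, sigma_stop = sigma_stop,
                 p_go_omission = p_go_omission, p_premature = p_premature),
            class = "race_params")
}

#' Stop-signal task structure
#'
#' Trial counts and timing of the SST session: each run mixes go and stop
#' trials 3:1 in pseudo-random order, a variable fore-period precedes the go
#' cue, responses are accepted for `max_rt` ms after the go cue, and trials
#' are separated by a fixed inter-trial interval.
#'
#' @param n_go_per_run,n_stop_per_run,n_runs Trial counts (defaults: 75 go and
#'   25 stop trials per run, 3 runs).
#' @param max_rt Response window after the go cue (ms); later responses are go
#'   errors.
#' @param iti Inter-trial interval (ms); carried in the config for
#'   completeness, it does not affect race outcomes.
#' @param foreperiod_min,foreperiod_max Fore-period range (ms) before the go
#'   cue.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_go_per_run = 75, n_stop_per_run = 25, n_runs = 3,
                        max_rt = 1000, iti = 2000,
                        foreperiod_min = 1000, foreperiod_max = 5000) {
  chk_num(n_go_per_run, "n_go_per_run", lower = 1)
  chk_num(n_stop_per_run, "n_stop_per_run", lower = 1)
  chk_num(n_runs, "n_runs", lower = 1)
  chk_num(max_rt, "max_rt", lower = 0, strict = TRUE)
  chk_num(iti, "iti", lower = 0, strict = TRUE)
  chk_num(foreperiod_min, "foreperiod_min", lower = 0, strict = TRUE)
  chk_num(foreperiod_max, "foreperiod_max", lower = foreperiod_min)
  structure(list(n_go_per_run = as.integer(n_go_per_run),
                 n_stop_per_run = as.integer(n_stop_per_run),
                 n_runs = as.integer(n_runs),
                 max_rt = max_rt, iti = iti,
                 foreperiod_min = foreperiod_min, foreperiod_max = foreperiod_max),
            class = "task_config")
}

#' Staircase (tracking) schedule for the stop-signal delay
#'
#' One-up/one-down tracking with a fixed step: the SSD increases by `step`
#' after a successful stop (making stopping harder) and decreases by `step`
#' after a stop error, clamped to `[ssd_min, ssd_max]`.  For a continuous go-RT
#' distribution this rule converges on the delay with 50% stop success, i.e.
#' the critical SSD.
#'
#' @param initial_ssd Starting SSD (ms), within `[ssd_min, ssd_max]`.
#' @param step Step size (ms), strictly positive.
#' @param ssd_min,ssd_max Clamp bounds (ms).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(initial_ssd = 200, step = 50, ssd_min = 0, ssd_max = 900) {
  chk_num(ssd_min, "ssd_min", lower = 0)
  chk_num(ssd_max, "ssd_max", lower = ssd_min)
  chk_num(step, "step", lower = 0, strict = TRUE)
  chk_num(initial_ssd, "initial_ssd", lower = ssd_min, upper = ssd_max)
  structure(list(initial_ssd = initial_ssd, step = step,
                 ssd_min = ssd_min, ssd_max = ssd_max),
            class = "staircase_config")
}

#' Synthetic cohort configuration
#'
#' Configuration of the synthetic participant cohort.  Metabolic and
#' demographic covariates are drawn to mimic an obese type-2-diabetes study
#' sample: HOMA-IR log-normal (median ~6.7, quartiles ~5/10), BMI normal
#' 37 +/- 4.5 kg/m2, age normal 47 +/- 7 truncated to 31-60 years, fasting
#' glucose normal 133 +/- 41 mg/dl (floored), metformin dose sampled from
#' 0-2500 mg in 500 mg increments, and fasting insulin back-computed so that
#' glucose x insulin / 405 reproduces the drawn HOMA-IR exactly.
#'
#' The causal structure is a configurable single-mediator chain: the ROI
#' activation contrast is `M = path_a * HOMA-IR + N(0, noise_sd_m)` and the
#' participant's expected median go RT is
#' `mgrt_baseline + path_b * M + path_c_prime * HOMA-IR + N(0, noise_sd_y)`.
#'
#' @param n_participants Cohort size (>= 3).
#' @param homa_meanlog,homa_sdlog Log-normal parameters of HOMA-IR.
#' @param bmi_mean,bmi_sd Normal parameters of BMI (kg/m2).
#' @param age_mean,age_sd,age_range Normal parameters of age (years) and the
#'   truncation range.
#' @param p_male Probability of `sex == 1` (male).
#' @param metformin_levels Candidate daily metformin doses (mg), sampled
#'   uniformly.
#' @param glucose_mean,glucose_sd,glucose_min Normal parameters of fasting
#'   glucose (mg/dl) and its floor.
#' @param path_a Effect of HOMA-IR on the ROI contrast (activation units per
#'   HOMA-IR unit).
#' @param path_b Effect of the ROI contrast on median go RT (ms per activation
#'   unit).
#' @param path_c_prime Direct effect of HOMA-IR on median go RT (ms per
#'   HOMA-IR unit).
#' @param noise_sd_m,noise_sd_y Residual SDs of the mediator (activation
#'   units) and of the expected median go RT (ms).
#' @param mgrt_baseline Intercept of the expected median go RT (ms); the
#'   default puts the default cohort's mean mGRT near 605 ms.
#' @param roi_name Column name used for the ROI activation contrast.
#' @param seed Integer seed; the cohort is bit-reproducible from it, and each
#'   participant gets an RNG stream derived from `(seed, participant index)`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 47,
                          homa_meanlog = log(6.7), homa_sdlog = 0.52,
                          bmi_mean = 37, bmi_sd = 4.5,
                          age_mean = 47, age_sd = 7, age_range = c(31, 60),
                          p_male = 0.4,
                          metformin_levels = seq(0, 2500, by = 500),
                          glucose_mean = 133, glucose_sd = 41, glucose_min = 70,
                          path_a = 0.5, path_b = -40, path_c_prime = 0,
                          noise_sd_m = 1, noise_sd_y = 20,
                          mgrt_baseline = 760,
                          roi_name = "con_se_gt_ss_r_putamen",
                          seed = 1L) {
  chk_num(n_participants, "n_participants", lower = 3)
  chk_num(homa_sdlog, "homa_sdlog", lower = 0)
  chk_num(bmi_sd, "bmi_sd", lower = 0)
  chk_num(age_sd, "age_sd", lower = 0)
  chk_num(p_male, "p_male", 0, 1)
  chk_num(glucose_sd, "glucose_sd", lower = 0)
  chk_num(glucose_min, "glucose_min", lower = 0, strict = TRUE)
  chk_num(noise_sd_m, "noise_sd_m", lower = 0)
  chk_num(noise_sd_y, "noise_sd_y", lower = 0)
  chk_num(seed, "seed")
  if (!is.numeric(metformin_levels) || !length(metformin_levels))
    stop_validation("metformin_levels must be a non-empty numeric vector")
  structure(list(n_participants = as.integer(n_participants),
                 homa_meanlog = homa_meanlog, homa_sdlog = homa_sdlog,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 p_male = p_male, metformin_levels = metformin_levels,
                 glucose_mean = glucose_mean, glucose_sd = glucose_sd,
                 glucose_min = glucose_min,
                 path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
                 noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
                 mgrt_baseline = mgrt_baseline, roi_name = roi_name,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters (ms):\n")
  cat(sprintf("  go  ~ exGaussian(mu = %g, sigma = %g, tau = %g)\n",
              x$mu_go, x$sigma_go, x$tau_go))
  cat(sprintf("  stop ~ Normal(mu = %g, sd = %g), truncated at 0\n",
              x$mu_stop, x$sigma_stop))
  cat(sprintf("  P(go omission) = %g, P(premature) = %g\n",
              x$p_go_omission, x$p_premature))
  invisible(x)
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("SST task: %d runs x (%d go + %d stop), max RT %g ms, fore-period %g-%g ms\n",
              x$n_runs, x$n_go_per_run, x$n_stop_per_run, x$max_rt,
              x$foreperiod_min, x$foreperiod_max))
  invisible(x)
}

#' @export
print.staircase_config <- function(x, ...) {
  cat(sprintf("SSD staircase: start %g ms, step %g ms (1-up/1-down), clamp [%g, %g] ms\n",
              x$initial_ssd, x$step, x$ssd_min, x$ssd_max))
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort: n = %d, seed = %d\n", x$n_participants, x$seed))
  cat(sprintf("  mediation paths: a = %g, b = %g, c' = %g (noise SDs m = %g, y = %g)\n",
              x$path_a, x$path_b, x$path_c_prime, x$noise_sd_m, x$noise_sd_y))
  invisible(x)
}
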