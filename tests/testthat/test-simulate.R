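test_that("race kernel decides stop trials by the independent-race inequality", {
  # goRT 500 vs ssd 300 + stopRT 100: go loses, stop succeeds
  r <- sstmediate:::race_outcome(TRUE, go_rt = 500, stop_rt = 100, ssd = 300,
                                 max_rt = 1000)
  expect_identical(r$outcome, "SS")
  expect_identical(r$responded, 0L)
  expect_true(is.na(r$rt))
  # goRT 500 vs ssd 450 + stopRT 100: go wins, response escapes at 500 ms
  r <- sstmediate:::race_outcome(TRUE, 500, 100, 450, 1000)
  expect_identical(r$outcome, "SE")
  expect_identical(r$rt, 500)
  # go-trial outcomes: in-window success, late, absent, premature
  expect_identical(sstmediate:::race_outcome(FALSE, 700, 100, NA, 1000)$outcome, "GS")
  expect_identical(sstmediate:::race_outcome(FALSE, 1200, 100, NA, 1000)$outcome, "GE")
  expect_identical(sstmediate:::race_outcome(FALSE, 700, 100, NA, 1000,
                                             omitted = TRUE)$outcome, "GE")
  pr <- sstmediate:::race_outcome(FALSE, 700, 100, NA, 1000,
                                  premature = TRUE, pre_rt = -350)
  expect_identical(pr$outcome, "GE")
  expect_lt(pr$rt, 0)
})

test_that("simulate_trial validates stop-trial delays and labels outcomes", {
  p <- race_params()
  expect_error(simulate_trial(p, is_stop = TRUE, ssd = -5),
               class = "sst_validation_error")
  expect_error(simulate_trial(p, is_stop = TRUE, ssd = NA),
               class = "sst_validation_error")
  set.seed(1)
  tr <- simulate_trial(p, is_stop = TRUE, ssd = 250)
  expect_true(tr$outcome %in% c("SS", "SE"))
  expect_identical(tr$ssd_ms, 250)
  tg <- simulate_trial(p, is_stop = FALSE)
  expect_true(tg$outcome %in% c("GS", "GE"))
  expect_true(is.na(tg$ssd_ms))
})

test_that("Monte-Carlo stop-error probability matches the race integral", {
  p <- race_params(mu_go = 450, sigma_go = 60, tau_go = 100,
                   mu_stop = 200, sigma_stop = 30,
                   p_go_omission = 0, p_premature = 0)
  ssd <- 250
  n <- 1e5
  set.seed(42)
  go <- rexgauss(n, 450, 60, 100)
  stp <- 200 + 30 * rnorm(n)
  p_hat <- mean(go < ssd + stp)
  p_true <- race_respond_prob_oracle(ssd, 450, 60, 100, 200, 30)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
  # package closed form agrees with the numerical integral
  expect_equal(stop_respond_prob(ssd, p), p_true, tolerance = 1e-6)
  # and the closed-form critical delay agrees with the root of the integral
  expect_equal(cssd_true(p), cssd_true_oracle(450, 60, 100, 200, 30),
               tolerance = 1e-3)
})

test_that("sessions have the configured composition, order reproducibility, and config validation", {
  s <- simulate_session(race_params(), seed = 7)
  expect_identical(nrow(s), 300L)
  comp <- table(s$run, s$trial_type)
  expect_true(all(comp[, "go"] == 75))
  expect_true(all(comp[, "stop"] == 25))
  expect_true(all(is.na(s$ssd_ms[s$trial_type == "go"])))
  expect_true(all(!is.na(s$ssd_ms[s$trial_type == "stop"])))
  expect_true(all(is.na(s$rt_ms[s$responded == 0L])))
  # seeded determinism
  expect_identical(s, simulate_session(race_params(), seed = 7))
  expect_false(identical(s, simulate_session(race_params(), seed = 8)))
  # a zero staircase step is a config error
  expect_error(staircase_config(step = 0), class = "sst_validation_error")
  # fixed SSD schedule cycles instead of tracking
  sched <- c(100, 300, 500)
  sf <- simulate_session(race_params(), seed = 3, ssd_schedule = sched)
  expect_identical(sort(unique(sf$ssd_ms[sf$trial_type == "stop"])), sched)
})

test_that("the 1-up/1-down staircase converges on 50% stop success", {
  p <- race_params(mu_go = 450, sigma_go = 60, tau_go = 100,
                   mu_stop = 200, sigma_stop = 30,
                   p_go_omission = 0, p_premature = 0)
  tk <- task_config(n_go_per_run = 1, n_stop_per_run = 100, n_runs = 100)
  s <- simulate_session(p, tk, seed = 11)
  st <- s[s$trial_type == "stop", ]
  final_half <- st$outcome[(nrow(st) / 2 + 1):nrow(st)]
  expect_lt(abs(mean(final_half == "SS") - 0.5), 0.03)
})

test_that("go-omission rate in output matches the configured probability", {
  p <- race_params(p_go_omission = 0.08, p_premature = 0)
  tk <- task_config(n_go_per_run = 500, n_stop_per_run = 1, n_runs = 4)
  s <- simulate_session(p, tk, seed = 5)
  go <- s[s$trial_type == "go", ]
  rate <- mean(go$responded == 0L)
  se <- sqrt(0.08 * 0.92 / nrow(go))
  expect_lt(abs(rate - 0.08), 3.5 * se)
})

test_that("stop-error responses are faster than successful go responses", {
  # the escaping responses come from the fast tail of the go distribution
  for (sd in 1:20) {
    s <- simulate_session(race_params(), seed = 100 + sd)
    se_rt <- s$rt_ms[s$outcome == "SE"]
    gs_rt <- s$rt_ms[s$outcome == "GS"]
    if (length(se_rt) >= 20) expect_lt(mean(se_rt), mean(gs_rt))
  }
})

test_that("cohorts are reproducible and carry the configured causal structure", {
  cfg <- cohort_config(n_participants = 30, seed = 99)
  c1 <- simulate_cohort(cfg, sessions = "none")
  c2 <- simulate_cohort(cfg, sessions = "none")
  expect_identical(c1$cohort, c2$cohort)
  expect_null(c1$sessions)
  expect_named(c1$cohort,
               c("participant_id", "glucose_mgdl", "insulin_uUml", "bmi",
                 "age", "sex", "metformin_mg", "con_se_gt_ss_r_putamen", "mgrt"))
  # with both paths zeroed there is no HOMA-IR -> mGRT association
  null_cfg <- cohort_config(n_participants = 2000, path_a = 0,
                            path_c_prime = 0, seed = 12)
  cn <- add_homa_ir(simulate_cohort(null_cfg, sessions = "none")$cohort)
  expect_lt(abs(cor(cn$homa_ir, cn$mgrt)), 0.1)
})

test_that("OLS recovers the generator's a and b paths within 10%", {
  cfg <- cohort_config(n_participants = 500, path_a = 0.5, path_b = -40,
                       path_c_prime = 0, noise_sd_m = 0.3, noise_sd_y = 5,
                       seed = 21)
  cc <- add_homa_ir(simulate_cohort(cfg, sessions = "none")$cohort)
  a_hat <- coef(lm(con_se_gt_ss_r_putamen ~ homa_ir, cc))[2]
  b_hat <- coef(lm(mgrt ~ homa_ir + con_se_gt_ss_r_putamen, cc))[3]
  expect_lt(abs(a_hat - 0.5) / 0.5, 0.10)
  expect_lt(abs(b_hat - (-40)) / 40, 0.10)
})

test_that("full-session cohorts put the mediation structure into scored mGRT", {
  cfg <- cohort_config(n_participants = 20, seed = 4)
  sim <- simulate_cohort(cfg, sessions = "full")
  expect_length(sim$sessions, 20)
  expect_false("mgrt" %in% names(sim$cohort))
  behav <- score_cohort(sim$sessions)
  expect_identical(behav$participant_id, sim$cohort$participant_id)
  expect_true(all(is.finite(behav$mgrt)))
})
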