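test_that("path estimates: deterministic chain, oracle agreement, decomposition identity", {
  # M = 2X, Y = 3M: b is identified only through (documented) tiny jitter in M
  set.seed(10)
  x <- rnorm(50)
  d <- data.frame(x = x, m = 2 * x + rnorm(50, 0, 1e-6))
  d$y <- 3 * d$m
  p <- estimate_paths(d, "x", "m", "y")
  expect_equal(p$a, 2, tolerance = 1e-4)
  expect_equal(p$b, 3, tolerance = 1e-4)
  expect_equal(p$c, 6, tolerance = 1e-4)
  expect_equal(p$c_prime, 0, tolerance = 1e-3)
  expect_equal(p$indirect, 6, tolerance = 1e-3)
  # mediator unrelated to x: indirect near zero
  set.seed(11)
  d0 <- data.frame(x = rnorm(200), m = rnorm(200), y = rnorm(200))
  expect_lt(abs(estimate_paths(d0, "x", "m", "y")$indirect), 0.05)
})

test_that("paths equal the normal-equations oracle; c = c' + a*b to 1e-10", {
  d <- med_fixture()
  p <- estimate_paths(d, "x", "m", "y", covariates = "age")
  Xm <- cbind(1, d$x, d$age)
  Xy <- cbind(1, d$x, d$m, d$age)
  expect_equal(p$a, ols_oracle(Xm, d$m)[2], tolerance = 1e-10)
  expect_equal(p$b, ols_oracle(Xy, d$y)[3], tolerance = 1e-10)
  expect_equal(p$c_prime, ols_oracle(Xy, d$y)[2], tolerance = 1e-10)
  expect_equal(p$c, ols_oracle(Xm, d$y)[2], tolerance = 1e-10)
  expect_lt(abs(p$c - (p$c_prime + p$a * p$b)), 1e-10)
  # identity holds on arbitrary generated tables too
  for (sd in 1:10) {
    set.seed(sd)
    n <- 30
    dd <- data.frame(x = rlnorm(n), m = rnorm(n), y = rnorm(n), w = rnorm(n))
    pp <- estimate_paths(dd, "x", "m", "y", "w")
    expect_lt(abs(pp$c - (pp$c_prime + pp$a * pp$b)), 1e-10)
  }
})

test_that("bootstrap CIs are seed-reproducible and redraw accounting hard-fails on degenerate data", {
  d <- med_fixture()
  b1 <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 5)
  b2 <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$draws, b2$draws)
  b3 <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 6)
  expect_false(identical(b1$ci, b3$ci))
  # x nearly constant: most resamples lose its variance entirely
  dg <- data.frame(x = c(1, rep(0, 5)), m = rnorm(6), y = rnorm(6))
  expect_error(suppressWarnings(
    bootstrap_indirect(dg, "x", "m", "y", n_boot = 200, seed = 1)),
    regexp = "degenerate", class = "sst_validation_error")
})

test_that("BCa intervals are computable and bracket the percentile interval's ballpark", {
  d <- med_fixture()
  bp <- bootstrap_indirect(d, "x", "m", "y", n_boot = 2000, seed = 9)
  bb <- bootstrap_indirect(d, "x", "m", "y", n_boot = 2000, seed = 9,
                           ci_type = "bca")
  expect_true(all(is.finite(bb$ci)))
  expect_lt(bb$ci[1], bb$ci[2])
  expect_lt(abs(bb$ci[1] - bp$ci[1]) / diff(bp$ci), 0.5)
})

test_that("kappa-squared: zero indirect, unit interval, grid-oracle agreement", {
  # exactly orthogonal mediator: a = 0, so kappa^2 = 0 even though x -> y
  d0 <- data.frame(x = c(-2, -1, 0, 1, 2), m = c(1, -1, 0, -1, 1))
  d0$y <- d0$x
  expect_identical(kappa_squared(d0, "x", "m", "y")$kappa2, 0)
  # bounded on arbitrary tables
  for (sd in 1:15) {
    set.seed(300 + sd)
    n <- 40
    dd <- data.frame(x = rlnorm(n, 1, 0.5), m = rnorm(n), y = rnorm(n))
    dd$m <- dd$m + 0.3 * dd$x
    dd$y <- dd$y - 0.5 * dd$m + 0.2 * dd$x
    k <- kappa_squared(dd, "x", "m", "y")$kappa2
    expect_gte(k, 0); expect_lte(k, 1)
    expect_equal(k, kappa2_grid_oracle(dd$x, dd$m, dd$y), tolerance = 1e-3)
  }
  # zero variance is an explicit error
  dz <- data.frame(x = rep(1, 10), m = rnorm(10), y = rnorm(10))
  expect_error(kappa_squared(dz, "x", "m", "y"), class = "sst_validation_error")
})

test_that("kappa-squared shrinks as outcome noise grows, holding the paths", {
  k_low <- k_high <- numeric(100)
  for (r in 1:100) {
    lo <- simulate_cohort(cohort_config(n_participants = 100, noise_sd_y = 10,
                                        seed = 4000 + r), sessions = "none")$cohort
    hi <- simulate_cohort(cohort_config(n_participants = 100, noise_sd_y = 120,
                                        seed = 4000 + r), sessions = "none")$cohort
    lo <- add_homa_ir(lo); hi <- add_homa_ir(hi)
    k_low[r] <- kappa_squared(lo, "homa_ir", "con_se_gt_ss_r_putamen", "mgrt")$kappa2
    k_high[r] <- kappa_squared(hi, "homa_ir", "con_se_gt_ss_r_putamen", "mgrt")$kappa2
  }
  expect_gt(mean(k_low), mean(k_high))
})

test_that("evidence rule combines the CI zero-crossing with the kappa^2 threshold", {
  ev <- evidence_rule(list(indirect_ci = c(0.015, 0.46), kappa2 = 0.19))
  expect_true(ev$evidence)
  expect_match(ev$narrative, "evidence for mediation")
  expect_false(evidence_rule(list(indirect_ci = c(-0.1, 0.3), kappa2 = 0.25))$evidence)
  expect_false(evidence_rule(list(indirect_ci = c(0.05, 0.2), kappa2 = 0.08))$evidence)
  # negative indirect effects count when the interval is fully below zero
  expect_true(evidence_rule(list(indirect_ci = c(-0.5, -0.1), kappa2 = 0.3))$evidence)
})

test_that("mediate() assembles a coherent result object", {
  cc <- add_homa_ir(simulate_cohort(cohort_config(n_participants = 80, seed = 13),
                                    sessions = "none")$cohort)
  m <- mediate(cc, "homa_ir", "con_se_gt_ss_r_putamen", "mgrt",
               covariates = c("age", "sex", "metformin_mg"),
               n_boot = 1000, seed = 3)
  expect_s3_class(m, "sst_mediation")
  expect_equal(m$indirect, m$a * m$b, tolerance = 1e-12)
  expect_lt(abs(m$c - (m$c_prime + m$indirect)), 1e-10)
  expect_identical(length(m$indirect_ci), 2L)
  expect_true(m$kappa2 >= 0 && m$kappa2 <= 1)
  expect_identical(nrow(m$draws), 1000L)
  expect_type(m$evidence, "logical")
  expect_output(print(m), "kappa\\^2")
  # same seed, same result end to end
  m2 <- mediate(cc, "homa_ir", "con_se_gt_ss_r_putamen", "mgrt",
                covariates = c("age", "sex", "metformin_mg"),
                n_boot = 1000, seed = 3)
  expect_identical(m$indirect_ci, m2$indirect_ci)
  expect_identical(m$kappa2_ci, m2$kappa2_ci)
})

test_that("end-to-end pipeline detects the planted mediation and stays quiet under the null", {
  fire <- function(path_a, seed) {
    sim <- simulate_cohort(cohort_config(n_participants = 60, path_a = path_a,
                                         seed = seed), sessions = "full")
    behav <- score_cohort(sim$sessions)
    tab <- add_homa_ir(merge(sim$cohort, behav, by = "participant_id"))
    tab <- tab[tab$included, ]
    m <- mediate(tab, "homa_ir", "con_se_gt_ss_r_putamen", "mgrt",
                 n_boot = 1000, seed = seed, kappa_draws = FALSE)
    m$evidence
  }
  planted <- vapply(1:8, function(r) fire(0.5, 6000 + r), TRUE)
  null_runs <- vapply(1:8, function(r) fire(0, 6100 + r), TRUE)
  expect_gte(mean(planted), 7 / 8)
  expect_lte(sum(null_runs), 2)
})
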