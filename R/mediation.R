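# Simple mediation: OLS paths, percentile bootstrap, kappa-squared ----------

# Complete-case design matrices shared by every sub-model, so that the
# decomposition c = c' + a*b holds exactly on the common case set.
build_mediation_data <- function(data, x, m, y, covariates) {
  if (anyDuplicated(c(x, m, y))) stop_validation("x, m and y must be distinct columns")
  vars <- c(x, m, y, covariates)
  chk_cols(data, vars)
  d <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  covm <- if (length(covariates)) as.matrix(d[, covariates, drop = FALSE]) else NULL
  Xm <- cbind(1, d[[x]], covm)
  colnames(Xm) <- c("(Intercept)", x, covariates)
  Xy <- cbind(1, d[[x]], d[[m]], covm)
  colnames(Xy) <- c("(Intercept)", x, m, covariates)
  n_min <- max(ncol(Xy) + 2, 4)
  if (nrow(d) < n_min)
    stop_validation("too few complete cases (", nrow(d), ") for mediation")
  list(Xm = Xm, Xy = Xy, xv = d[[x]], mv = d[[m]], yv = d[[y]],
       covm = covm, n = nrow(d))
}

# .lm.fit coefficients come back in pivoted order; restore column order.
lmfit_coef <- function(fit, p) {
  co <- numeric(p)
  co[fit$pivot] <- fit$coefficients
  co
}

#' OLS path estimates for a simple mediation model
#'
#' Estimates the paths of the single-mediator chain X -> M -> Y with optional
#' covariates entering every sub-model identically: `a` from
#' `M ~ X + covariates`, `b` and the direct effect `c'` from
#' `Y ~ X + M + covariates`, and the total effect `c` from
#' `Y ~ X + covariates`, all on the same complete-case set, so that
#' `c = c' + a*b` holds to floating-point precision.  The indirect effect is
#' `a*b`.  Sobel's normal-theory z for the indirect effect is included as a
#' diagnostic only; inference should use the bootstrap.
#'
#' @param data Data frame.
#' @param x,m,y Column names of the predictor, mediator and outcome.
#' @param covariates Character vector of covariate columns.
#' @return List with `a`, `b`, `c`, `c_prime` (each with `*_se`), `indirect`,
#'   `sobel_z`, `sobel_p`, `n`.
#' @export
estimate_paths <- function(data, x, m, y, covariates = character()) {
  md <- build_mediation_data(data, x, m, y, covariates)
  fm <- ols_qr(md$Xm, md$mv)                       # M ~ X + covs
  fy <- ols_qr(md$Xy, md$yv)                       # Y ~ X + M + covs
  fc <- ols_qr(md$Xm, md$yv)                       # Y ~ X + covs (same design)
  a <- fm$coef[2]; a_se <- fm$se[2]
  b <- fy$coef[3]; b_se <- fy$se[3]
  c_prime <- fy$coef[2]; c_prime_se <- fy$se[2]
  cc <- fc$coef[2]; c_se <- fc$se[2]
  sobel_se <- sqrt(b^2 * a_se^2 + a^2 * b_se^2)
  sobel_z <- if (sobel_se > 0) a * b / sobel_se else NA_real_
  list(a = a, a_se = a_se, b = b, b_se = b_se,
       c = cc, c_se = c_se, c_prime = c_prime, c_prime_se = c_prime_se,
       indirect = a * b,
       sobel_z = sobel_z,
       sobel_p = if (is.na(sobel_z)) NA_real_ else 2 * pnorm(-abs(sobel_z)),
       n = md$n)
}

# kappa^2 on (optionally covariate-residualized) vectors.  Preacher-Kelley
# construction: the observed indirect effect as a fraction of the largest
# indirect effect attainable under the sample variances and the observed
# X-Y correlation, with each path maximized to its positive-semidefiniteness
# boundary (sign-consistently) while the other correlations are held at
# their observed values.
kappa2_point <- function(xv, mv, yv, covm = NULL) {
  if (!is.null(covm)) {
    C <- cbind(1, covm)
    xv <- .lm.fit(C, xv)$residuals
    mv <- .lm.fit(C, mv)$residuals
    yv <- .lm.fit(C, yv)$residuals
  }
  sx <- sd(xv); sm <- sd(mv); sy <- sd(yv)
  if (sx == 0 || sm == 0 || sy == 0)
    stop_validation("kappa-squared undefined: zero variance in x, m or y")
  rxm <- cor(xv, mv); rxy <- cor(xv, yv); rmy <- cor(mv, yv)
  if (1 - rxm^2 < 1e-12)
    stop_validation("kappa-squared undefined: mediator collinear with predictor")
  a <- rxm * sm / sx
  b <- (rmy - rxm * rxy) / (1 - rxm^2) * sy / sm
  if (a == 0 || b == 0) return(0)
  if (1 - rxy^2 < 1e-12)
    stop_validation("kappa-squared undefined: degenerate correlation structure")
  # largest |a|: r_XM at the PSD boundary given observed r_MY, r_XY
  a_max <- (rmy * rxy + sign(a) * sqrt((1 - rmy^2) * (1 - rxy^2))) * sm / sx
  # largest |b|: r_MY at the PSD boundary given observed r_XM, r_XY
  b_max <- sign(b) * sqrt((1 - rxy^2) / (1 - rxm^2)) * sy / sm
  denom <- abs(a_max * b_max)
  if (denom == 0) return(NA_real_)
  min(abs(a * b) / denom, 1)
}

#' Kappa-squared mediation effect size
#'
#' The ratio of the observed indirect effect to the maximum indirect effect
#' attainable given the sample variances of X, M, Y and the observed X-Y
#' correlation, subject to the implied 3 x 3 correlation matrix remaining
#' positive semidefinite (the Preacher-Kelley construction).  Each path is
#' maximized to its sign-consistent admissibility boundary with the remaining
#' observed correlations held fixed, which keeps the maximum finite and
#' kappa^2 in `[0, 1]`.  With covariates, X, M and Y are first residualized
#' on them (with intercept).
#'
#' @param data Data frame.
#' @param x,m,y,covariates As in [estimate_paths()].
#' @param boot_draws Optional data frame of bootstrap draws (from
#'   [bootstrap_indirect()] with `kappa_draws = TRUE`) used for a percentile
#'   CI.
#' @param ci_level CI level for the bootstrap interval.
#' @return List with `kappa2` and, when draws are supplied, `kappa2_ci`.
#' @export
kappa_squared <- function(data, x, m, y, covariates = character(),
                          boot_draws = NULL, ci_level = 0.95) {
  md <- build_mediation_data(data, x, m, y, covariates)
  k2 <- kappa2_point(md$xv, md$mv, md$yv, md$covm)
  out <- list(kappa2 = k2)
  if (!is.null(boot_draws)) {
    if (is.null(boot_draws$kappa2))
      stop_validation("boot_draws has no kappa2 column; rerun with kappa_draws = TRUE")
    alpha <- (1 - ci_level) / 2
    out$kappa2_ci <- unname(quantile(boot_draws$kappa2, c(alpha, 1 - alpha),
                                     na.rm = TRUE))
  }
  out
}

# Shared bootstrap engine: resamples rows, refits the two sub-models, and
# returns per-resample a, b, c', indirect (and kappa^2 when asked).
# Rank-deficient resamples are redrawn and counted; more than
# max_redraw_frac * n_boot redraws aborts.
boot_mediation_draws <- function(md, n_boot, kappa_draws = TRUE,
                                 max_redraw_frac = 0.1) {
  pm <- ncol(md$Xm); py <- ncol(md$Xy); n <- md$n
  a <- b <- cp <- k2 <- numeric(n_boot)
  redrawn <- 0L
  limit <- max_redraw_frac * n_boot
  for (bi in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      f1 <- .lm.fit(md$Xm[idx, , drop = FALSE], md$mv[idx])
      f2 <- .lm.fit(md$Xy[idx, , drop = FALSE], md$yv[idx])
      if (f1$rank == pm && f2$rank == py) break
      redrawn <- redrawn + 1L
      if (redrawn > limit)
        stop_validation("more than ", round(100 * max_redraw_frac),
                        "% of bootstrap resamples were rank-deficient; ",
                        "data too degenerate for resampling inference")
    }
    c1 <- lmfit_coef(f1, pm); c2 <- lmfit_coef(f2, py)
    a[bi] <- c1[2]; b[bi] <- c2[3]; cp[bi] <- c2[2]
    if (kappa_draws)
      k2[bi] <- tryCatch(
        kappa2_point(md$xv[idx], md$mv[idx], md$yv[idx],
                     if (is.null(md$covm)) NULL else md$covm[idx, , drop = FALSE]),
        error = function(e) NA_real_)
  }
  draws <- data.frame(a = a, b = b, c_prime = cp, indirect = a * b)
  if (kappa_draws) draws$kappa2 <- k2
  list(draws = draws, n_redrawn = redrawn)
}

boot_ci <- function(draws, observed, ci_level, type, jackknife = NULL) {
  alpha <- (1 - ci_level) / 2
  if (type == "percentile")
    return(unname(quantile(draws, c(alpha, 1 - alpha), na.rm = TRUE)))
  # BCa: bias correction from the draw distribution, acceleration from the
  # jackknife of the statistic.
  z0 <- qnorm((sum(draws < observed) + 0.5 * sum(draws == observed)) / length(draws))
  jm <- mean(jackknife)
  num <- sum((jm - jackknife)^3)
  den <- 6 * (sum((jm - jackknife)^2))^1.5
  acc <- if (den == 0) 0 else num / den
  zlo <- qnorm(alpha); zhi <- qnorm(1 - alpha)
  p_lo <- pnorm(z0 + (z0 + zlo) / (1 - acc * (z0 + zlo)))
  p_hi <- pnorm(z0 + (z0 + zhi) / (1 - acc * (z0 + zhi)))
  unname(quantile(draws, c(p_lo, p_hi), na.rm = TRUE))
}

#' Bootstrap confidence interval for the indirect effect
#'
#' Resamples participants (rows) with replacement, re-estimates the mediation
#' paths in each resample, and returns the percentile (default) or BCa
#' interval for the indirect effect `a*b`.  Resamples in which a sub-model is
#' rank-deficient are redrawn and counted; more than 10% redraws is a hard
#' failure.
#'
#' @param data Data frame.
#' @param x,m,y,covariates As in [estimate_paths()].
#' @param n_boot Number of resamples (default 5000; at least 1000 is
#'   recommended for reported CIs and fewer triggers a warning).
#' @param ci_level Interval level (default 0.95).
#' @param seed Optional seed; the same seed reproduces identical endpoints.
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @param kappa_draws Also compute kappa^2 per resample (needed for its CI).
#' @return List with `ci` (length-2), `draws` (data frame of per-resample
#'   a, b, c_prime, indirect, optionally kappa2), `n_redrawn`, `ci_level`,
#'   `ci_type`.
#' @export
bootstrap_indirect <- function(data, x, m, y, covariates = character(),
                               n_boot = 5000, ci_level = 0.95, seed = NULL,
                               ci_type = c("percentile", "bca"),
                               kappa_draws = FALSE) {
  ci_type <- match.arg(ci_type)
  chk_num(n_boot, "n_boot", lower = 1)
  chk_num(ci_level, "ci_level", 0, 1, strict = TRUE)
  if (n_boot < 1000)
    warning("n_boot < 1000: bootstrap CI endpoints will be noisy")
  if (!is.null(seed)) set.seed(seed)
  md <- build_mediation_data(data, x, m, y, covariates)
  bt <- boot_mediation_draws(md, n_boot, kappa_draws = kappa_draws)
  observed <- {
    fm <- ols_qr(md$Xm, md$mv); fy <- ols_qr(md$Xy, md$yv)
    fm$coef[2] * fy$coef[3]
  }
  jack <- NULL
  if (ci_type == "bca") {
    jack <- vapply(seq_len(md$n), function(i) {
      f1 <- .lm.fit(md$Xm[-i, , drop = FALSE], md$mv[-i])
      f2 <- .lm.fit(md$Xy[-i, , drop = FALSE], md$yv[-i])
      lmfit_coef(f1, ncol(md$Xm))[2] * lmfit_coef(f2, ncol(md$Xy))[3]
    }, 1.0)
  }
  list(ci = boot_ci(bt$draws$indirect, observed, ci_level, ci_type, jack),
       draws = bt$draws, n_redrawn = bt$n_redrawn,
       ci_level = ci_level, ci_type = ci_type)
}

#' Evidence rule for mediation
#'
#' Mediation is declared when the bootstrap confidence interval for the
#' indirect effect excludes zero AND the kappa-squared point estimate reaches
#' 0.1.
#'
#' @param result An `sst_mediation` object from [mediate()], or any list with
#'   `indirect_ci` (length-2) and `kappa2`.
#' @param kappa2_threshold Minimum kappa^2 (default 0.1).
#' @return List with `evidence` (flag) and `narrative` (one sentence).
#' @export
evidence_rule <- function(result, kappa2_threshold = 0.1) {
  ci <- result$indirect_ci
  k2 <- result$kappa2
  if (is.null(ci) || length(ci) != 2 || is.null(k2))
    stop_validation("result must carry indirect_ci (length 2) and kappa2")
  excl <- !is.na(ci[1]) && !is.na(ci[2]) && (ci[1] > 0 || ci[2] < 0)
  k_ok <- !is.na(k2) && k2 >= kappa2_threshold
  ev <- excl && k_ok
  narrative <- sprintf(
    "Indirect-effect CI [%.4g, %.4g] %s zero; kappa^2 = %.3g %s %.2g: %s.",
    ci[1], ci[2], if (excl) "excludes" else "includes",
    k2, if (k_ok) ">=" else "<", kappa2_threshold,
    if (ev) "evidence for mediation" else "no evidence for mediation")
  list(evidence = ev, narrative = narrative)
}

#' Bootstrapped simple mediation analysis
#'
#' One-call wrapper: OLS path estimates ([estimate_paths()]), percentile (or
#' BCa) bootstrap intervals for every path and the indirect effect,
#' kappa-squared with its bootstrap interval, and the evidence rule
#' (CI excludes zero and kappa^2 >= 0.1).
#'
#' @inheritParams bootstrap_indirect
#' @param kappa_draws Compute kappa^2 per resample (gives its CI; switch off
#'   to speed up large simulation studies).
#' @return An object of class `sst_mediation`: paths with SEs and bootstrap
#'   CIs, `indirect`, `indirect_ci`, `kappa2`, `kappa2_ci`, `evidence`,
#'   `narrative`, `sobel_z`, `sobel_p`, `n`, `n_boot`, `n_redrawn`, `draws`.
#' @export
mediate <- function(data, x, m, y, covariates = character(),
                    n_boot = 5000, ci_level = 0.95, seed = NULL,
                    ci_type = c("percentile", "bca"), kappa_draws = TRUE) {
  ci_type <- match.arg(ci_type)
  chk_num(n_boot, "n_boot", lower = 1)
  if (n_boot < 1000)
    warning("n_boot < 1000: bootstrap CI endpoints will be noisy")
  if (!is.null(seed)) set.seed(seed)
  md <- build_mediation_data(data, x, m, y, covariates)
  paths <- estimate_paths(data, x, m, y, covariates)
  bt <- boot_mediation_draws(md, n_boot, kappa_draws = kappa_draws)
  alpha <- (1 - ci_level) / 2
  qs <- function(v) unname(quantile(v, c(alpha, 1 - alpha), na.rm = TRUE))
  jack <- NULL
  if (ci_type == "bca") {
    jack <- vapply(seq_len(md$n), function(i) {
      f1 <- .lm.fit(md$Xm[-i, , drop = FALSE], md$mv[-i])
      f2 <- .lm.fit(md$Xy[-i, , drop = FALSE], md$yv[-i])
      lmfit_coef(f1, ncol(md$Xm))[2] * lmfit_coef(f2, ncol(md$Xy))[3]
    }, 1.0)
  }
  k2 <- kappa2_point(md$xv, md$mv, md$yv, md$covm)
  res <- structure(list(
    x = x, m = m, y = y, covariates = covariates,
    a = paths$a, a_se = paths$a_se, a_ci = qs(bt$draws$a),
    b = paths$b, b_se = paths$b_se, b_ci = qs(bt$draws$b),
    c = paths$c, c_se = paths$c_se,
    c_prime = paths$c_prime, c_prime_se = paths$c_prime_se,
    c_prime_ci = qs(bt$draws$c_prime),
    indirect = paths$indirect,
    indirect_ci = boot_ci(bt$draws$indirect, paths$indirect, ci_level,
                          ci_type, jack),
    kappa2 = k2,
    kappa2_ci = if (kappa_draws) qs(bt$draws$kappa2) else NULL,
    sobel_z = paths$sobel_z, sobel_p = paths$sobel_p,
    n = paths$n, n_boot = n_boot, n_redrawn = bt$n_redrawn,
    ci_level = ci_level, ci_type = ci_type, draws = bt$draws),
    class = "sst_mediation")
  ev <- evidence_rule(res)
  res$evidence <- ev$evidence
  res$narrative <- ev$narrative
  res
}

#' @export
print.sst_mediation <- function(x, ...) {
  ci <- function(v) sprintf("[%.4g, %.4g]", v[1], v[2])
  cat(sprintf("Mediation: %s -> %s -> %s", x$x, x$m, x$y))
  if (length(x$covariates))
    cat(sprintf("  (covariates: %s)", paste(x$covariates, collapse = ", ")))
  cat(sprintf("\n  n = %d, %d bootstrap resamples (%s CI, level %.2f)\n",
              x$n, x$n_boot, x$ci_type, x$ci_level))
  cat(sprintf("  a  = %10.4g (se %.4g)  %s\n", x$a, x$a_se, ci(x$a_ci)))
  cat(sprintf("  b  = %10.4g (se %.4g)  %s\n", x$b, x$b_se, ci(x$b_ci)))
  cat(sprintf("  c  = %10.4g (se %.4g)\n", x$c, x$c_se))
  cat(sprintf("  c' = %10.4g (se %.4g)  %s\n", x$c_prime, x$c_prime_se,
              ci(x$c_prime_ci)))
  cat(sprintf("  indirect a*b = %.4g  %s\n", x$indirect, ci(x$indirect_ci)))
  if (!is.null(x$kappa2_ci))
    cat(sprintf("  kappa^2 = %.3g  %s\n", x$kappa2, ci(x$kappa2_ci)))
  else cat(sprintf("  kappa^2 = %.3g\n", x$kappa2))
  cat(" ", x$narrative, "\n")
  invisible(x)
}
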