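# Per-participant SST performance measures -----------------------------------

#' Go-trial metrics
#'
#' Median go response time over successful go (GS) trials, the go response
#' rate, and a breakdown of go errors into premature (negative RT, i.e. a
#' press before the go cue), late (RT beyond the response window) and absent.
#'
#' @param log A session log (see [simulate_session()] for the schema).
#' @param max_rt Response window in ms used to classify late responses.
#' @return List with `mgrt`, `go_response_rate`, `n_go`, `n_gs`,
#'   `n_premature`, `n_late`, `n_absent`, and `mgrt_defined` (FALSE when there
#'   is no successful go trial to take a median over; `mgrt` is then `NA` and
#'   the participant cannot be scored).
#' @export
compute_go_metrics <- function(log, max_rt = 1000) {
  chk_cols(log, c("trial_type", "responded", "rt_ms", "outcome"), "session log")
  go <- log[log$trial_type == "go", , drop = FALSE]
  n_go <- nrow(go)
  if (!n_go) stop_validation("session log contains no go trials")
  gs_rt <- go$rt_ms[go$outcome == "GS"]
  defined <- length(gs_rt) > 0
  if (!defined)
    warning("no successful go trials: mGRT undefined, participant cannot be scored")
  resp <- go$responded == 1L
  list(mgrt = if (defined) median(gs_rt) else NA_real_,
       go_response_rate = length(gs_rt) / n_go,
       n_go = n_go, n_gs = length(gs_rt),
       n_premature = sum(resp & !is.na(go$rt_ms) & go$rt_ms < 0),
       n_late = sum(resp & !is.na(go$rt_ms) & go$rt_ms > max_rt),
       n_absent = sum(!resp),
       mgrt_defined = defined)
}

#' Construct an inhibition function from explicit bins
#'
#' Low-level constructor for the empirical inhibition function: the
#' probability of successfully stopping as a function of the stop-signal
#' delay.
#'
#' @param ssd Bin delays (ms), strictly increasing.
#' @param n_ss Stop-success counts per bin.
#' @param n Stop-trial counts per bin (each >= 1).
#' @return A data frame of class `inhibition_function` with columns `ssd`,
#'   `n_ss`, `n`, `p_ss`.
#' @export
as_inhibition_function <- function(ssd, n_ss, n) {
  if (length(ssd) != length(n) || length(n_ss) != length(n))
    stop_validation("ssd, n_ss and n must have equal length")
  if (any(n < 1)) stop_validation("each bin needs at least one trial")
  if (any(n_ss < 0 | n_ss > n)) stop_validation("n_ss must lie in [0, n]")
  o <- order(ssd)
  if (anyDuplicated(ssd)) stop_validation("bin delays must be distinct")
  structure(data.frame(ssd = ssd[o], n_ss = n_ss[o], n = n[o],
                       p_ss = n_ss[o] / n[o]),
            class = c("inhibition_function", "data.frame"))
}

#' Empirical inhibition function of a session
#'
#' Groups stop trials by stop-signal delay — exactly, or into bins of
#' `bin_width` ms for staircase data — and computes the stop-success
#' proportion per group.  Groups with fewer than `min_n` trials are merged
#' into their nearest neighbour (counts pooled, delay replaced by the pooled
#' trial-weighted mean).
#'
#' @param log A session log.
#' @param bin_width Optional bin width in ms; `NULL` groups exact SSD values.
#' @param min_n Minimum trials per group before merging.
#' @return An `inhibition_function` (see [as_inhibition_function()]).  A
#'   single distinct delay yields a one-bin function with a warning: it cannot
#'   support interpolation and signals use of the `"staircase_mean"` fallback.
#' @export
inhibition_function <- function(log, bin_width = NULL, min_n = 1) {
  chk_cols(log, c("trial_type", "ssd_ms", "outcome"), "session log")
  st <- log[log$trial_type == "stop" & !is.na(log$ssd_ms), , drop = FALSE]
  if (!nrow(st)) stop_validation("session log contains no stop trials with a delay")
  key <- if (is.null(bin_width)) st$ssd_ms else {
    chk_num(bin_width, "bin_width", lower = 0, strict = TRUE)
    floor(st$ssd_ms / bin_width) * bin_width + bin_width / 2
  }
  grp <- split(st$outcome == "SS", key)
  ssd <- as.numeric(names(grp))
  n <- vapply(grp, length, 1L)
  n_ss <- vapply(grp, sum, 1L)
  # merge under-filled groups into the nearest neighbour by delay
  while (length(n) > 1L && any(n < min_n)) {
    j <- which.min(n)
    d <- abs(ssd - ssd[j]); d[j] <- Inf
    k <- which.min(d)
    ssd[k] <- (ssd[k] * n[k] + ssd[j] * n[j]) / (n[k] + n[j])
    n[k] <- n[k] + n[j]; n_ss[k] <- n_ss[k] + n_ss[j]
    ssd <- ssd[-j]; n <- n[-j]; n_ss <- n_ss[-j]
  }
  if (length(ssd) < 2L)
    warning("single distinct SSD: inhibition function cannot support ",
            "interpolation; use the 'staircase_mean' estimator")
  as_inhibition_function(ssd, n_ss, n)
}

# Weighted pool-adjacent-violators for a non-increasing fit (classic PAVA on
# the negated series; blocks stay contiguous).  Returns regularized values.
pava_decreasing <- function(p, w) {
  val <- -p; wt <- w; cnt <- rep(1L, length(p))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-15) {
      pooled <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) / (wt[i] + wt[i + 1L])
      val[i] <- pooled
      wt[i] <- wt[i] + wt[i + 1L]
      cnt[i] <- cnt[i] + cnt[i + 1L]
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; cnt <- cnt[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  -rep(val, cnt)
}

#' Estimate the critical stop-signal delay
#'
#' The critical SSD (cSSD) is the delay at which half of go responses can be
#' successfully countermanded.  Three estimators are available:
#'
#' * `"interpolate"` (default): the inhibition function is first regularized
#'   to be non-increasing in SSD by trial-count-weighted
#'   pool-adjacent-violators, then the 50% point is linearly interpolated
#'   between the adjacent delays bracketing it (first crossing from short
#'   delays if the regularized curve is flat at 0.5).
#' * `"logistic"`: a two-parameter logistic is fit to the per-bin
#'   success/failure counts by (weighted) maximum likelihood via
#'   [stats::glm()]; the cSSD is its 50% point `-intercept/slope`.
#' * `"staircase_mean"`: the mean SSD over stop trials after discarding the
#'   first `burn_in` stop trials; valid for one-up/one-down tracking, which
#'   hovers around the 50% point.
#'
#' @param x An `inhibition_function`, or a session log (from which the
#'   inhibition function is built for the first two methods; required for
#'   `"staircase_mean"`).
#' @param method Estimator; see above.
#' @param bin_width,min_n Passed to [inhibition_function()] when `x` is a log.
#' @param burn_in Stop trials discarded by `"staircase_mean"`.
#' @return The cSSD in ms, or `NA` with a warning when the regularized
#'   inhibition function never crosses 0.5 (such participants are excluded
#'   from cSSD-dependent analyses).
#' @export
estimate_cssd <- function(x, method = c("interpolate", "logistic", "staircase_mean"),
                          bin_width = NULL, min_n = 1, burn_in = 10) {
  method <- match.arg(method)
  is_log <- is.data.frame(x) && "trial_type" %in% names(x)
  if (method == "staircase_mean") {
    if (!is_log)
      stop_validation("'staircase_mean' needs the session log (SSD trace)")
    ssd <- x$ssd_ms[x$trial_type == "stop" & !is.na(x$ssd_ms)]
    if (length(ssd) <= burn_in)
      stop_validation("not enough stop trials beyond the burn-in")
    return(mean(ssd[-seq_len(burn_in)]))
  }
  inh <- if (is_log) suppressWarnings(inhibition_function(x, bin_width, min_n))
         else if (inherits(x, "inhibition_function")) x
         else stop_validation("x must be a session log or an inhibition_function")

  if (method == "logistic") {
    if (nrow(inh) < 2L)
      stop_validation("logistic estimator needs at least two distinct SSD bins")
    fit <- glm(cbind(n_ss, n - n_ss) ~ ssd, family = binomial(), data = inh)
    cf <- coef(fit)
    if (!is.finite(cf[2]) || cf[2] >= 0) {
      warning("logistic fit has no decreasing 50% crossing; cSSD undefined")
      return(NA_real_)
    }
    return(unname(-cf[1] / cf[2]))
  }

  # interpolate
  p <- pava_decreasing(inh$p_ss, inh$n)
  if (any(abs(p - 0.5) < 1e-12))
    return(inh$ssd[which(abs(p - 0.5) < 1e-12)[1]])
  if (p[1] < 0.5 || p[length(p)] > 0.5) {
    warning("inhibition function never crosses 0.5: no-crossing condition, ",
            "cSSD undefined for this participant")
    return(NA_real_)
  }
  j <- which(p < 0.5)[1]          # first bin below one half
  i <- j - 1L
  inh$ssd[i] + (p[i] - 0.5) / (p[i] - p[j]) * (inh$ssd[j] - inh$ssd[i])
}

#' Stop-signal response time
#'
#' The latency of the covert stopping process, defined as the median go
#' response time minus the critical stop-signal delay: `SSRT = mGRT - cSSD`.
#' A negative value flags estimation failure and is returned (not clamped)
#' with a warning.
#'
#' @param mgrt Median go RT (ms).
#' @param cssd Critical SSD (ms).
#' @return `mgrt - cssd`, vectorized.
#' @examples
#' compute_ssrt(605, 310)  # 295 ms
#' @export
compute_ssrt <- function(mgrt, cssd) {
  out <- mgrt - cssd
  if (any(!is.na(out) & out < 0))
    warning("negative SSRT: mGRT below cSSD suggests estimation failure")
  out
}

#' Race-model consistency check
#'
#' Under the independent race, responses that escape inhibition are drawn from
#' the fast part of the go distribution, so the mean stop-error RT must fall
#' below the median go RT.  With no stop-error trial the check cannot be
#' falsified and passes with a warning.
#'
#' @param log A session log.
#' @param mgrt The participant's median go RT (ms).
#' @return Logical flag.
#' @export
race_model_check <- function(log, mgrt) {
  chk_cols(log, c("trial_type", "outcome", "rt_ms"), "session log")
  se_rt <- log$rt_ms[log$trial_type == "stop" & log$outcome == "SE" & !is.na(log$rt_ms)]
  if (!length(se_rt)) {
    warning("no stop-error trials: race-model check indeterminate, passing")
    return(TRUE)
  }
  mean(se_rt) < mgrt
}

#' Performance-based inclusion filters
#'
#' A participant's SST data are included iff successful inhibition occurred on
#' 25-75% of stop trials (closed interval), the go response rate exceeded 60%
#' (strict), and the race-model check passed.
#'
#' @param summary A list or one-row data frame with `stop_success_rate`,
#'   `go_response_rate` and `race_model_ok`.
#' @return List with `included` (flag) and `reasons` (character vector naming
#'   each failed criterion; empty when included).
#' @export
apply_inclusion_filters <- function(summary) {
  ssr <- summary$stop_success_rate
  grr <- summary$go_response_rate
  ok <- isTRUE(as.logical(summary$race_model_ok))
  reasons <- character()
  if (is.na(ssr) || ssr < 0.25 || ssr > 0.75)
    reasons <- c(reasons, "stop-success outside 25-75%")
  if (is.na(grr) || grr <= 0.60)
    reasons <- c(reasons, "go response rate not above 60%")
  if (!ok)
    reasons <- c(reasons, "race-model violation (mean SE RT >= mGRT)")
  list(included = length(reasons) == 0L, reasons = reasons)
}

#' Score one SST session
#'
#' Computes the full per-participant behavioural summary: mGRT, cSSD, SSRT,
#' go response and stop-success rates, mean stop-error RT, trial counts, the
#' race-model flag, and the inclusion decision with its reasons.  The
#' identity `ssrt = mgrt - cssd` holds exactly.  A participant whose
#' inhibition function never crosses 0.5 gets `cssd = NA` (and hence
#' `ssrt = NA`) and drops out of cSSD-dependent analyses by listwise deletion;
#' the inclusion flag itself reflects only the performance thresholds and the
#' race-model check.
#'
#' @param log A session log.
#' @param method cSSD estimator, passed to [estimate_cssd()].
#' @param max_rt Response window (ms), passed to [compute_go_metrics()].
#' @param ... Further arguments to [estimate_cssd()].
#' @return One-row data frame (a `BehavioralSummary`).
#' @export
score_session <- function(log, method = "interpolate", max_rt = 1000, ...) {
  gm <- compute_go_metrics(log, max_rt = max_rt)
  st <- log[log$trial_type == "stop", , drop = FALSE]
  n_stop <- nrow(st)
  n_ss <- sum(st$outcome == "SS")
  n_se <- sum(st$outcome == "SE")
  se_rt <- st$rt_ms[st$outcome == "SE" & !is.na(st$rt_ms)]
  cssd <- if (n_stop) estimate_cssd(log, method = method, ...) else NA_real_
  ssrt <- if (!is.na(cssd) && gm$mgrt_defined) compute_ssrt(gm$mgrt, cssd) else NA_real_
  race_ok <- if (gm$mgrt_defined)
    suppressWarnings(race_model_check(log, gm$mgrt)) else NA
  out <- data.frame(participant_id = log$participant_id[1],
                    mgrt = gm$mgrt, cssd = cssd, ssrt = ssrt,
                    go_response_rate = gm$go_response_rate,
                    stop_success_rate = if (n_stop) n_ss / n_stop else NA_real_,
                    mean_se_rt = if (length(se_rt)) mean(se_rt) else NA_real_,
                    n_go = gm$n_go, n_stop = n_stop, n_ss = n_ss, n_se = n_se,
                    race_model_ok = isTRUE(race_ok),
                    stringsAsFactors = FALSE)
  filt <- apply_inclusion_filters(out)
  out$included <- filt$included
  out$exclusion_reasons <- paste(filt$reasons, collapse = "; ")
  out
}

#' Score every session of a cohort
#'
#' @param sessions Named list of session logs (e.g. from
#'   [simulate_cohort()]).
#' @param method,... Passed to [score_session()].
#' @return Data frame with one `BehavioralSummary` row per participant.
#' @export
score_cohort <- function(sessions, method = "interpolate", ...) {
  if (!length(sessions)) stop_validation("no sessions to score")
  rows <- lapply(sessions, function(l)
    suppressWarnings(score_session(l, method = method, ...)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
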