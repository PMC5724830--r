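# Ex-Gaussian helpers and the race integral ---------------------------------

#' Ex-Gaussian random deviates
#'
#' Sum of a Gaussian and an independent exponential, the conventional
#' response-time model.  `tau = 0` degenerates to the Gaussian.
#'
#' @param n Number of deviates.
#' @param mu,sigma Gaussian component mean and SD.
#' @param tau Mean of the exponential component (>= 0).
#' @return Numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  out <- rnorm(n, mu, sigma)
  if (tau > 0) out <- out + rexp(n, rate = 1 / tau)
  out
}

#' Ex-Gaussian distribution function
#'
#' Numerically stable CDF of the ex-Gaussian distribution; the exponential
#' cross-term is evaluated on the log scale so that far-left tails do not
#' overflow.
#'
#' @param q Quantiles.
#' @param mu,sigma Gaussian component mean and SD (`sigma > 0`).
#' @param tau Mean of the exponential component (>= 0; 0 gives the Gaussian
#'   CDF).
#' @return `P(T <= q)`.
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  if (sigma <= 0) stop_validation("sigma must be positive")
  if (tau < 0) stop_validation("tau must be non-negative")
  z <- (q - mu) / sigma
  if (tau == 0) return(pnorm(z))
  # F(q) = Phi(z) - exp(sigma^2/(2 tau^2) - (q - mu)/tau) * Phi(z - sigma/tau)
  lg <- sigma^2 / (2 * tau^2) - (q - mu) / tau +
    pnorm(z - sigma / tau, log.p = TRUE)
  p <- pnorm(z) - exp(lg)
  pmin(pmax(p, 0), 1)
}

# Median of the ex-Gaussian go distribution (root of the CDF at 1/2).
exg_median <- function(mu, sigma, tau) {
  lo <- mu - 8 * sigma
  hi <- mu + 8 * (sigma + tau) + 10
  uniroot(function(q) pexgauss(q, mu, sigma, tau) - 0.5, c(lo, hi),
          tol = 1e-10)$root
}

#' Probability of responding on a stop trial
#'
#' Under the independent race, a response is emitted on a stop trial iff the
#' go process finishes before `ssd + stopRT` (and the go process was not
#' omitted).  Since goRT - stopRT is itself ex-Gaussian with mean
#' `mu_go - mu_stop`, SD `sqrt(sigma_go^2 + sigma_stop^2)` and the same tail,
#' the probability has a closed form.  The truncation of the stop process at 0
#' and the `max_rt` response window are ignored here; both are negligible for
#' realistic parameters (stop latencies many SDs above zero, go tail mass
#' beyond the window well under 1%).
#'
#' @param ssd Stop-signal delay(s), ms.
#' @param params A [race_params()] object.
#' @return `P(response | stop trial at ssd)`, same length as `ssd`.
#' @export
stop_respond_prob <- function(ssd, params) {
  (1 - params$p_go_omission) *
    pexgauss(ssd, params$mu_go - params$mu_stop,
             sqrt(params$sigma_go^2 + params$sigma_stop^2), params$tau_go)
}

#' True critical stop-signal delay of a race model
#'
#' The delay at which exactly half of go responses are countermanded, i.e. the
#' root of `P(response | ssd) = 0.5` with [stop_respond_prob()].  This is the
#' quantity the empirical cSSD estimators target.
#'
#' @param params A [race_params()] object.  If `p_go_omission >= 0.5` the
#'   response probability never reaches one half and the delay is undefined.
#' @return The critical SSD in ms.
#' @export
cssd_true <- function(params) {
  if (params$p_go_omission >= 0.5)
    stop_validation("response probability never reaches 0.5 (p_go_omission >= 0.5)")
  mu_d <- params$mu_go - params$mu_stop
  sd_d <- sqrt(params$sigma_go^2 + params$sigma_stop^2)
  lo <- mu_d - 10 * sd_d
  hi <- mu_d + 10 * (sd_d + params$tau_go) + 10
  uniroot(function(s) stop_respond_prob(s, params) - 0.5, c(lo, hi),
          tol = 1e-8)$root
}

# Gaussian truncated at zero, via inverse-CDF so each deviate consumes exactly
# one uniform (keeps per-participant streams aligned).
rtruncnorm0 <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  p0 <- pnorm(0, mu, sigma)
  qnorm(p0 + runif(n) * (1 - p0), mu, sigma)
}
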