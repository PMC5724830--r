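# Independent oracles and fixed fixtures used across the suite.

# Normal-equations OLS (independent of the package's QR route).
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# Ex-Gaussian density written out directly (independent of pexgauss).
dexg_oracle <- function(t, mu, sigma, tau) {
  if (tau == 0) return(dnorm(t, mu, sigma))
  (1 / tau) * exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
    pnorm((t - mu) / sigma - sigma / tau)
}

# Race integral by numerical integration: P(response | stop trial at ssd)
# = integral of f_go(t) * P(stopRT > t - ssd) dt.
race_respond_prob_oracle <- function(ssd, mu_go, sigma_go, tau_go,
                                     mu_stop, sigma_stop) {
  integrate(function(t)
    dexg_oracle(t, mu_go, sigma_go, tau_go) *
      pnorm((t - ssd - mu_stop) / sigma_stop, lower.tail = FALSE),
    lower = mu_go - 10 * sigma_go,
    upper = mu_go + 12 * (sigma_go + tau_go),
    rel.tol = 1e-9)$value
}

cssd_true_oracle <- function(mu_go, sigma_go, tau_go, mu_stop, sigma_stop) {
  uniroot(function(s)
    race_respond_prob_oracle(s, mu_go, sigma_go, tau_go, mu_stop, sigma_stop) - 0.5,
    c(mu_go - mu_stop - 600, mu_go - mu_stop + 600 + 6 * tau_go),
    tol = 1e-6)$root
}

# Brute-force kappa^2: grid search of each sign-consistent PSD boundary
# (coarse grid, then local refinement), on already-residualized vectors.
kappa2_grid_oracle <- function(xv, mv, yv, n_grid = 2000) {
  sx <- sd(xv); sm <- sd(mv); sy <- sd(yv)
  rxm <- cor(xv, mv); rxy <- cor(xv, yv); rmy <- cor(mv, yv)
  a <- rxm * sm / sx
  b <- (rmy - rxm * rxy) / (1 - rxm^2) * sy / sm
  if (a == 0 || b == 0) return(0)
  psd <- function(r12, r13, r23)
    1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23 >= -1e-12
  grid_max <- function(f, keep, lo = -1, hi = 1) {
    g <- seq(lo, hi, length.out = n_grid)
    v <- vapply(g, f, 1.0)
    ok <- vapply(g, keep, TRUE)
    v[!ok] <- -Inf
    i <- which.max(v)
    step <- g[2] - g[1]
    g2 <- seq(max(lo, g[i] - 2 * step), min(hi, g[i] + 2 * step),
              length.out = n_grid)
    v2 <- vapply(g2, f, 1.0)
    ok2 <- vapply(g2, keep, TRUE)
    v2[!ok2] <- -Inf
    max(v2)
  }
  a_max <- grid_max(function(r) abs(r * sm / sx),
                    function(r) psd(r, rxy, rmy) && sign(r) == sign(a))
  b_max <- grid_max(function(r) abs((r - rxm * rxy) / (1 - rxm^2) * sy / sm),
                    function(r) psd(rxm, rxy, r) &&
                      sign((r - rxm * rxy)) == sign(b * (1 - rxm^2)))
  abs(a * b) / (a_max * b_max)
}

# Fixed 8-row worked table for the regression oracle.
reg_fixture <- function() {
  data.frame(
    y  = c(2.3, 0.8, 1.9, 4.2, -1.1, 0.6, 3.5, -0.2),
    x1 = c(1.2, -0.4, 0.7, 2.1, -1.5, 0.3, 1.8, -0.9),
    x2 = c(0.5, 1.1, -0.7, 0.2, 0.9, -1.3, 0.4, 1.6),
    z  = c(3, 1, 4, 2, 5, 3, 2, 4))
}

# Fixed 12-row mediation table (x ~ insulin-resistance scale, m ~ activation
# contrast, y ~ go speed in ms, age as covariate).
med_fixture <- function() {
  data.frame(
    x   = c(2.5, 6.7, 8.1, 3.9, 10.2, 5.5, 7.3, 12.8, 4.4, 9.0, 6.1, 11.5),
    m   = c(1.8, 3.1, 4.5, 2.2, 5.9, 2.7, 3.6, 6.8, 2.0, 4.9, 3.3, 6.1),
    y   = c(640, 590, 545, 615, 500, 600, 570, 455, 625, 520, 585, 470),
    age = c(41, 48, 52, 39, 55, 44, 47, 58, 42, 50, 46, 53))
}

# Minimal hand-built session log.
mk_log <- function(trial_type, rt, outcome, ssd = NA_real_, responded = NULL,
                   id = "T01") {
  n <- length(trial_type)
  data.frame(participant_id = id, run = 1L, trial_index = seq_len(n),
             trial_type = trial_type, foreperiod_ms = 2000,
             ssd_ms = rep_len(ssd, n),
             responded = if (is.null(responded)) as.integer(!is.na(rt)) else responded,
             rt_ms = rt, outcome = outcome, stringsAsFactors = FALSE)
}
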