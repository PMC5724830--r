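# Covariate-adjusted regression screens --------------------------------------

# QR-based OLS on an explicit design matrix; returns what the mediation and
# regression layers need without formula overhead.
ols_qr <- function(X, y) {
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p)]]
    stop_validation("rank-deficient design; collinear column(s): ",
                    paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- nrow(X) - p
  rss <- sum(res^2)
  sigma2 <- rss / df
  # qr.R is in pivoted column order; map the (X'X)^-1 diagonal back
  d_inv <- numeric(p)
  d_inv[qx$pivot] <- diag(chol2inv(qr.R(qx)))
  se <- sqrt(pmax(d_inv, 0) * sigma2)
  list(coef = as.numeric(beta), se = se, df = df, rss = rss,
       residuals = as.numeric(res))
}

#' Partial correlation from a t statistic
#'
#' Converts a per-term t statistic of a multiple regression into the partial
#' correlation between that term and the outcome given the other terms:
#' `r = t / sqrt(t^2 + df)`.  This is the conventional rule for reporting a
#' per-predictor r from a covariate-adjusted model.  Infinite `t` (a perfect
#' fit) maps to `r = +/-1`.
#'
#' @param t t statistic(s).
#' @param df Residual degrees of freedom (>= 1).
#' @return Partial correlation(s) in `[-1, 1]`, with `sign(r) = sign(t)`.
#' @export
partial_r_from_t <- function(t, df) {
  if (any(df < 1)) stop_validation("df must be >= 1")
  ifelse(is.infinite(t), sign(t), t / sqrt(t^2 + df))
}

#' Covariate-adjusted multiple regression
#'
#' Ordinary least squares with an intercept, listwise deletion of incomplete
#' rows, per-term t and two-sided p from the residual-df t distribution, the
#' partial correlation via [partial_r_from_t()], and both the full-model R^2
#' and each term's increment `delta_r2` (the drop in R^2 when that column is
#' removed).  Predictors and covariates enter identically; the split is kept
#' for reporting.  Interactions among predictors can be requested but are off
#' by default.
#'
#' @param data Data frame.
#' @param outcome Outcome column name; must not appear among the right-hand
#'   side terms.
#' @param predictors Character vector of predictor columns.
#' @param covariates Character vector of covariate columns.
#' @param include_interactions Add pairwise interactions among `predictors`.
#' @return An object of class `sst_regression`: list with `outcome`, `terms`
#'   (data frame: term, role, estimate, se, t, p, partial_r, delta_r2),
#'   `r_squared`, `adj_r_squared`, `df_residual`, `n`.
#' @export
fit_regression <- function(data, outcome, predictors, covariates = character(),
                           include_interactions = FALSE) {
  rhs <- c(predictors, covariates)
  if (!length(rhs)) stop_validation("at least one predictor is required")
  if (outcome %in% rhs) stop_validation("outcome must not appear among predictors/covariates")
  if (anyDuplicated(rhs)) stop_validation("duplicated right-hand-side columns")
  chk_cols(data, c(outcome, rhs))
  d <- data[complete.cases(data[, c(outcome, rhs), drop = FALSE]),
            c(outcome, rhs), drop = FALSE]
  terms_rhs <- rhs
  if (include_interactions && length(predictors) > 1)
    terms_rhs <- c(terms_rhs,
                   combn(predictors, 2, FUN = paste, collapse = ":"))
  fml <- reformulate(terms_rhs, response = outcome)
  X <- model.matrix(fml, d)
  if (nrow(d) < ncol(X) + 2)
    stop_validation("too few complete cases (", nrow(d), ") for ", ncol(X), " terms")
  y <- d[[outcome]]
  fit <- ols_qr(X, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop_validation("outcome has zero variance")
  r2 <- 1 - fit$rss / tss
  tval <- fit$coef / fit$se
  pval <- 2 * pt(-abs(tval), fit$df)
  # increment in R^2 when each column is dropped (intercept excluded)
  delta_r2 <- rep(NA_real_, ncol(X))
  for (j in seq.int(2L, ncol(X))) {
    fr <- .lm.fit(X[, -j, drop = FALSE], y)
    delta_r2[j] <- r2 - (1 - sum(fr$residuals^2) / tss)
  }
  role <- ifelse(colnames(X) == "(Intercept)", "intercept",
          ifelse(colnames(X) %in% predictors, "predictor",
          ifelse(colnames(X) %in% covariates, "covariate", "interaction")))
  terms_df <- data.frame(term = colnames(X), role = role,
                         estimate = fit$coef, se = fit$se, t = tval, p = pval,
                         partial_r = partial_r_from_t(tval, fit$df),
                         delta_r2 = delta_r2,
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(outcome = outcome, terms = terms_df, r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (nrow(d) - 1) / fit$df,
                 df_residual = fit$df, n = nrow(d),
                 spec = list(predictors = predictors, covariates = covariates,
                             include_interactions = include_interactions)),
            class = "sst_regression")
}

#' @export
print.sst_regression <- function(x, digits = 3, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d, R^2 = %.3f, residual df = %d)\n",
              x$outcome,
              paste(c(x$spec$predictors, x$spec$covariates), collapse = " + "),
              x$n, x$r_squared, x$df_residual))
  tt <- x$terms
  tt[, c("estimate", "se", "t", "p", "partial_r", "delta_r2")] <-
    lapply(tt[, c("estimate", "se", "t", "p", "partial_r", "delta_r2")],
           signif, digits = digits)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Run one regression model over several outcomes
#'
#' Fits the same covariate-adjusted model for each outcome and returns a
#' tidy long-format table of per-term results — the screening layout used
#' when asking which metabolic or neural measures predict task performance.
#' Benjamini-Hochberg q-values over the predictor terms can be appended;
#' they are off by default (an uncorrected screen).
#'
#' @param data Data frame.
#' @param outcomes Character vector of outcome columns; an empty vector gives
#'   an empty result table.
#' @param predictors,covariates Passed to [fit_regression()].
#' @param adjust_bh Append BH-adjusted `q_value` across all predictor terms.
#' @return Data frame: one row per (outcome, term) with estimate, se, t, p,
#'   partial_r, delta_r2, model R^2 and n.
#' @export
screen_predictors <- function(data, outcomes, predictors,
                              covariates = character(), adjust_bh = FALSE) {
  cols <- c("outcome", "term", "role", "estimate", "se", "t", "p",
            "partial_r", "delta_r2", "r_squared", "n")
  if (!length(outcomes)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$outcome <- out$term <- out$role <- character(0)
    return(out)
  }
  rows <- lapply(outcomes, function(oc) {
    fit <- fit_regression(data, oc, predictors, covariates)
    tt <- fit$terms[fit$terms$role != "intercept", , drop = FALSE]
    tt$outcome <- oc
    tt$r_squared <- fit$r_squared
    tt$n <- fit$n
    tt
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))[, cols]
  if (adjust_bh) {
    out$q_value <- NA_real_
    sel <- out$role == "predictor"
    out$q_value[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out
}
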