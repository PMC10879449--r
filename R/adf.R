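# MacKinnon response-surface constants for the Dickey-Fuller t distribution.
# Critical values: MacKinnon (2010), "Critical values for cointegration
# tests", surface cv(p) = b0 + b1/T + b2/T^2 + b3/T^3 at levels 1/5/10%.
# P-values: MacKinnon (1994) cumulative-distribution polynomials
# p = Phi(g0 + g1*tau + g2*tau^2 [+ g3*tau^3]).
.adf_tables <- list(
  "single-mean" = list(
    cv = rbind("0.01" = c(-3.43035, -6.5393, -16.786, -79.433),
               "0.05" = c(-2.86154, -2.8903, -4.234, -40.04),
               "0.10" = c(-2.56677, -1.5384, -2.809, 0)),
    tau_star = -1.61, tau_min = -18.83, tau_max = 2.74,
    smallp = c(2.1659, 1.4412, 0.038269),
    largep = c(1.7339, 0.93202, -0.12745, -0.010368)),
  trend = list(
    cv = rbind("0.01" = c(-3.95877, -9.0531, -28.428, -134.155),
               "0.05" = c(-3.41049, -4.3904, -9.036, -45.374),
               "0.10" = c(-3.12705, -2.5856, -3.925, -22.38)),
    tau_star = -2.89, tau_min = -16.18, tau_max = 0.7,
    smallp = c(3.2512, 1.6047, 0.049588),
    largep = c(2.5261, 0.61654, -0.37956, -0.060285)))

adf_pvalue <- function(stat, model) {
  tb <- .adf_tables[[model]]
  if (stat <= tb$tau_min) return(0)
  if (stat >= tb$tau_max) return(1)
  co <- if (stat <= tb$tau_star) tb$smallp else tb$largep
  stats::pnorm(sum(co * stat^(seq_along(co) - 1L)))
}

adf_critical_value <- function(alpha, n, model) {
  tb <- .adf_tables[[model]]
  key <- sprintf("%.2f", alpha)
  if (!key %in% rownames(tb$cv))
    stop("critical-value surface tabulated only for alpha 0.01, 0.05, 0.10")
  b <- tb$cv[key, ]
  b[1L] + b[2L] / n + b[3L] / n^2 + b[4L] / n^3
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the ADF regression with one augmentation lag (the study convention):
#' \deqn{\Delta y_t = c [+ \delta t] + \rho y_{t-1} + \psi \Delta y_{t-1} + e_t}
#' with a constant only (`"single-mean"`) or constant plus linear trend
#' (`"trend"`), and evaluates the t statistic of `rho` against the
#' Dickey-Fuller distribution using MacKinnon's response-surface
#' approximations for finite-sample critical values and p-values. When the
#' series carries a validity mask, the longest contiguous valid run is used
#' (the regression requires contiguous observations).
#'
#' @param series Numeric vector of per-second values; `NA` marks invalid
#'   seconds.
#' @param model `"single-mean"` or `"trend"`.
#' @param lags Number of lagged differences (default 1).
#' @param alpha Rejection level for `reject_unit_root` (0.01, 0.05 or 0.10).
#' @return An object of class `adf_result`: list with `statistic`, `p_value`,
#'   `model`, `lags`, `n_used`, `reject_unit_root`.
#' @export
adf_test <- function(series, model = c("single-mean", "trend"), lags = 1L,
                     alpha = 0.05) {
  model <- match.arg(model)
  y <- longest_valid_run(series)
  n <- length(y)
  if (n < 20L)
    stop("degenerate input: fewer than 20 contiguous valid observations")
  if (stats::sd(y) < 1e-12)
    stop("degenerate input: constant series")
  dy <- diff(y)
  # regression sample: t = lags+2, ..., n (indices of y)
  idx <- (lags + 1L):(n - 1L)
  resp <- dy[idx]
  X <- cbind(intercept = 1, ylag = y[idx])
  if (model == "trend") X <- cbind(X, trend = seq_along(idx))
  for (j in seq_len(lags)) X <- cbind(X, dy[idx - j])
  fit <- stats::lm.fit(X, resp)
  rss <- sum(fit$residuals^2)
  df <- length(resp) - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[2L, 2L])
  stat <- fit$coefficients["ylag"] / se
  p <- adf_pvalue(stat, model)
  cv <- adf_critical_value(alpha, length(resp), model)
  structure(list(statistic = unname(stat), p_value = p, model = model,
                 lags = lags, n_used = n,
                 reject_unit_root = unname(stat < cv)),
            class = "adf_result")
}

longest_valid_run <- function(series) {
  ok <- is.finite(series)
  if (!any(ok)) return(numeric(0))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  series[(ends[best] - r$lengths[best] + 1L):ends[best]]
}

#' Stationarity screen for one dyad-task record
#'
#' Applies the ADF test in both the single-mean and trend specifications to
#' each partner's RSA series. A series "meets stationarity" when the unit
#' root is rejected in at least one of the two specifications; the dyad flag
#' is true only when both series meet it. The screen is advisory: flagged
#' dyads are retained in analysis (all available data are modelled), the
#' flag travels with the outputs.
#'
#' @param parent_rsa,child_rsa `rsa_series` objects (or data.frames with
#'   `rsa` and `valid` columns) from [estimate_rsa()].
#' @param alpha Rejection level.
#' @return A data.frame with one row per role: ADF statistics and p-values
#'   for both models, `meets_stationarity`, plus attribute
#'   `"dyad_stationary"`.
#' @export
screen_dyad <- function(parent_rsa, child_rsa, alpha = 0.05) {
  one <- function(rsa, role) {
    vals <- ifelse(rsa$valid, rsa$rsa, NA_real_)
    if (!sum(is.finite(vals)))
      stop("degenerate input: empty ", role, " series")
    m1 <- adf_test(vals, "single-mean", alpha = alpha)
    m2 <- adf_test(vals, "trend", alpha = alpha)
    data.frame(role = role,
               adf_stat_mean = m1$statistic, p_mean = m1$p_value,
               adf_stat_trend = m2$statistic, p_trend = m2$p_value,
               meets_stationarity = m1$reject_unit_root ||
                 m2$reject_unit_root)
  }
  out <- rbind(one(parent_rsa, "parent"), one(child_rsa, "child"))
  attr(out, "dyad_stationary") <- all(out$meets_stationarity)
  out
}
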