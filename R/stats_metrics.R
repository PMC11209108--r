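# Validation statistics for one-descriptor QSAR models: R2, leave-one-out
# Q2, RMSE, MAE, Fisher F, and the two correlation-quality indices used by
# the Monte Carlo target function:
#
#   IIC (index of ideality of correlation): the Pearson correlation damped
#   by the asymmetry between the mean absolute errors of over- and
#   under-predicted observations,
#       IIC = r * min(MAEneg, MAEpos) / max(MAEneg, MAEpos),
#   where residual = observed - calculated, MAEneg averages |residual| over
#   strictly negative residuals and MAEpos over the rest.
#
#   CII (correlation intensity index): one minus the total improvement in
#   correlation obtainable by deleting single points,
#       CII = 1 - sum_k max(0, R_k - R),
#   with R the full-sample Pearson correlation and R_k the correlation with
#   point k removed. CII = 1 means no single point props up the correlation.

#' Determination coefficient
#'
#' Squared Pearson correlation between observed and calculated values.
#'
#' @param obs,pred numeric vectors of equal length (n >= 3).
#' @return R-squared in \[0, 1\]; 0 with a warning when either vector has
#'   zero variance.
#' @export
r_squared <- function(obs, pred) {
  check_paired(obs, pred, min_n = 3L)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("zero variance in r_squared input; returning 0")
    return(0)
  }
  stats::cor(obs, pred)^2
}

#' Fisher F ratio for a one-predictor regression
#'
#' `F = R2 * (n - 2) / (1 - R2)`. Reported tables conventionally round this
#' to the nearest integer.
#'
#' @param r2 determination coefficient in \[0, 1).
#' @param n number of observations (n >= 3).
#' @return the F ratio; `Inf` when `r2 == 1`.
#' @export
fisher_f <- function(r2, n) {
  if (any(r2 < 0 | r2 > 1)) {
    coral_stop("r2 must lie in [0, 1]", "coral_invalid_parameter")
  }
  if (any(n < 3)) {
    coral_stop("n must be at least 3", "coral_invalid_parameter")
  }
  ifelse(r2 == 1, Inf, r2 * (n - 2) / (1 - r2))
}

#' Root mean squared error and mean absolute error
#'
#' @param obs,pred numeric vectors of equal length.
#' @return named numeric vector `c(rmse = ..., mae = ...)`.
#' @export
rmse_mae <- function(obs, pred) {
  check_paired(obs, pred, min_n = 1L)
  res <- obs - pred
  c(rmse = sqrt(mean(res^2)), mae = mean(abs(res)))
}

#' Leave-one-out cross-validated Q2 for a simple linear regression
#'
#' Each point is predicted from the ordinary-least-squares line refit on the
#' remaining n - 1 points; `Q2 = 1 - PRESS / SS_tot`. Computed through the
#' PRESS identity `e_(i) = e_i / (1 - h_i)` (algebraically identical to the
#' explicit refits).
#'
#' @param x descriptor values (n >= 4, non-degenerate after any deletion).
#' @param y response values.
#' @return Q2 (at most 1; can be negative when the model predicts worse
#'   than the mean).
#' @export
q2_loo <- function(x, y) {
  check_paired(x, y, min_n = 4L)
  n <- length(x)
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) {
    coral_stop("descriptor has zero variance", "coral_degenerate_descriptor")
  }
  # degenerate when deleting one point leaves a constant x
  for (i in seq_len(n)) {
    if (stats::sd(x[-i]) == 0) {
      coral_stop("descriptor degenerate after removing one point",
                 "coral_degenerate_descriptor")
    }
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  e <- fit$residuals
  h <- 1 / n + (x - xb)^2 / sxx
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Index of ideality of correlation
#'
#' @param obs observed values; `pred` calculated values (n >= 3).
#' @param pred calculated values.
#' @return IIC in \[-1, 1\]. When all residuals share one sign (one error
#'   class empty but errors present) the MAE ratio is 0 and IIC = 0; for an
#'   exact fit the ratio is taken as 1 so IIC equals the correlation.
#' @export
iic <- function(obs, pred) {
  check_paired(obs, pred, min_n = 3L)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("zero variance in iic input; returning 0")
    return(0)
  }
  r <- stats::cor(obs, pred)
  res <- obs - pred
  neg <- res < 0  # ties (residual exactly 0) count in the non-negative class
  mae_neg <- if (any(neg)) mean(abs(res[neg])) else 0
  mae_pos <- if (any(!neg)) mean(abs(res[!neg])) else 0
  hi <- max(mae_neg, mae_pos)
  ratio <- if (hi == 0) 1 else min(mae_neg, mae_pos) / hi
  r * ratio
}

#' Correlation intensity index
#'
#' @param obs,pred numeric vectors (n >= 4); every single-point deletion
#'   must leave non-degenerate variance.
#' @param protest_threshold only correlation gains `R_k - R` above this
#'   value count against CII; default 0.
#' @return CII (at most 1).
#' @export
cii <- function(obs, pred, protest_threshold = 0) {
  check_paired(obs, pred, min_n = 4L)
  n <- length(obs)
  sx <- sum(obs); sy <- sum(pred)
  sxx <- sum(obs^2); syy <- sum(pred^2); sxy <- sum(obs * pred)
  denom_all <- (n * sxx - sx^2) * (n * syy - sy^2)
  if (denom_all <= 0) {
    coral_stop("zero variance in cii input", "coral_degenerate_statistic")
  }
  r_all <- (n * sxy - sx * sy) / sqrt(denom_all)
  m <- n - 1
  sx_k <- sx - obs; sy_k <- sy - pred
  sxx_k <- sxx - obs^2; syy_k <- syy - pred^2; sxy_k <- sxy - obs * pred
  denom_k <- (m * sxx_k - sx_k^2) * (m * syy_k - sy_k^2)
  if (any(denom_k <= 0)) {
    coral_stop("variance degenerate after a single-point deletion",
               "coral_degenerate_statistic")
  }
  r_k <- (m * sxy_k - sx_k * sy_k) / sqrt(denom_k)
  gain <- r_k - r_all
  1 - sum(gain[gain > protest_threshold])
}

#' Full statistics panel for one subset
#'
#' Computes the per-subset row of the standard model report: n, R2, IIC,
#' CII, Q2 (leave-one-out on descriptor vs endpoint), RMSE, MAE, Fisher F.
#' Statistics that are undefined for the subset (too few points, degenerate
#' variance) are reported as `NA` rather than failing the pipeline.
#'
#' @param obs observed log endpoints.
#' @param pred calculated log endpoints.
#' @param x descriptor (DCW) values, used for Q2; defaults to `pred` (for a
#'   one-descriptor linear model the LOO refits are equivalent).
#' @return one-row data.frame: n, r2, iic, cii, q2, rmse, mae, f.
#' @export
fit_statistics <- function(obs, pred, x = pred) {
  n <- length(obs)
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NA_real_)
  r2 <- safe(r_squared(obs, pred))
  err <- safe(rmse_mae(obs, pred))
  if (length(err) == 1L && is.na(err)) err <- c(rmse = NA_real_, mae = NA_real_)
  data.frame(
    n = n,
    r2 = r2,
    iic = safe(iic(obs, pred)),
    cii = safe(cii(obs, pred)),
    q2 = safe(q2_loo(x, obs)),
    rmse = unname(err["rmse"]),
    mae = unname(err["mae"]),
    f = if (is.na(r2) || r2 == 1) NA_real_ else fisher_f(r2, n)
  )
}

check_paired <- function(a, b, min_n) {
  if (length(a) != length(b)) {
    coral_stop("input vectors differ in length", "coral_input_error")
  }
  if (length(a) < min_n) {
    coral_stop(sprintf("need at least %d points", min_n), "coral_input_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    coral_stop("inputs must be finite", "coral_input_error")
  }
  invisible(TRUE)
}
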