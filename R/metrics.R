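#' @name evaluation_metrics
#' @title Fit statistics for DBH models
#' @description
#' The four statistics used to compare model stages. With residual sum of
#' squares SSE and total sum of squares SST about the observed mean:
#' \deqn{R^2 = 1 - \frac{SSE}{SST}\,\frac{n-1}{n-p}, \quad
#'       RMSE = \sqrt{SSE/(n-p)}, \quad
#'       TRE = 100\,SSE / \sum D_i^2, \quad
#'       AIC = -2\ln l + 2p.}
#' The degrees-of-freedom adjustment in \eqn{R^2} can make it negative for a
#' model fitting worse than the mean; it is reported as-is. TRE (total
#' relative error) is reported in percent.
NULL

#' Compute fit metrics from observed and predicted values
#'
#' @param observed,predicted Numeric vectors of equal length `n > p`.
#' @param p Number of model parameters consumed (used in the `n - p`
#'   denominators).
#' @return A list of class `fir_metrics`: `r2`, `rmse_cm`, `tre_pct`, `n`,
#'   `p`. `r2` is `NA` when the observations are constant (zero SST).
#' @export
compute_metrics <- function(observed, predicted, p) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed/predicted length mismatch")
  if (n <= p) stop("need n > p")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  structure(list(
    r2 = if (sst == 0) NA_real_ else 1 - (sse / sst) * ((n - 1) / (n - p)),
    rmse_cm = sqrt(sse / (n - p)),
    tre_pct = 100 * sse / sum(observed^2),
    n = n, p = p), class = "fir_metrics")
}

#' Akaike information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param p Parameter count, `>= 1`. Throughout the package `p` includes the
#'   residual-variance parameter, a convention applied uniformly so that
#'   only AIC differences matter for selection.
#' @return `-2 * loglik + 2 * p`.
#' @export
compute_aic <- function(loglik, p) {
  if (!is.numeric(p) || p < 1) stop("p must be >= 1")
  -2 * loglik + 2 * p
}

#' @export
print.fir_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f, RMSE = %.3f cm, TRE = %.3f%% (n = %d, p = %d)\n",
              x$r2, x$rmse_cm, x$tre_pct, x$n, x$p))
  invisible(x)
}
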