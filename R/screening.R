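#' @name screening
#' @title Collinearity screening of candidate predictors
#' @description
#' Variance-inflation-factor filtering followed by Pearson correlation
#' ranking, the standard pre-modeling screen for LiDAR-derived covariates,
#' which are often strongly collinear.
NULL

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of determination
#' of regressing predictor `j` on the remaining predictors (with intercept).
#' An exactly collinear predictor is reported as `Inf`, not an error.
#'
#' @param table Data.frame containing the predictor columns.
#' @param predictors Character vector of at least two column names.
#' @return Named numeric vector of VIFs, all `>= 1`.
#' @export
compute_vif <- function(table, predictors) {
  if (length(predictors) < 2L) stop("need at least two predictors")
  x <- as.data.frame(table[predictors])
  for (p in predictors) {
    if (!is.numeric(x[[p]])) stop("predictor not numeric: ", p)
    if (var(x[[p]]) == 0) stop("constant predictor column: ", p)
  }
  vif <- vapply(predictors, function(p) {
    fit <- lm(stats::reformulate(setdiff(predictors, p), response = p),
              data = x)
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  vif
}

#' Pearson correlation matrix
#'
#' Symmetric correlation matrix with unit diagonal. A zero-variance variable
#' yields `NA` in its row and column (flagged by a warning) rather than an
#' error.
#'
#' @param table Data.frame containing the variables.
#' @param variables Character vector of at least two column names; at least
#'   three rows are required.
#' @return Correlation matrix with entries in `[-1, 1]`.
#' @export
pearson_matrix <- function(table, variables) {
  if (length(variables) < 2L) stop("need at least two variables")
  if (nrow(table) < 3L) stop("need at least three rows")
  x <- as.matrix(as.data.frame(table[variables]))
  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning("zero-variance variable(s): ",
            paste(variables[const], collapse = ", "))
  }
  m <- suppressWarnings(cor(x))
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}

#' Screen predictors by iterative VIF filtering
#'
#' Repeatedly drops the highest-VIF candidate until every remaining VIF is
#' below the threshold (ties broken by dropping the later candidate in input
#' order), then ranks the survivors by absolute Pearson correlation with the
#' response. `iterative = FALSE` performs a single pass instead, dropping
#' all candidates at or above the threshold at once (but never all of them).
#'
#' @param table Data.frame with candidate and response columns.
#' @param candidates Character vector of candidate predictor names.
#' @param response Response column name (not among the candidates).
#' @param vif_threshold Retain only candidates with VIF strictly below this
#'   value (default 5, the conventional collinearity cut-off).
#' @param iterative Use greedy one-at-a-time removal (default) or a single
#'   pass.
#' @return A list of class `fir_screening`: `vif` (of the original
#'   candidates), `dropped`, `retained` (ranked by |r| with the response),
#'   `cor_with_response`, `cor_matrix`, `threshold`.
#' @export
select_predictors <- function(table, candidates, response,
                              vif_threshold = 5, iterative = TRUE) {
  if (response %in% candidates) stop("response must not be a candidate")
  vif0 <- compute_vif(table, candidates)
  keep <- candidates
  if (iterative) {
    repeat {
      if (length(keep) < 2L) break
      v <- compute_vif(table, keep)
      if (max(v) < vif_threshold) break
      # ties: drop the later candidate in input order (which.max on the
      # reversed vector picks the last maximum)
      worst <- length(v) + 1L - which.max(rev(v) >= max(v))
      keep <- keep[-worst]
    }
  } else {
    v <- vif0
    drop <- names(v)[v >= vif_threshold]
    if (length(drop) == length(keep)) drop <- drop[-1L]
    keep <- setdiff(keep, drop)
  }
  if (length(keep) == 0L) {
    stop("no candidate survived VIF screening at threshold ", vif_threshold)
  }
  r <- vapply(keep, function(p) cor(table[[p]], table[[response]]),
              numeric(1))
  keep <- keep[order(abs(r), decreasing = TRUE)]
  structure(list(
    vif = vif0,
    dropped = setdiff(candidates, keep),
    retained = keep,
    cor_with_response = r[keep],
    cor_matrix = pearson_matrix(table, c(response, candidates)),
    threshold = vif_threshold), class = "fir_screening")
}

#' @export
print.fir_screening <- function(x, ...) {
  cat("Predictor screening (VIF threshold", x$threshold, ")\n")
  cat("  VIF:", paste(sprintf("%s=%.3f", names(x$vif), x$vif),
                      collapse = ", "), "\n")
  if (length(x$dropped)) {
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  cat("  retained (by |r| with response):",
      paste(sprintf("%s (r=%.3f)", x$retained, x$cor_with_response),
            collapse = ", "), "\n")
  invisible(x)
}
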