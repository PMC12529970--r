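#' @name base_models
#' @title Candidate DBH-height model forms and nonlinear least squares
#' @description
#' Ten candidate base forms relate DBH (cm) to LiDAR tree height H (m).
#' M1-M6 have two parameters, M7-M10 three. M5, M6 and M8-M10 are height
#' forms from the height-diameter literature solved for D (reversed
#' Schumacher, Wykoff, Yang, Chapman-Richards and a three-parameter Wykoff
#' variant); each reversed form inverts its published H(D) counterpart
#' exactly, so forms containing the term `H - 1.3` are only defined for
#' trees taller than breast height.
#'
#' \tabular{lll}{
#'   M1 \tab \eqn{D = a + bH} \tab linear \cr
#'   M2 \tab \eqn{D = aH^b} \tab allometric \cr
#'   M3 \tab \eqn{D = ae^{bH}} \tab exponential \cr
#'   M4 \tab \eqn{D = a\ln H + b} \tab logarithmic \cr
#'   M5 \tab \eqn{D = ((H-1.3)/a)^b} \tab reversed Schumacher \cr
#'   M6 \tab \eqn{D = b/(\ln(H-1.3) - a) - 1} \tab reversed Wykoff \cr
#'   M7 \tab \eqn{D = a + bH^c} \tab allometric with intercept \cr
#'   M8 \tab \eqn{D = [\ln(a/(a-(H-1.3)))/b]^{1/c}} \tab reversed Yang \cr
#'   M9 \tab \eqn{D = -\ln(1 - ((H-1.3)/a)^{1/c})/b} \tab reversed Chapman-Richards \cr
#'   M10 \tab \eqn{D = b/(\ln(H-1.3) - a) - c} \tab reversed Wykoff, 3 par.
#' }
#'
#' The generalized form extends M7 with multiplicative covariate powers on
#' the scale term: \eqn{D = a + b\,LH^{c_{lh}}\prod_j X_j^{c_j}}.
NULL

# exponent parameter name for a covariate column
exponent_name <- function(col) {
  switch(col,
         lh_m = "c_lh", lcd_m = "c_lcd", density_ha = "c_s",
         paste0("c_", col))
}

base_form_registry <- function() {
  list(
    M1 = list(
      params = c("a", "b"), needs_h13 = FALSE, linear = TRUE,
      fun = function(p, H) p[["a"]] + p[["b"]] * H,
      lmform = dbh_cm ~ lh_m, lmmap = c(a = "(Intercept)", b = "lh_m"),
      init = function(H, D) {
        cf <- coef(lm(D ~ H)); c(a = cf[[1]], b = cf[[2]])
      }),
    M2 = list(
      params = c("a", "b"), needs_h13 = FALSE, linear = FALSE,
      fun = function(p, H) p[["a"]] * H^p[["b"]],
      init = function(H, D) {
        cf <- coef(lm(log(D) ~ log(H))); c(a = exp(cf[[1]]), b = cf[[2]])
      }),
    M3 = list(
      params = c("a", "b"), needs_h13 = FALSE, linear = FALSE,
      fun = function(p, H) p[["a"]] * exp(p[["b"]] * H),
      init = function(H, D) {
        cf <- coef(lm(log(D) ~ H)); c(a = exp(cf[[1]]), b = cf[[2]])
      }),
    M4 = list(
      params = c("a", "b"), needs_h13 = FALSE, linear = TRUE,
      fun = function(p, H) p[["a"]] * log(H) + p[["b"]],
      lmform = dbh_cm ~ log(lh_m),
      lmmap = c(a = "log(lh_m)", b = "(Intercept)"),
      init = function(H, D) {
        cf <- coef(lm(D ~ log(H))); c(a = cf[[2]], b = cf[[1]])
      }),
    M5 = list(
      params = c("a", "b"), needs_h13 = TRUE, linear = FALSE,
      fun = function(p, H) ((H - 1.3) / p[["a"]])^p[["b"]],
      lower = c(a = 1e-8, b = -Inf),
      init = function(H, D) {
        cf <- coef(lm(log(D) ~ log(H - 1.3)))
        b0 <- cf[[2]]
        c(a = exp(-cf[[1]] / b0), b = b0)
      }),
    M6 = list(
      params = c("a", "b"), needs_h13 = TRUE, linear = FALSE,
      fun = function(p, H) p[["b"]] / (log(H - 1.3) - p[["a"]]) - 1,
      init = function(H, D) {
        cf <- coef(lm(I(1 / (D + 1)) ~ log(H - 1.3)))
        b0 <- 1 / cf[[2]]
        c(a = -cf[[1]] * b0, b = b0)
      },
      upper_dyn = function(H) c(a = min(log(H - 1.3)) - 1e-6, b = Inf)),
    M7 = list(
      params = c("a", "b", "c"), needs_h13 = FALSE, linear = FALSE,
      fun = function(p, H) p[["a"]] + p[["b"]] * H^p[["c"]],
      init = function(H, D) {
        a0 <- 0.5 * min(D)
        b0 <- coef(lm(I(D - a0) ~ 0 + H))[[1]]
        c(a = a0, b = b0, c = 1)
      }),
    M8 = list(
      params = c("a", "b", "c"), needs_h13 = TRUE, linear = FALSE,
      fun = function(p, H) {
        (log(p[["a"]] / (p[["a"]] - (H - 1.3))) / p[["b"]])^(1 / p[["c"]])
      },
      init = function(H, D) {
        a0 <- 1.2 * max(H - 1.3)
        z <- log(a0 / (a0 - (H - 1.3)))
        cf <- coef(lm(log(z) ~ log(D)))
        c(a = a0, b = exp(cf[[1]]), c = cf[[2]])
      },
      lower_dyn = function(H) c(a = max(H - 1.3) + 1e-6, b = 1e-10, c = 1e-3)),
    M9 = list(
      params = c("a", "b", "c"), needs_h13 = TRUE, linear = FALSE,
      fun = function(p, H) {
        -log(1 - ((H - 1.3) / p[["a"]])^(1 / p[["c"]])) / p[["b"]]
      },
      init = function(H, D) {
        a0 <- 1.2 * max(H - 1.3)
        b0 <- mean(-log(1 - (H - 1.3) / a0) / D)
        c(a = a0, b = b0, c = 1)
      },
      lower_dyn = function(H) c(a = max(H - 1.3) + 1e-6, b = 1e-10, c = 1e-3)),
    M10 = list(
      params = c("a", "b", "c"), needs_h13 = TRUE, linear = FALSE,
      fun = function(p, H) p[["b"]] / (log(H - 1.3) - p[["a"]]) - p[["c"]],
      init = function(H, D) {
        cf <- coef(lm(I(1 / (D + 1)) ~ log(H - 1.3)))
        b0 <- 1 / cf[[2]]
        c(a = -cf[[1]] * b0, b = b0, c = 1)
      },
      upper_dyn = function(H) c(a = min(log(H - 1.3)) - 1e-6, b = Inf,
                                c = Inf))
  )
}

#' Base model form identifiers
#' @return Character vector `"M1"` ... `"M10"`.
#' @export
base_forms <- function() names(base_form_registry())

#' Model specification
#'
#' Builds the declarative description of a mean function used by the
#' fitters: a base form (`"M1"`-`"M10"`) or `"generalized"`, the latter
#' being M7 with multiplicative covariate powers attached to the scale term.
#'
#' @param form_id One of [base_forms()], `"generalized"`, or `"dummy"` (a
#'   generalized form with one parameter replaced by five growth-stage
#'   coefficients; see [fit_dummy_model()]).
#' @param covariates For `"generalized"`/`"dummy"`: character vector of
#'   covariate columns beyond `lh_m` (e.g. `c("lcd_m", "density_ha")`), each
#'   entering as a power factor.
#' @param placement For `"dummy"` only: which parameter carries the stage
#'   coefficients (`"a"`, `"b"`, or an exponent such as `"c_lh"`).
#' @param stages Growth stages whose coefficients are estimated (default all
#'   five); stages absent from a training set are excluded by the fitter and
#'   flagged.
#' @return A list of class `fir_model_spec` with elements `form_id`,
#'   `params`, `covariates`, `needs_h13` (plus `placement` and `stages` for
#'   dummy forms).
#' @export
model_spec <- function(form_id, covariates = character(), placement = "b",
                       stages = stage_levels()) {
  if (form_id == "generalized") {
    params <- c("a", "b", "c_lh", vapply(covariates, exponent_name,
                                         character(1)))
    spec <- list(form_id = "generalized", params = unname(params),
                 covariates = covariates, needs_h13 = FALSE)
  } else if (form_id == "dummy") {
    base_par <- c("a", "b", "c_lh", vapply(covariates, exponent_name,
                                           character(1)))
    if (!placement %in% base_par) {
      stop("placement must be one of: ", paste(base_par, collapse = ", "))
    }
    sidx <- match(stages, stage_levels())
    if (any(is.na(sidx))) stop("unknown stage name")
    staged <- paste0(placement, sidx)
    params <- unlist(lapply(base_par, function(p) {
      if (p == placement) staged else p
    }))
    spec <- list(form_id = "dummy", params = unname(params),
                 covariates = covariates, needs_h13 = FALSE,
                 placement = placement, stages = stages)
  } else {
    reg <- base_form_registry()
    if (!form_id %in% names(reg)) stop("unknown form: ", form_id)
    spec <- list(form_id = form_id, params = reg[[form_id]]$params,
                 covariates = character(), needs_h13 = reg[[form_id]]$needs_h13)
  }
  class(spec) <- "fir_model_spec"
  spec
}

# rows of `data` on which the form is defined
form_domain <- function(spec, data) {
  ok <- is.finite(data$lh_m) & data$lh_m > 0
  if (isTRUE(spec$needs_h13)) ok <- ok & data$lh_m > 1.3
  if (spec$form_id %in% c("generalized", "dummy")) {
    for (cv in spec$covariates) ok <- ok & is.finite(data[[cv]]) & data[[cv]] > 0
  }
  if (spec$form_id == "dummy") {
    ok <- ok & is.finite(data$age_y) & data$age_y >= 1 &
      (stage_levels()[as.integer(assign_growth_stage(pmax(data$age_y, 1)))]
       %in% spec$stages)
  }
  ok
}

#' Evaluate a model form
#'
#' Deterministic evaluation of a mean function at given parameters. Input
#' outside the form's domain (heights at or below 1.3 m for forms using
#' `H - 1.3`, non-positive power bases) raises an error.
#'
#' @param spec A `fir_model_spec` or a form id string.
#' @param params Named numeric vector matching `spec$params`.
#' @param data Data.frame with `lh_m` and any generalized covariates.
#' @return Numeric vector of predicted DBH (cm).
#' @examples
#' evaluate_form("M1", c(a = 2, b = 0.5), data.frame(lh_m = 10))  # 7
#' @export
evaluate_form <- function(spec, params, data) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!all(form_domain(spec, data))) {
    stop("covariates outside the domain of form ", spec$form_id)
  }
  pred <- eval_form_quiet(spec, params, data)
  if (any(!is.finite(pred))) {
    stop("form ", spec$form_id, " undefined at the given parameters")
  }
  pred
}

# as evaluate_form, but lets parameter-dependent domain violations surface
# as non-finite values instead of errors (used inside optimizers/ranking)
eval_form_quiet <- function(spec, params, data) {
  if (!all(spec$params %in% names(params))) {
    stop("params must name: ", paste(spec$params, collapse = ", "))
  }
  p <- as.list(params[spec$params])
  if (spec$form_id == "generalized") {
    out <- p[["b"]] * data$lh_m^p[["c_lh"]]
    for (cv in spec$covariates) {
      out <- out * data[[cv]]^p[[exponent_name(cv)]]
    }
    return(p[["a"]] + out)
  }
  if (spec$form_id == "dummy") {
    G <- build_stage_design(data$age_y)
    sidx <- match(spec$stages, stage_levels())
    staged <- paste0(spec$placement, sidx)
    placed <- as.vector(G[, sidx, drop = FALSE] %*% unlist(p[staged]))
    placed[rowSums(G[, sidx, drop = FALSE]) == 0] <- NA_real_
    val <- function(nm) if (nm == spec$placement) placed else p[[nm]]
    out <- val("b") * data$lh_m^val("c_lh")
    for (cv in spec$covariates) {
      out <- out * data[[cv]]^val(exponent_name(cv))
    }
    return(val("a") + out)
  }
  reg <- base_form_registry()[[spec$form_id]]
  suppressWarnings(reg$fun(p, data$lh_m))
}

# internal: build a fir_fit from an optimized parameter vector
make_fir_fit <- function(spec, coefs, vc, sse, n, n_dropped, converged,
                         fitted, observed, extra = list()) {
  p_mean <- length(spec$params)
  # floor the SSE at numerical zero so exact fits get a finite loglik and
  # equally exact fits tie instead of ranking on rounding noise
  ll <- gaussian_loglik(max(sse, n * 1e-20), n)
  se <- if (is.null(vc)) rep(NA_real_, p_mean) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(coefs)
  structure(c(list(
    spec = spec, coef = coefs, se = se, vcov = vc,
    sse = sse, sigma2_ml = sse / n, loglik = ll,
    n = n, n_dropped = n_dropped, p_mean = p_mean, p = p_mean + 1L,
    converged = converged, fitted = fitted, observed = observed),
    extra), class = "fir_fit")
}

#' Fit a model form by nonlinear least squares
#'
#' Minimizes the Gaussian sum of squared residuals by Levenberg-Marquardt
#' (via \pkg{minpack.lm}), with form-specific analytic initializations
#' (log-log or reciprocal linearizations of each form). Linear forms M1 and
#' M4 are solved exactly by ordinary least squares. Rows outside the form's
#' domain are dropped and counted. Non-convergence or an unidentifiable
#' configuration yields a flagged result, not an error.
#'
#' @param spec A `fir_model_spec` or form id string.
#' @param table Inventory data.frame (`dbh_cm` response).
#' @param init Optional named starting values; default uses the form's
#'   heuristic.
#' @return An object of class `fir_fit` with elements `coef`, `se`, `vcov`,
#'   `loglik` (Gaussian maximum likelihood), `sse`, `n`, `n_dropped`,
#'   `p_mean`, `p` (mean parameters + residual variance), `converged`,
#'   `fitted`, `observed`.
#' @export
fit_nls <- function(spec, table, init = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  ok <- form_domain(spec, table) & is.finite(table$dbh_cm)
  data <- table[ok, , drop = FALSE]
  n_dropped <- sum(!ok)
  n <- nrow(data)
  p_mean <- length(spec$params)
  if (n <= p_mean) stop("need more rows than parameters (n = ", n, ")")
  D <- data$dbh_cm
  H <- data$lh_m

  reg <- if (!spec$form_id %in% c("generalized", "dummy")) {
    base_form_registry()[[spec$form_id]]
  }

  # exact OLS path for forms linear in their parameters
  if (!is.null(reg) && isTRUE(reg$linear)) {
    lf <- lm(reg$lmform, data = data)
    cf <- coef(lf)[reg$lmmap]
    names(cf) <- names(reg$lmmap)
    vc <- vcov(lf)[reg$lmmap, reg$lmmap, drop = FALSE]
    dimnames(vc) <- list(names(reg$lmmap), names(reg$lmmap))
    fitted <- unname(stats::fitted(lf))
    return(make_fir_fit(spec, cf, vc, sum(resid(lf)^2), n, n_dropped,
                        TRUE, fitted, D))
  }

  predfun <- function(par) eval_form_quiet(spec, par, data)
  if (is.null(init)) {
    init <- if (spec$form_id == "generalized") {
      cf <- tryCatch(coef(fit_nls("M7", data)),
                     error = function(e) c(a = 0.5 * min(D), b = 1, c = 1))
      st <- c(a = cf[["a"]], b = cf[["b"]], c_lh = cf[["c"]])
      c(st, setNames(rep(0, p_mean - 3L), spec$params[-(1:3)]))
    } else if (spec$form_id == "dummy") {
      gf <- fit_nls(model_spec("generalized", spec$covariates), data)
      dummy_init_from(gf, spec)
    } else {
      tryCatch(reg$init(H, D), error = function(e) {
        setNames(rep(1, p_mean), spec$params)
      })
    }
  }
  init <- init[spec$params]
  lower <- setNames(rep(-Inf, p_mean), spec$params)
  upper <- setNames(rep(Inf, p_mean), spec$params)
  if (!is.null(reg)) {
    if (!is.null(reg[["lower"]])) {
      lower[names(reg[["lower"]])] <- reg[["lower"]]
    }
    if (!is.null(reg[["lower_dyn"]])) {
      ld <- reg[["lower_dyn"]](H); lower[names(ld)] <- ld
    }
    if (!is.null(reg[["upper_dyn"]])) {
      ud <- reg[["upper_dyn"]](H); upper[names(ud)] <- ud
    }
    init <- pmin(pmax(init, lower + 1e-10), upper - 1e-10)
  }

  resfun <- function(par) {
    par <- setNames(par, spec$params)
    pred <- tryCatch(predfun(par), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(1e10, n))
    }
    D - pred
  }
  opt <- minpack.lm::nls.lm(
    par = init, fn = resfun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  cf <- setNames(coef(opt), spec$params)
  fitted <- tryCatch(predfun(cf), error = function(e) rep(NA_real_, n))
  sse <- sum((D - fitted)^2)
  converged <- opt$info %in% 1:4

  # numeric Jacobian at the optimum for standard errors
  vc <- tryCatch({
    J <- matrix(0, n, p_mean)
    for (k in seq_len(p_mean)) {
      h <- max(1e-7 * abs(cf[k]), 1e-9)
      up <- cf; up[k] <- up[k] + h
      dn <- cf; dn[k] <- dn[k] - h
      J[, k] <- (predfun(up) - predfun(dn)) / (2 * h)
    }
    jtj <- crossprod(J)
    if (rcond(jtj) < 1e-14) {
      converged <- FALSE
      NULL
    } else {
      s2 <- sse / (n - p_mean)
      v <- s2 * solve(jtj)
      dimnames(v) <- list(spec$params, spec$params)
      v
    }
  }, error = function(e) {
    converged <<- FALSE
    NULL
  })
  make_fir_fit(spec, cf, vc, sse, n, n_dropped, converged, fitted, D)
}

#' @export
print.fir_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d%s, loglik = %.2f, AIC = %.1f%s)\n",
              x$spec$form_id, x$n,
              if (x$n_dropped) paste0(", ", x$n_dropped, " dropped") else "",
              x$loglik, compute_aic(x$loglik, x$p),
              if (x$converged) "" else ", NOT CONVERGED"))
  tab <- cbind(Estimate = x$coef, `Std.Error` = x$se)
  print(round(tab, 5))
  invisible(x)
}

#' @export
coef.fir_fit <- function(object, ...) object$coef

#' @export
logLik.fir_fit <- function(object, ...) {
  structure(object$loglik, df = object$p, nobs = object$n, class = "logLik")
}

#' @export
predict.fir_fit <- function(object, newdata, ...) {
  evaluate_form(object$spec, object$coef, newdata)
}

#' Fit and rank the ten base forms
#'
#' Fits M1-M10 on the training set, evaluates each on the training and test
#' sets, and ranks by AIC (ascending). A form that fails to fit is retained
#' as a row of `NA`s rather than aborting the ranking.
#'
#' @param train,test Inventory data.frames.
#' @return A list of class `fir_ranking`: `table` (one row per form with
#'   train/test R2 and RMSE, AIC, n, convergence) sorted by AIC, and `fits`.
#' @export
rank_base_models <- function(train, test) {
  forms <- base_forms()
  fits <- setNames(vector("list", length(forms)), forms)
  rows <- lapply(forms, function(f) {
    fit <- tryCatch(fit_nls(f, train), error = function(e) NULL)
    fits[[f]] <<- fit
    if (is.null(fit)) {
      return(data.frame(form = f, r2_train = NA, rmse_train = NA,
                        r2_test = NA, rmse_test = NA, aic = NA,
                        n_train = NA, converged = FALSE))
    }
    mtr <- compute_metrics(fit$observed, fit$fitted, fit$p)
    ok <- form_domain(fit$spec, test) & is.finite(test$dbh_cm)
    pte <- eval_form_quiet(fit$spec, fit$coef, test[ok, , drop = FALSE])
    fin <- is.finite(pte)
    mte <- compute_metrics(test$dbh_cm[ok][fin], pte[fin], fit$p)
    data.frame(form = f, r2_train = mtr$r2, rmse_train = mtr$rmse_cm,
               r2_test = mte$r2, rmse_test = mte$rmse_cm,
               aic = compute_aic(fit$loglik, fit$p), p = fit$p,
               n_train = fit$n, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # ties (exact fits) resolved toward parsimony, then input order
  tab <- tab[order(tab$aic, tab$p, match(tab$form, forms)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "fir_ranking")
}

#' @export
print.fir_ranking <- function(x, ...) {
  cat("Base model ranking (by AIC)\n")
  print(transform(x$table,
                  r2_train = round(r2_train, 4), rmse_train = round(rmse_train, 3),
                  r2_test = round(r2_test, 4), rmse_test = round(rmse_test, 3),
                  aic = round(aic, 1)))
  invisible(x)
}

#' Expand a base fit with multiplicative covariate powers
#'
#' Greedy forward selection: at each step every remaining candidate `X` is
#' attached as a factor `X^e` on the scale term `b * LH^c`, and the addition
#' with the lowest AIC is kept if it improves on the current AIC; the search
#' stops otherwise. Candidates with non-positive values are skipped with a
#' warning (a power of a non-positive base is undefined).
#'
#' @param base A fitted M7 `fir_fit`.
#' @param train Inventory data.frame.
#' @param candidates Character vector of candidate covariate columns.
#' @return A `fir_fit` of the generalized form (equal to a relabeled `base`
#'   when no candidate improves AIC or `candidates` is empty).
#' @export
expand_covariates <- function(base, train, candidates) {
  if (!inherits(base, "fir_fit") || base$spec$form_id != "M7") {
    stop("base must be a fitted M7 model")
  }
  usable <- character()
  for (cv in candidates) {
    if (any(!is.finite(train[[cv]]) | train[[cv]] <= 0)) {
      warning("skipping candidate with non-positive values: ", cv)
    } else {
      usable <- c(usable, cv)
    }
  }
  cur_cov <- character()
  cur <- fit_nls(model_spec("generalized", cur_cov), train,
                 init = c(a = base$coef[["a"]], b = base$coef[["b"]],
                          c_lh = base$coef[["c"]]))
  cur_aic <- compute_aic(cur$loglik, cur$p)
  remaining <- usable
  while (length(remaining)) {
    trials <- lapply(remaining, function(cv) {
      sp <- model_spec("generalized", c(cur_cov, cv))
      ini <- c(cur$coef, setNames(0, exponent_name(cv)))
      tryCatch(fit_nls(sp, train, init = ini), error = function(e) NULL)
    })
    aics <- vapply(trials, function(f) {
      if (is.null(f)) Inf else compute_aic(f$loglik, f$p)
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur_aic) break
    cur <- trials[[best]]
    cur_aic <- aics[best]
    cur_cov <- c(cur_cov, remaining[best])
    remaining <- remaining[-best]
  }
  cur
}

#' F-test between nested least-squares fits
#'
#' \deqn{F = \frac{(SSE_r - SSE_f)/(p_f - p_r)}{SSE_f/(n - p_f)}}
#' with the p-value from the F distribution. Both fits must use the same
#' training rows; the restricted parameter set must be strictly smaller.
#'
#' @param restricted,full `fir_fit` objects.
#' @return List with `F`, `df1`, `df2`, `p_value`, `sse_restricted`,
#'   `sse_full`.
#' @export
f_test_nested <- function(restricted, full) {
  if (restricted$n != full$n) {
    stop("fits use different numbers of rows; refit on common data")
  }
  df1 <- full$p_mean - restricted$p_mean
  if (df1 < 0) stop("restricted model has more parameters than full")
  df2 <- full$n - full$p_mean
  num <- max(restricted$sse - full$sse, 0)
  Fstat <- if (df1 == 0) 0 else (num / df1) / (full$sse / df2)
  pval <- if (df1 == 0) 1 else pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = df1, df2 = df2, p_value = pval,
       sse_restricted = restricted$sse, sse_full = full$sse)
}
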