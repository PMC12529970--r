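#' @name mixed_effects
#' @title Two-level nonlinear mixed-effects DBH models
#' @description
#' The final model stage adds nested random effects to the growth-stage
#' dummy model: region-level effects \eqn{u_i \sim N(0, \Psi_1)} on a chosen
#' subset of the parameters (diagonal covariance by default), a plot-level
#' random intercept \eqn{v_{ij} \sim N(0, \psi_2)}, and residual errors
#' \eqn{\varepsilon_{ijk} \sim N(0, \sigma^2 \Gamma_s)} optionally stratified
#' by growth stage with the young class as reference. Estimation uses the
#' Lindstrom-Bates alternating scheme (penalized nonlinear least squares for
#' fixed effects and random-effect modes, REML or ML updates of the variance
#' components on the linearized model) as implemented by \pkg{nlme}, the
#' standard engine for this model family in forest biometrics. Mean
#' functions that are linear in their parameters are dispatched to the
#' linear-mixed-model solver, to which the scheme reduces exactly in that
#' case.
NULL

#' @importFrom nlme nlme lme fixef ranef VarCorr pdDiag varIdent nlmeControl
#'   lmeControl
NULL

# build the nlme model formula string for a generalized/dummy spec
spec_formula <- function(spec) {
  if (spec$form_id == "dummy") {
    sidx <- match(spec$stages, stage_levels())
    staged <- function(p) {
      paste0("(", paste0(p, sidx, " * G", sidx, collapse = " + "), ")")
    }
    term <- function(p) if (p == spec$placement) staged(p) else p
  } else {
    term <- function(p) p
  }
  rhs <- paste0(term("b"), " * lh_m^", term("c_lh"))
  for (cv in spec$covariates) {
    rhs <- paste0(rhs, " * ", cv, "^", term(exponent_name(cv)))
  }
  paste0("dbh_cm ~ ", term("a"), " + ", rhs)
}

# data frame with stage factor and dummy columns, region/plot factors and a
# globally unique plot key ("region/plot", matching nlme's nested ranef
# row names)
nlme_frame <- function(table) {
  d <- table
  if (!"plot" %in% names(d)) d$plot <- "P1"
  if ("age_y" %in% names(d)) {
    d$stage <- factor(as.character(assign_growth_stage(d$age_y)),
                      levels = stage_levels())
    G <- build_stage_design(d$age_y)
    colnames(G) <- paste0("G", 1:5)
    d <- cbind(d, G)
  }
  d$region <- factor(d$region)
  d$plot <- factor(d$plot)
  d$plot_key <- paste(as.character(d$region), as.character(d$plot),
                      sep = "/")
  d
}

re_formula <- function(pars) {
  if (length(pars) == 1L) {
    stats::as.formula(paste(pars, "~ 1"))
  } else {
    pdDiag(stats::as.formula(paste(paste(pars, collapse = " + "), "~ 1")))
  }
}

#' Fit the two-level nonlinear mixed-effects model
#'
#' @param train Inventory data.frame with at least two regions (and two
#'   plots per region when a plot level is requested).
#' @param mean_spec The mean function: a fitted `fir_fit` (dummy or
#'   generalized model; supplies structure and starting values), a
#'   `fir_model_spec`, or the string `"intercept"` for the
#'   intercept-only linear benchmark \eqn{y = a + u + \varepsilon}.
#' @param re_region Region-level random effects: `"intercept"` (default,
#'   robust), `"all"` (every mean parameter, diagonal covariance), or a
#'   character vector of parameter names.
#' @param re_plot Plot-level random effects: `"intercept"` or `"none"`.
#' @param variance `"constant"` or `"stage"` (residual variance multipliers
#'   per growth stage, young fixed at 1).
#' @param method `"REML"` (default) or `"ML"`. Use ML when the fit will be
#'   compared against models with different fixed effects.
#' @param control Passed to [nlme::nlmeControl()] overrides.
#' @return An object of class `fir_nlme`: fixed-effect estimates and
#'   standard errors, variance components (`psi1` matrix, `psi2_var`,
#'   `sigma2`, `stage_multipliers`), per-group random-effect estimates
#'   (EBLUPs), log-likelihood, parameter count `p` (fixed + variance
#'   parameters), convergence flag, and the underlying \pkg{nlme} fit.
#' @export
fit_nlme <- function(train, mean_spec, re_region = "intercept",
                     re_plot = c("intercept", "none"),
                     variance = c("constant", "stage"),
                     method = c("REML", "ML"), control = list()) {
  re_plot <- match.arg(re_plot)
  variance <- match.arg(variance)
  method <- match.arg(method)
  if (length(unique(train$region)) < 2L) {
    stop("need at least two regions")
  }

  linear <- identical(mean_spec, "intercept")
  start_fit <- NULL
  if (inherits(mean_spec, "fir_fit")) {
    start_fit <- mean_spec
    spec <- mean_spec$spec
  } else if (inherits(mean_spec, "fir_model_spec")) {
    spec <- mean_spec
  } else if (linear) {
    spec <- NULL
  } else {
    stop("mean_spec must be a fir_fit, fir_model_spec, or \"intercept\"")
  }

  d <- nlme_frame(train)
  params <- if (linear) "a" else spec$params
  # models whose intercept carries the stage dummies have no plain "a";
  # an additive intercept random effect is then a latent parameter u0
  # appearing only in the random part
  int_par <- if ("a" %in% params) "a" else "u0"
  reg_pars <- switch(paste(re_region, collapse = ","),
                     intercept = int_par, all = params, re_region)
  if (!all(reg_pars %in% c(params, "u0"))) {
    stop("unknown parameter in re_region")
  }

  ctrl_args <- utils::modifyList(
    list(maxIter = 100, msMaxIter = 200, pnlsMaxIter = 10,
         returnObject = TRUE), control)

  if (linear) {
    rand <- if (re_plot == "intercept") {
      list(region = ~1, plot = ~1)
    } else {
      list(region = ~1)
    }
    wts <- if (variance == "stage") varIdent(form = ~1 | stage) else NULL
    fit <- lme(dbh_cm ~ 1, data = d, random = rand, weights = wts,
               method = method,
               control = do.call(lmeControl,
                                 ctrl_args[setdiff(names(ctrl_args),
                                                   c("pnlsMaxIter"))]))
    converged <- TRUE
    fallback <- FALSE
  } else {
    if (is.null(start_fit)) {
      start_fit <- fit_nls(spec, d)
    }
    start <- start_fit$coef[params]
    if (any(!is.finite(start))) {
      stop("mean_spec contains unidentifiable parameters; refit on data ",
           "containing the relevant growth stages")
    }
    form_str <- spec_formula(spec)
    if ("u0" %in% reg_pars || (re_plot == "intercept" && int_par == "u0")) {
      form_str <- paste(form_str, "+ u0")
    }
    form <- stats::as.formula(form_str)
    fixed <- stats::as.formula(paste(paste(params, collapse = " + "), "~ 1"))
    rand <- if (re_plot == "intercept") {
      list(region = re_formula(reg_pars), plot = re_formula(int_par))
    } else {
      list(region = re_formula(reg_pars))
    }
    wts <- if (variance == "stage") varIdent(form = ~1 | stage) else NULL
    converged <- TRUE
    call_nlme <- function(rnd) {
      withCallingHandlers(
        nlme(form, data = d, fixed = fixed, random = rnd,
             groups = if (length(rnd) == 2L) ~region / plot else ~region,
             start = start, weights = wts, method = method,
             control = do.call(nlmeControl, ctrl_args)),
        warning = function(w) {
          if (grepl("maximum number of iterations", conditionMessage(w))) {
            converged <<- FALSE
            invokeRestart("muffleWarning")
          }
        })
    }
    fallback <- FALSE
    fit <- tryCatch(call_nlme(rand), error = function(e) e)
    if (inherits(fit, "error") && length(reg_pars) > 1L) {
      # singular multi-parameter region covariance: retry intercept-only
      reg_pars <- int_par
      rand <- if (re_plot == "intercept") {
        list(region = re_formula(int_par), plot = re_formula(int_par))
      } else {
        list(region = re_formula(int_par))
      }
      fallback <- TRUE
      fit <- tryCatch(call_nlme(rand), error = function(e) e)
    }
    if (inherits(fit, "error")) {
      stop("mixed-effects fit failed: ", conditionMessage(fit))
    }
  }

  sig2 <- fit$sigma^2
  re <- fit$modelStruct$reStruct
  psi1 <- sig2 * as.matrix(re[["region"]])
  dimnames(psi1) <- list(reg_pars, reg_pars)
  psi2 <- if (re_plot == "intercept") {
    unname(sig2 * as.matrix(re[["plot"]])[1, 1])
  } else {
    0
  }

  stage_mult <- setNames(rep(1, 5), stage_levels())
  sigma2 <- sig2
  if (variance == "stage") {
    vs <- coef(fit$modelStruct$varStruct, unconstrained = FALSE,
               allCoef = TRUE)
    rel <- setNames(rep(NA_real_, 5), stage_levels())
    rel[names(vs)] <- vs
    rel <- rel / rel[["young"]]
    sigma2 <- sig2 * (coef(fit$modelStruct$varStruct,
                           unconstrained = FALSE,
                           allCoef = TRUE)[["young"]])^2
    stage_mult <- rel^2
  }

  rf <- ranef(fit)
  if (is.data.frame(rf)) rf <- list(region = rf)
  u <- as.matrix(rf[["region"]])
  colnames(u) <- reg_pars
  v <- if (re_plot == "intercept") {
    pl <- rf[["plot"]]
    setNames(pl[["a"]] %||% pl[["u0"]] %||% pl[["(Intercept)"]],
             rownames(pl))
  } else {
    NULL
  }

  smry <- summary(fit)$tTable
  fixed_est <- fixef(fit)
  names(fixed_est) <- params
  se <- smry[, "Std.Error"]
  names(se) <- params

  n_varpar <- length(coef(fit$modelStruct)) + 1L
  structure(list(
    fit = fit, linear = linear, spec = spec,
    fixed = fixed_est, se = se,
    psi1 = psi1, psi2_var = psi2, sigma2 = sigma2,
    stage_multipliers = stage_mult,
    ranef_region = u, ranef_plot = v,
    loglik = as.numeric(logLik(fit)),
    method = method, n = fit$dims$N,
    p = length(fixed_est) + n_varpar,
    re_region = reg_pars, re_plot = re_plot, variance = variance,
    converged = converged, fallback = fallback),
    class = "fir_nlme")
}

#' @export
print.fir_nlme <- function(x, ...) {
  cat(sprintf(
    "Two-level mixed-effects DBH model (%s, loglik = %.2f, AIC = %.1f)\n",
    x$method, x$loglik, compute_aic(x$loglik, x$p)))
  cat("Fixed effects:\n")
  print(round(cbind(Estimate = x$fixed, `Std.Error` = x$se), 5))
  cat(sprintf("Region-level variances (%s): %s\n",
              paste(x$re_region, collapse = ", "),
              paste(signif(diag(x$psi1), 5), collapse = ", ")))
  cat(sprintf("Plot intercept variance: %.5f; residual sigma2: %.5f\n",
              x$psi2_var, x$sigma2))
  if (x$variance == "stage") {
    cat("Stage variance multipliers:",
        paste(sprintf("%s=%.3f", names(x$stage_multipliers),
                      x$stage_multipliers), collapse = ", "), "\n")
  }
  if (!x$converged) cat("NOTE: convergence not reached\n")
  if (x$fallback) cat("NOTE: region covariance fell back to intercept-only\n")
  invisible(x)
}

#' @export
logLik.fir_nlme <- function(object, ...) {
  structure(object$loglik, df = object$p, nobs = object$n, class = "logLik")
}

# mean prediction with per-region parameter offsets u (named) and plot
# intercept offsets v (named by "region/plot")
nlme_mean <- function(object, d, u = NULL, v = NULL) {
  params <- names(object$fixed)
  if (object$linear) {
    pred <- rep(object$fixed[["a"]], nrow(d))
  } else {
    pred <- rep(NA_real_, nrow(d))
  }
  regions <- as.character(d$region)
  for (r in unique(regions)) {
    idx <- regions == r
    theta <- object$fixed
    shift <- 0
    if (!is.null(u) && r %in% rownames(u)) {
      known <- intersect(colnames(u), names(theta))
      theta[known] <- theta[known] + u[r, known]
      if ("u0" %in% colnames(u)) shift <- u[r, "u0"]
    }
    pred[idx] <- shift + if (object$linear) {
      theta[["a"]]
    } else {
      eval_form_quiet(object$spec, theta, d[idx, , drop = FALSE])
    }
  }
  if (!is.null(v)) {
    add <- v[d$plot_key]
    add[is.na(add)] <- 0
    pred <- pred + unname(add)
  }
  pred
}

#' Predict DBH from a fitted mixed-effects model
#'
#' `level = "marginal"` sets all random effects to zero; `"region"` adds the
#' region EBLUPs; `"plot"` adds region and plot EBLUPs. Rows belonging to
#' groups unseen in training fall back to the next-coarser level and are
#' flagged in the `"unknown_groups"` attribute.
#'
#' @param object A `fir_nlme` fit.
#' @param newdata Inventory data.frame.
#' @param level `"marginal"`, `"region"`, or `"plot"`.
#' @param ... Unused.
#' @return Numeric vector of predicted DBH (cm).
#' @export
predict.fir_nlme <- function(object, newdata,
                             level = c("plot", "region", "marginal"), ...) {
  level <- match.arg(level)
  d <- nlme_frame(newdata)
  u <- if (level %in% c("region", "plot")) object$ranef_region else NULL
  v <- if (level == "plot") object$ranef_plot else NULL
  pred <- nlme_mean(object, d, u, v)
  unknown <- character()
  if (!is.null(u)) {
    unknown <- setdiff(unique(as.character(d$region)), rownames(u))
  }
  if (!is.null(v)) {
    unknown <- c(unknown, setdiff(unique(d$plot_key), names(v)))
  }
  if (length(unknown)) attr(pred, "unknown_groups") <- unknown
  pred
}

#' Calibrate random effects for unseen groups (EBLUP)
#'
#' Computes the posterior mode of a new group's random-effect vector given
#' the fitted fixed effects and variance components: for a new region,
#' minimize
#' \deqn{\sum_k (y_k - f(x_k, \theta + u))^2 / (\sigma^2 \Gamma_{s_k}) + u' \Psi_1^{-1} u}
#' over `u`; for a new plot within a known region, the scalar analogue with
#' \eqn{\psi_2}. In the linear case this reduces to the familiar shrinkage
#' estimator \eqn{n\sigma_u^2 / (n\sigma_u^2 + \sigma^2)\,(\bar y - \beta)}.
#'
#' @param fit A `fir_nlme`.
#' @param newdata Inventory rows for groups absent from training (several
#'   groups allowed; each is calibrated separately).
#' @param level `"region"` or `"plot"`.
#' @return Matrix of random-effect estimates, one row per new group (columns
#'   are the region-level parameters, or a single `a` column for plots).
#'   Groups with no usable rows get a zero vector and are listed in the
#'   `"empty_groups"` attribute.
#' @export
estimate_eblup <- function(fit, newdata, level = c("region", "plot")) {
  level <- match.arg(level)
  d <- nlme_frame(newdata)
  w <- if ("stage" %in% names(d) && fit$variance == "stage") {
    fit$sigma2 * unname(fit$stage_multipliers[as.integer(d$stage)])
  } else {
    rep(fit$sigma2, nrow(d))  # per-row residual variance
  }

  if (level == "region") {
    q <- length(fit$re_region)
    psi <- fit$psi1
    groups <- unique(as.character(d$region))
    out <- matrix(0, length(groups), q,
                  dimnames = list(groups, fit$re_region))
    if (max(diag(psi)) < 1e-12) return(out)  # no between-group variance
    psi_inv <- solve(psi + diag(1e-12, q))
    empty <- character()
    for (g in groups) {
      idx <- which(as.character(d$region) == g)
      dg <- d[idx, , drop = FALSE]
      yg <- dg$dbh_cm
      wg <- w[idx]
      ok <- is.finite(yg)
      if (!any(ok)) {
        empty <- c(empty, g)
        next
      }
      obj <- function(u) {
        theta <- fit$fixed
        names(u) <- fit$re_region
        known <- intersect(fit$re_region, names(theta))
        theta[known] <- theta[known] + u[known]
        shift <- if ("u0" %in% fit$re_region) u[["u0"]] else 0
        mu <- shift + if (fit$linear) rep(theta[["a"]], nrow(dg)) else
          eval_form_quiet(fit$spec, theta, dg)
        if (any(!is.finite(mu[ok]))) return(1e12)
        sum((yg[ok] - mu[ok])^2 / wg[ok]) +
          drop(t(u) %*% psi_inv %*% u)
      }
      opt <- nlminb(rep(0, q), obj)
      out[g, ] <- opt$par
    }
    if (length(empty)) attr(out, "empty_groups") <- empty
    return(out)
  }

  # new plots within known regions: scalar intercept effect
  if (fit$psi2_var < 1e-12) {
    groups <- unique(d$plot_key)
    return(matrix(0, length(groups), 1, dimnames = list(groups, "a")))
  }
  base <- nlme_mean(fit, d, u = fit$ranef_region, v = NULL)
  groups <- unique(d$plot_key)
  out <- matrix(0, length(groups), 1, dimnames = list(groups, "a"))
  empty <- character()
  for (g in groups) {
    idx <- which(d$plot_key == g)
    r <- d$dbh_cm[idx] - base[idx]
    wg <- w[idx]
    ok <- is.finite(r)
    if (!any(ok)) {
      empty <- c(empty, g)
      next
    }
    # closed form: v = sum(r/w) / (sum(1/w) + 1/psi2)
    out[g, 1] <- sum(r[ok] / wg[ok]) / (sum(1 / wg[ok]) + 1 / fit$psi2_var)
  }
  if (length(empty)) attr(out, "empty_groups") <- empty
  out
}

#' Likelihood-ratio test between nested model fits
#'
#' `LRT = 2 (loglik_full - loglik_restricted)` referred to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference. When the two models share identical fixed effects and differ
#' only in random structure the test concerns variance components on the
#' boundary of their space, and the chi-squared p-value is conservative;
#' this is flagged. Comparing models that differ in fixed effects requires
#' both log-likelihoods to be ML (not REML).
#'
#' @param restricted,full `fir_fit` or `fir_nlme` objects fitted to the same
#'   data.
#' @return List with `lrt`, `df`, `p_value`, `boundary`.
#' @export
likelihood_ratio_test <- function(restricted, full) {
  get_ll <- function(m) {
    if (inherits(m, "fir_fit")) {
      list(ll = m$loglik, p = m$p, pfix = m$p_mean, reml = FALSE, n = m$n)
    } else if (inherits(m, "fir_nlme")) {
      list(ll = m$loglik, p = m$p, pfix = length(m$fixed),
           reml = m$method == "REML", n = m$n)
    } else {
      stop("models must be fir_fit or fir_nlme objects")
    }
  }
  r <- get_ll(restricted)
  f <- get_ll(full)
  if (r$n != f$n) stop("models fitted to different numbers of rows")
  df <- f$p - r$p
  if (df <= 0) stop("full model must have more parameters than restricted")
  same_fixed <- r$pfix == f$pfix
  if (r$reml != f$reml) {
    stop("log-likelihoods mix ML and REML targets; refit with method = \"ML\"")
  }
  if (!same_fixed && f$reml) {
    stop("models differing in fixed effects must both be fitted by ML")
  }
  stat <- 2 * (f$ll - r$ll)
  if (stat < -1e-6 * max(1, abs(f$ll))) {
    stop("full model has lower log-likelihood than restricted; ",
         "this indicates non-convergence")
  }
  stat <- max(stat, 0)
  list(lrt = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       boundary = same_fixed)
}
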