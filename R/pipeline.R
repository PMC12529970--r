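#' @name evaluation_pipeline
#' @title End-to-end model progression on an inventory
#' @description
#' Orchestrates the full workflow: (optional) simulation, 70/30 train/test
#' split, collinearity screening, base-form ranking, covariate expansion,
#' growth-stage dummy placement search, and the two-level mixed-effects
#' fit, evaluating every stage on both sets and testing each structural
#' addition (F-test for the covariate expansion, likelihood-ratio tests for
#' the random-effect levels).
NULL

#' Run the full DBH modeling pipeline
#'
#' Stages evaluated, in order: the best three-parameter base form (M7), the
#' covariate-expanded generalized model, the growth-stage dummy model
#' (AIC-chosen placement), and the two-level mixed-effects model (marginal
#' fit by ML for comparability; test predictions use plot-level EBLUPs).
#' Later stages are skipped, with an explicit status, if an earlier stage
#' fails.
#'
#' @param input A `fir_sim_config` (the inventory is simulated) or an
#'   inventory data.frame.
#' @param seed Integer seed driving simulation and the train/test split.
#' @param fraction Training fraction for the split.
#' @param candidates Covariate columns offered to the expansion.
#' @param re_region,re_plot Random-effect structure for the final stage.
#' @return A list of class `fir_stage_report`:
#' \describe{
#'   \item{stages}{data.frame with one row per stage: train/test R2, RMSE
#'     (cm), TRE (percent), AIC, n, p.}
#'   \item{tests}{list with `f_expansion` (M7 vs generalized),
#'     `lrt_region` (dummy vs + region effects), `lrt_plot` (+ plot level).}
#'   \item{screening}{[select_predictors()] report.}
#'   \item{ranking}{[rank_base_models()] table.}
#'   \item{placement}{chosen dummy placement and its AIC table.}
#'   \item{models}{the fitted model objects.}
#'   \item{status}{per-stage status strings.}
#' }
#' @export
run_pipeline <- function(input, seed = 1L, fraction = 0.7,
                         candidates = c("lcd_m", "density_ha"),
                         re_region = "intercept", re_plot = "intercept") {
  if (inherits(input, "fir_sim_config")) {
    sim <- simulate_inventory(input, seed)
    table <- sim$table
  } else {
    sim <- NULL
    table <- input
  }
  sp <- split_train_test(table, fraction, seed)
  train <- sp$train
  test <- sp$test

  status <- character()
  models <- list()
  stage_rows <- list()
  tests <- list()

  eval_stage <- function(name, fit, pred_train, pred_test) {
    mtr <- compute_metrics(train$dbh_cm, pred_train, fit$p)
    mte <- compute_metrics(test$dbh_cm, pred_test, fit$p)
    ll <- if (inherits(fit, "fir_nlme")) fit$loglik else fit$loglik
    data.frame(stage = name,
               r2_train = mtr$r2, rmse_train = mtr$rmse_cm,
               tre_train = mtr$tre_pct,
               r2_test = mte$r2, rmse_test = mte$rmse_cm,
               tre_test = mte$tre_pct,
               aic = compute_aic(ll, fit$p),
               n_train = mtr$n, p = fit$p,
               stringsAsFactors = FALSE)
  }

  screening <- tryCatch(
    select_predictors(train, c("lh_m", candidates), "dbh_cm"),
    error = function(e) e)
  status["screening"] <- if (inherits(screening, "error")) {
    paste("failed:", conditionMessage(screening))
  } else "ok"

  ranking <- tryCatch(rank_base_models(train, test), error = function(e) e)
  status["ranking"] <- if (inherits(ranking, "error")) {
    paste("failed:", conditionMessage(ranking))
  } else "ok"

  m7 <- tryCatch(fit_nls("M7", train), error = function(e) e)
  if (inherits(m7, "error")) {
    status["base"] <- paste("failed:", conditionMessage(m7))
  } else {
    status["base"] <- "ok"
    models$base <- m7
    stage_rows$base <- eval_stage("M7", m7, predict(m7, train),
                                  predict(m7, test))
  }

  gen <- NULL
  if (!inherits(m7, "error")) {
    gen <- tryCatch(expand_covariates(m7, train, candidates),
                    error = function(e) e)
    if (inherits(gen, "error")) {
      status["generalized"] <- paste("failed:", conditionMessage(gen))
      gen <- NULL
    } else {
      status["generalized"] <- "ok"
      models$generalized <- gen
      stage_rows$generalized <- eval_stage(
        "generalized", gen, predict(gen, train), predict(gen, test))
      # refit M7 through the same machinery for a clean nested F-test
      tests$f_expansion <- f_test_nested(
        fit_nls(model_spec("generalized", character()), train,
                init = c(a = m7$coef[["a"]], b = m7$coef[["b"]],
                         c_lh = m7$coef[["c"]])), gen)
    }
  } else {
    status["generalized"] <- "skipped"
  }

  dummy <- NULL
  placement <- NULL
  if (!is.null(gen)) {
    placement <- tryCatch(search_dummy_placement(train, gen),
                          error = function(e) e)
    if (inherits(placement, "error")) {
      status["dummy"] <- paste("failed:", conditionMessage(placement))
      placement <- NULL
    } else {
      dummy <- placement$fits[[placement$best]]
      status["dummy"] <- "ok"
      models$dummy <- dummy
      ptr <- predict(dummy, train)
      pte <- predict(dummy, test)
      stage_rows$dummy <- eval_stage("dummy", dummy, ptr, pte)
    }
  } else {
    status["dummy"] <- "skipped"
  }

  if (!is.null(dummy)) {
    m_region <- tryCatch(
      fit_nlme(train, dummy, re_region = re_region, re_plot = "none",
               method = "ML"),
      error = function(e) e)
    m_two <- tryCatch(
      fit_nlme(train, dummy, re_region = re_region, re_plot = re_plot,
               method = "ML"),
      error = function(e) e)
    if (inherits(m_two, "error")) {
      status["mixed"] <- paste("failed:", conditionMessage(m_two))
    } else {
      status["mixed"] <- "ok"
      models$mixed <- m_two
      stage_rows$mixed <- eval_stage(
        "two_level", m_two,
        predict(m_two, train, level = "plot"),
        predict(m_two, test, level = "plot"))
      if (!inherits(m_region, "error")) {
        models$mixed_region <- m_region
        tests$lrt_region <- tryCatch(
          likelihood_ratio_test(dummy, m_region), error = function(e) NULL)
        tests$lrt_plot <- tryCatch(
          likelihood_ratio_test(m_region, m_two), error = function(e) NULL)
      }
    }
  } else {
    status["mixed"] <- "skipped"
  }

  stages <- do.call(rbind, stage_rows)
  rownames(stages) <- NULL
  structure(list(
    stages = stages, tests = tests,
    screening = if (inherits(screening, "error")) NULL else screening,
    ranking = if (inherits(ranking, "error")) NULL else ranking$table,
    placement = if (is.null(placement)) NULL else
      list(best = placement$best, table = placement$table),
    models = models, status = status, seed = seed,
    n_train = nrow(train), n_test = nrow(test)),
    class = "fir_stage_report")
}

#' @export
print.fir_stage_report <- function(x, ...) {
  cat(sprintf("DBH pipeline report (train %d / test %d, seed %d)\n",
              x$n_train, x$n_test, x$seed))
  if (!is.null(x$stages)) {
    s <- x$stages
    num <- vapply(s, is.numeric, logical(1))
    s[num] <- lapply(s[num], function(v) round(v, 4))
    print(s)
  }
  if (!is.null(x$tests$f_expansion)) {
    cat(sprintf("Covariate expansion F = %.1f (p = %.3g)\n",
                x$tests$f_expansion$F, x$tests$f_expansion$p_value))
  }
  if (!is.null(x$tests$lrt_region)) {
    cat(sprintf("Region random effects LRT = %.1f (p = %.3g)\n",
                x$tests$lrt_region$lrt, x$tests$lrt_region$p_value))
  }
  if (!is.null(x$tests$lrt_plot)) {
    cat(sprintf("Plot level LRT = %.1f (p = %.3g)\n",
                x$tests$lrt_plot$lrt, x$tests$lrt_plot$p_value))
  }
  bad <- x$status[x$status != "ok"]
  if (length(bad)) {
    cat("Stage status:", paste(names(bad), bad, sep = "=",
                               collapse = "; "), "\n")
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the numeric content of a stage report (stage metrics, test
#' statistics, screening summary, placement table) to a JSON file that
#' [read_stage_report()] restores losslessly.
#'
#' @param report A `fir_stage_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stage_report <- function(report, path) {
  payload <- list(
    seed = report$seed, n_train = report$n_train, n_test = report$n_test,
    stages = report$stages, status = as.list(report$status),
    tests = lapply(report$tests, function(t) t[vapply(t, is.numeric,
                                                      logical(1))]),
    placement = report$placement,
    ranking = report$ranking)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a serialized pipeline report
#'
#' @param path Path written by [write_stage_report()].
#' @return A list with the report's numeric content (not the fitted model
#'   objects).
#' @export
read_stage_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$stages <- as.data.frame(x$stages)
  if (!is.null(x$ranking)) x$ranking <- as.data.frame(x$ranking)
  x
}
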