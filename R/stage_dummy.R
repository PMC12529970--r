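#' @name stage_dummy
#' @title Growth-stage dummy-variable models
#' @description
#' The growth-stage dummy model replaces exactly one parameter of the
#' generalized model with five stage-specific coefficients selected by
#' indicator (dummy) variables:
#' \deqn{DBH = a + (b_1 G_1 + \dots + b_5 G_5)\,LH^{c_{lh}} LCD^{c_{lcd}} S^{c_s} + \varepsilon}
#' for placement on the scale parameter `b`, and analogously for the
#' intercept or an exponent. Restricting one parameter keeps the model
#' parsimonious while letting the allometry shift across age classes; the
#' placement itself is chosen by AIC over all candidates.
NULL

#' One-hot growth-stage design matrix
#'
#' @param ages Integer vector of ages in years, all `>= 1`.
#' @return `length(ages) x 5` indicator matrix, columns ordered young to
#'   overmature; every row sums to 1.
#' @export
build_stage_design <- function(ages) {
  st <- assign_growth_stage(ages)
  G <- matrix(0, length(ages), 5,
              dimnames = list(NULL, stage_levels()))
  G[cbind(seq_along(ages), as.integer(st))] <- 1
  G
}

# starting values for a dummy spec from a generalized fit: every stage
# coefficient starts at the generalized model's single estimate, which makes
# the generalized optimum reachable (nesting identity)
dummy_init_from <- function(gfit, spec) {
  cf <- gfit$coef
  ini <- setNames(numeric(length(spec$params)), spec$params)
  sidx <- match(spec$stages, stage_levels())
  staged <- paste0(spec$placement, sidx)
  for (p in spec$params) {
    ini[p] <- if (p %in% staged) cf[[spec$placement]] else cf[[p]]
  }
  ini
}

#' Fit a growth-stage dummy-variable model
#'
#' Nonlinear least squares with five stage-specific coefficients substituted
#' at the chosen placement. All stage coefficients are initialized at the
#' generalized model's single estimate, so the dummy model can never fit
#' worse than the generalized model it nests. Stages absent from the
#' training data are excluded from estimation and flagged as unidentifiable
#' (their coefficients are `NA`).
#'
#' @param train Inventory data.frame.
#' @param placement Parameter carrying the dummies: `"a"`, `"b"` (default),
#'   `"c_lh"`, or a covariate exponent (`"c_lcd"`, `"c_s"`).
#' @param covariates Generalized-model covariates beyond `lh_m`.
#' @param init Optional `fir_fit` of the generalized model (or a named
#'   vector) supplying starting values.
#' @param constrain_equal If `TRUE`, constrain all five stage coefficients
#'   to a common value; the result is exactly the generalized model fit
#'   (used to verify the nesting identity).
#' @return A `fir_fit` whose `coef` contains the five stage coefficients
#'   (`NA` for unidentifiable stages listed in `$unidentifiable`).
#' @export
fit_dummy_model <- function(train, placement = "b",
                            covariates = c("lcd_m", "density_ha"),
                            init = NULL, constrain_equal = FALSE) {
  if (inherits(init, "fir_fit") && missing(covariates)) {
    covariates <- init$spec$covariates
  }
  if (constrain_equal) {
    return(fit_nls(model_spec("generalized", covariates), train))
  }
  present <- stage_levels()[sort(unique(as.integer(
    assign_growth_stage(train$age_y[is.finite(train$age_y) &
                                      train$age_y >= 1]))))]
  if (length(present) < 2L) {
    warning("fewer than two growth stages present; dummy model degenerate")
  }
  spec <- model_spec("dummy", covariates, placement, stages = present)
  ini <- NULL
  if (inherits(init, "fir_fit")) {
    ini <- dummy_init_from(init, spec)
  } else if (!is.null(init)) {
    ini <- init[spec$params]
  }
  fit <- fit_nls(spec, train, init = ini)
  absent <- setdiff(stage_levels(), present)
  if (length(absent)) {
    aidx <- match(absent, stage_levels())
    miss <- paste0(placement, aidx)
    fit$coef <- c(fit$coef, setNames(rep(NA_real_, length(miss)), miss))
    fit$se <- c(fit$se, setNames(rep(NA_real_, length(miss)), miss))
    fit$unidentifiable <- miss
  } else {
    fit$unidentifiable <- character()
  }
  fit
}

#' Choose the dummy-variable placement by AIC
#'
#' Fits the dummy model with the stage coefficients placed on each parameter
#' of the generalized model in turn and returns the AIC-minimal placement
#' together with the full comparison table. Individual placement failures
#' are recorded, not fatal (an error is raised only if every placement
#' fails).
#'
#' @param train Inventory data.frame.
#' @param generalized Optional fitted generalized model used for starting
#'   values (fitted on `train` if omitted).
#' @param covariates Generalized-model covariates beyond `lh_m`.
#' @return A list of class `fir_placement_search`: `best` (placement name),
#'   `table` (one row per placement with loglik and AIC), `fits`.
#' @export
search_dummy_placement <- function(train, generalized = NULL,
                                   covariates = c("lcd_m", "density_ha")) {
  if (is.null(generalized)) {
    generalized <- fit_nls(model_spec("generalized", covariates), train)
  } else if (missing(covariates)) {
    covariates <- generalized$spec$covariates
  }
  placements <- c("a", "b", "c_lh",
                  vapply(covariates, exponent_name, character(1)))
  fits <- setNames(lapply(placements, function(pl) {
    tryCatch(fit_dummy_model(train, pl, covariates, init = generalized),
             error = function(e) e)
  }), placements)
  rows <- lapply(placements, function(pl) {
    f <- fits[[pl]]
    if (inherits(f, "fir_fit")) {
      data.frame(placement = pl, loglik = f$loglik,
                 aic = compute_aic(f$loglik, f$p), converged = f$converged,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(placement = pl, loglik = NA_real_, aic = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$aic))) {
    stop("all dummy placements failed: ",
         paste(vapply(fits, function(f) conditionMessage(f), character(1)),
               collapse = "; "))
  }
  best <- tab$placement[which.min(tab$aic)]
  structure(list(best = best, table = tab, fits = fits),
            class = "fir_placement_search")
}

#' @export
print.fir_placement_search <- function(x, ...) {
  cat("Dummy-variable placement search (best:", x$best, ")\n")
  print(transform(x$table, loglik = round(loglik, 2), aic = round(aic, 1)))
  invisible(x)
}
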