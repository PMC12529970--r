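test_that("linear benchmark matches the balanced one-way REML closed form", {
  toy <- balanced_toy()
  fit <- fit_nlme(toy, "intercept", re_region = "intercept",
                  re_plot = "none")
  expect_close(fit$fixed[["a"]], 4, 1e-4)
  expect_close(fit$sigma2, 1, 1e-4)
  expect_close(fit$psi1[1, 1], 23 / 3, 1e-3)
})

test_that("EBLUP calibration matches the scalar shrinkage formula", {
  fit <- fit_nlme(balanced_toy(), "intercept", re_region = "intercept",
                  re_plot = "none")
  nd <- data.frame(region = "C", dbh_cm = c(1, 2, 3))
  u <- estimate_eblup(fit, nd, level = "region")
  expect_close(u[1, 1], -23 / 12, 1e-4)
  # no between-group variance: EBLUP is exactly zero
  fit0 <- fit
  fit0$psi1[1, 1] <- 0
  expect_equal(unname(estimate_eblup(fit0, nd, "region")[1, 1]), 0)
  # many observations: shrinkage vanishes toward the raw group deviation
  big <- data.frame(region = "D", dbh_cm = rep(2, 4000))
  expect_close(estimate_eblup(fit, big, "region")[1, 1], -2, 1e-2)
  # empty group flagged with zero vector
  empty <- data.frame(region = "E", dbh_cm = NA_real_)
  u0 <- estimate_eblup(fit, empty, "region")
  expect_equal(unname(u0[1, 1]), 0)
  expect_equal(attr(u0, "empty_groups"), "E")
})

test_that("zero generating variances collapse to the fixed-effects fit", {
  cfg <- small_config(40)
  cfg$psi1 <- matrix(0, 9, 9, dimnames = dimnames(cfg$psi1))
  cfg$psi2_var <- 0
  sim <- simulate_inventory(cfg, seed = 31)
  dum <- fit_dummy_model(sim$table)
  mix <- suppressWarnings(
    fit_nlme(sim$table, dum, re_region = "intercept", re_plot = "intercept",
             method = "ML", control = list(tolerance = 1e-9)))
  ref <- dum$coef[names(mix$fixed)]
  expect_true(all(abs(mix$fixed - ref) <= 1e-3 * pmax(1, abs(ref))))
  expect_lt(mix$psi1[1, 1], 0.05)
  expect_lt(mix$psi2_var, 0.05)
})

test_that("predictions honour the requested level and EBLUP structure", {
  sim <- simulate_inventory(small_config(25), seed = 32)
  dum <- fit_dummy_model(sim$table)
  mix <- suppressWarnings(
    fit_nlme(sim$table, dum, re_region = "intercept",
             re_plot = "intercept"))
  d <- sim$table
  pm <- predict(mix, d, level = "marginal")
  expect_close(pm, evaluate_form(mix$spec, mix$fixed, d), 1e-10)
  # a region with its EBLUP zeroed predicts marginally
  mix0 <- mix
  mix0$ranef_region[, 1] <- 0
  expect_close(predict(mix0, d, level = "region"), pm, 1e-10)
  # conditional plot-level predictions beat marginal ones in-sample
  pp <- predict(mix, d, level = "plot")
  expect_lt(sqrt(mean((d$dbh_cm - pp)^2)), sqrt(mean((d$dbh_cm - pm)^2)))
  # unknown groups fall back and are flagged
  nd <- d[1:5, ]
  nd$region <- "ZZ"
  pz <- predict(mix, nd, level = "plot")
  expect_equal(attr(pz, "unknown_groups")[1], "ZZ")
})

test_that("plot-level EBLUPs for new plots use the closed-form shrinkage", {
  sim <- simulate_inventory(small_config(25), seed = 33)
  dum <- fit_dummy_model(sim$table)
  mix <- suppressWarnings(
    fit_nlme(sim$table, dum, re_region = "intercept",
             re_plot = "intercept"))
  d <- sim$table[sim$table$region == "R01" & sim$table$plot == "P01", ]
  d$plot <- "NEW"
  v <- estimate_eblup(mix, d, level = "plot")
  r <- d$dbh_cm - predict(mix, d, level = "region")
  stage_i <- as.integer(assign_growth_stage(d$age_y))
  w <- mix$sigma2 * (if (mix$variance == "stage")
    mix$stage_multipliers[stage_i] else rep(1, nrow(d)))
  expect_close(v[1, 1],
               sum(r / w) / (sum(1 / w) + 1 / mix$psi2_var), 1e-8)
})

test_that("likelihood-ratio testing enforces nesting conventions", {
  lrt <- likelihood_ratio_test(
    structure(list(loglik = -105, p = 3, p_mean = 2, n = 50),
              class = "fir_fit"),
    structure(list(loglik = -100, p = 4, p_mean = 3, n = 50),
              class = "fir_fit"))
  expect_equal(lrt$lrt, 10)
  expect_equal(lrt$df, 1)
  expect_false(lrt$boundary)
  sim <- simulate_inventory(small_config(15), seed = 34)
  dum <- fit_dummy_model(sim$table)
  m_reml <- suppressWarnings(fit_nlme(sim$table, dum, method = "REML"))
  expect_error(likelihood_ratio_test(dum, m_reml), "ML")
  m_ml <- suppressWarnings(fit_nlme(sim$table, dum, method = "ML"))
  lrt2 <- likelihood_ratio_test(dum, m_ml)
  expect_true(lrt2$lrt > 0)
  expect_true(lrt2$boundary)
})

test_that("adding the plot level never decreases the restricted loglik", {
  for (seed in 35:37) {
    sim <- simulate_inventory(small_config(15), seed = seed)
    dum <- fit_dummy_model(sim$table)
    one <- suppressWarnings(
      fit_nlme(sim$table, dum, re_region = "intercept", re_plot = "none"))
    two <- suppressWarnings(
      fit_nlme(sim$table, dum, re_region = "intercept",
               re_plot = "intercept"))
    expect_true(is.finite(one$loglik) && is.finite(two$loglik))
    expect_gte(two$loglik, one$loglik - 1e-6)
  }
})

test_that("stage-stratified residual variance is exposed with young at 1", {
  sim <- simulate_inventory(small_config(30), seed = 38)
  dum <- fit_dummy_model(sim$table)
  mix <- suppressWarnings(
    fit_nlme(sim$table, dum, re_region = "intercept",
             re_plot = "intercept", variance = "stage"))
  expect_equal(unname(mix$stage_multipliers[["young"]]), 1)
  expect_true(all(mix$stage_multipliers > 0))
  expect_gt(mix$sigma2, 0)
})
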