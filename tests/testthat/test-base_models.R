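test_that("form evaluation reproduces hand arithmetic", {
  expect_equal(evaluate_form("M1", c(a = 2, b = 0.5),
                             data.frame(lh_m = 10)), 7)
  expect_equal(evaluate_form("M7", c(a = 0, b = 1, c = 1),
                             data.frame(lh_m = 5)), 5)
  g <- model_spec("generalized", c("lcd_m", "density_ha"))
  expect_equal(
    evaluate_form(g, c(a = 2.520, b = 3.842, c_lh = 0.894, c_lcd = 0.062,
                       c_s = -0.152),
                  data.frame(lh_m = 1, lcd_m = 1, density_ha = 1)),
    6.362)
  expect_error(evaluate_form("M5", c(a = 1, b = 1),
                             data.frame(lh_m = 1.2)), "domain")
  expect_error(evaluate_form("M8", c(a = 2, b = 0.1, c = 1),
                             data.frame(lh_m = 10)), "undefined")
})

test_that("reversed forms invert their published height equations", {
  D <- seq(4, 40, length.out = 20)
  h <- list(
    M5 = function(p, D) 1.3 + p[["a"]] * D^(1 / p[["b"]]),
    M6 = function(p, D) 1.3 + exp(p[["a"]] + p[["b"]] / (D + 1)),
    M8 = function(p, D) 1.3 + p[["a"]] * (1 - exp(-p[["b"]] * D^p[["c"]])),
    M9 = function(p, D) 1.3 + p[["a"]] * (1 - exp(-p[["b"]] * D))^p[["c"]],
    M10 = function(p, D) 1.3 + exp(p[["a"]] + p[["b"]] / (D + p[["c"]])))
  pars <- list(M5 = c(a = 1.4, b = 1.2), M6 = c(a = 4, b = -20),
               M8 = c(a = 30, b = 0.05, c = 1.1),
               M9 = c(a = 32, b = 0.07, c = 1.4),
               M10 = c(a = 4, b = -25, c = 2))
  for (f in names(h)) {
    H <- h[[f]](pars[[f]], D)
    expect_close(evaluate_form(f, pars[[f]], data.frame(lh_m = H)), D, 1e-9)
  }
})

test_that("every form recovers its own noise-free parameters", {
  set.seed(42)
  H <- runif(50, 4, 30)
  truth <- list(
    M1 = c(a = 1.5, b = 0.9), M2 = c(a = 0.8, b = 1.1),
    M3 = c(a = 4, b = 0.05), M4 = c(a = 9, b = -6),
    M5 = c(a = 1.2, b = 1.05), M6 = c(a = -2, b = 40),
    M7 = c(a = 2, b = 3, c = 0.9), M8 = c(a = 35, b = 0.05, c = 0.8),
    M9 = c(a = 40, b = 0.06, c = 1.3), M10 = c(a = -2, b = 45, c = 2))
  for (f in base_forms()) {
    d <- data.frame(lh_m = H)
    d$dbh_cm <- evaluate_form(f, truth[[f]], d)
    fit <- suppressWarnings(fit_nls(f, d))
    expect_true(fit$converged, label = f)
    expect_close(fit$coef, truth[[f]][fit$spec$params], 1e-6)
  }
})

test_that("linear forms match the ordinary least-squares closed form", {
  set.seed(1)
  d <- data.frame(lh_m = runif(100, 3, 25))
  d$dbh_cm <- 2 + 0.8 * d$lh_m + rnorm(100)
  fit <- fit_nls("M1", d)
  X <- cbind(1, d$lh_m)
  beta <- solve(crossprod(X), crossprod(X, d$dbh_cm))
  expect_close(unname(fit$coef), as.vector(beta), 1e-10)
})

test_that("constant heights give a flagged degenerate fit", {
  d <- data.frame(lh_m = rep(10, 30), dbh_cm = rnorm(30, 12))
  fit <- suppressWarnings(fit_nls("M7", d))
  expect_false(fit$converged)
})

test_that("reported AIC equals -2 loglik + 2p recomputed independently", {
  set.seed(4)
  d <- data.frame(lh_m = runif(80, 4, 25))
  d$dbh_cm <- 1 + 2.5 * d$lh_m^0.8 + rnorm(80, 0, 1.5)
  fit <- fit_nls("M7", d)
  sse <- sum((fit$observed - fit$fitted)^2)
  n <- fit$n
  ll <- -n / 2 * (log(2 * pi) + log(sse / n) + 1)
  expect_close(compute_aic(fit$loglik, fit$p), -2 * ll + 2 * 4, 1e-8)
  expect_close(as.numeric(stats::AIC(fit)), -2 * ll + 2 * 4, 1e-8)
})

test_that("increasing forms are monotone in height", {
  set.seed(6)
  H <- sort(runif(40, 2, 30))
  for (i in 1:10) {
    p2 <- c(a = runif(1, 0.5, 3), b = runif(1, 0.05, 1.5))
    p3 <- c(p2, c = runif(1, 0.3, 1.5))
    for (f in c("M1", "M2", "M3")) {
      pred <- evaluate_form(f, p2, data.frame(lh_m = H))
      expect_true(all(diff(pred) > 0), label = paste(f, i))
    }
    pred <- evaluate_form("M7", p3, data.frame(lh_m = H))
    expect_true(all(diff(pred) > 0), label = paste("M7", i))
  }
})

test_that("ranking reports all ten forms and wins go to the generating form", {
  set.seed(9)
  # noise-free linear data: M1 fits exactly and ranks first
  tr <- data.frame(lh_m = runif(200, 4, 28))
  tr$dbh_cm <- 3 + 0.9 * tr$lh_m
  te <- data.frame(lh_m = runif(100, 4, 28))
  te$dbh_cm <- 3 + 0.9 * te$lh_m
  rk <- suppressWarnings(rank_base_models(tr, te))
  expect_equal(nrow(rk$table), 10)
  expect_setequal(rk$table$form, base_forms())
  expect_equal(rk$table$form[1], "M1")
  expect_lt(rk$table$rmse_train[1], 1e-8)
  expect_true(all(c("r2_train", "rmse_train", "r2_test", "rmse_test",
                    "aic") %in% names(rk$table)))
})

test_that("the allometric-with-intercept form is recognized on its own data", {
  set.seed(13)
  wins <- 0L
  for (r in 1:10) {
    H <- runif(2000, 4, 30)
    d <- data.frame(lh_m = H,
                    dbh_cm = 2 + 3 * H^0.9 + rnorm(2000, 0, 2.5))
    sp <- split_train_test(d0 <- cbind(d, region = "R", plot = "P",
                                       tree = seq_len(2000), lcd_m = 1,
                                       density_ha = 1, age_y = 10),
                           0.7, seed = r)
    rk <- suppressWarnings(rank_base_models(sp$train, sp$test))
    wins <- wins + (rk$table$form[1] == "M7")
  }
  expect_gte(wins, 9)
})

test_that("covariate expansion recovers generating exponents and rejects noise", {
  set.seed(21)
  n <- 5000
  d <- data.frame(lh_m = exp(rnorm(n, 2.5, 0.3)),
                  lcd_m = exp(rnorm(n, 0.8, 0.5)),
                  density_ha = exp(rnorm(n, 7.9, 0.35)))
  truth <- c(a = 2.520, b = 3.842, c_lh = 0.894, c_lcd = 0.062,
             c_s = -0.152)
  g <- model_spec("generalized", c("lcd_m", "density_ha"))
  d$dbh_cm <- evaluate_form(g, truth, d) + rnorm(n, 0, 2)
  m7 <- fit_nls("M7", d)
  gen <- expand_covariates(m7, d, c("lcd_m", "density_ha"))
  expect_setequal(gen$spec$covariates, c("lcd_m", "density_ha"))
  for (p in c("c_lh", "c_lcd", "c_s")) {
    expect_lt(abs(gen$coef[[p]] - truth[[p]]), 2 * gen$se[[p]])
  }
  # empty candidate set: base returned unchanged (relabeled)
  gen0 <- expand_covariates(m7, d, character())
  expect_close(unname(gen0$coef),
               unname(m7$coef), 1e-4)
  # pure-noise candidate is usually rejected by AIC
  rejected <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    dd <- d[sample(n, 1500), ]
    dd$noise <- exp(rnorm(1500))
    m7r <- fit_nls("M7", dd)
    genr <- expand_covariates(m7r, dd, "noise")
    rejected <- rejected + !("noise" %in% genr$spec$covariates)
  }
  expect_gte(rejected, 8)
})

test_that("nested F-test is calibrated and powered", {
  f0 <- list(n = 100, p_mean = 3, sse = 50)
  class(f0) <- "fir_fit"
  same <- f_test_nested(f0, f0)
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  # type-I error under a true restricted model
  set.seed(31)
  rej <- 0L
  R <- 100
  for (r in 1:R) {
    n <- 400
    d <- data.frame(lh_m = runif(n, 4, 28),
                    lcd_m = exp(rnorm(n, 0.8, 0.5)))
    d$dbh_cm <- 2 + 3 * d$lh_m^0.9 + rnorm(n, 0, 2)
    m7 <- fit_nls(model_spec("generalized", character()), d)
    full <- fit_nls(model_spec("generalized", "lcd_m"), d,
                    init = c(m7$coef, c_lcd = 0))
    ft <- f_test_nested(m7, full)
    rej <- rej + (ft$p_value < 0.05)
  }
  expect_gte(rej / R, 0.01)
  expect_lte(rej / R, 0.11)
  # power against a real covariate effect
  sig <- 0L
  for (r in 1:10) {
    n <- 1000
    d <- data.frame(lh_m = runif(n, 4, 28),
                    lcd_m = exp(rnorm(n, 0.8, 0.5)))
    d$dbh_cm <- 2 + 3 * d$lh_m^0.9 * d$lcd_m^0.3 + rnorm(n, 0, 2)
    m7 <- fit_nls(model_spec("generalized", character()), d)
    full <- fit_nls(model_spec("generalized", "lcd_m"), d,
                    init = c(m7$coef, c_lcd = 0))
    sig <- sig + (f_test_nested(m7, full)$p_value < 0.001)
  }
  expect_equal(sig, 10L)
})
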