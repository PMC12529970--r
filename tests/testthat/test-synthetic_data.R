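test_that("default configuration carries the reference study conditions", {
  cfg <- default_config()
  expect_equal(cfg$psi2_var, 1.9409)
  expect_equal(cfg$sigma2, 7.8822)
  expect_equal(unname(cfg$fixed_effects[["a"]]), 4.462)
  expect_equal(unname(cfg$fixed_effects[paste0("b", 1:5)]),
               c(0.1906, 0.2008, 0.2035, 0.2138, 0.2307))
  expect_equal(unname(cfg$fixed_effects[c("c_lh", "c_lcd", "c_s")]),
               c(1.461, 0.0429, 0.0072))
  expect_equal(sum(cfg$plots_per_region), 130)
  expect_length(cfg$plots_per_region, 9)
  # region covariance: symmetric PSD by construction
  ev <- eigen(cfg$psi1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
})

test_that("simulated inventories have the nested structure and are reproducible", {
  sim <- simulate_inventory(default_config(trees_per_plot = 5), seed = 2)
  tab <- sim$table
  expect_equal(length(unique(tab$region)), 9)
  expect_equal(nrow(unique(tab[c("region", "plot")])), 130)
  expect_equal(nrow(sim$truth$u), 9)
  expect_equal(nrow(sim$truth$v), 130)
  sim2 <- simulate_inventory(default_config(trees_per_plot = 5), seed = 2)
  expect_identical(sim$table, sim2$table)
  expect_false(identical(
    sim$table, simulate_inventory(default_config(trees_per_plot = 5),
                                  seed = 3)$table))
})

test_that("degenerate variances reduce DBH to the deterministic mean", {
  cfg <- small_config(10)
  cfg$psi1 <- matrix(0, 9, 9, dimnames = dimnames(cfg$psi1))
  cfg$psi2_var <- 0
  cfg$sigma2 <- 1e-16
  cfg$min_dbh <- -Inf
  sim <- simulate_inventory(cfg, seed = 4)
  tab <- sim$table
  fe <- cfg$fixed_effects
  s <- as.integer(assign_growth_stage(tab$age_y))
  mean_dbh <- fe[["a"]] +
    fe[paste0("b", s)] * tab$lh_m^fe[["c_lh"]] *
    tab$lcd_m^fe[["c_lcd"]] * tab$density_ha^fe[["c_s"]]
  expect_close(tab$dbh_cm, unname(mean_dbh), 1e-6)
  # realized random effects are reported as exactly zero
  expect_equal(max(abs(sim$truth$u)), 0)
  expect_equal(max(abs(sim$truth$v$v)), 0)
})

test_that("study-scale marginals match the survey summary", {
  sim <- simulate_inventory(default_config(), seed = 9)
  tab <- sim$table
  expect_gt(nrow(tab), 26000)
  expect_true(all(tab$dbh_cm >= 5))
  expect_lt(abs(mean(tab$dbh_cm) - 14.69), 1.5)
  # heights and crowns span the observed LiDAR ranges
  expect_lt(abs(mean(tab$lh_m) - 13.14), 1.0)
  expect_lt(abs(mean(tab$lcd_m) - 2.32), 0.5)
  expect_true(all(tab$density_ha >= 433 & tab$density_ha <= 5311))
  expect_true(all(tab$age_y >= 6 & tab$age_y <= 40))
})

test_that("residual variance is stage-stratified as configured", {
  cfg <- default_config(trees_per_plot = 160)
  cfg$min_dbh <- -Inf  # truncation would deflate the young classes
  sim <- simulate_inventory(cfg, seed = 11)
  tab <- sim$table
  fe <- cfg$fixed_effects
  s <- as.integer(assign_growth_stage(tab$age_y))
  u <- sim$truth$u[tab$region, ]
  v <- sim$truth$v$v[match(paste(tab$region, tab$plot),
                           paste(sim$truth$v$region, sim$truth$v$plot))]
  mu <- (fe[["a"]] + u[, "a"] + v) +
    (fe[paste0("b", s)] + u[cbind(seq_len(nrow(tab)), 1L + s)]) *
    tab$lh_m^(fe[["c_lh"]] + u[, "c_lh"]) *
    tab$lcd_m^(fe[["c_lcd"]] + u[, "c_lcd"]) *
    tab$density_ha^(fe[["c_s"]] + u[, "c_s"])
  res <- tab$dbh_cm - mu
  for (k in 1:5) {
    target <- cfg$sigma2 * cfg$stage_multipliers[[k]]
    expect_lt(abs(var(res[s == k]) / target - 1), 0.1)
  }
})

test_that("plot-level variance appears iff psi2 is positive", {
  plot_mean_spread <- function(psi2) {
    cfg <- small_config(30)
    cfg$psi1 <- matrix(0, 9, 9, dimnames = dimnames(cfg$psi1))
    cfg$psi2_var <- psi2
    cfg$sigma2 <- 1e-8
    cfg$min_dbh <- -Inf
    sim <- simulate_inventory(cfg, seed = 6)
    tab <- sim$table
    fe <- cfg$fixed_effects
    s <- as.integer(assign_growth_stage(tab$age_y))
    res <- tab$dbh_cm - (fe[["a"]] +
      fe[paste0("b", s)] * tab$lh_m^fe[["c_lh"]] *
      tab$lcd_m^fe[["c_lcd"]] * tab$density_ha^fe[["c_s"]])
    var(tapply(res, paste(tab$region, tab$plot), mean))
  }
  expect_equal(plot_mean_spread(0), 0)
  expect_gt(plot_mean_spread(1.9409), 0.5)
})

test_that("invalid configurations are rejected", {
  cfg <- small_config(5)
  cfg$psi1[1, 2] <- 0.5  # asymmetric
  expect_error(simulate_inventory(cfg, 1), "symmetric")
  cfg <- small_config(5)
  cfg$psi1 <- matrix(-1, 9, 9, dimnames = dimnames(cfg$psi1))
  expect_error(simulate_inventory(cfg, 1), "positive semi-definite")
  cfg <- small_config(5)
  cfg$sigma2 <- -1
  expect_error(simulate_inventory(cfg, 1), "sigma2")
  cfg <- small_config(5)
  cfg$fixed_effects["a"] <- -500  # mean structure far below threshold
  expect_error(simulate_inventory(cfg, 1), "truncation")
})

test_that("measurement-error injection hits the target correlations", {
  sim <- simulate_inventory(default_config(trees_per_plot = 80), seed = 8)
  tab <- sim$table
  me <- add_measurement_error(tab, 1.0, 1.0, seed = 1)
  expect_identical(me$table$lh_m, tab$lh_m)
  expect_identical(me$table$lcd_m, tab$lcd_m)
  me <- add_measurement_error(tab, 0.79, 0.63, seed = 1)
  expect_true(cor(me$table$lh_m, me$clean$lh_m) > 0.76 &&
                cor(me$table$lh_m, me$clean$lh_m) < 0.82)
  expect_true(cor(me$table$lcd_m, me$clean$lcd_m) > 0.60 &&
                cor(me$table$lcd_m, me$clean$lcd_m) < 0.66)
  expect_true(all(me$table$lh_m > 0))
  expect_true(all(me$table$lcd_m > 0))
  expect_error(add_measurement_error(tab, 1.2, 0.5), "target")
  expect_error(add_measurement_error(tab, 0.5, 0), "target")
})
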