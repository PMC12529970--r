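# Shared fixtures: all data is generated in code at test time.

# small inventory with known structure, no simulation machinery involved
toy_inventory <- function(n = 12) {
  data.frame(
    region = rep(c("RA", "RB"), each = n / 2),
    plot = rep(c("P1", "P2", "P1", "P2"), each = n / 4),
    tree = seq_len(n),
    dbh_cm = seq(6, 6 + n - 1),
    lh_m = seq(5, 5 + 0.5 * (n - 1), by = 0.5),
    lcd_m = rep(2, n),
    density_ha = rep(1500, n),
    age_y = rep(c(8, 15, 23, 30), each = n / 4),
    stringsAsFactors = FALSE)
}

# the balanced one-way toy whose REML solution is known in closed form
balanced_toy <- function() {
  data.frame(region = rep(c("A", "B"), each = 3),
             dbh_cm = c(1, 2, 3, 5, 6, 7),
             stringsAsFactors = FALSE)
}

# reduced-scale study configuration (9 regions x 14 plots)
small_config <- function(trees_per_plot = 25, ...) {
  default_config(trees_per_plot = trees_per_plot,
                 plots_per_region = rep(14L, 9), ...)
}

# study configuration with all random effects and stage differences removed
null_config <- function(trees_per_plot = 16) {
  cfg <- small_config(trees_per_plot)
  cfg$psi1 <- matrix(0, 9, 9, dimnames = dimnames(cfg$psi1))
  cfg$psi2_var <- 0
  cfg$fixed_effects[paste0("b", 1:5)] <- 0.2035
  cfg$stage_multipliers[] <- 1
  cfg
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max dev %.3g <= %.3g",
                              max(abs(actual - expected)), tol))
}
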