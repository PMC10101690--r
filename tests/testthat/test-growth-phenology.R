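test_that("ring-width normalization pools trees correctly", {
  obs <- data.frame(tree_id = c("a", "b"), date = as.Date("2018-06-01"),
                    n_a = c(2, 4), n_b = c(3, 6), n_c = c(5, 10),
                    n_total = c(10, 20), prev_ring_width_mm = c(1, 2))
  norm <- normalize_counts(obs)
  # identical count/width ratios pool to that ratio
  expect_equal(norm$pooled$n_total, 10)
  expect_equal(norm$pooled$n_c, 5)
  # width 1 leaves a single tree's counts unchanged
  one <- normalize_counts(obs[1, ])
  expect_equal(one$pooled$n_total, 10)
  # missing width drops the tree with a warning
  obs$prev_ring_width_mm[2] <- NA
  expect_warning(norm2 <- normalize_counts(obs), "ring width")
  expect_equal(norm2$pooled$n_total, 10)
})

test_that("Gompertz fits recover known parameters", {
  doy <- seq(1, 160, by = 6)
  truth <- c(A = 40, beta = 200, kappa = 0.08)
  y <- gompertz(doy, truth["A"], truth["beta"], truth["kappa"])
  fit <- fit_gompertz(doy, y)
  expect_lt(max(abs(fit$par - truth) / truth), 1e-4)
  # the fitted curve approaches the asymptote
  expect_equal(predict(fit, 1000), unname(fit$par["A"]), tolerance = 1e-3)
  # fitted curve is non-decreasing on a fine grid
  expect_true(all(diff(predict(fit, seq(0, 300, by = 0.5))) >= 0))
  # adding a constant scales the asymptote upward, monotonicity preserved
  fit2 <- fit_gompertz(doy, y + 5)
  expect_gt(fit2$par["A"], fit$par["A"])
  expect_true(all(diff(predict(fit2, seq(0, 300, by = 0.5))) >= 0))
  expect_error(fit_gompertz(1:4, 1:4), "at least 6")
})

test_that("active-phase counts derive from the difference of fitted curves", {
  doy <- seq(120, 280, by = 7)
  tot <- fit_gompertz(doy, gompertz(doy, 40, exp(0.06 * 160), 0.06))
  # mature identical to total -> no active cells
  same <- derive_active_phase(tot, tot, 120:280)
  expect_true(all(same$n_ab == 0))
  # mature curve delayed 30 days -> active peak between the two midpoints
  mat <- fit_gompertz(doy, gompertz(doy, 40, exp(0.06 * 190), 0.06))
  ap <- derive_active_phase(tot, mat, 120:280)
  pk <- ap$doy[which.max(ap$n_ab)]
  expect_gt(pk, 160)
  expect_lt(pk, 190)
  expect_true(all(ap$n_ab >= 0))
  expect_true(all(ap$growth_rate >= -1e-10))
  # growth rate equals the day-over-day increase of the fitted total curve
  expect_equal(ap$growth_rate[5],
               predict(tot, ap$doy[5]) - predict(tot, ap$doy[5] - 1))
})

test_that("growth-period classification is threshold-monotone and centred", {
  doy <- seq(120, 280, by = 7)
  tot <- fit_gompertz(doy, gompertz(doy, 40, exp(0.06 * 160), 0.06))
  mat <- fit_gompertz(doy, gompertz(doy, 40, exp(0.05 * 195), 0.05))
  grid <- 120:280
  per <- classify_growth_periods(tot, mat, grid,
                                 origin = as.Date("2018-01-01"))
  expect_true(all(per$start_doy <= per$end_doy))
  # max-rate interval nests inside its parent period and brackets the peak
  prod <- per[per$period == "production", ]
  maxp <- per[per$period == "max_production", ]
  expect_gte(maxp$start_doy, prod$start_doy)
  expect_lte(maxp$end_doy, prod$end_doy)
  expect_true(maxp$start_doy <= 160 && maxp$end_doy >= 160)
  # the Gompertz rate is near-symmetric around its peak at these settings
  expect_lt(abs((maxp$start_doy + maxp$end_doy) / 2 - 160), 3)
  # f1 = 0 -> production spans the whole grid; larger f1 never widens it
  per0 <- classify_growth_periods(tot, mat, grid, f1 = 0)
  expect_equal(per0$start_doy[per0$period == "production"], 120)
  expect_equal(per0$end_doy[per0$period == "production"], 280)
  per10 <- classify_growth_periods(tot, mat, grid, f1 = 0.10)
  prod10 <- per10[per10$period == "production", ]
  expect_gte(prod10$start_doy, prod$start_doy)
  expect_lte(prod10$end_doy, prod$end_doy)
  # earlywood/transition/latewood tile the season in order
  ew <- per[per$period == "earlywood", ]
  tr <- per[per$period == "ew_lw_transition", ]
  lw <- per[per$period == "latewood", ]
  expect_equal(tr$start_doy, ew$end_doy + 1)
  expect_equal(lw$start_doy, tr$end_doy + 1)
})

test_that("configured production truth is recovered within a few days", {
  # simulate pooled counts from a known curve and check the classified
  # production period against the truth-derived one
  cfg <- sim_config(seed = 21)
  obs <- simulate_tracheid_counts(cfg)
  norm <- normalize_counts(obs)
  tot <- fit_gompertz(norm$pooled$doy, norm$pooled$n_total)
  mat <- fit_gompertz(norm$pooled$doy, norm$pooled$n_c)
  grid <- seq(min(norm$pooled$doy), max(norm$pooled$doy))
  per <- classify_growth_periods(tot, mat, grid)
  g <- cfg$gompertz$total
  rate_true <- gompertz_rate(grid, g$A, exp(g$kappa * g$t_mid), g$kappa)
  truth_span <- range(grid[rate_true >= 0.05 * max(rate_true)])
  prod <- per[per$period == "production", ]
  expect_lte(abs(prod$start_doy - truth_span[1]), 3)
  expect_lte(abs(prod$end_doy - truth_span[2]), 3)
})

test_that("root pulse detection finds configured pulses in order", {
  days <- seq(as.Date("2018-05-01"), as.Date("2018-09-30"), by = 1)
  pulse <- function(c0, w, amp) {
    amp * exp(-as.numeric(days - as.Date(c0))^2 / (2 * w^2))
  }
  # single pulse -> one bracketing period
  r1 <- data.frame(scanner_id = "s1", date = days,
                   elongation_mm = pulse("2018-06-20", 8, 3))
  p1 <- detect_root_periods(r1, min_amp = 0.5)
  expect_equal(nrow(p1), 1L)
  expect_true(p1$start < as.Date("2018-06-20") &
                p1$end > as.Date("2018-06-20"))
  # three disjoint pulses across scanners -> three ordered periods
  r3 <- rbind(
    data.frame(scanner_id = "s1", date = days,
               elongation_mm = pulse("2018-06-10", 6, 4)),
    data.frame(scanner_id = "s2", date = days,
               elongation_mm = pulse("2018-07-25", 6, 4)),
    data.frame(scanner_id = "s3", date = days,
               elongation_mm = pulse("2018-09-05", 6, 4)))
  p3 <- detect_root_periods(r3, min_amp = 0.5)
  expect_equal(nrow(p3), 3L)
  expect_true(all(diff(as.numeric(p3$start)) > 0))
  expect_equal(p3$period, paste0("root_period_", c("I", "II", "III")))
  # threshold above the global maximum -> no periods, not an error
  expect_equal(nrow(detect_root_periods(r3, min_amp = 99)), 0L)
})
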