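test_that("gap interpolation is linear, trimmed and bounded", {
  d <- as.Date("2018-06-01") + 0:2
  s <- interpolate_gaps(d, c(-26, NA, -28), max_gap_frac = 0.5)
  expect_equal(s$value, c(-26, -27, -28))
  expect_equal(s$gap_mask, c(FALSE, TRUE, FALSE))
  # no gaps -> identity
  s2 <- interpolate_gaps(d, c(-26, -27, -28))
  expect_equal(s2$value, c(-26, -27, -28))
  expect_equal(s2$gap_fraction, 0)
  # leading/trailing gaps are trimmed, not extrapolated
  s3 <- interpolate_gaps(as.Date("2018-06-01") + 0:4,
                         c(NA, -26, -27, -28, NA), max_gap_frac = 0.5)
  expect_equal(length(s3$value), 3L)
  # gap ceiling enforced
  expect_error(interpolate_gaps(as.Date("2018-06-01") + c(0, 10),
                                c(-26, -28), max_gap_frac = 0.1),
               "exceeds")
  # small random gaps on a smooth series reconstruct accurately
  set.seed(5)
  n <- 150
  dates <- as.Date("2018-05-01") + 0:(n - 1)
  smooth <- sin(2 * pi * (1:n) / 40) + 0.3 * sin(2 * pi * (1:n) / 25)
  drop <- sample(2:(n - 1), 3)
  v <- smooth; v[drop] <- NA
  sf <- interpolate_gaps(dates, v)
  expect_lt(sqrt(mean((sf$value[drop] - smooth[drop])^2)),
            0.05 * sd(smooth))
})

test_that("Morlet CWT localizes period, kills constants and is linear", {
  n <- 256
  x <- sin(2 * pi * (1:n) / 32)
  cw <- cwt_morlet(x)
  mid <- 100:156
  pk <- cw$period[which.max(rowMeans(abs(cw$W[, mid])^2))]
  expect_lt(abs(log2(pk / 32)), 1 / 12 + 1e-9)  # within one voice
  # constant series -> zero modulus
  expect_lt(max(abs(cwt_morlet(rep(3.7, n))$W)), 1e-10)
  # linearity
  y <- cos(2 * pi * (1:n) / 10)
  Wx <- cwt_morlet(x)$W; Wy <- cwt_morlet(y)$W
  Wxy <- cwt_morlet(2 * x + 3 * y)$W
  expect_lt(max(abs(Wxy - 2 * Wx - 3 * Wy)), 1e-9 * max(abs(Wxy)))
  # over-long period request is truncated with a warning
  expect_warning(cwt_morlet(x, period_max = 300), "truncated")
})

test_that("coherence obeys self, anti-phase, symmetry and lag identities", {
  n <- 160
  dates <- as.Date("2018-05-01") + 0:(n - 1)
  x <- daily(sin(2 * pi * (1:n) / 32) + 0.2 * sin(2 * pi * (1:n) / 9))
  # self-coherence is 1 with zero phase
  self <- wavelet_coherence(x, x, period_max = 64)
  expect_true(all(self$coherence[self$inside_coi] > 0.999))
  expect_lt(max(abs(self$phase[self$inside_coi])), 1e-6)
  # anti-phase pair -> phase pi
  anti <- wavelet_coherence(x, daily(-x$value), period_max = 64)
  i32 <- which.min(abs(anti$period - 32))
  expect_lt(max(abs(abs(anti$phase[i32, anti$inside_coi[i32, ]]) - pi)),
            1e-6)
  # 8-day delayed copy at period 32 -> phase pi/2, lag 8 +- 1 d
  y <- daily(sin(2 * pi * ((1:n) - 8) / 32))
  xs <- daily(sin(2 * pi * (1:n) / 32))
  lagwc <- wavelet_coherence(xs, y, period_max = 64)
  ph <- mean(lagwc$phase[i32, lagwc$inside_coi[i32, ]])
  expect_equal(ph, pi / 2, tolerance = 0.05)
  expect_equal(ph * 32 / (2 * pi), 8, tolerance = 1)
  # symmetry: coherence(x, y) = coherence(y, x), phase antisymmetric
  set.seed(6)
  a <- daily(rnorm(n)); b <- daily(rnorm(n))
  w1 <- wavelet_coherence(a, b, period_max = 64)
  w2 <- wavelet_coherence(b, a, period_max = 64)
  expect_equal(w1$coherence, w2$coherence, tolerance = 1e-10)
  expect_equal(w1$phase, -w2$phase, tolerance = 1e-8)
  # coherence bounded in [0, 1] for random inputs
  for (i in 1:5) {
    wr <- wavelet_coherence(daily(rnorm(n)), daily(rnorm(n)),
                            period_max = 64)
    expect_true(all(wr$coherence >= 0 & wr$coherence <= 1))
  }
})

test_that("significance mask localizes injected coupling", {
  set.seed(7)
  n <- 180
  base <- sin(2 * pi * (1:n) / 16)
  x <- rnorm(n, sd = 0.6); y <- rnorm(n, sd = 0.6)
  win <- 50:100
  x[win] <- x[win] + 2 * base[win]
  y[win] <- y[win] + 2 * base[win]
  dx <- daily(x); dy <- daily(y)
  wc <- wavelet_coherence(dx, dy, period_max = 45)
  sig <- coherence_significance(dx, dy, result = wc, n_surrogates = 200,
                                seed = 3)
  band <- wc$period >= 10 & wc$period <= 24
  inwin <- sig$mask[band, win]
  # smoothing leaks coherence about one scale beyond the window; judge the
  # background well away from it
  outwin <- sig$mask[band, setdiff(1:n, 25:125)]
  expect_gt(mean(inwin), 0.5)
  expect_lt(mean(outwin), 0.2)
  expect_gt(mean(inwin), 3 * max(mean(outwin), 0.01))
  # alpha = 1 -> every cell inside the cone is significant
  sig1 <- coherence_significance(dx, dy, result = wc, n_surrogates = 100,
                                 alpha = 1, seed = 3)
  expect_true(all(sig1$mask[wc$inside_coi]))
  expect_error(coherence_significance(daily(rep(1, n)), dy, result = wc,
                                      n_surrogates = 100),
               "degenerate")
  # reproducible under a fixed seed
  sig2 <- coherence_significance(dx, dy, result = wc, n_surrogates = 200,
                                 seed = 3)
  expect_identical(sig$mask, sig2$mask)
})

test_that("lead/lag summary reports lags, empty strata and wrapped phases", {
  set.seed(8)
  n <- 180
  dates <- as.Date("2018-05-01") + 0:(n - 1)
  common <- sin(2 * pi * (1:n) / 16)
  x <- daily(common + rnorm(n, sd = 0.2))
  y <- daily(sin(2 * pi * ((1:n) - 4) / 16) + rnorm(n, sd = 0.2))
  wc <- wavelet_coherence(x, y, period_max = 45)
  sig <- coherence_significance(x, y, result = wc, n_surrogates = 150,
                                seed = 4)
  periods <- data.frame(period = "mid",
                        start = dates[30], end = dates[150])
  s <- lead_lag_summary(wc, sig, periods,
                        bands = list(c(8, 16), c(16, 32)))
  row <- s[s$band == "16-32d", ]  # period 16 falls in [16, 32)
  expect_gt(row$frac_significant, 0.3)
  expect_equal(row$lag_days, 4, tolerance = 1)
  # a stratum with no significant cells yields a fraction-zero row
  off <- lead_lag_summary(wc, sig,
                          data.frame(period = "edge", start = dates[1],
                                     end = dates[6]),
                          bands = list(c(2, 4)))
  expect_true(off$frac_significant[1] == 0 || is.na(off$frac_significant))
  # circular mean of near-pi phases has magnitude near pi, not zero
  th <- c(pi - 0.05, -pi + 0.05, pi - 0.1)
  expect_gt(abs(carboniso:::circular_mean(th)), 3)
})
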