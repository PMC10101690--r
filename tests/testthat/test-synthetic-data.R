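test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11)
  env1 <- simulate_environment(cfg)
  env2 <- simulate_environment(cfg)
  expect_identical(env1, env2)
  tr1 <- simulate_true_fluxes(env1, cfg)
  tr2 <- simulate_true_fluxes(env2, cfg)
  expect_identical(tr1, tr2)
  expect_identical(simulate_tracheid_counts(cfg),
                   simulate_tracheid_counts(cfg))
  expect_identical(simulate_nsc_series(cfg), simulate_nsc_series(cfg))
  expect_identical(simulate_root_growth(env1, cfg),
                   simulate_root_growth(env1, cfg))
})

test_that("environment honours night hours and the configured dry window", {
  cfg <- sim_config(seed = 2)
  env <- simulate_environment(cfg)
  hour <- as.numeric(strftime(env$time, "%H", tz = "UTC")) +
    as.numeric(strftime(env$time, "%M", tz = "UTC")) / 60
  night <- hour < cfg$env$day_start_hour | hour >= cfg$env$day_end_hour
  expect_true(all(env$PAR[night] == 0))
  expect_true(all(env$PAR >= 0))
  expect_true(all(diff(as.numeric(env$time)) == cfg$env$step_min * 60))
  # soil moisture minimum falls inside the dry window and moisture is
  # non-increasing throughout it
  dmin <- as.Date(env$time[which.min(env$soil_moisture)], tz = "UTC")
  expect_gte(as.numeric(dmin - cfg$dry_start), 0)
  expect_lte(as.numeric(cfg$dry_end - dmin), as.numeric(cfg$dry_end -
                                                          cfg$dry_start))
  in_dry <- as.Date(env$time, tz = "UTC") >= cfg$dry_start &
    as.Date(env$time, tz = "UTC") <= cfg$dry_end
  expect_true(all(diff(env$soil_moisture[in_dry]) <= 1e-12))
  expect_error(sim_config(seed = 1, dry_start = "2018-03-01"),
               "dry period")
})

test_that("true fluxes respect sign, range and construction identities", {
  cfg <- sim_config(seed = 3)
  env <- simulate_environment(cfg)
  truth <- simulate_true_fluxes(env, cfg)
  expect_true(all(truth$R_stem >= 0))
  expect_true(all(truth$R_soil >= 0))
  expect_true(all(truth$A_shoot[env$PAR == 0] == 0))
  expect_true(all(truth$A_shoot[env$PAR > 0] >= 0))
  for (v in c("delta_shoot", "delta_stem", "delta_soil")) {
    expect_true(all(truth[[v]] >= -40 & truth[[v]] <= 0))
  }

  # b = 0 and no growth term -> constant stem efflux equal to the base rate
  cfg0 <- sim_config(seed = 3,
                     fluxes = list(stem_b = 0, stem_growth_coef = 0))
  truth0 <- simulate_true_fluxes(env, cfg0)
  expect_equal(unique(truth0$R_stem), cfg0$fluxes$stem_a)

  # lag L, zero fractionation, constant coupling -> exact delayed copy
  cfgL <- sim_config(seed = 3,
                     isotopes = list(lag_stem_days = 3, frac_stem = 0,
                                     coupling_in = 1, coupling_out = 1))
  truthL <- simulate_true_fluxes(env, cfgL)
  ds <- tapply(truthL$delta_shoot, truthL$date, mean)
  dt <- tapply(truthL$delta_stem, truthL$date, mean)
  n <- length(ds)
  expect_equal(unname(dt[4:n]), unname(ds[1:(n - 3)]), tolerance = 1e-12)

  # zero lag, 4.5 permil fractionation -> exact mean offset
  cfgF <- sim_config(seed = 3,
                     isotopes = list(lag_stem_days = 0, frac_stem = 4.5,
                                     coupling_in = 1, coupling_out = 1))
  truthF <- simulate_true_fluxes(env, cfgF)
  expect_equal(mean(truthF$delta_shoot - truthF$delta_stem), 4.5,
               tolerance = 1e-10)
})

test_that("chamber forward model matches an independent ODE integration", {
  # dC/dt = F*S*Vm/V + q*(C_amb - C), solved with deSolve as the oracle
  skip_if_not_installed("deSolve")
  f <- 1.0; v <- 80; s <- 0.4; q <- 0.001; camb <- 400; temp <- 15
  rhs <- function(t, y, p) {
    list(f * s * molar_volume(temp) / v + q * (camb - y))
  }
  t <- 0:300
  num <- deSolve::lsoda(c(C = camb), t, rhs, NULL, rtol = 1e-12,
                        atol = 1e-12)[, "C"]
  ana <- chamber_trace(t, f, s, v, q, camb, temp)
  expect_lt(max(abs(num - ana)), 1e-6)

  # F = 0 -> trace constant at ambient; q -> 0 -> linear with slope F*S*Vm/V
  expect_equal(chamber_trace(t, 0, s, v, q, camb, temp), rep(camb, 301))
  lin <- chamber_trace(t, f, s, v, 1e-13, camb, temp)
  expect_equal(diff(lin), rep(f * s * molar_volume(temp) / v, 300),
               tolerance = 1e-6)
})

test_that("forward closures conserve flux and delta construction", {
  cfg <- quiet_config(seed = 4)
  env <- simulate_environment(cfg)
  truth <- simulate_true_fluxes(env, cfg)
  set <- simulate_chamber_closures(truth, cfg, chambers = "soil")
  i <- which(set$info$F_true > 0.5)[1]
  tr <- set$traces[set$traces$closure_id == set$info$closure_id[i], ]
  info <- set$info[i, ]
  # initial slope of the noise-free total trace recovers F*S*Vm/V
  rate_fac <- info$area_m2 * molar_volume(info$temp_C) / info$volume_l
  slope0 <- (tr$c12_ppm[2] + tr$c13_ppm[2] - tr$c12_ppm[1] - tr$c13_ppm[1])
  expect_lt(abs(slope0 - info$F_true * rate_fac) /
              (info$F_true * rate_fac), 1e-3)
  # converting the isotopologue fluxes back through the delta definition
  # returns the configured truth
  fx <- carboniso:::split_isotopologues(info$F_true, info$delta_true)
  expect_equal(delta_from_fluxes(fx$c12, fx$c13), info$delta_true,
               tolerance = 1e-9)
})

test_that("tracheid observations sit on the truth curves when noise-free", {
  cfg <- sim_config(seed = 5, gompertz = list(count_noise_frac = 0))
  obs <- simulate_tracheid_counts(cfg)
  truth <- attr(obs, "truth")
  tr <- truth[1, ]
  d <- obs[obs$tree_id == tr$tree_id, ]
  expected <- gompertz(d$doy, tr$A, exp(tr$kappa_total * tr$t_mid_total),
                       tr$kappa_total) * tr$prev_ring_width_mm
  expect_equal(d$n_total, expected, tolerance = 1e-12)
  # phases partition the total count and everything is non-negative
  expect_equal(obs$n_total, obs$n_a + obs$n_b + obs$n_c, tolerance = 1e-9)
  expect_true(all(obs[c("n_a", "n_b", "n_c")] >= 0))
  # mature and total curves share the asymptote: all cells mature
  late <- gompertz(500, tr$A, exp(tr$kappa_mature * tr$t_mid_mature),
                   tr$kappa_mature)
  expect_equal(late, tr$A, tolerance = 1e-4)
})

test_that("NSC series honour pool identities and configured levels", {
  cfg <- sim_config(seed = 6)
  nsc <- simulate_nsc_series(cfg)
  ph <- nsc[nsc$organ == "phloem", ]
  # WSC = sucrose + glucose + fructose per replicate and date
  for (dt in unique(ph$date)[c(1, 4)]) {
    for (r in 1:2) {
      sub <- ph[ph$date == dt & ph$replicate == r, ]
      expect_equal(sub$conc_mg_g[sub$compound == "wsc"],
                   sum(sub$conc_mg_g[sub$compound %in%
                                       c("sucrose", "glucose",
                                         "fructose")]),
                   tolerance = 1e-9)
    }
  }
  # starch re-mobilization: the configured template peaks at 72 mg/g and
  # drops to 26 mg/g across the transition window ...
  expect_equal(max(cfg$nsc$phloem$starch$val), 72)
  expect_equal(cfg$nsc$phloem$starch$val[cfg$nsc$phloem$starch$doy == 213],
               26)
  # ... and the generated means show the depletion at the sampled dates
  st <- ph[ph$compound == "starch", ]
  m <- tapply(st$conc_mg_g, st$date, mean)
  doy <- as.integer(strftime(as.Date(names(m)), "%j", tz = "UTC"))
  peak_i <- which.max(m)
  expect_gt(m[peak_i], 55)
  expect_lt(min(m[doy > doy[peak_i]]), 40)
  # sucrose rises while starch falls across the depletion
  su_m <- tapply(ph$conc_mg_g[ph$compound == "sucrose"],
                 ph$date[ph$compound == "sucrose"], mean)
  expect_gt(su_m[doy > 200][1], su_m[peak_i])
  # sucrose constitutes about a third of WSC on average
  suc <- mean(ph$conc_mg_g[ph$compound == "sucrose"])
  wsc <- mean(ph$conc_mg_g[ph$compound == "wsc"])
  expect_lt(abs(suc / wsc - 0.34), 0.03)
  # delta13C of starch is more stable than that of sucrose
  sd_st <- sd(tapply(st$d13C_permil, st$date, mean))
  su <- ph[ph$compound == "sucrose", ]
  sd_su <- sd(tapply(su$d13C_permil, su$date, mean))
  expect_lt(sd_st, sd_su)
})

test_that("root growth expresses the configured pulse windows", {
  cfg <- sim_config(seed = 7)
  env <- simulate_environment(cfg)
  roots <- simulate_root_growth(env, cfg)
  expect_true(all(roots$elongation_mm >= 0))
  for (sc in names(cfg$roots$scanners)) {
    d <- roots[roots$scanner_id == sc, ]
    peak_date <- d$date[which.max(d$elongation_mm)]
    windows <- cfg$roots$scanners[[sc]]$pulses
    hit <- any(vapply(windows, function(p) {
      peak_date >= as.Date(p$start) && peak_date <= as.Date(p$end)
    }, logical(1)))
    expect_true(hit)
  }
  # zero-amplitude configuration produces an all-zero series
  zero <- list(pulses = list(list(start = "2018-06-06",
                                  end = "2018-07-12", amp = 0)))
  cfg0 <- sim_config(seed = 7, roots = list(scanners = list(
    scanner1 = zero, scanner2 = zero, scanner3 = zero)))
  expect_true(all(simulate_root_growth(env, cfg0)$elongation_mm == 0))
})
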