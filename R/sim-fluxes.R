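#' Simulate ground-truth CO2 fluxes and their delta13C
#'
#' Builds the "true" flux series the chamber forward model observes. Stem
#' efflux is an exponential function of air temperature plus a term
#' proportional to the tracheid growth-rate truth; soil efflux is a
#' moisture-modulated exponential function of soil temperature plus a
#' root-growth-linked term; shoot influx is a saturating light response with
#' a seasonal amplitude (zero whenever PAR is zero). The delta13C of fresh
#' assimilates varies with a vapour-pressure-deficit proxy (day-level
#' temperature anomaly); delta13C of the stem and soil effluxes equals the
#' assimilate signal delayed by the configured allocation lags minus the
#' apparent respiratory fractionation, mixed with an uncoupled baseline
#' outside the configured high carbon-demand windows.
#'
#' @param env an `environment_series` from [simulate_environment()].
#' @param config a [sim_config()] object.
#' @return data.frame of class `true_flux_series` with columns `time`,
#'   `doy`, `date`, `A_shoot`, `R_stem`, `R_soil` (umol m-2 s-1, all >= 0)
#'   and `delta_shoot`, `delta_stem`, `delta_soil` (per mil V-PDB).
#' @export
simulate_true_fluxes <- function(env, config) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$fluxes
  iso <- config$isotopes
  set.seed(stage_seed(config, "fluxes"))

  date <- as.Date(env$time, tz = "UTC")
  days <- seq(config$season_start, config$season_end, by = 1)
  n_day <- length(days)
  doy_days <- as.integer(strftime(days, "%j", tz = "UTC"))

  # tracheid growth-rate truth (pooled trees), cells per day
  g <- config$gompertz
  rate_day <- gompertz_rate(doy_days, A = g$total$A,
                            beta = exp(g$total$kappa * g$total$t_mid),
                            kappa = g$total$kappa)
  # root elongation truth: sum of configured pulse templates
  root_day <- rowSums(vapply(config$roots$scanners, function(sc) {
    rowSums(vapply(sc$pulses, function(p) {
      pulse_template(days, as.Date(p$start), as.Date(p$end), p$amp)
    }, numeric(n_day)))
  }, numeric(n_day)))
  root_day <- root_day / max(root_day, 1e-12)

  idx <- match(date, days)
  R_stem <- f$stem_a * exp(f$stem_b * env$air_T) +
    f$stem_growth_coef * rate_day[idx]
  moist <- pmin(1.2, sqrt(pmax(env$soil_moisture, 0) / f$soil_moisture_ref))
  R_soil <- f$soil_a * exp(f$soil_b * env$soil_T) * moist +
    f$soil_root_coef * root_day[idx]
  season_amp <- 0.7 + 0.3 * sin(2 * pi * (doy_days[idx] - 110) / 365)
  A_shoot <- f$shoot_amax * season_amp * env$PAR / (env$PAR + f$shoot_par_half)

  # day-level delta13C of assimilates: VPD proxy + AR(1) noise
  t_day <- tapply(env$air_T, date, max)[as.character(days)]
  z <- as.numeric(scale(t_day))
  ar <- as.numeric(stats::filter(
    stats::rnorm(n_day, sd = iso$delta_shoot_noise_sd *
                   sqrt(1 - iso$delta_shoot_noise_phi^2)),
    iso$delta_shoot_noise_phi, method = "recursive"))
  trend <- iso$delta_shoot_trend * (seq_len(n_day) - 1) / (n_day - 1)
  d_shoot_day <- iso$delta_shoot_base + iso$delta_shoot_amp * z + trend + ar

  d_stem_day <- coupled_delta(d_shoot_day, days, iso$lag_stem_days,
                              iso$frac_stem, iso$stem_windows,
                              iso$coupling_in, iso$coupling_out,
                              iso$uncoupled_noise_sd, iso$delta_shoot_base)
  d_soil_day <- coupled_delta(d_shoot_day, days, iso$lag_soil_days,
                              iso$frac_soil, iso$soil_windows,
                              iso$coupling_in, iso$coupling_out,
                              iso$uncoupled_noise_sd, iso$delta_shoot_base)

  clip <- function(x) pmin(0, pmax(-40, x))
  out <- data.frame(time = env$time, doy = env$doy, date = date,
                    PAR = env$PAR, air_T = env$air_T,
                    A_shoot = pmax(0, A_shoot), R_stem = pmax(0, R_stem),
                    R_soil = pmax(0, R_soil),
                    delta_shoot = clip(d_shoot_day[idx]),
                    delta_stem = clip(d_stem_day[idx]),
                    delta_soil = clip(d_soil_day[idx]))
  class(out) <- c("true_flux_series", "data.frame")
  out
}

# raised-cosine pulse over [start, end], peak amplitude amp
pulse_template <- function(days, start, end, amp) {
  u <- (as.numeric(days - start)) / max(as.numeric(end - start), 1)
  ifelse(u >= 0 & u <= 1, amp * 0.5 * (1 - cos(2 * pi * u)), 0)
}

# day-level delta of an efflux coupled to the assimilate signal:
# lagged source minus fractionation inside windows, drifting baseline outside
coupled_delta <- function(d_source, days, lag, frac, windows,
                          w_in, w_out, noise_sd, base) {
  n <- length(days)
  lagged <- d_source[pmax(1, seq_len(n) - lag)]
  w <- rep(w_out, n)
  for (win in windows) {
    w[days >= as.Date(win[1]) & days <= as.Date(win[2])] <- w_in
  }
  noise <- as.numeric(stats::filter(stats::rnorm(n, sd = noise_sd * 0.6),
                                    0.6, method = "recursive"))
  uncoupled <- base - frac + noise
  w * (lagged - frac) + (1 - w) * uncoupled
}

#' Closed-form chamber concentration trace
#'
#' Analytic solution of the closed-chamber mass balance
#' dC/dt = F*S*Vm/V + q*(C_amb - C) for one gas, with the chamber starting
#' at concentration `c0` (ambient by default). This forward solution is the
#' oracle used to test the inversion in [fit_closure()].
#'
#' @param t seconds since closure.
#' @param flux gas flux into the chamber, umol m-2 s-1 (negative for uptake).
#' @param area_m2 exchange surface or leaf area, m2.
#' @param volume_l chamber volume, litres.
#' @param q_per_s first-order replacement (leak) rate toward ambient, s-1.
#' @param c_amb ambient concentration, ppm.
#' @param temp_C chamber air temperature, degC (sets the molar volume).
#' @param c0 concentration at t = 0, ppm.
#' @return concentration trace in ppm.
#' @export
chamber_trace <- function(t, flux, area_m2, volume_l, q_per_s, c_amb,
                          temp_C = 15, c0 = c_amb) {
  rate0 <- flux * area_m2 * molar_volume(temp_C) / volume_l  # ppm s-1 at t=0
  c_amb + rate0 * sat_ramp(q_per_s, t) + (c0 - c_amb) * exp(-q_per_s * t)
}

# (1 - exp(-q t)) / q, stable as q -> 0
sat_ramp <- function(q, t) {
  if (abs(q) < 1e-12) return(t * (1 - q * t / 2))
  -expm1(-q * t) / q
}

#' Forward-simulate chamber closures from the flux truth
#'
#' Generates per-closure 1-s concentration traces of 12CO2 and 13CO2 by the
#' analytic chamber mass balance ([chamber_trace()]) applied per
#' isotopologue (the 13C flux is the 12C flux times the isotope ratio
#' implied by the true delta13C), plus independent Gaussian analyzer noise.
#'
#' @param truth a `true_flux_series` from [simulate_true_fluxes()].
#' @param config a [sim_config()] object.
#' @param chambers which chamber kinds to simulate.
#' @return a list of class `closure_set` with elements `info` (one row per
#'   closure: closure_id, chamber, start time, PAR, chamber geometry, true
#'   flux and delta) and `traces` (long table closure_id, time_s, c12_ppm,
#'   c13_ppm).
#' @export
simulate_chamber_closures <- function(truth, config,
                                      chambers = c("shoot", "stem", "soil")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "closures"))
  amb <- config$ambient
  days <- seq(config$season_start, config$season_end, by = 1)

  info_list <- list()
  trace_list <- list()
  id0 <- 0L
  for (ch in chambers) {
    spec <- config$chambers[[ch]]
    # closure start times, evenly spread over each day
    off <- (seq_len(spec$closures_per_day) - 0.5) * 86400 /
      spec$closures_per_day
    starts <- as.POSIXct(rep(days, each = spec$closures_per_day),
                         tz = "UTC") + rep(off, length(days))
    j <- findInterval(as.numeric(starts), as.numeric(truth$time))
    j[j < 1] <- 1
    flux_col <- switch(ch, shoot = "A_shoot", stem = "R_stem",
                       soil = "R_soil")
    delta_col <- switch(ch, shoot = "delta_shoot", stem = "delta_stem",
                        soil = "delta_soil")
    f_true <- truth[[flux_col]][j]
    d_true <- truth[[delta_col]][j]
    # sign convention in the chamber balance: influx to the chamber air is
    # positive; shoot assimilation draws CO2 down
    f_signed <- if (ch == "shoot") -f_true else f_true
    par <- if (!is.null(truth$PAR)) truth$PAR[j] else NA_real_

    n <- length(starts)
    ids <- id0 + seq_len(n)
    id0 <- id0 + n
    tsec <- 0:spec$duration_s
    m <- length(tsec)

    hour <- as.numeric(strftime(starts, "%H", tz = "UTC"))
    c_amb_tot <- amb$co2_ppm + amb$diurnal_amp_ppm * cos(2 * pi * hour / 24)
    amb_split <- split_isotopologues(c_amb_tot, amb$delta_permil)
    fx <- split_isotopologues(f_signed, d_true)

    rate_fac <- spec$area_m2 * molar_volume(amb$chamber_temp_C) /
      spec$volume_l
    ramp <- sat_ramp(spec$q_per_s, tsec)                      # length m
    c12 <- rep(amb_split$c12, each = m) +
      rep(fx$c12 * rate_fac, each = m) * rep(ramp, n)
    c13 <- rep(amb_split$c13, each = m) +
      rep(fx$c13 * rate_fac, each = m) * rep(ramp, n)
    if (config$analyzer$c12_sd_ppm > 0) {
      c12 <- c12 + stats::rnorm(length(c12), sd = config$analyzer$c12_sd_ppm)
    }
    if (config$analyzer$c13_sd_ppm > 0) {
      c13 <- c13 + stats::rnorm(length(c13), sd = config$analyzer$c13_sd_ppm)
    }

    info_list[[ch]] <- data.frame(
      closure_id = ids, chamber = ch, start = starts, PAR = par,
      volume_l = spec$volume_l, area_m2 = spec$area_m2,
      temp_C = amb$chamber_temp_C,
      duration_s = spec$duration_s, q_true = spec$q_per_s,
      F_true = f_true, delta_true = d_true)
    trace_list[[ch]] <- data.frame(
      closure_id = rep(ids, each = m), time_s = rep(tsec, n),
      c12_ppm = c12, c13_ppm = c13)
  }
  out <- list(info = do.call(rbind, info_list),
              traces = do.call(rbind, trace_list))
  rownames(out$info) <- NULL
  class(out) <- "closure_set"
  out
}

#' @export
print.closure_set <- function(x, ...) {
  cat("<closure_set>", nrow(x$info), "closures,",
      nrow(x$traces), "trace samples\n")
  print(table(x$info$chamber))
  invisible(x)
}
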