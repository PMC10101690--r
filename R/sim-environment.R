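#' Simulate half-hourly environmental drivers for one growing season
#'
#' Produces air and soil temperature, photosynthetically active radiation
#' (PAR), soil moisture and precipitation on a fixed 30-min grid. Air
#' temperature is a seasonal sinusoid plus a diurnal cycle and day-level
#' AR(1) noise; soil temperature is a damped multi-day running mean of air
#' temperature; PAR follows a half-sine daylight course and is exactly zero
#' during the configured night hours; soil moisture follows a simple bucket
#' balance (rain input, drainage + evapotranspiration output) with
#' precipitation suppressed during the configured dry window so moisture
#' declines monotonically through it and recovers afterwards.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `time` (POSIXct, UTC), `doy`, `air_T`
#'   (degC), `soil_T` (degC), `PAR` (umol m-2 s-1), `soil_moisture`
#'   (m3 m-3) and `precip` (mm per step), of class `environment_series`.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  e <- config$env
  set.seed(stage_seed(config, "environment"))

  step_s <- e$step_min * 60
  time <- seq(as.POSIXct(paste(config$season_start, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(config$season_end, "23:59:59"), tz = "UTC"),
              by = step_s)
  doy <- as.integer(strftime(time, "%j", tz = "UTC"))
  hour <- as.numeric(strftime(time, "%H", tz = "UTC")) +
    as.numeric(strftime(time, "%M", tz = "UTC")) / 60
  date <- as.Date(time, tz = "UTC")
  days <- seq(config$season_start, config$season_end, by = 1)
  n_day <- length(days)

  # day-level AR(1) temperature anomaly, interpolated to the 30-min grid
  anom <- stats::filter(stats::rnorm(n_day, sd = e$t_noise_sd *
                                       sqrt(1 - e$t_noise_phi^2)),
                        e$t_noise_phi, method = "recursive")
  anom_step <- as.numeric(anom)[match(date, days)]

  t_seas <- e$t_mean + e$t_seas_amp * sin(2 * pi * (doy - e$t_seas_phase) / 365)
  air_T <- t_seas + e$t_diurnal_amp * sin(2 * pi * (hour - 9) / 24) + anom_step

  # soil T: damped running mean of daily air T
  day_T <- tapply(air_T, date, mean)
  k <- e$soil_t_smooth_days
  sm_T <- stats::filter(day_T, rep(1 / k, k), sides = 1)
  sm_T[is.na(sm_T)] <- cumsum(day_T)[seq_len(sum(is.na(sm_T)))] /
    seq_len(sum(is.na(sm_T)))
  soil_T <- e$soil_t_damp * as.numeric(sm_T)[match(date, days)] +
    e$soil_t_offset

  # PAR: half-sine daylight course, exactly zero at night
  daylen <- e$day_end_hour - e$day_start_hour
  frac <- (hour - e$day_start_hour) / daylen
  par_season <- 0.6 + 0.4 * sin(2 * pi * (doy - e$t_seas_phase) / 365)
  PAR <- ifelse(frac > 0 & frac < 1,
                e$par_max * par_season * pmax(0, sin(pi * frac))^1.5, 0)

  # precipitation: day-level wet/dry, suppressed in the dry window,
  # forced rain on the first day after it so moisture recovers
  in_dry_day <- days >= config$dry_start & days <= config$dry_end
  wet <- stats::runif(n_day) < e$rain_prob & !in_dry_day
  after <- which(days == config$dry_end + 1)
  if (length(after) == 1) wet[after] <- TRUE
  day_rain <- ifelse(wet, stats::rexp(n_day, 1 / e$rain_mean_mm), 0)
  steps_per_day <- as.integer(24 * 60 / e$step_min)
  precip <- day_rain[match(date, days)] / steps_per_day
  precip[hour < 10 | hour > 18] <- 0            # rain within a daytime block
  day_tot <- tapply(precip, date, sum)
  scale <- day_rain / ifelse(day_tot > 0, day_tot, 1)
  precip <- precip * scale[match(date, days)]

  # bucket soil moisture balance
  n <- length(time)
  sm <- numeric(n)
  sm[1] <- e$sm_init
  frac_step <- 1 / steps_per_day
  for (i in seq_len(n - 1)) {
    drain <- e$sm_drain * (sm[i] - e$sm_min) * frac_step
    et <- e$sm_et * frac_step * (sm[i] > e$sm_min)
    sm[i + 1] <- min(e$sm_max,
                     max(e$sm_min, sm[i] + e$sm_rain_gain * precip[i] -
                           drain - et))
  }

  out <- data.frame(time = time, doy = doy, air_T = air_T, soil_T = soil_T,
                    PAR = PAR, soil_moisture = sm, precip = precip)
  class(out) <- c("environment_series", "data.frame")
  out
}
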