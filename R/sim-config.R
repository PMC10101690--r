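#' Simulation configuration for the synthetic study season
#'
#' Builds the configuration object consumed by all `simulate_*()` generators.
#' Defaults emulate one boreal Scots pine growing season with automated
#' shoot, stem and soil chambers, weekly micro-core tracheid counts for five
#' trees, phloem/root non-structural carbohydrate (NSC) sampling and three
#' in-soil root scanners. The chamber closure schedule (shoot 60 closures per
#' day for 65 s, stem 48 per day for 90 s, soil 8 per day for 840 s), the
#' late-season dry period (Aug 16 to Sep 11) and the magnitudes of fluxes and
#' isotopic offsets follow the study system the package models.
#'
#' @param seed integer seed controlling every stochastic component.
#' @param ... named overrides of any default component; nested lists are
#'   merged recursively. Unknown names are rejected.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    season_start = as.Date("2018-05-01"),
    season_end   = as.Date("2018-09-30"),
    dry_start    = as.Date("2018-08-16"),
    dry_end      = as.Date("2018-09-11"),
    env = list(
      step_min = 30,
      day_start_hour = 4, day_end_hour = 21,   # PAR == 0 outside
      par_max = 1400,
      t_mean = 8, t_seas_amp = 9, t_seas_phase = 110,
      t_diurnal_amp = 4,
      t_noise_sd = 1.5, t_noise_phi = 0.7,
      soil_t_damp = 0.8, soil_t_offset = 2, soil_t_smooth_days = 5,
      rain_prob = 0.35, rain_mean_mm = 6,
      sm_init = 0.32, sm_min = 0.06, sm_max = 0.45,
      sm_drain = 0.025, sm_et = 0.004, sm_rain_gain = 0.004
    ),
    chambers = list(
      shoot = list(volume_l = 2.1, area_m2 = 0.01, closures_per_day = 60,
                   duration_s = 65, q_per_s = 0.004, window_s = c(5, 50)),
      stem  = list(volume_l = 1.0, area_m2 = 0.075, closures_per_day = 48,
                   duration_s = 90, q_per_s = 0.002, window_s = c(10, 40)),
      soil  = list(volume_l = 80, area_m2 = 0.4, closures_per_day = 8,
                   duration_s = 840, q_per_s = 2e-4, window_s = c(40, 200))
    ),
    analyzer = list(c12_sd_ppm = 0.1, c13_sd_ppm = 0.1 * R_VPDB),
    ambient = list(co2_ppm = 400, delta_permil = -8.5, diurnal_amp_ppm = 6,
                   chamber_temp_C = 15),
    fluxes = list(
      stem_a = 0.12, stem_b = 0.07, stem_growth_coef = 0.5,
      soil_a = 0.6, soil_b = 0.08, soil_moisture_ref = 0.30,
      soil_root_coef = 0.8,
      shoot_amax = 8, shoot_par_half = 300
    ),
    isotopes = list(
      delta_shoot_base = -26, delta_shoot_amp = 2.0,
      delta_shoot_trend = -5,
      delta_shoot_noise_sd = 1.2, delta_shoot_noise_phi = 0.6,
      lag_stem_days = 1, lag_soil_days = 4,
      frac_stem = 4.5, frac_soil = 1.0,
      coupling_in = 1, coupling_out = 0.15,
      uncoupled_noise_sd = 1.5,
      # high carbon-demand windows with strengthened allocation coupling
      stem_windows = list(c("2018-06-01", "2018-06-15"),
                          c("2018-07-14", "2018-08-13"),
                          c("2018-08-16", "2018-09-11")),
      soil_windows = list(c("2018-06-06", "2018-07-12"),
                          c("2018-08-17", "2018-09-30"))
    ),
    gompertz = list(
      n_trees = 5,
      total = list(A = 40, beta_log = NA_real_, kappa = 0.055, t_mid = 158),
      mature = list(A = 40, beta_log = NA_real_, kappa = 0.045, t_mid = 190),
      tree_A_sd_frac = 0.15,
      count_noise_frac = 0.05,
      ring_width_mean = 1.5, ring_width_sd = 0.3,
      sample_interval_days = 7
    ),
    nsc = list(
      phloem_dates = as.Date(c("2018-05-10", "2018-05-24", "2018-06-20",
                               "2018-07-18", "2018-08-15", "2018-09-12")),
      root_dates = seq(as.Date("2018-05-10"), as.Date("2018-10-05"),
                       by = 15),
      n_phloem_trees = 5, n_root_spots = 3,
      conc_noise_frac = 0.08,
      delta_noise_sd = 0.25, starch_delta_noise_sd = 0.1,
      # anchor DOY / value pairs for seasonal concentration templates, mg g-1
      phloem = list(
        starch   = list(doy = c(121, 155, 185, 213, 250, 273),
                        val = c(20, 55, 72, 26, 35, 40)),
        sucrose  = list(doy = c(121, 185, 213, 273),
                        val = c(40, 38, 55, 45)),
        glucose  = list(doy = c(121, 160, 213, 273),
                        val = c(40, 50, 45, 42)),
        fructose = list(doy = c(121, 273), val = c(41, 41))
      ),
      root = list(
        wsc    = list(doy = c(121, 157, 175, 196, 228, 250, 273),
                      val = c(25, 60, 45, 70, 50, 75, 60)),
        starch = list(doy = c(121, 157, 175, 196, 228, 250, 273),
                      val = c(5, 45, 20, 55, 25, 60, 35))
      ),
      delta = list(
        sucrose = -25.4, glucose = -25.8, fructose = -25.6, starch = -24.8,
        sugar_amp = 0.6, starch_amp = 0.15, root_wsc = -24.6, root_amp = 0.8
      )
    ),
    roots = list(
      # pulse windows follow the three root growth periods of the system
      scanners = list(
        scanner1 = list(pulses = list(list(start = "2018-06-06",
                                           end = "2018-07-12", amp = 4),
                                      list(start = "2018-07-13",
                                           end = "2018-08-16", amp = 3))),
        scanner2 = list(pulses = list(list(start = "2018-07-13",
                                           end = "2018-08-16", amp = 4))),
        scanner3 = list(pulses = list(list(start = "2018-08-17",
                                           end = "2018-09-30", amp = 3.5)))
      ),
      noise_sd_log = 0.25
    )
  )
  cfg <- merge_config(cfg, list(...), path = "sim_config")
  cfg$season_start <- as.Date(cfg$season_start)
  cfg$season_end <- as.Date(cfg$season_end)
  cfg$dry_start <- as.Date(cfg$dry_start)
  cfg$dry_end <- as.Date(cfg$dry_end)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# recursive merge of overrides into defaults; unknown keys are an error
merge_config <- function(defaults, overrides, path = "config") {
  if (length(overrides) == 0) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("all overrides under '", path, "' must be named", call. = FALSE)
  }
  unknown <- setdiff(nms, names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) under '", path, "': ",
         paste0(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in nms) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     path = paste(path, nm, sep = "$"))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

validate_sim_config <- function(cfg) {
  if (cfg$season_end <= cfg$season_start) {
    stop("season_end must be after season_start", call. = FALSE)
  }
  if (cfg$dry_start < cfg$season_start || cfg$dry_end > cfg$season_end ||
      cfg$dry_end < cfg$dry_start) {
    stop("dry period must lie within the season", call. = FALSE)
  }
  for (ch in names(cfg$chambers)) {
    spec <- cfg$chambers[[ch]]
    if (spec$duration_s <= 0 || spec$volume_l <= 0 || spec$area_m2 <= 0 ||
        spec$closures_per_day <= 0) {
      stop("chamber '", ch, "' must have positive volume, area, duration ",
           "and closure count", call. = FALSE)
    }
    if (spec$window_s[2] > spec$duration_s) {
      stop("fit window for chamber '", ch,
           "' exceeds its closure duration", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> season", format(x$season_start), "to",
      format(x$season_end), "| seed", x$seed, "\n")
  cat("  dry period:", format(x$dry_start), "to", format(x$dry_end), "\n")
  cat("  chambers:", paste(names(x$chambers), collapse = ", "), "\n")
  invisible(x)
}

# deterministic child seed for a named simulation stage
stage_seed <- function(cfg, stage) {
  offs <- c(environment = 101L, fluxes = 211L, closures = 307L,
            tracheids = 401L, nsc = 503L, roots = 601L)
  (cfg$seed * 7919L + offs[[stage]]) %% .Machine$integer.max
}
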