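#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage of [run_pipeline()]. `sim` holds
#' overrides forwarded to [sim_config()]; `fluxes`, `phenology`,
#' `associate` and `coherence` hold the per-module tuning parameters
#' documented in the respective functions.
#'
#' @param seed integer master seed.
#' @return nested list of defaults.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    run_id = "run1",
    seed = as.integer(seed),
    sim = list(),
    fluxes = list(
      windows = list(shoot = c(5, 50), stem = c(10, 40), soil = c(40, 200)),
      par_night = 30),
    phenology = list(f1 = 0.05, f2 = 0.75, ew_frac = 0.65, lw_frac = 0.9,
                     root_min_amp = 0.5, root_min_gap_days = 5,
                     root_smooth_width = 7),
    associate = list(lag_days = 1, drop_p = 0.05, exclude_dates = list()),
    coherence = list(alpha = 0.05, n_surrogates = 300, omega0 = 6,
                     voices = 12, period_min = 2, period_max = 64,
                     max_gap_frac = 0.1)
  )
}

#' Load and validate a pipeline configuration from YAML
#'
#' Reads a YAML file, applies the defaults of [default_pipeline_config()]
#' and rejects unknown keys by name. The `sim` block is validated by
#' [sim_config()] when the pipeline runs.
#'
#' @param path YAML file path.
#' @return validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), raw, path = "pipeline")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(cfg)), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-to-coherence analysis pipeline
#'
#' Executes the stages in dependency order: simulate (environment, flux
#' truth, chamber closures, tracheid counts, NSC series, root growth) ->
#' chamber flux inversion and daily aggregation -> growth phenology ->
#' temperature/moisture detrending and association models -> wavelet
#' coherence with significance and lead/lag summary. Any stage failure
#' halts execution and the report carries the per-stage status. All key
#' intermediate tables are written as CSV when `out_dir` is given.
#'
#' @param config a `pipeline_config` (from [load_config()] or
#'   [default_pipeline_config()]), or a path to a YAML file.
#' @param out_dir optional directory for the CSV outputs.
#' @return list of class `run_report`: `status` (named character per
#'   stage), `config`, `config_hash`, `version` and the key outputs
#'   (`daily_fluxes`, `periods`, `models`, `coherence_summary`, plus the
#'   raw stage objects under `objects`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  status <- c(simulate = "pending", fluxes = "pending",
              phenology = "pending", associate = "pending",
              coherence = "pending")
  objects <- list()
  report <- function() {
    out <- list(status = status, config = config,
                config_hash = config_hash(config),
                version = as.character(utils::packageVersion("carboniso")),
                daily_fluxes = objects$daily_fluxes,
                periods = objects$periods, models = objects$models,
                coherence_summary = objects$coherence_summary,
                objects = objects)
    class(out) <- "run_report"
    out
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      status[name] <<- paste("failed:", conditionMessage(res))
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    status[name] <<- "ok"
    res
  }

  sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  objects$sim_config <- sim_cfg

  objects <- c(objects, run_stage("simulate", {
    env <- simulate_environment(sim_cfg)
    truth <- simulate_true_fluxes(env, sim_cfg)
    closures <- simulate_chamber_closures(truth, sim_cfg)
    tracheids <- simulate_tracheid_counts(sim_cfg)
    nsc <- simulate_nsc_series(sim_cfg)
    roots <- simulate_root_growth(env, sim_cfg)
    list(env = env, truth = truth, closures = closures,
         tracheids = tracheids, nsc = nsc, roots = roots)
  }))

  objects <- c(objects, run_stage("fluxes", {
    fits <- fit_closures(objects$closures, windows = config$fluxes$windows)
    daily <- do.call(rbind, lapply(c("shoot", "stem", "soil"), function(k) {
      aggregate_daily(fits, k, env = objects$env,
                      par_night = config$fluxes$par_night)
    }))
    list(closure_fits = fits, daily_fluxes = daily)
  }))

  objects <- c(objects, run_stage("phenology", {
    ph <- config$phenology
    norm <- normalize_counts(objects$tracheids)
    total_fit <- fit_gompertz(norm$pooled$doy, norm$pooled$n_total)
    mature_fit <- fit_gompertz(norm$pooled$doy, norm$pooled$n_c)
    doy_grid <- seq(min(norm$pooled$doy), max(norm$pooled$doy))
    active <- derive_active_phase(total_fit, mature_fit, doy_grid)
    origin <- as.Date(format(sim_cfg$season_start, "%Y-01-01"))
    stem_periods <- classify_growth_periods(total_fit, mature_fit, doy_grid,
                                            f1 = ph$f1, f2 = ph$f2,
                                            ew_frac = ph$ew_frac,
                                            lw_frac = ph$lw_frac,
                                            origin = origin)
    root_periods <- detect_root_periods(objects$roots,
                                        min_amp = ph$root_min_amp,
                                        min_gap_days = ph$root_min_gap_days,
                                        smooth_width = ph$root_smooth_width)
    periods <- rbind(
      stem_periods[c("period", "start", "end")],
      data.frame(period = "dry", start = sim_cfg$dry_start,
                 end = sim_cfg$dry_end),
      root_periods)
    list(norm_counts = norm, total_fit = total_fit,
         mature_fit = mature_fit, active_phase = active,
         periods = periods)
  }))

  objects <- c(objects, run_stage("associate", {
    list(models = association_table(objects, config, sim_cfg))
  }))

  objects <- c(objects, run_stage("coherence", {
    ch <- config$coherence
    daily <- objects$daily_fluxes
    ds <- function(kind) {
      d <- daily[daily$kind == kind, ]
      interpolate_gaps(d$date, d$delta, max_gap_frac = ch$max_gap_frac)
    }
    x <- ds("shoot")
    out <- list()
    for (kind in c("stem", "soil")) {
      y <- ds(kind)
      lo <- max(min(x$date), min(y$date)); hi <- min(max(x$date),
                                                     max(y$date))
      xi <- trim_series(x, lo, hi); yi <- trim_series(y, lo, hi)
      wc <- wavelet_coherence(xi, yi, omega0 = ch$omega0,
                              voices = ch$voices,
                              period_min = ch$period_min,
                              period_max = ch$period_max)
      sig <- coherence_significance(xi, yi, result = wc,
                                    n_surrogates = ch$n_surrogates,
                                    alpha = ch$alpha,
                                    seed = config$seed + 17)
      summ <- lead_lag_summary(wc, sig, objects$periods)
      summ$pair <- paste0("dAshoot_vs_dR", kind)
      out[[kind]] <- list(coherence = wc, significance = sig,
                          summary = summ)
    }
    list(coherence_stem = out$stem, coherence_soil = out$soil,
         coherence_summary = rbind(out$stem$summary, out$soil$summary))
  }))

  rep <- report()
  if (!is.null(out_dir)) write_report_tables(rep, out_dir)
  rep
}

trim_series <- function(s, lo, hi) {
  keep <- s$date >= lo & s$date <= hi
  out <- list(date = s$date[keep], value = s$value[keep],
              gap_mask = s$gap_mask[keep], gap_fraction = s$gap_fraction)
  class(out) <- "daily_series"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> carboniso", x$version, "| config", x$config_hash, "\n")
  for (s in names(x$status)) cat(sprintf("  %-10s %s\n", s, x$status[s]))
  invisible(x)
}

write_report_tables <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep$daily_fluxes,
                   file.path(out_dir, "daily_fluxes.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$periods, file.path(out_dir, "growth_periods.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$models, file.path(out_dir, "association_models.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$coherence_summary,
                   file.path(out_dir, "coherence_summary.csv"),
                   row.names = FALSE)
  ph <- rep$objects$active_phase
  utils::write.csv(ph, file.path(out_dir, "phenology_daily.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

# daily nighttime mean of a driver, defined by the PAR threshold
nightly_mean <- function(env, var, par_night = 30) {
  night <- env$PAR < par_night
  d <- as.Date(env$time, tz = "UTC")
  out <- stats::aggregate(list(value = env[[var]][night]),
                          by = list(date = d[night]), FUN = mean)
  out
}

# the association analyses: mixed model for tracheid growth vs phloem NSC,
# linear models for detrended stem efflux, delta13C pairs, and root growth
association_table <- function(objects, config, sim_cfg) {
  ac <- config$associate
  env <- objects$env
  daily <- objects$daily_fluxes
  nsc <- objects$nsc
  rows <- list()
  add <- function(analysis, response, predictor, model) {
    pt <- predictor_test(model)
    r2 <- if (length(model$r2) > 1) model$r2[["marginal"]] else model$r2
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, response = response, predictor = predictor,
      model = model$kind, estimate = pt$estimate, sign = pt$sign,
      p = pt$p, r2 = r2, n = model$n,
      doy_included = model$doy_included)
  }

  # --- tracheid growth vs phloem NSC concentration (mixed model) --------
  per_tree <- objects$norm_counts$per_tree
  phloem_dates <- sort(unique(nsc$date[nsc$organ == "phloem"]))
  growth_tree <- per_tree_growth(per_tree, phloem_dates)
  for (cp in c("sucrose", "glucose", "starch", "wsc")) {
    conc <- nsc[nsc$organ == "phloem" & nsc$compound == cp, ]
    m <- merge(growth_tree,
               data.frame(date = conc$date,
                          tree_id = paste0("tree", conc$replicate),
                          conc = conc$conc_mg_g),
               by = c("date", "tree_id"))
    m$doy <- as.integer(strftime(m$date, "%j", tz = "UTC"))
    mod <- fit_lmm(m, "growth", "conc", doy = "doy", tree = "tree_id",
                   drop_p = ac$drop_p)
    add("G_tracheid ~ phloem NSC", "G_tracheid", paste0("C_", cp), mod)
  }

  # --- stem efflux residuals vs growth rate and phloem NSC (linear) ----
  stem <- daily[daily$kind == "stem", ]
  t_night <- nightly_mean(env, "air_T", config$fluxes$par_night)
  m <- merge(stem, t_night, by = "date")
  ef <- fit_exponential_temperature(m$flux, m$value)
  resid_daily <- data.frame(date = m$date, value = ef$residuals)
  shifted <- lag_shift(resid_daily, ac$lag_days)
  active <- objects$active_phase
  origin <- as.Date(format(sim_cfg$season_start, "%Y-01-01"))
  growth_daily <- data.frame(date = origin + active$doy - 1,
                             growth = active$growth_rate)
  # stand-average models are evaluated on the NSC observation days
  g_obs <- data.frame(date = phloem_dates,
                      growth = stats::approx(as.numeric(growth_daily$date),
                                             growth_daily$growth,
                                             xout =
                                               as.numeric(phloem_dates),
                                             rule = 2)$y)
  m3 <- merge_nearest(shifted, g_obs, max_days = 3)
  mod <- fit_lm(m3, "value", "growth", doy = NULL, drop_p = ac$drop_p)
  add("Rstem residuals ~ growth/NSC", "Rstem_resid", "G_tracheid", mod)
  phloem_mean <- mean_by_date(nsc, "phloem")
  for (cp in c("sucrose", "glucose", "starch", "wsc")) {
    cc <- phloem_mean[phloem_mean$compound == cp, ]
    m4 <- merge_nearest(shifted, cc[c("date", "conc")], max_days = 3)
    mod <- fit_lm(m4, "value", "conc", doy = NULL, drop_p = ac$drop_p)
    add("Rstem residuals ~ growth/NSC", "Rstem_resid", paste0("C_", cp),
        mod)
  }

  # --- delta13C of Rstem vs delta13C of phloem NSC (linear) ------------
  stem_delta <- data.frame(date = stem$date, value = stem$delta)
  for (cp in c("sucrose", "glucose", "starch", "wsc")) {
    cc <- phloem_mean[phloem_mean$compound == cp, ]
    m5 <- merge_nearest(stem_delta, cc[c("date", "d13C")], max_days = 3)
    mod <- fit_lm(m5, "value", "d13C", doy = NULL,
                  exclude_dates = ac$exclude_dates, drop_p = ac$drop_p)
    add("d13C Rstem ~ d13C phloem NSC", "d13C_Rstem", paste0("d13C_", cp),
        mod)
  }

  # --- root growth residuals vs root NSC (linear) ----------------------
  roots <- objects$roots
  root_mean <- stats::aggregate(list(elong = roots$elongation_mm),
                                by = list(date = roots$date), FUN = mean)
  env_day <- stats::aggregate(env[c("soil_T", "soil_moisture")],
                              by = list(date = as.Date(env$time,
                                                       tz = "UTC")),
                              FUN = mean)
  mr <- merge(root_mean, env_day, by = "date")
  er <- fit_env_regression(mr$elong, mr$soil_T, mr$soil_moisture)
  root_resid <- data.frame(date = mr$date, value = er$residuals)
  root_nsc <- mean_by_date(nsc, "root")
  for (cp in c("starch", "wsc")) {
    cc <- root_nsc[root_nsc$compound == cp, ]
    m6 <- merge_nearest(root_resid, cc[c("date", "conc")], max_days = 3)
    mod <- fit_lm(m6, "value", "conc", doy = NULL, drop_p = ac$drop_p)
    add("G_fibrous residuals ~ root NSC", "G_fibrous_resid",
        paste0("C_", cp), mod)
  }

  # --- soil efflux residuals vs root growth and root NSC ---------------
  soil <- daily[daily$kind == "soil", ]
  ms <- merge(soil, env_day, by = "date")
  es <- fit_env_regression(ms$flux, ms$soil_T, ms$soil_moisture)
  soil_resid <- data.frame(date = ms$date, value = es$residuals)
  root_dates <- sort(unique(nsc$date[nsc$organ == "root"]))
  m7 <- merge(merge_nearest(soil_resid,
                            data.frame(date = root_dates, obs = 1),
                            max_days = 3),
              stats::setNames(root_resid, c("date", "root_resid")),
              by = "date")
  mod <- fit_lm(m7, "value", "root_resid", doy = NULL, drop_p = ac$drop_p)
  add("Rsoil residuals ~ roots/NSC", "Rsoil_resid", "G_fibrous_resid", mod)
  for (cp in c("starch", "wsc")) {
    cc <- root_nsc[root_nsc$compound == cp, ]
    m8 <- merge_nearest(soil_resid, cc[c("date", "conc")], max_days = 3)
    mod <- fit_lm(m8, "value", "conc", doy = NULL, drop_p = ac$drop_p)
    add("Rsoil residuals ~ roots/NSC", "Rsoil_resid", paste0("C_", cp),
        mod)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-tree tracheid growth rate at the phloem sampling dates: day-over-day
# increase of the per-tree normalized total count, interpolated in time
per_tree_growth <- function(per_tree, dates) {
  out <- list()
  for (tr in unique(per_tree$tree_id)) {
    d <- per_tree[per_tree$tree_id == tr, ]
    d <- d[order(d$date), ]
    t_num <- as.numeric(d$date)
    rate <- diff(d$n_total) / diff(t_num)
    mid <- t_num[-1] - diff(t_num) / 2
    g <- stats::approx(mid, rate, xout = as.numeric(dates), rule = 2)$y
    out[[tr]] <- data.frame(tree_id = tr, date = dates, growth = g)
  }
  do.call(rbind, out)
}

mean_by_date <- function(nsc, organ) {
  x <- nsc[nsc$organ == organ, ]
  agg <- stats::aggregate(list(conc = x$conc_mg_g, d13C = x$d13C_permil),
                          by = x[c("compound", "date")], FUN = mean)
  agg
}

# match each right-hand date to the nearest left-hand date within max_days
merge_nearest <- function(left, right, max_days = 3) {
  out <- list()
  for (i in seq_len(nrow(right))) {
    dd <- abs(as.numeric(left$date - right$date[i]))
    j <- which.min(dd)
    if (length(j) == 1 && dd[j] <= max_days) {
      out[[length(out) + 1]] <- cbind(left[j, , drop = FALSE],
                                      right[i, -1, drop = FALSE],
                                      row.names = NULL)
    }
  }
  do.call(rbind, out)
}
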