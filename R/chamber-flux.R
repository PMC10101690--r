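#' delta13C of a flux from its isotopologue components
#'
#' The carbon-isotope composition of a CO2 flux is determined from the
#' ratio of the 13CO2 flux to the 12CO2 flux, expressed in delta notation
#' relative to V-PDB: delta = ((F13/F12)/R_VPDB - 1) * 1000.
#'
#' @param F12,F13 12CO2 and 13CO2 fluxes, umol m-2 s-1.
#' @return delta13C in per mil.
#' @export
delta_from_fluxes <- function(F12, F13) {
  if (any(F12 == 0)) {
    stop("delta13C is undefined for a zero 12CO2 flux", call. = FALSE)
  }
  delta_from_ratio(F13 / F12)
}

#' Invert one chamber closure to isotopologue fluxes and delta13C
#'
#' Fits the saturating-exponential chamber model
#' C(t) = C_amb + (F*S*Vm/V) * (1 - exp(-q t)) / q
#' to the 12CO2 and 13CO2 traces over the fit window by nonlinear least
#' squares, with the leak rate q shared between the two isotopologues (the
#' physical replacement rate is isotopologue-independent). The fit is solved
#' by variable projection: for a candidate q the intercept and initial slope
#' of each trace are the exact linear least-squares solution, and q is
#' profiled by 1-D minimisation of the pooled residual sum of squares. If
#' the optimal q lies at the search boundary the linear-slope estimate over
#' the window is used instead and the record is flagged.
#'
#' @param closure a list or one-row data view with `time_s`, `c12`, `c13`,
#'   `volume_l`, `area_m2`, `chamber` and optionally `temp_C`, `PAR`,
#'   `closure_id`, `start` (see [closure_records()]).
#' @param window length-2 numeric, seconds since closure defining the fit
#'   window; defaults to the chamber kind's standard window (shoot 5-50 s,
#'   stem 10-40 s, soil 40-200 s).
#' @param q_max upper bound of the leak-rate search, s-1.
#' @return a one-row data.frame (class `isotope_flux`): `closure_id`,
#'   `chamber`, `start`, `PAR`, fitted `F12`, `F13` (chamber mass-balance
#'   sign), `flux` (positive efflux for stem/soil, positive influx for
#'   shoot), `delta` (per mil), `q`, RMSE per trace, window used and `flag`
#'   ("ok", "linear_fallback" or "zero_flux").
#' @export
fit_closure <- function(closure, window = NULL, q_max = 0.02) {
  if (is.null(window)) window <- default_window(closure$chamber)
  t <- closure$time_s
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 8) {
    stop("fit window [", window[1], ", ", window[2],
         "] s contains fewer than 8 samples", call. = FALSE)
  }
  t <- t[keep]
  y12 <- closure$c12[keep]
  y13 <- closure$c13[keep]
  temp <- if (!is.null(closure$temp_C) && is.finite(closure$temp_C))
    closure$temp_C else 15

  sse_q <- function(q) {
    X <- cbind(1, sat_ramp(q, t))
    r12 <- stats::lm.fit(X, y12)$residuals
    r13 <- stats::lm.fit(X, y13)$residuals
    sum(r12^2) + sum(r13^2) * 1e4   # bring the small 13CO2 trace on scale
  }
  opt <- stats::optimize(sse_q, c(-q_max, q_max), tol = 1e-10)
  q_hat <- opt$minimum
  flag <- "ok"
  # a negative fitted leak rate is unphysical and a boundary optimum means
  # the curvature is not identified; fall back to the linear-slope estimate
  # (the q -> 0 limit of the same model) and flag the record
  if (q_hat < 0 || q_hat > q_max * (1 - 1e-3)) {
    q_hat <- 0
    flag <- "linear_fallback"
  }
  X <- cbind(1, sat_ramp(q_hat, t))
  f12 <- stats::lm.fit(X, y12)
  f13 <- stats::lm.fit(X, y13)
  vfac <- closure$volume_l / (closure$area_m2 * molar_volume(temp))
  F12 <- unname(f12$coefficients[2]) * vfac
  F13 <- unname(f13$coefficients[2]) * vfac

  rmse12 <- sqrt(mean(f12$residuals^2))
  rmse13 <- sqrt(mean(f13$residuals^2))
  # concentration change over the window too small to carry isotopic
  # information -> delta undefined
  signal <- abs(unname(f12$coefficients[2])) * sat_ramp(q_hat, diff(range(t)))
  if (signal < max(1e-9, 4 * rmse12 / sqrt(length(t)))) {
    flag <- "zero_flux"
  }
  delta <- if (flag == "zero_flux" || F12 == 0) NA_real_ else
    delta_from_fluxes(F12, F13)
  dir <- if (identical(closure$chamber, "shoot")) -1 else 1
  out <- data.frame(
    closure_id = closure$closure_id %||% NA_integer_,
    chamber = closure$chamber,
    start = closure$start %||% as.POSIXct(NA),
    PAR = closure$PAR %||% NA_real_,
    F12 = F12, F13 = F13, flux = dir * (F12 + F13),
    delta = delta, q = q_hat,
    rmse12 = rmse12, rmse13 = rmse13,
    window_lo = window[1], window_hi = window[2], flag = flag)
  class(out) <- c("isotope_flux", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_window <- function(chamber) {
  switch(chamber,
         shoot = c(5, 50), stem = c(10, 40), soil = c(40, 200),
         stop("no default fit window for chamber kind '", chamber, "'",
              call. = FALSE))
}

#' Split a closure set into per-closure records
#'
#' @param set a `closure_set` from [simulate_chamber_closures()] or
#'   [read_closures_csv()].
#' @return list of per-closure lists suitable for [fit_closure()].
#' @export
closure_records <- function(set) {
  tr <- split(set$traces[c("time_s", "c12_ppm", "c13_ppm")],
              factor(set$traces$closure_id, levels = set$info$closure_id))
  lapply(seq_len(nrow(set$info)), function(i) {
    info <- set$info[i, ]
    list(closure_id = info$closure_id, chamber = info$chamber,
         start = info$start, PAR = info$PAR,
         volume_l = info$volume_l, area_m2 = info$area_m2,
         temp_C = info$temp_C %||% 15,
         time_s = tr[[i]]$time_s, c12 = tr[[i]]$c12_ppm,
         c13 = tr[[i]]$c13_ppm)
  })
}

#' Fit every closure in a closure set
#'
#' @param set a `closure_set`.
#' @param windows optional named list of fit windows per chamber kind, e.g.
#'   `list(shoot = c(5, 50))`; missing kinds use their defaults.
#' @return data.frame of per-closure [fit_closure()] results.
#' @export
fit_closures <- function(set, windows = NULL) {
  recs <- closure_records(set)
  out <- do.call(rbind, lapply(recs, function(r) {
    w <- windows[[r$chamber]] %||% default_window(r$chamber)
    fit_closure(r, window = w)
  }))
  rownames(out) <- NULL
  out
}

#' Calibrate measured delta13C values against reference gases
#'
#' Builds the linear mapping from measured to true delta13C from reference
#' gas measurements (two-point exact when two references, least squares when
#' more) and applies it.
#'
#' @param deltas measured delta13C values, per mil.
#' @param reference data.frame or matrix with columns `measured` and `true`
#'   (per mil), at least two distinct reference points.
#' @return calibrated delta values; the calibration (slope, intercept) is
#'   attached as attribute `calibration`.
#' @export
calibrate_delta <- function(deltas, reference) {
  reference <- as.data.frame(reference)
  stopifnot(all(c("measured", "true") %in% names(reference)))
  if (nrow(reference) < 2 ||
      diff(range(reference$measured)) < .Machine$double.eps^0.5) {
    stop("calibration requires at least two distinct reference points",
         call. = FALSE)
  }
  fit <- stats::lm(true ~ measured, data = reference)
  out <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * deltas)
  attr(out, "calibration") <- c(intercept = unname(stats::coef(fit)[1]),
                                slope = unname(stats::coef(fit)[2]))
  out
}

#' Aggregate per-closure fluxes to daily means and flux-weighted delta13C
#'
#' Closures are classified as nighttime when PAR at closure is below
#' 30 umol m-2 s-1. Daily shoot assimilation uses daytime closures only,
#' nighttime stem efflux uses nighttime closures only, and soil efflux uses
#' all closures of the day. The daily delta13C is the flux-weighted mean
#' sum(F_i * delta_i) / sum(F_i) over the member closures; days with no
#' usable member closures are omitted (missing, not zero). Flagged closures
#' (`flag != "ok"`) are excluded.
#'
#' @param fluxes data.frame of per-closure fits from [fit_closures()].
#' @param kind one of "shoot", "stem", "soil".
#' @param env optional `environment_series` used to look up PAR at closure
#'   start when the flux table has no `PAR` column.
#' @param par_night PAR threshold (umol m-2 s-1) below which a closure is
#'   nighttime.
#' @return data.frame (class `daily_flux`): `date`, `kind`, `flux` (daily
#'   mean, umol m-2 s-1), `delta` (flux-weighted, per mil), `n` closures.
#' @export
aggregate_daily <- function(fluxes, kind, env = NULL, par_night = 30) {
  kind <- match.arg(kind, c("shoot", "stem", "soil"))
  x <- fluxes[fluxes$chamber == kind & fluxes$flag != "zero_flux" &
                is.finite(fluxes$flux), , drop = FALSE]
  if (is.null(x$PAR) || all(is.na(x$PAR))) {
    if (is.null(env)) stop("PAR unavailable: supply `env`", call. = FALSE)
    j <- findInterval(as.numeric(x$start), as.numeric(env$time))
    j[j < 1] <- 1
    x$PAR <- env$PAR[j]
  }
  night <- x$PAR < par_night
  use <- switch(kind, shoot = !night, stem = night,
                soil = rep(TRUE, nrow(x)))
  x <- x[use & !is.na(x$delta), , drop = FALSE]
  if (nrow(x) == 0) {
    return(structure(data.frame(date = as.Date(character()),
                                kind = character(), flux = numeric(),
                                delta = numeric(), n = integer()),
                     class = c("daily_flux", "data.frame")))
  }
  x$date <- as.Date(x$start, tz = "UTC")
  parts <- split(x, x$date)
  out <- do.call(rbind, lapply(parts, function(d) {
    w <- abs(d$flux)
    delta <- if (sum(w) > 0) sum(w * d$delta) / sum(w) else mean(d$delta)
    data.frame(date = d$date[1], kind = kind, flux = mean(d$flux),
               delta = delta, n = nrow(d))
  }))
  rownames(out) <- NULL
  class(out) <- c("daily_flux", "data.frame")
  out
}
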