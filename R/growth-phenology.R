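#' Gompertz growth curve and its daily rate
#'
#' The three-parameter Gompertz form standard in xylogenesis,
#' y(t) = A * exp(-beta * exp(-kappa * t)) with t in day of year: `A` is the
#' asymptotic cell count, `beta` the displacement and `kappa` the rate.
#' `gompertz_rate()` is the analytic derivative dy/dt.
#'
#' @param t day of year.
#' @param A,beta,kappa curve parameters (A > 0, kappa > 0).
#' @return fitted count (or its time derivative) at `t`.
#' @export
gompertz <- function(t, A, beta, kappa) {
  A * exp(-beta * exp(-kappa * t))
}

#' @rdname gompertz
#' @export
gompertz_rate <- function(t, A, beta, kappa) {
  u <- beta * exp(-kappa * t)
  A * exp(-u) * u * kappa
}

#' Normalize tracheid counts by previous-year ring width
#'
#' Divides each tree's phenophase counts by that tree's previous-year
#' tree-ring width, then pools (averages) the normalized counts across trees
#' per sampling date. Per-tree normalized values are retained for
#' mixed-effects modelling.
#'
#' @param obs data.frame with columns `tree_id`, `date`, `n_a`, `n_b`,
#'   `n_c`, `n_total`, `prev_ring_width_mm`.
#' @return list with `pooled` (per-date means of normalized counts, columns
#'   `date`, `doy`, `n_a`, `n_b`, `n_c`, `n_total`) and `per_tree` (the
#'   normalized per-tree table). Trees with missing or non-positive ring
#'   width are dropped with a warning.
#' @export
normalize_counts <- function(obs) {
  bad <- !is.finite(obs$prev_ring_width_mm) | obs$prev_ring_width_mm <= 0
  if (any(bad)) {
    warning("dropping ", length(unique(obs$tree_id[bad])),
            " tree(s) with missing or non-positive ring width")
    obs <- obs[!bad, , drop = FALSE]
  }
  cols <- c("n_a", "n_b", "n_c", "n_total")
  per_tree <- obs
  per_tree[cols] <- obs[cols] / obs$prev_ring_width_mm
  agg <- stats::aggregate(per_tree[cols], by = list(date = per_tree$date),
                          FUN = mean)
  agg$doy <- as.integer(strftime(agg$date, "%j", tz = "UTC"))
  list(pooled = agg[order(agg$date),
                    c("date", "doy", cols)], per_tree = per_tree)
}

#' Fit a Gompertz curve to cumulative tracheid counts
#'
#' Nonlinear least squares via [minpack.lm::nlsLM()] with documented
#' initializers (A from the maximum count, kappa and beta from a
#' log-linearization of the mid-rise observations) and multi-start jittering
#' to guard against local minima.
#'
#' @param doy day of year of each observation.
#' @param count observed (normalized) cumulative count.
#' @param n_starts number of jittered restarts.
#' @return list of class `gompertz_fit`: `par` (A, beta, kappa), `fitted`,
#'   `residuals`, `sigma` (residual SD), `converged`, plus `doy`, `count`.
#' @export
fit_gompertz <- function(doy, count, n_starts = 5) {
  ok <- is.finite(doy) & is.finite(count)
  doy <- doy[ok]; count <- count[ok]
  if (length(doy) < 6) {
    stop("need at least 6 observations to fit a Gompertz curve",
         call. = FALSE)
  }
  A0 <- max(count)
  mid <- count > 0.05 * A0 & count < 0.95 * A0 & count > 0
  init <- c(A = A0 * 1.02, beta = NA, kappa = NA)
  if (sum(mid) >= 2) {
    z <- log(-log(pmin(count[mid] / (A0 * 1.05), 0.999)))
    lf <- stats::lm(z ~ doy[mid])
    init["kappa"] <- max(1e-3, -unname(stats::coef(lf)[2]))
    init["beta"] <- exp(unname(stats::coef(lf)[1]))
  } else {
    init["kappa"] <- 0.05
    init["beta"] <- exp(0.05 * stats::median(doy))
  }

  best <- NULL
  set_jitter <- c(1, 0.7, 1.3, 0.85, 1.15, 0.5, 2)[seq_len(max(1, n_starts))]
  for (j in set_jitter) {
    st <- list(A = init[["A"]], lbeta = log(init[["beta"]]) * j,
               kappa = init[["kappa"]] * j)
    fit <- tryCatch(
      minpack.lm::nlsLM(count ~ A * exp(-exp(lbeta - kappa * doy)),
                        start = st,
                        lower = c(A = 1e-8, lbeta = -50, kappa = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    stop("Gompertz fit did not converge after ", length(set_jitter),
         " starts (A0 = ", signif(A0, 4), ")", call. = FALSE)
  }
  cf <- stats::coef(best)
  par <- c(A = unname(cf["A"]), beta = exp(unname(cf["lbeta"])),
           kappa = unname(cf["kappa"]))
  out <- list(par = par,
              fitted = gompertz(doy, par["A"], par["beta"], par["kappa"]),
              residuals = count - gompertz(doy, par["A"], par["beta"],
                                           par["kappa"]),
              sigma = sqrt(stats::deviance(best) /
                             max(1, length(doy) - 3)),
              converged = TRUE, doy = doy, count = count)
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("<gompertz_fit> A =", signif(x$par["A"], 4),
      " beta =", signif(x$par["beta"], 4),
      " kappa =", signif(x$par["kappa"], 4),
      " sigma =", signif(x$sigma, 3), "\n")
  invisible(x)
}

#' @export
predict.gompertz_fit <- function(object, doy, ...) {
  gompertz(doy, object$par[["A"]], object$par[["beta"]],
           object$par[["kappa"]])
}

#' Daily active-phase counts and tracheid growth rate
#'
#' Subtracting the fitted mature-phase curve from the fitted total curve
#' gives the daily number of tracheids in the enlargement plus
#' wall-thickening phases (clipped at zero, with a warning when the fitted
#' curves cross). The tracheid growth rate is the day-over-day increase of
#' the fitted total curve, i.e. the rate at which new cells enter the active
#' phases; it is non-negative by construction.
#'
#' @param total_fit,mature_fit `gompertz_fit` objects for total and mature
#'   counts.
#' @param doy_grid integer grid of days of year to evaluate on.
#' @return data.frame `doy`, `n_ab`, `growth_rate`.
#' @export
derive_active_phase <- function(total_fit, mature_fit, doy_grid) {
  stopifnot(inherits(total_fit, "gompertz_fit"),
            inherits(mature_fit, "gompertz_fit"))
  y_tot <- predict(total_fit, doy_grid)
  y_mat <- predict(mature_fit, doy_grid)
  n_ab <- y_tot - y_mat
  if (any(n_ab < -1e-8)) {
    warning("fitted total and mature curves cross; clipping active-phase ",
            "counts at zero")
  }
  rate <- y_tot - predict(total_fit, doy_grid - 1)
  data.frame(doy = doy_grid, n_ab = pmax(0, n_ab), growth_rate = rate)
}

#' Delimit stem growth periods from fitted tracheid curves
#'
#' Production (maturation) period: days where the daily rate of the fitted
#' total (mature) curve exceeds a fraction `f1` of its seasonal maximum.
#' Maximum-rate periods: days where the rate is at least a fraction `f2` of
#' the peak. Earlywood/latewood boundaries come from configurable fractions
#' of the fitted total asymptote: earlywood ends where the fitted total
#' curve first exceeds `ew_frac * A`, latewood starts where it first exceeds
#' `lw_frac * A`, with the earlywood-latewood transition in between. These
#' thresholds are free parameters; the rule producing the field-reported
#' period dates is not derivable from the curves alone.
#'
#' @param total_fit,mature_fit `gompertz_fit` objects.
#' @param doy_grid evaluation grid (days of year).
#' @param f1 rate fraction delimiting production/maturation periods.
#' @param f2 rate fraction delimiting maximum-rate periods.
#' @param ew_frac,lw_frac fractions of the asymptote bounding the
#'   earlywood-latewood transition.
#' @param origin optional year origin (Date of Jan 1) to add calendar dates.
#' @return data.frame `period`, `start_doy`, `end_doy` (+ `start`, `end`
#'   Dates when `origin` given), class `growth_periods`.
#' @export
classify_growth_periods <- function(total_fit, mature_fit, doy_grid,
                                    f1 = 0.05, f2 = 0.75,
                                    ew_frac = 0.65, lw_frac = 0.9,
                                    origin = NULL) {
  rate_tot <- gompertz_rate(doy_grid, total_fit$par["A"],
                            total_fit$par["beta"], total_fit$par["kappa"])
  rate_mat <- gompertz_rate(doy_grid, mature_fit$par["A"],
                            mature_fit$par["beta"], mature_fit$par["kappa"])
  span <- function(sel, what) {
    if (!any(sel)) {
      stop("no days satisfy the threshold for period '", what, "'",
           call. = FALSE)
    }
    range(doy_grid[sel])
  }
  prod <- span(rate_tot >= f1 * max(rate_tot), "production")
  matu <- span(rate_mat >= f1 * max(rate_mat), "maturation")
  maxp <- span(rate_tot >= f2 * max(rate_tot), "max production")
  maxm <- span(rate_mat >= f2 * max(rate_mat), "max maturation")
  y_tot <- predict(total_fit, doy_grid)
  A <- total_fit$par[["A"]]
  ew_end <- doy_grid[which(y_tot >= ew_frac * A)[1]]
  lw_start <- doy_grid[which(y_tot >= lw_frac * A)[1]]
  if (is.na(ew_end) || is.na(lw_start)) {
    stop("fitted curve does not reach the earlywood/latewood fractions ",
         "on the evaluation grid", call. = FALSE)
  }
  out <- data.frame(
    period = c("production", "maturation", "max_production",
               "max_maturation", "earlywood", "ew_lw_transition",
               "latewood"),
    start_doy = c(prod[1], matu[1], maxp[1], maxm[1], prod[1], ew_end + 1,
                  lw_start),
    end_doy = c(prod[2], matu[2], maxp[2], maxm[2], ew_end, lw_start - 1,
                matu[2]))
  if (!is.null(origin)) {
    out$start <- as.Date(origin) + out$start_doy - 1
    out$end <- as.Date(origin) + out$end_doy - 1
  }
  class(out) <- c("growth_periods", "data.frame")
  out
}

#' Detect root growth periods from scanner elongation series
#'
#' Each scanner's daily elongation is smoothed by a centered moving mean,
#' segmented into pulses where the smoothed series reaches `min_amp`, runs
#' separated by less than `min_gap_days` are merged within a scanner, and
#' overlapping pulses are merged across scanners into named periods.
#'
#' @param roots data.frame `scanner_id`, `date`, `elongation_mm`.
#' @param min_amp minimum smoothed elongation (mm day-1) inside a pulse.
#' @param min_gap_days merge within-scanner runs separated by fewer days.
#' @param smooth_width centered moving-mean width, days (odd).
#' @return data.frame `period`, `start`, `end` (Dates), class
#'   `growth_periods`; zero rows when no pulse reaches `min_amp`.
#' @export
detect_root_periods <- function(roots, min_amp = 0.5, min_gap_days = 5,
                                smooth_width = 7) {
  runs <- list()
  for (sc in unique(roots$scanner_id)) {
    d <- roots[roots$scanner_id == sc, ]
    d <- d[order(d$date), ]
    k <- smooth_width
    sm <- stats::filter(d$elongation_mm, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- d$elongation_mm[is.na(sm)]
    on <- as.numeric(sm) >= min_amp
    if (!any(on)) next
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    seg <- data.frame(start = d$date[starts[r$values]],
                      end = d$date[ends[r$values]])
    # merge within-scanner runs separated by short gaps
    i <- 1
    while (i < nrow(seg)) {
      if (as.numeric(seg$start[i + 1] - seg$end[i]) <= min_gap_days) {
        seg$end[i] <- seg$end[i + 1]
        seg <- seg[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    runs[[length(runs) + 1]] <- seg
  }
  if (length(runs) == 0) {
    out <- data.frame(period = character(), start = as.Date(character()),
                      end = as.Date(character()))
    class(out) <- c("growth_periods", "data.frame")
    return(out)
  }
  seg <- do.call(rbind, runs)
  seg <- seg[order(seg$start), , drop = FALSE]
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg$start[i] <= merged$end[last] + 1) {
        merged$end[last] <- max(merged$end[last], seg$end[i])
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  out <- data.frame(period = paste0("root_period_",
                                    utils::as.roman(seq_len(nrow(merged)))),
                    start = merged$start, end = merged$end)
  rownames(out) <- NULL
  class(out) <- c("growth_periods", "data.frame")
  out
}
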