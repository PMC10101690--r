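#' Fill interior gaps of a daily series by linear interpolation
#'
#' Builds a contiguous daily grid between the first and last observed dates,
#' linearly interpolates interior missing values, trims leading/trailing
#' gaps and records which dates were filled.
#'
#' @param date observation dates.
#' @param value values (NA for missing); missing dates are also gaps.
#' @param max_gap_frac error when the gap fraction exceeds this ceiling.
#' @return list of class `daily_series`: `date`, `value`, `gap_mask`,
#'   `gap_fraction`.
#' @export
interpolate_gaps <- function(date, value, max_gap_frac = 0.1) {
  date <- as.Date(date)
  ok <- is.finite(value)
  if (sum(ok) < 2) stop("need at least two observed values", call. = FALSE)
  lo <- min(date[ok]); hi <- max(date[ok])
  grid <- seq(lo, hi, by = 1)
  v <- rep(NA_real_, length(grid))
  v[match(date[ok], grid)] <- value[ok]
  gap <- !is.finite(v)
  frac <- mean(gap)
  if (frac > max_gap_frac) {
    stop(sprintf("gap fraction %.1f%% exceeds the ceiling %.1f%%",
                 100 * frac, 100 * max_gap_frac), call. = FALSE)
  }
  if (any(gap)) {
    v <- stats::approx(as.numeric(grid[!gap]), v[!gap],
                       xout = as.numeric(grid))$y
  }
  out <- list(date = grid, value = v, gap_mask = gap, gap_fraction = frac)
  class(out) <- "daily_series"
  out
}

as_daily_series <- function(x) {
  if (inherits(x, "daily_series")) return(x)
  if (is.data.frame(x)) return(interpolate_gaps(x$date, x$value))
  stop("expected a daily_series or a data.frame(date, value)",
       call. = FALSE)
}

# Fourier factor converting Morlet scale to period
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based continuous wavelet transform with the analytic Morlet wavelet
#' (default omega0 = 6), zero-padded to the next power of two, on a dyadic
#' scale grid with `voices` sub-octaves.
#'
#' @param x numeric series (mean is removed before transforming).
#' @param dt sampling step (days).
#' @param omega0 Morlet non-dimensional frequency.
#' @param voices voices per octave of the dyadic scale grid.
#' @param period_min,period_max requested Fourier-period range (days);
#'   `period_max` defaults to half the series length and is truncated to it
#'   with a warning when larger.
#' @return list of class `cwt`: `W` (complex matrix, scales x time),
#'   `period`, `scale`, `coi` (per-time maximum unaffected period), `dt`,
#'   `omega0`.
#' @export
cwt_morlet <- function(x, dt = 1, omega0 = 6, voices = 12,
                       period_min = 2 * dt, period_max = NULL) {
  n <- length(x)
  ff <- morlet_fourier_factor(omega0)
  lim <- n * dt / 2
  if (is.null(period_max)) period_max <- lim
  if (period_max > lim) {
    warning("period_max truncated to half the series length (",
            signif(lim, 4), " d)")
    period_max <- lim
  }
  s0 <- period_min / ff
  s1 <- period_max / ff
  j <- seq(0, log2(s1 / s0), by = 1 / voices)
  scale <- s0 * 2^j
  period <- scale * ff

  npad <- 2^ceiling(log2(n))
  xz <- c(x - mean(x), rep(0, npad - n))
  xf <- stats::fft(xz)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  W <- matrix(0 + 0i, nrow = length(scale), ncol = n)
  norm0 <- pi^(-1 / 4)
  for (i in seq_along(scale)) {
    s <- scale[i]
    psi <- norm0 * sqrt(2 * pi * s / dt) * exp(-(s * omega - omega0)^2 / 2) *
      (omega > 0)
    w <- stats::fft(xf * psi, inverse = TRUE) / npad
    W[i, ] <- w[seq_len(n)]
  }
  d <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- ff / sqrt(2) * pmax(d, 1e-8)
  out <- list(W = W, period = period, scale = scale, coi = coi, dt = dt,
              omega0 = omega0, voices = voices, n = n)
  class(out) <- "cwt"
  out
}

# smoothing operator of the coherence recipe: Gaussian in time with sd equal
# to the wavelet scale (applied in the Fourier domain on a zero-padded grid,
# the standard recipe), then a boxcar over ~0.6 octave across scales
smooth_wavelet <- function(M, scale, dt, voices, scale_smooth_octaves = 0.6) {
  n <- ncol(M); ns <- nrow(M)
  npad <- 2^ceiling(log2(n))
  Mp <- cbind(M, matrix(0 + 0i, ns, npad - n))
  Fr <- t(stats::mvfft(t(Mp)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / npad,
                  -2 * pi * (npad - k) / npad) / dt
  G <- exp(-0.5 * (outer(scale, omega))^2)
  out <- t(stats::mvfft(t(Fr * G), inverse = TRUE))[, seq_len(n),
                                                    drop = FALSE] / npad
  nw <- max(1, round(scale_smooth_octaves * voices / 2) * 2 + 1)
  if (nw > 1 && ns > 1) {
    half <- (nw - 1) / 2
    sm <- out
    for (i in seq_len(ns)) {
      rows <- max(1, i - half):min(ns, i + half)
      sm[i, ] <- colMeans(out[rows, , drop = FALSE])
    }
    out <- sm
  }
  out
}

#' Morlet wavelet coherence and phase between two daily series
#'
#' Squared wavelet coherence |S(W_xy / s)|^2 / (S(|W_x|^2 / s) *
#' S(|W_y|^2 / s)) with the standard smoothing S (Gaussian in time with the
#' wavelet scale, boxcar over ~0.6 octave across scales). Phase is the
#' argument of the smoothed cross-spectrum; a positive phase in (0, pi)
#' means x leads y at that period, and the implied lag in days is
#' phase * period / (2 pi).
#'
#' @param x,y `daily_series` objects (see [interpolate_gaps()]) or
#'   data.frames with `date` and `value`, on a common daily grid.
#' @param omega0,voices,period_min,period_max passed to [cwt_morlet()].
#' @return list of class `wavelet_coherence`: `coherence` and `phase`
#'   matrices (scales x time), `period`, `date`, `coi`, `inside_coi`
#'   logical matrix, and the smoothing spec.
#' @export
wavelet_coherence <- function(x, y, omega0 = 6, voices = 12,
                              period_min = 2, period_max = NULL) {
  x <- as_daily_series(x); y <- as_daily_series(y)
  if (length(x$value) != length(y$value) ||
      !all(x$date == y$date)) {
    stop("series must share a common daily date grid", call. = FALSE)
  }
  dt <- 1
  wx <- cwt_morlet(x$value, dt, omega0, voices, period_min, period_max)
  wy <- cwt_morlet(y$value, dt, omega0, voices, period_min, period_max)
  sinv <- 1 / wx$scale
  Sxx <- Re(smooth_wavelet(sinv * (abs(wx$W)^2 + 0i), wx$scale, dt, voices))
  Syy <- Re(smooth_wavelet(sinv * (abs(wy$W)^2 + 0i), wx$scale, dt, voices))
  Sxy <- smooth_wavelet(sinv * (wx$W * Conj(wy$W)), wx$scale, dt, voices)
  coh <- pmin(pmax(abs(Sxy)^2 / (Sxx * Syy), 0), 1)
  phase <- Arg(Sxy)
  inside <- outer(wx$period, wx$coi, "<=")
  out <- list(coherence = coh, phase = phase, period = wx$period,
              date = x$date, coi = wx$coi, inside_coi = inside,
              omega0 = omega0, voices = voices,
              smoothing = "gaussian(time, sd = scale) + boxcar(0.6 octave)")
  class(out) <- "wavelet_coherence"
  out
}

#' @export
print.wavelet_coherence <- function(x, ...) {
  cat("<wavelet_coherence>", length(x$date), "days x", length(x$period),
      "periods (", signif(min(x$period), 3), "-", signif(max(x$period), 3),
      "d )\n")
  invisible(x)
}

# fit AR(1) parameters and simulate a surrogate of the same length
ar1_params <- function(v) {
  phi <- stats::cor(v[-1], v[-length(v)])
  phi <- max(min(phi, 0.99), -0.99)
  c(phi = phi, sd = stats::sd(v) * sqrt(1 - phi^2))
}

ar1_surrogate <- function(n, phi, sd_innov) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sd_innov), phi,
                           method = "recursive"))
}

#' Monte-Carlo significance mask for wavelet coherence
#'
#' Builds the null distribution of squared coherence per period from
#' surrogate pairs of independent AR(1) processes matched to each input
#' series' lag-1 autocorrelation and variance (values pooled over time
#' inside the cone of influence), and marks observed cells exceeding the
#' (1 - alpha) null quantile of their period. The mask is restricted to the
#' cone of influence.
#'
#' @param x,y the two daily series (as in [wavelet_coherence()]).
#' @param result optional precomputed [wavelet_coherence()] result for
#'   (x, y); computed when NULL.
#' @param n_surrogates number of surrogate pairs (>= 100).
#' @param alpha significance level.
#' @param seed integer seed for the surrogate draws.
#' @param ... passed to [wavelet_coherence()].
#' @return list of class `coherence_significance`: `mask` (logical matrix),
#'   `null_quantile` (per period), `alpha`, `n_surrogates`, `seed`.
#' @export
coherence_significance <- function(x, y, result = NULL, n_surrogates = 300,
                                   alpha = 0.05, seed = 1, ...) {
  if (n_surrogates < 100) {
    stop("use at least 100 surrogate pairs", call. = FALSE)
  }
  x <- as_daily_series(x); y <- as_daily_series(y)
  if (stats::sd(x$value) == 0 || stats::sd(y$value) == 0) {
    stop("degenerate (constant) series: coherence null is undefined",
         call. = FALSE)
  }
  if (is.null(result)) result <- wavelet_coherence(x, y, ...)
  px <- ar1_params(x$value); py <- ar1_params(y$value)
  n <- length(x$value)
  np <- length(result$period)
  set.seed(as.integer(seed))
  counts <- rowSums(result$inside_coi)
  null_vals <- lapply(counts, function(k) {
    if (k > 0) matrix(NA_real_, n_surrogates, k) else NULL
  })
  for (b in seq_len(n_surrogates)) {
    sx <- list(date = x$date, value = ar1_surrogate(n, px["phi"], px["sd"]))
    sy <- list(date = y$date, value = ar1_surrogate(n, py["phi"], py["sd"]))
    class(sx) <- class(sy) <- "daily_series"
    wc <- wavelet_coherence(sx, sy, omega0 = result$omega0,
                            voices = result$voices,
                            period_min = min(result$period),
                            period_max = max(result$period))
    for (i in seq_len(np)) {
      if (counts[i] > 0) {
        null_vals[[i]][b, ] <- wc$coherence[i, result$inside_coi[i, ]]
      }
    }
  }
  qs <- vapply(null_vals, function(v) {
    if (alpha >= 1) return(-Inf)
    if (is.null(v)) Inf else stats::quantile(v, 1 - alpha, names = FALSE)
  }, numeric(1))
  mask <- sweep(result$coherence, 1, qs, ">") & result$inside_coi
  out <- list(mask = mask, null_quantile = qs, alpha = alpha,
              n_surrogates = n_surrogates, seed = seed,
              surrogate_model = "independent AR(1), variance-matched")
  class(out) <- "coherence_significance"
  out
}

circular_mean <- function(theta) {
  if (length(theta) == 0) return(NA_real_)
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' Lead/lag summary of significant coherence per named period and band
#'
#' For every combination of a named calendar period and a period band,
#' summarizes the cells inside the cone of influence: the fraction of cells
#' significant, and over the significant cells where x leads y (phase in
#' (0, pi), the only phases treated as meaningful since the isotopic signal
#' travels from assimilation to respiration), the circular-mean phase and
#' the mean implied lag phase * period / (2 pi) in days.
#'
#' @param result a [wavelet_coherence()] result.
#' @param significance a [coherence_significance()] result for it.
#' @param periods data.frame with `period` (name), `start`, `end` (Dates).
#' @param bands list of length-2 numeric period bands in days.
#' @return data.frame `period`, `band`, `n_cells`, `frac_significant`,
#'   `mean_phase`, `lag_days` (NA when no leading significant cell).
#' @export
lead_lag_summary <- function(result, significance, periods,
                             bands = list(c(2, 4), c(4, 8), c(8, 16),
                                          c(16, 32))) {
  rows <- list()
  for (i in seq_len(nrow(periods))) {
    tsel <- result$date >= as.Date(periods$start[i]) &
      result$date <= as.Date(periods$end[i])
    for (bd in bands) {
      psel <- result$period >= bd[1] & result$period < bd[2]
      inside <- result$inside_coi[psel, tsel, drop = FALSE]
      if (!any(inside)) {
        rows[[length(rows) + 1]] <- data.frame(
          period = periods$period[i],
          band = paste0(bd[1], "-", bd[2], "d"), n_cells = 0L,
          frac_significant = NA_real_, mean_phase = NA_real_,
          lag_days = NA_real_)
        next
      }
      m <- significance$mask[psel, tsel, drop = FALSE] & inside
      ph <- result$phase[psel, tsel, drop = FALSE]
      per <- matrix(result$period[psel], nrow = sum(psel),
                    ncol = sum(tsel))
      lead <- m & ph > 0 & ph < pi
      mean_phase <- circular_mean(ph[lead])
      lag <- if (any(lead)) mean(ph[lead] * per[lead] / (2 * pi)) else
        NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        period = periods$period[i],
        band = paste0(bd[1], "-", bd[2], "d"),
        n_cells = sum(inside),
        frac_significant = sum(m) / sum(inside),
        mean_phase = mean_phase, lag_days = lag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
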