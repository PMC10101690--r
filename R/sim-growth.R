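#' Simulate repeated tracheid phenophase counts for several trees
#'
#' Per-tree total and mature cumulative counts are noisy observations of
#' tree-specific Gompertz truths (the mature curve delayed and below the
#' total; both share the tree asymptote since every cell eventually
#' matures). Counts in the enlargement (a) and wall-thickening (b) phases
#' partition total minus mature, with the enlargement share tracking the
#' production rate. Counts are scaled by each tree's previous-year ring
#' width so normalization by [normalize_counts()] recovers the common truth.
#'
#' @param config a [sim_config()] object.
#' @return data.frame `tree_id`, `date`, `doy`, `n_a`, `n_b`, `n_c`,
#'   `n_total`, `prev_ring_width_mm`; attribute `truth` holds the
#'   tree-specific Gompertz parameters.
#' @export
simulate_tracheid_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$gompertz
  set.seed(stage_seed(config, "tracheids"))
  dates <- seq(config$season_start, config$season_end,
               by = g$sample_interval_days)
  doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
  trees <- paste0("tree", seq_len(g$n_trees))

  truth <- data.frame(
    tree_id = trees,
    A = g$total$A * pmax(0.3, stats::rnorm(g$n_trees, 1, g$tree_A_sd_frac)),
    kappa_total = g$total$kappa, t_mid_total = g$total$t_mid,
    kappa_mature = g$mature$kappa, t_mid_mature = g$mature$t_mid,
    prev_ring_width_mm = pmax(0.3, stats::rnorm(g$n_trees,
                                                g$ring_width_mean,
                                                g$ring_width_sd)))
  out <- do.call(rbind, lapply(seq_len(g$n_trees), function(i) {
    tr <- truth[i, ]
    w <- tr$prev_ring_width_mm
    tot <- gompertz(doy, tr$A, exp(tr$kappa_total * tr$t_mid_total),
                    tr$kappa_total) * w
    mat <- gompertz(doy, tr$A, exp(tr$kappa_mature * tr$t_mid_mature),
                    tr$kappa_mature) * w
    sd <- g$count_noise_frac * tr$A * w
    tot_obs <- pmax(0, tot + stats::rnorm(length(doy), sd = sd))
    mat_obs <- pmax(0, pmin(tot_obs, mat + stats::rnorm(length(doy),
                                                        sd = sd)))
    ab <- tot_obs - mat_obs
    rate <- gompertz_rate(doy, tr$A, exp(tr$kappa_total * tr$t_mid_total),
                          tr$kappa_total)
    a_share <- 0.2 + 0.6 * rate / max(rate)
    data.frame(tree_id = tr$tree_id, date = dates, doy = doy,
               n_a = ab * a_share, n_b = ab * (1 - a_share), n_c = mat_obs,
               n_total = tot_obs, prev_ring_width_mm = w)
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate daily fibrous-root elongation per scanner
#'
#' Each scanner expresses the configured pulse windows (raised-cosine
#' pulses) with multiplicative lognormal noise; elongation is non-negative
#' and exactly zero outside all pulses of a scanner.
#'
#' @param env an `environment_series` (defines the daily grid).
#' @param config a [sim_config()] object.
#' @return data.frame `scanner_id`, `date`, `elongation_mm`.
#' @export
simulate_root_growth <- function(env, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "roots"))
  days <- sort(unique(as.Date(env$time, tz = "UTC")))
  out <- do.call(rbind, lapply(names(config$roots$scanners), function(sc) {
    pulses <- config$roots$scanners[[sc]]$pulses
    base <- rowSums(vapply(pulses, function(p) {
      pulse_template(days, as.Date(p$start), as.Date(p$end), p$amp)
    }, numeric(length(days))))
    noise <- exp(stats::rnorm(length(days),
                              sd = config$roots$noise_sd_log))
    data.frame(scanner_id = sc, date = days,
               elongation_mm = pmax(0, base * noise))
  }))
  rownames(out) <- NULL
  out
}
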