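#' Simulate seasonal non-structural carbohydrate series
#'
#' Generates phloem (sucrose, glucose, fructose, starch and their sum WSC)
#' and root (WSC, starch) concentration and delta13C observations for
#' replicate trees/spots per sampling date. Templates are piecewise-linear
#' seasonal anchors: phloem starch depletes sharply across the
#' earlywood-latewood transition while sucrose rises (starch
#' re-mobilization); WSC equals the sum of the sugar pools at every date by
#' construction; delta13C of starch is more stable than that of the
#' transport sugars.
#'
#' @param config a [sim_config()] object.
#' @return data.frame `organ` ("phloem"/"root"), `compound`, `date`,
#'   `replicate`, `conc_mg_g`, `d13C_permil`.
#' @export
simulate_nsc_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$nsc
  set.seed(stage_seed(config, "nsc"))

  template <- function(anchors, doy) {
    stats::approx(anchors$doy, anchors$val, xout = doy, rule = 2)$y
  }
  season_wave <- function(doy, amp) {
    amp * sin(2 * pi * (doy - 150) / 200)
  }

  gen <- function(organ, compounds, dates, n_rep) {
    doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
    rows <- list()
    for (cp in names(compounds)) {
      conc0 <- compounds[[cp]]$conc(doy)
      d0 <- compounds[[cp]]$delta(doy)
      dsd <- compounds[[cp]]$delta_sd
      for (r in seq_len(n_rep)) {
        conc <- pmax(0.5, conc0 * (1 + stats::rnorm(length(doy),
                                                    sd = n$conc_noise_frac)))
        d13 <- d0 + stats::rnorm(length(doy), sd = dsd)
        rows[[length(rows) + 1]] <- data.frame(
          organ = organ, compound = cp, date = dates, replicate = r,
          conc_mg_g = conc, d13C_permil = d13)
      }
    }
    do.call(rbind, rows)
  }

  dl <- n$delta
  phloem_compounds <- list(
    sucrose = list(conc = function(d) template(n$phloem$sucrose, d),
                   delta = function(d) dl$sucrose + season_wave(d,
                                                                dl$sugar_amp),
                   delta_sd = n$delta_noise_sd),
    glucose = list(conc = function(d) template(n$phloem$glucose, d),
                   delta = function(d) dl$glucose + season_wave(d,
                                                                dl$sugar_amp),
                   delta_sd = n$delta_noise_sd),
    fructose = list(conc = function(d) template(n$phloem$fructose, d),
                    delta = function(d) dl$fructose +
                      season_wave(d, dl$sugar_amp),
                    delta_sd = n$delta_noise_sd),
    starch = list(conc = function(d) template(n$phloem$starch, d),
                  delta = function(d) dl$starch + season_wave(d,
                                                              dl$starch_amp),
                  delta_sd = n$starch_delta_noise_sd))
  phloem <- gen("phloem", phloem_compounds, n$phloem_dates, n$n_phloem_trees)

  root_compounds <- list(
    wsc = list(conc = function(d) template(n$root$wsc, d),
               delta = function(d) dl$root_wsc + season_wave(d, dl$root_amp),
               delta_sd = n$delta_noise_sd),
    starch = list(conc = function(d) template(n$root$starch, d),
                  delta = function(d) dl$root_wsc - 0.5 +
                    season_wave(d, dl$starch_amp),
                  delta_sd = n$starch_delta_noise_sd))
  root <- gen("root", root_compounds, n$root_dates, n$n_root_spots)

  out <- rbind(phloem, root)
  # phloem WSC = sum of the sugar pools per replicate and date
  sug <- out[out$organ == "phloem" &
               out$compound %in% c("sucrose", "glucose", "fructose"), ]
  wsc <- stats::aggregate(sug["conc_mg_g"],
                          by = sug[c("date", "replicate")], FUN = sum)
  dmix <- stats::aggregate(
    list(d13C_permil = sug$conc_mg_g * sug$d13C_permil),
    by = sug[c("date", "replicate")], FUN = sum)
  wsc$d13C_permil <- dmix$d13C_permil / wsc$conc_mg_g
  wsc$organ <- "phloem"; wsc$compound <- "wsc"
  out <- rbind(out, wsc[, names(out)])
  rownames(out) <- NULL
  out[order(out$organ, out$compound, out$date, out$replicate), ]
}
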