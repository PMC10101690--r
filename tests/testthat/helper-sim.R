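# shared fixtures built in code

# noise-free simulation config (short of analyzer noise only)
quiet_config <- function(seed = 1, ...) {
  sim_config(seed = seed, analyzer = list(c12_sd_ppm = 0, c13_sd_ppm = 0),
             ...)
}

# build a single synthetic closure record from the analytic forward model
make_closure <- function(flux, delta = -26, chamber = "soil",
                         volume_l = 80, area_m2 = 0.4, q = 0.001,
                         duration_s = 300, c_amb = 400, delta_amb = -8.5,
                         temp_C = 15, noise12 = 0, noise13 = 0,
                         par = NA_real_, id = 1L) {
  t <- 0:duration_s
  dir <- if (chamber == "shoot") -1 else 1
  fx <- carboniso:::split_isotopologues(dir * flux, delta)
  ca <- carboniso:::split_isotopologues(c_amb, delta_amb)
  c12 <- chamber_trace(t, fx$c12, area_m2, volume_l, q, ca$c12, temp_C)
  c13 <- chamber_trace(t, fx$c13, area_m2, volume_l, q, ca$c13, temp_C)
  if (noise12 > 0) c12 <- c12 + rnorm(length(t), sd = noise12)
  if (noise13 > 0) c13 <- c13 + rnorm(length(t), sd = noise13)
  list(closure_id = id, chamber = chamber, start = as.POSIXct(NA),
       PAR = par, volume_l = volume_l, area_m2 = area_m2, temp_C = temp_C,
       time_s = t, c12 = c12, c13 = c13)
}

# daily series wrapper
daily <- function(values, start = as.Date("2018-05-01")) {
  s <- list(date = start + seq_along(values) - 1, value = values,
            gap_mask = rep(FALSE, length(values)), gap_fraction = 0)
  class(s) <- "daily_series"
  s
}
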