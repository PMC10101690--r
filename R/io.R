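#' Plain-CSV readers and writers for the pipeline table dialects
#'
#' All pipeline tables are plain CSV with fixed, documented headers:
#' closures (`closure_id, chamber, start, PAR, volume_l, area_m2, temp_C,
#' time_s, c12_ppm, c13_ppm` split over an info and a trace file),
#' environment (`timestamp, air_T, soil_T, PAR, soil_moisture, precip`),
#' tracheids (`tree_id, date, n_a, n_b, n_c, n_total, prev_ring_width_mm`),
#' NSC (`organ, compound, date, replicate, conc_mg_g, d13C_permil`) and
#' roots (`scanner_id, date, elongation_mm`).
#'
#' @param set,env,obs,nsc,roots objects produced by the `simulate_*()`
#'   generators (or equivalent user tables in the same dialect).
#' @param path,info_path,traces_path file paths.
#' @return readers return the corresponding object; writers return the path
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_closures_csv <- function(set, info_path, traces_path) {
  info <- set$info
  info$start <- format(info$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(info, info_path, row.names = FALSE)
  utils::write.csv(set$traces, traces_path, row.names = FALSE)
  invisible(c(info_path, traces_path))
}

#' @rdname pipeline_io
#' @export
read_closures_csv <- function(info_path, traces_path) {
  info <- utils::read.csv(info_path)
  info$start <- as.POSIXct(info$start, format = "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC")
  out <- list(info = info, traces = utils::read.csv(traces_path))
  class(out) <- "closure_set"
  out
}

#' @rdname pipeline_io
#' @export
write_env_csv <- function(env, path) {
  out <- data.frame(timestamp = format(env$time, "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"),
                    air_T = env$air_T, soil_T = env$soil_T, PAR = env$PAR,
                    soil_moisture = env$soil_moisture, precip = env$precip)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_env_csv <- function(path) {
  x <- utils::read.csv(path)
  out <- data.frame(time = as.POSIXct(x$timestamp,
                                      format = "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC"),
                    air_T = x$air_T, soil_T = x$soil_T, PAR = x$PAR,
                    soil_moisture = x$soil_moisture, precip = x$precip)
  out$doy <- as.integer(strftime(out$time, "%j", tz = "UTC"))
  class(out) <- c("environment_series", "data.frame")
  out
}

#' @rdname pipeline_io
#' @export
write_tracheids_csv <- function(obs, path) {
  utils::write.csv(obs[c("tree_id", "date", "n_a", "n_b", "n_c", "n_total",
                         "prev_ring_width_mm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tracheids_csv <- function(path) {
  x <- utils::read.csv(path)
  x$date <- as.Date(x$date)
  x$doy <- as.integer(strftime(x$date, "%j", tz = "UTC"))
  x
}

#' @rdname pipeline_io
#' @export
write_nsc_csv <- function(nsc, path) {
  utils::write.csv(nsc[c("organ", "compound", "date", "replicate",
                         "conc_mg_g", "d13C_permil")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_nsc_csv <- function(path) {
  x <- utils::read.csv(path)
  x$date <- as.Date(x$date)
  x
}

#' @rdname pipeline_io
#' @export
write_roots_csv <- function(roots, path) {
  utils::write.csv(roots[c("scanner_id", "date", "elongation_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_roots_csv <- function(path) {
  x <- utils::read.csv(path)
  x$date <- as.Date(x$date)
  x
}
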