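#' Exponential temperature response of nighttime stem efflux
#'
#' Fits R = a * exp(b * T) by nonlinear least squares
#' ([minpack.lm::nlsLM()]), initialized in log space when all fluxes are
#' positive and from quartile ratios otherwise. The residual series
#' (observed - fitted) is the temperature-detrended efflux used in the
#' association models; the implied Q10 is exp(10 b).
#'
#' @param flux daily (nighttime mean) efflux, umol m-2 s-1.
#' @param temp paired nightly mean temperature, degC.
#' @return list of class `exp_fit`: `a`, `b`, `fitted`, `residuals`, `r2`,
#'   `q10`, `n`.
#' @export
fit_exponential_temperature <- function(flux, temp) {
  ok <- is.finite(flux) & is.finite(temp)
  flux <- flux[ok]; temp <- temp[ok]
  if (length(flux) < 10) {
    stop("need at least 10 paired days for the exponential fit",
         call. = FALSE)
  }
  if (all(flux > 0)) {
    lf <- stats::lm(log(flux) ~ temp)
    st <- list(a = exp(unname(stats::coef(lf)[1])),
               b = unname(stats::coef(lf)[2]))
  } else {
    lo <- temp <= stats::median(temp)
    r_lo <- stats::median(flux[lo]); r_hi <- stats::median(flux[!lo])
    t_lo <- stats::median(temp[lo]); t_hi <- stats::median(temp[!lo])
    b0 <- if (r_lo > 0 && r_hi > 0 && t_hi > t_lo)
      log(r_hi / r_lo) / (t_hi - t_lo) else 0.07
    st <- list(a = max(1e-6, stats::median(flux)) / exp(b0 *
                                                          stats::median(temp)),
               b = b0)
  }
  fit <- minpack.lm::nlsLM(flux ~ a * exp(b * temp), start = st,
                           control = minpack.lm::nls.lm.control(maxiter =
                                                                  200))
  a <- unname(stats::coef(fit)["a"]); b <- unname(stats::coef(fit)["b"])
  fitted <- a * exp(b * temp)
  res <- flux - fitted
  out <- list(a = a, b = b, fitted = fitted, residuals = res,
              r2 = 1 - sum(res^2) / sum((flux - mean(flux))^2),
              q10 = exp(10 * b), n = length(flux))
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> a =", signif(x$a, 4), " b =", signif(x$b, 4),
      " Q10 =", signif(x$q10, 4), " R2 =", signif(x$r2, 3), "\n")
  invisible(x)
}

#' Shift a daily response series to account for a lagged response
#'
#' Aligns a response so that the predictor on day t pairs with the response
#' on day t + `lag_days` (stem efflux lags stem growth by one day in the
#' modelled system); the unmatched boundary days are dropped.
#'
#' @param x data.frame with columns `date` and `value`, on a daily grid.
#' @param lag_days non-negative integer lag.
#' @return data.frame `date`, `value` where `value[date]` is the original
#'   response at `date + lag_days`.
#' @export
lag_shift <- function(x, lag_days = 1) {
  stopifnot(is.data.frame(x), all(c("date", "value") %in% names(x)))
  lag_days <- as.integer(lag_days)
  n <- nrow(x)
  if (lag_days < 0) stop("lag_days must be >= 0", call. = FALSE)
  if (lag_days >= n) {
    stop("lag (", lag_days, " d) is not shorter than the series (", n,
         " d)", call. = FALSE)
  }
  if (lag_days == 0) return(x)
  data.frame(date = x$date[seq_len(n - lag_days)],
             value = x$value[(1 + lag_days):n])
}

#' Residuals of a response regressed on soil temperature and moisture
#'
#' Additive linear regression of a daily response on soil temperature and
#' soil moisture; the residuals carry the environmental-detrended signal.
#'
#' @param response daily response values.
#' @param soil_T,soil_moisture aligned daily drivers.
#' @return list of class `env_regression`: `residuals`, `fitted`, `model`
#'   (the `lm` fit), `r2`.
#' @export
fit_env_regression <- function(response, soil_T, soil_moisture) {
  stopifnot(length(response) == length(soil_T),
            length(response) == length(soil_moisture))
  if (abs(stats::cor(soil_T, soil_moisture)) > 0.999) {
    warning("soil temperature and moisture are collinear (|r| > 0.999)")
  }
  fit <- stats::lm(response ~ soil_T + soil_moisture)
  list(residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)), model = fit,
       r2 = summary(fit)$r.squared) |>
    structure(class = "env_regression")
}

#' Linear mixed-effects association model with a per-tree random intercept
#'
#' Fits `response ~ predictor + doy` with a random intercept per tree by
#' maximum likelihood ([nlme::lme()]). Day of year enters as a covariate and
#' is removed when not significant (p >= `drop_p`), following the covariate
#' rule of the modelled analyses. On a singular or non-converging fit the
#' model falls back to an ordinary linear model and the result is noted.
#'
#' @param data data.frame with the model columns.
#' @param response,predictor,doy,tree column names.
#' @param drop_p significance threshold for dropping the DOY covariate.
#' @return list of class `assoc_model`: `kind` ("lmm" or "lm fallback"),
#'   `terms` (data.frame term/estimate/p/sign), `doy_included`, `r2`
#'   (marginal and conditional for the mixed model), `n`, `df`, `note`.
#' @export
fit_lmm <- function(data, response, predictor, doy = "doy",
                    tree = "tree_id", drop_p = 0.05) {
  d <- data.frame(y = data[[response]], x = data[[predictor]],
                  doy = data[[doy]], tree = factor(data[[tree]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$tree)) < 2) {
    stop("mixed model needs at least two trees", call. = FALSE)
  }
  run <- function(formula) {
    nlme::lme(formula, random = ~ 1 | tree, data = d, method = "ML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
  }
  note <- NA_character_
  fit <- tryCatch(run(y ~ x + doy), error = function(e) e)
  if (inherits(fit, "error")) {
    note <- paste("lme failed, plain linear fallback:",
                  conditionMessage(fit))
    res <- fit_lm(data, response, predictor, doy = doy, drop_p = drop_p)
    res$kind <- "lm_fallback"; res$note <- note
    return(res)
  }
  tt <- summary(fit)$tTable
  doy_included <- TRUE
  if (tt["doy", "p-value"] >= drop_p) {
    doy_included <- FALSE
    fit <- run(y ~ x)
    tt <- summary(fit)$tTable
  }
  # variance-partition R2: marginal (fixed) and conditional (fixed + random)
  vf <- stats::var(as.numeric(stats::fitted(fit, level = 0)))
  vr <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"])
  ve <- fit$sigma^2
  terms <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      p = tt[, "p-value"],
                      sign = ifelse(tt[, "Value"] >= 0, "+", "-"),
                      row.names = NULL)
  out <- list(kind = "lmm", terms = terms, doy_included = doy_included,
              r2 = c(marginal = vf / (vf + vr + ve),
                     conditional = (vf + vr) / (vf + vr + ve)),
              n = nrow(d), df = unname(tt["x", "DF"]), note = note,
              fit = fit)
  class(out) <- "assoc_model"
  out
}

#' Ordinary linear association model on stand averages
#'
#' Fits `response ~ predictor` (plus optional DOY with the same
#' drop-if-not-significant rule) by OLS on per-date averages, supporting an
#' exclusion-dates argument for dates where starch re-mobilization blurs the
#' isotopic signal.
#'
#' @param data data.frame with the model columns (and a `date` column when
#'   `exclude_dates` is used).
#' @param response,predictor column names.
#' @param doy optional DOY column name (NULL to omit).
#' @param exclude_dates Dates removed from the design before fitting.
#' @param drop_p threshold for dropping the DOY covariate.
#' @return `assoc_model` list as in [fit_lmm()] with a single `r2`.
#' @export
fit_lm <- function(data, response, predictor, doy = NULL,
                   exclude_dates = NULL, drop_p = 0.05) {
  if (length(exclude_dates) > 0) {
    data <- data[!(as.Date(data$date) %in%
                     as.Date(unlist(exclude_dates))), , drop = FALSE]
  }
  d <- data.frame(y = data[[response]], x = data[[predictor]])
  if (!is.null(doy)) d$doy <- data[[doy]]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) <= ncol(d)) {
    stop("too few observations (n = ", nrow(d), ") for ", ncol(d) - 1,
         " predictor(s)", call. = FALSE)
  }
  doy_included <- FALSE
  if (!is.null(doy)) {
    fit <- stats::lm(y ~ x + doy, data = d)
    p_doy <- summary(fit)$coefficients["doy", 4]
    if (p_doy < drop_p) doy_included <- TRUE
  }
  if (!doy_included) fit <- stats::lm(y ~ x, data = d)
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), estimate = sm[, 1], p = sm[, 4],
                      sign = ifelse(sm[, 1] >= 0, "+", "-"),
                      row.names = NULL)
  out <- list(kind = "lm", terms = terms, doy_included = doy_included,
              r2 = summary(fit)$r.squared, n = nrow(d),
              df = fit$df.residual, note = NA_character_, fit = fit)
  class(out) <- "assoc_model"
  out
}

#' @export
print.assoc_model <- function(x, ...) {
  cat("<assoc_model>", x$kind, "| n =", x$n, "| df =", x$df,
      "| DOY included:", x$doy_included, "\n")
  print(x$terms, digits = 3)
  cat("R2:", paste(signif(x$r2, 3), collapse = " / "), "\n")
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Extract the predictor's p-value and sign from an association model
#'
#' @param model an `assoc_model`.
#' @return named list with `p`, `estimate`, `sign` for the `x` term.
#' @export
predictor_test <- function(model) {
  row <- model$terms[model$terms$term == "x", ]
  list(p = row$p, estimate = row$estimate, sign = row$sign)
}
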