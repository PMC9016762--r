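# Growth kinetics: GV->OD calibration, smoothing-spline growth-curve fits,
# lag-phase geometry, and the no-growth QC rule.

#' Calibration model for plate-reader signals
#'
#' Holds the constants of the green-value (GV) to OD600 conversion and the
#' per-strain cell-dry-weight (CDW) calibration slopes. The default constants
#' are the published Growth Profiler calibration for Delft medium
#' (a = 0.019, b = 1, c = 3.82e-6, d = 2.66, e = 3.111e-22, f = 10.5,
#' GV_blank = 26.3). The functional form used by [gv_to_od()] is
#' \deqn{OD = a (GV - GV_{blank})^b + c (GV - GV_{blank})^d + e (GV - GV_{blank})^f}
#' i.e. a dominant linear term plus two power-law corrections; a different
#' callable can be plugged in via `od_fun` if an instrument uses another form.
#'
#' @param a,b,c,d,e,f Dimensionless calibration constants.
#' @param gv_blank Blank (medium-only) green value; must be > 0.
#' @param cdw_slopes Named numeric vector: g dry weight per liter per OD
#'   unit, one entry per strain.
#' @param od_fun Optional replacement conversion `function(delta_gv, cal)`
#'   evaluated on `GV - gv_blank`.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(a = 0.019, b = 1, c = 3.82e-6, d = 2.66,
                              e = 3.111e-22, f = 10.5, gv_blank = 26.3,
                              cdw_slopes = NULL, od_fun = NULL) {
  consts <- c(a = a, b = b, c = c, d = d, e = e, f = f, gv_blank = gv_blank)
  if (anyNA(consts)) {
    stop("missing calibration constant(s): ",
         paste(names(consts)[is.na(consts)], collapse = ", "))
  }
  if (gv_blank <= 0) stop("gv_blank must be positive")
  if (!is.null(cdw_slopes)) {
    if (is.null(names(cdw_slopes)) || any(names(cdw_slopes) == "")) {
      stop("cdw_slopes must be a named vector (strain -> g/L per OD)")
    }
    if (any(cdw_slopes <= 0)) stop("cdw_slopes must be positive")
  }
  structure(
    list(a = a, b = b, c = c, d = d, e = e, f = f, gv_blank = gv_blank,
         cdw_slopes = cdw_slopes, od_fun = od_fun),
    class = "calibration_model"
  )
}

#' Convert green values to OD600
#'
#' Values below the blank clamp to OD 0 with a warning. The conversion is
#' continuous, equals 0 at the blank, and is monotone nondecreasing.
#'
#' @param gv Numeric vector of green values.
#' @param cal A [calibration_model()].
#' @return OD600 values, same length as `gv`.
#' @export
gv_to_od <- function(gv, cal = calibration_model()) {
  stopifnot(inherits(cal, "calibration_model"))
  delta <- gv - cal$gv_blank
  below <- delta < 0
  if (any(below, na.rm = TRUE)) {
    warning(sum(below, na.rm = TRUE),
            " green value(s) below the blank; clamped to OD 0")
    delta[below] <- 0
  }
  if (!is.null(cal$od_fun)) return(cal$od_fun(delta, cal))
  cal$a * delta^cal$b + cal$c * delta^cal$d + cal$e * delta^cal$f
}

#' Fit a growth curve to one well
#'
#' Fits a cubic smoothing spline (smoothness chosen by generalized
#' cross-validation unless `spar` is given) to the natural log of the signal
#' against time. The maximum specific growth rate is the maximum of the
#' spline's first derivative, located on a dense grid (`dense_factor` times
#' the input resolution, ties broken by the earliest time); the inflection
#' point is where that maximum occurs; `y0` is the spline value at the first
#' timepoint; `r_squared` is the coefficient of determination of the spline
#' against the log data.
#'
#' For GV signals pass `blank` (typically the calibration `gv_blank`) so the
#' background is removed before the log transform: the log-slope of the
#' blank-corrected signal is invariant to the roughly linear GV/OD scaling
#' over the growth range, so growth parameters are fitted on GV-derived
#' curves directly.
#'
#' @param ts A [ts_well()].
#' @param blank Background signal subtracted before the log transform
#'   (default 0; use the GV blank for GV signals).
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()]; NULL selects it by GCV.
#' @param dense_factor Derivative-grid refinement relative to the input
#'   sampling (>= 10 recommended).
#' @return An object of class `growth_fit` with fields `mu_max` (1/h), `lag`
#'   (h, NA until [compute_lag()] or if not grown), `r_squared`, `y0`,
#'   `inflection_time`, `inflection_value`, `grew`, plus the well identity.
#' @export
fit_growth_curve <- function(ts, blank = 0, spar = NULL, dense_factor = 10) {
  stopifnot(inherits(ts, "ts_well"))
  v <- ts$values - blank
  if (length(v) < 4L) stop("need at least 4 readings (well ", ts$well_id, ")")
  if (length(unique(ts$values)) == 1L) {
    return(new_growth_fit(ts, mu_max = 0, lag = NA_real_, r_squared = 0,
                          y0 = if (v[1] > 0) log(v[1]) else NA_real_,
                          inflection_time = NA_real_,
                          inflection_value = NA_real_, grew = FALSE))
  }
  if (any(v <= 0)) {
    stop("nonpositive signal after blank correction in well ", ts$well_id,
         "; cannot log-transform")
  }
  y <- log(v)
  fit <- if (is.null(spar)) {
    stats::smooth.spline(ts$times, y)
  } else {
    stats::smooth.spline(ts$times, y, spar = spar)
  }
  fitted_y <- stats::predict(fit, ts$times)$y
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  grid <- seq(min(ts$times), max(ts$times),
              length.out = max(dense_factor * length(ts$times), 100L))
  d1 <- stats::predict(fit, grid, deriv = 1)$y
  imax <- which.max(d1)  # ties: earliest time
  mu_max <- d1[imax]
  if (!is.finite(mu_max) || mu_max <= 0) {
    return(new_growth_fit(ts, mu_max = 0, lag = NA_real_, r_squared = r2,
                          y0 = fitted_y[1], inflection_time = NA_real_,
                          inflection_value = NA_real_, grew = FALSE))
  }
  t_inf <- grid[imax]
  v_inf <- stats::predict(fit, t_inf)$y
  new_growth_fit(ts, mu_max = mu_max, lag = NA_real_, r_squared = r2,
                 y0 = fitted_y[1], inflection_time = t_inf,
                 inflection_value = v_inf, grew = TRUE)
}

new_growth_fit <- function(ts, mu_max, lag, r_squared, y0, inflection_time,
                           inflection_value, grew) {
  structure(
    list(well_id = ts$well_id, strain = ts$strain,
         condition_id = ts$condition_id, replicate = ts$replicate,
         is_control = ts$is_control, mu_max = mu_max, lag = lag,
         r_squared = r_squared, y0 = y0, inflection_time = inflection_time,
         inflection_value = inflection_value, grew = grew),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit %s  mu_max=%.4f 1/h  lag=%s h  R2=%.4f  grew=%s>\n",
    x$well_id, x$mu_max,
    if (is.na(x$lag)) "NA" else sprintf("%.2f", x$lag),
    x$r_squared, x$grew))
  invisible(x)
}

#' Lag phase from the tangent construction
#'
#' The lag is the x coordinate of the intersection between the line of slope
#' `mu_max` through the inflection point of the log-signal curve and the
#' horizontal line through `y0`:
#' \deqn{\lambda = t_{inf} - (y_{inf} - y_0)/\mu_{max}}
#' Negative results (inflection tangent crossing left of t = 0) clamp to 0
#' with a warning, since a lag phase is physically nonnegative. Wells that
#' did not grow get a missing lag.
#'
#' @param fit A `growth_fit`.
#' @return The fit with its `lag` field set (hours, or NA).
#' @export
compute_lag <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$grew || fit$mu_max <= 0) {
    fit$lag <- NA_real_
    return(fit)
  }
  lag <- fit$inflection_time - (fit$inflection_value - fit$y0) / fit$mu_max
  if (lag < 0) {
    warning("negative lag (", signif(lag, 3), " h) clamped to 0 in well ",
            fit$well_id)
    lag <- 0
  }
  fit$lag <- lag
  fit
}

#' No-growth quality-control rule
#'
#' Wells whose spline fit explains the log data poorly are treated as not
#' grown: if `r_squared < r2_threshold` (default 0.99, strict inequality)
#' then `mu_max` is set to 0, the lag to NA and `grew` to FALSE; otherwise
#' the fit is returned unchanged. The rule is idempotent.
#'
#' @param fit A `growth_fit`.
#' @param r2_threshold Threshold in (0, 1].
#' @return The (possibly zeroed) `growth_fit`.
#' @export
apply_qc <- function(fit, r2_threshold = 0.99) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must be a single number in (0, 1]")
  }
  if (fit$r_squared < r2_threshold) {
    fit$mu_max <- 0
    fit$lag <- NA_real_
    fit$grew <- FALSE
  }
  fit
}

#' Fit, QC and lag-annotate every well of a plate
#'
#' Convenience wrapper chaining [fit_growth_curve()], [apply_qc()] and
#' [compute_lag()] over a collection of wells.
#'
#' @param wells A list of [ts_well()] objects (e.g. from
#'   [read_timeseries()]).
#' @param cal A [calibration_model()]; its `gv_blank` is used as the blank
#'   for GV signals (OD signals use blank 0).
#' @param r2_threshold QC threshold forwarded to [apply_qc()].
#' @param spar,dense_factor Forwarded to [fit_growth_curve()].
#' @return A data frame with one row per well: identity columns, `mu_max`,
#'   `lag`, `r_squared`, `y0`, `inflection_time`, `inflection_value`,
#'   `grew`.
#' @export
fit_plate <- function(wells, cal = calibration_model(), r2_threshold = 0.99,
                      spar = NULL, dense_factor = 10) {
  fits <- lapply(wells, function(w) {
    blank <- if (w$signal_kind == "GV") cal$gv_blank else 0
    f <- fit_growth_curve(w, blank = blank, spar = spar,
                          dense_factor = dense_factor)
    f <- apply_qc(f, r2_threshold)
    compute_lag(f)
  })
  do.call(rbind, lapply(fits, function(f) {
    data.frame(well_id = f$well_id, strain = f$strain,
               condition_id = f$condition_id, replicate = f$replicate,
               is_control = f$is_control, mu_max = f$mu_max, lag = f$lag,
               r_squared = f$r_squared, y0 = f$y0,
               inflection_time = f$inflection_time,
               inflection_value = f$inflection_value, grew = f$grew,
               stringsAsFactors = FALSE)
  }))
}
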