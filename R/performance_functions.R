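# Performance functions: the five cellular functions measured per well
# (mu_max, lag, CDW, biomass yield, ethanol yield) and assembly of the tidy
# function table that robustness scoring consumes.

# Registry of known functions and their units; extensible at run time so
# other readouts (biosensor signals, reporter expression, ...) can enter the
# same robustness machinery.
.function_registry <- new.env(parent = emptyenv())

#' Register an additional cellular function
#'
#' Built-in functions are mu_max (1/h), lag (h), cdw (g/L), biomass_yield
#' (g/g) and ethanol_yield (g/g). Additional readouts measured per well can
#' be registered so they flow through the same function table and robustness
#' metrics.
#'
#' @param name Function identifier (snake_case).
#' @param units Unit string, for documentation of outputs.
#' @return Invisibly, the registry as a named character vector.
#' @export
register_function <- function(name, units) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assign(name, units, envir = .function_registry)
  invisible(known_functions())
}

#' List the registered cellular functions and units
#' @return Named character vector (name -> units).
#' @export
known_functions <- function() {
  extra <- mget(ls(.function_registry), envir = .function_registry)
  c(FUNCTION_UNITS, unlist(extra))
}

#' Total consumed sugars for one well
#'
#' Sum over the measured sugars of max(initial - final, 0) in g/L. A final
#' concentration above its initial contributes 0 with a warning.
#'
#' @param row One row of an endpoint table (list or single-row data frame).
#' @return Consumed sugars in g/L.
#' @export
consumed_sugars <- function(row) {
  initials <- vapply(SUGARS, function(s) as.numeric(row[[paste0(s, "_initial")]]),
                     numeric(1))
  finals <- vapply(SUGARS, function(s) as.numeric(row[[paste0(s, "_final")]]),
                   numeric(1))
  if (all(initials == 0, na.rm = TRUE)) {
    stop("all initial sugar concentrations are zero: no substrate defined",
         if (!is.null(row[["well_id"]])) paste0(" (well ", row[["well_id"]], ")"))
  }
  diffs <- initials - finals
  neg <- which(diffs < 0)
  if (length(neg) > 0L) {
    warning("final exceeds initial for ", paste(SUGARS[neg], collapse = ", "),
            "; contribution set to 0")
    diffs[neg] <- 0
  }
  sum(diffs)
}

#' Ethanol yield on consumed sugars
#'
#' Grams of ethanol produced per gram of total consumed sugars. Undefined
#' (NA with a warning) when nothing was consumed.
#'
#' @param ethanol_produced Ethanol at the endpoint, g/L.
#' @param consumed Total consumed sugars, g/L.
#' @return Yield in g/g, or NA.
#' @export
ethanol_yield <- function(ethanol_produced, consumed) {
  if (is.na(consumed) || consumed <= 0) {
    warning("consumed sugars <= 0; ethanol yield undefined")
    return(NA_real_)
  }
  ethanol_produced / consumed
}

#' Biomass yield on consumed sugars
#'
#' Grams of cell dry weight produced per gram of total consumed sugars:
#' (final CDW - initial CDW) / consumed. A negative difference floors at 0
#' with a warning.
#'
#' @param cdw_final,cdw_initial Cell dry weight, g/L.
#' @param consumed Total consumed sugars, g/L.
#' @return Yield in g/g, or NA.
#' @export
biomass_yield <- function(cdw_final, cdw_initial, consumed) {
  if (is.na(consumed) || consumed <= 0) {
    warning("consumed sugars <= 0; biomass yield undefined")
    return(NA_real_)
  }
  dy <- cdw_final - cdw_initial
  if (!is.na(dy) && dy < 0) {
    warning("final CDW below initial; biomass yield floored at 0")
    dy <- 0
  }
  dy / consumed
}

#' Cell dry weight from OD600
#'
#' Linear per-strain calibration: CDW = OD x slope, with the slope from
#' gravimetric calibration curves.
#'
#' @param od OD600 (>= 0).
#' @param strain Strain name, looked up in `cal$cdw_slopes`.
#' @param cal A [calibration_model()] carrying `cdw_slopes`.
#' @return CDW in g/L.
#' @export
cdw_from_od <- function(od, strain, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (is.null(cal$cdw_slopes)) stop("calibration model has no cdw_slopes")
  if (!strain %in% names(cal$cdw_slopes)) {
    stop("no CDW slope for strain: ", strain)
  }
  slope <- cal$cdw_slopes[[strain]]
  if (any(od < 0, na.rm = TRUE)) stop("OD must be nonnegative")
  od * slope
}

#' Assemble the tidy function table
#'
#' Combines growth fits and endpoint measurements into one record per
#' (strain, function, condition, replicate): mu_max and lag from the fits;
#' CDW from the 48-h OD via the strain slope; biomass and ethanol yields
#' from consumed sugars. Lag is missing where the well did not grow. Wells
#' with fits but no endpoint row contribute mu_max and lag only, with a
#' warning. The initial CDW subtracted in the biomass yield is the
#' inoculation density (`inoculum_od` x strain slope) unless
#' `subtract_inoculum` is FALSE.
#'
#' @param fits Data frame from [fit_plate()].
#' @param endpoints An `endpoint_table` (or NULL for growth functions only).
#' @param layout A `plate_layout` resolving well identity (fits already
#'   carry identity; the layout is used to check coverage).
#' @param cal A [calibration_model()] with `cdw_slopes`.
#' @param inoculum_od Starting OD600 of the cultures (default 0.02).
#' @param subtract_inoculum Subtract the inoculum biomass in the yield
#'   (default TRUE).
#' @param min_consumed Consumption floor in g/L below which yields are
#'   recorded as missing (default 0.5). Enzymatic sugar assays carry noise
#'   of roughly 0.1 g/L, so a ratio over a smaller consumption is dominated
#'   by measurement error (non-growing wells would otherwise produce
#'   arbitrarily large apparent yields).
#' @return A `function_table` data frame with columns strain, fun,
#'   condition_id, replicate, value. An attribute `n_missing` counts missing
#'   values per function.
#' @export
assemble_function_table <- function(fits, endpoints, layout, cal,
                                    inoculum_od = 0.02,
                                    subtract_inoculum = TRUE,
                                    min_consumed = 0.5) {
  if (is.null(fits) || nrow(fits) == 0L) {
    out <- data.frame(strain = character(0), fun = character(0),
                      condition_id = character(0), replicate = integer(0),
                      value = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("function_table", "data.frame")
    return(out)
  }
  layout <- validate_layout(layout)
  missing_layout <- setdiff(fits$well_id, layout$well_id)
  if (length(missing_layout) > 0L) {
    stop("fitted wells absent from layout: ",
         paste(missing_layout, collapse = ", "))
  }
  ep_by_well <- NULL
  if (!is.null(endpoints) && nrow(endpoints) > 0L) {
    ep_by_well <- split(endpoints, endpoints$well_id)
  }
  rows <- vector("list", nrow(fits))
  no_endpoint <- character(0)
  for (i in seq_len(nrow(fits))) {
    f <- fits[i, ]
    rec <- function(fun, value) {
      data.frame(strain = f$strain, fun = fun, condition_id = f$condition_id,
                 replicate = f$replicate, value = value,
                 stringsAsFactors = FALSE)
    }
    out <- list(rec("mu_max", f$mu_max), rec("lag", f$lag))
    ep <- if (!is.null(ep_by_well)) ep_by_well[[f$well_id]] else NULL
    if (is.null(ep)) {
      no_endpoint <- c(no_endpoint, f$well_id)
    } else {
      cdw_final <- cdw_from_od(ep$od600_48h, f$strain, cal)
      cdw_init <- if (subtract_inoculum) {
        cdw_from_od(inoculum_od, f$strain, cal)
      } else 0
      consumed <- consumed_sugars(ep)
      if (consumed < min_consumed) consumed <- 0  # below the assay floor
      out <- c(out, list(
        rec("cdw", cdw_final),
        rec("biomass_yield",
            suppress_undefined(biomass_yield(cdw_final, cdw_init, consumed))),
        rec("ethanol_yield",
            suppress_undefined(ethanol_yield(ep$ethanol, consumed)))
      ))
    }
    rows[[i]] <- do.call(rbind, out)
  }
  if (length(no_endpoint) > 0L) {
    warning("no endpoint row for well(s) ",
            paste(no_endpoint, collapse = ", "),
            "; recording growth functions only")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- validate_function_table(tab)
  n_missing <- tapply(is.na(tab$value), tab$fun, sum)
  attr(tab, "n_missing") <- n_missing
  tab
}

# Yield helpers warn when consumption is zero; inside table assembly the
# per-well warning would repeat for every starved well, so keep it quiet and
# rely on the missing-value count attribute instead.
suppress_undefined <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("undefined", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
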