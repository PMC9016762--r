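# Plate-data file formats: time series, layouts, endpoint tables, tidy results.
#
# All files are plain CSV (comma separator, "." decimal, UTF-8, mandatory
# header, missing values written as "NA"). Time is always in hours; there is
# no unit auto-detection.

SUGARS <- c("glucose", "mannose", "xylose", "galactose", "arabinose")

FUNCTION_UNITS <- c(
  mu_max        = "1/h",
  lag           = "h",
  cdw           = "g/L",
  biomass_yield = "g/g",
  ethanol_yield = "g/g"
)

#' Construct a plate layout
#'
#' A plate layout maps each well to a strain, a perturbation (condition) and a
#' technical replicate index. One condition per layout may be flagged as the
#' control (e.g. 20 g/L glucose), which the Kitano-style robustness score
#' requires as its reference.
#'
#' @param well_id Character vector of well identifiers (e.g. "A1".."H12").
#' @param strain Character vector of strain names.
#' @param condition_id Character vector of perturbation labels
#'   (e.g. "furfural_2gL").
#' @param replicate Positive integer replicate indices.
#' @param is_control Logical; TRUE for wells of the control condition.
#' @return A data frame of class `plate_layout`.
#' @export
plate_layout <- function(well_id, strain, condition_id, replicate,
                         is_control = FALSE) {
  layout <- data.frame(
    well_id = as.character(well_id),
    strain = as.character(strain),
    condition_id = as.character(condition_id),
    replicate = as.integer(replicate),
    is_control = as.logical(is_control),
    stringsAsFactors = FALSE
  )
  validate_layout(layout)
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  required <- c("well_id", "strain", "condition_id", "replicate", "is_control")
  missing_cols <- setdiff(required, names(layout))
  if (length(missing_cols) > 0L) {
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(layout$well_id)) {
    dup <- unique(layout$well_id[duplicated(layout$well_id)])
    stop("duplicate well_id in layout: ", paste(dup, collapse = ", "))
  }
  key <- paste(layout$strain, layout$condition_id, layout$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- layout[duplicated(key), , drop = FALSE]
    stop(
      "duplicate (strain, condition_id, replicate) in layout: ",
      paste(sprintf("(%s, %s, %d)", dup$strain, dup$condition_id,
                    dup$replicate), collapse = "; ")
    )
  }
  if (any(layout$replicate < 1L, na.rm = TRUE)) {
    stop("replicate indices must be positive integers")
  }
  ctrl <- unique(layout$condition_id[layout$is_control])
  if (length(ctrl) > 1L) {
    stop("at most one condition may be flagged is_control; found: ",
         paste(ctrl, collapse = ", "))
  }
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Read a plate layout from CSV
#'
#' Expected columns: `well_id`, `strain`, `condition_id`, `replicate` and
#' optionally `is_control` (defaults to FALSE).
#'
#' @param path Path to the layout CSV.
#' @return A `plate_layout` data frame.
#' @export
read_layout <- function(path) {
  df <- read_csv_strict(path)
  if (is.null(df$is_control)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  plate_layout(df$well_id, df$strain, df$condition_id, df$replicate,
               df$is_control)
}

#' One well's density trajectory
#'
#' @param well_id Well identifier.
#' @param times Numeric vector of sampling times in hours; strictly
#'   increasing, nonnegative.
#' @param values Numeric density readings, nonnegative; green-value (GV)
#'   units or OD600 depending on `signal_kind`.
#' @param signal_kind Either "GV" or "OD".
#' @param strain,condition_id,replicate,is_control Layout identity of the
#'   well (optional until attached via a layout).
#' @return An object of class `ts_well`.
#' @export
ts_well <- function(well_id, times, values, signal_kind = c("GV", "OD"),
                    strain = NA_character_, condition_id = NA_character_,
                    replicate = NA_integer_, is_control = NA) {
  signal_kind <- match.arg(signal_kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) < 4L) {
    stop("a time series needs at least 4 timepoints (well ", well_id, ")")
  }
  if (anyNA(times) || anyNA(values)) {
    stop("non-numeric or missing readings in well ", well_id)
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0) + 1L
    stop("times are not strictly increasing in well ", well_id,
         " at rows ", paste(bad, collapse = ", "))
  }
  if (any(times < 0)) stop("negative times in well ", well_id)
  if (any(values < 0)) stop("negative readings in well ", well_id)
  structure(
    list(well_id = as.character(well_id), times = times, values = values,
         signal_kind = signal_kind, strain = strain,
         condition_id = condition_id, replicate = as.integer(replicate),
         is_control = is_control),
    class = "ts_well"
  )
}

#' @export
print.ts_well <- function(x, ...) {
  cat(sprintf("<ts_well %s  %s  %d points  %.1f-%.1f h  strain=%s cond=%s rep=%s>\n",
              x$well_id, x$signal_kind, length(x$times), min(x$times),
              max(x$times), x$strain, x$condition_id, x$replicate))
  invisible(x)
}

#' Read plate time series from CSV
#'
#' Accepts two shapes. Wide: first column `time_h`, one column per well id.
#' Long: columns `time_h`, `well_id`, `value`. Every well in the file must be
#' present in `layout`; rows may appear in any order (they are sorted by
#' time). Times are hours.
#'
#' @param path Path to the CSV file.
#' @param layout A `plate_layout` covering all wells in the file.
#' @param signal_kind "GV" (Growth Profiler green values) or "OD".
#' @return A named list of `ts_well` objects, one per well.
#' @export
read_timeseries <- function(path, layout, signal_kind = c("GV", "OD")) {
  signal_kind <- match.arg(signal_kind)
  layout <- validate_layout(layout)
  df <- read_csv_strict(path)
  if (!"time_h" %in% names(df)) {
    stop("time-series file must have a 'time_h' column: ", path)
  }
  long <- all(c("well_id", "value") %in% names(df))
  if (long) {
    wells <- unique(as.character(df$well_id))
  } else {
    wells <- setdiff(names(df), "time_h")
  }
  unknown <- setdiff(wells, layout$well_id)
  if (length(unknown) > 0L) {
    stop("wells present in ", path, " but absent from layout: ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(wells, function(w) {
    if (long) {
      sub <- df[df$well_id == w, , drop = FALSE]
      tt <- sub$time_h
      vv <- sub$value
    } else {
      tt <- df$time_h
      vv <- df[[w]]
    }
    if (!is.numeric(tt) || anyNA(tt)) {
      stop("non-numeric time in ", path, " for well ", w)
    }
    if (!is.numeric(vv) || anyNA(vv)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(vv))))
      stop("non-numeric value in ", path, " for well ", w,
           " at row(s) ", paste(bad, collapse = ", "))
    }
    ord <- order(tt)
    row <- layout[layout$well_id == w, , drop = FALSE]
    ts_well(w, tt[ord], vv[ord], signal_kind,
            strain = row$strain, condition_id = row$condition_id,
            replicate = row$replicate, is_control = row$is_control)
  })
  names(out) <- wells
  out
}

#' Read an endpoint table from CSV
#'
#' One row per well with initial and final concentrations (g/L) for each
#' sugar (columns `<sugar>_initial`, `<sugar>_final` for glucose, mannose,
#' xylose, galactose, arabinose), `ethanol` (g/L at the endpoint) and
#' `od600_48h`. Missing sugar columns are treated as 0 g/L. Wells where a
#' final concentration exceeds its initial beyond `tolerance` are flagged
#' with a warning (e.g. assay carryover) but retained.
#'
#' @param path Path to the CSV.
#' @param tolerance Allowed excess of final over initial (g/L) before
#'   flagging. Default 0.05.
#' @return A data frame of class `endpoint_table`.
#' @export
read_endpoints <- function(path, tolerance = 0.05) {
  df <- read_csv_strict(path, allow_empty = TRUE)
  if (nrow(df) == 0L) {
    warning("endpoint file is empty: ", path)
    df <- empty_endpoints()
    return(df)
  }
  validate_endpoints(df, tolerance = tolerance)
}

empty_endpoints <- function() {
  cols <- c("well_id", paste0(rep(SUGARS, each = 2), c("_initial", "_final")),
            "ethanol", "od600_48h")
  df <- as.data.frame(stats::setNames(
    c(list(character(0)), rep(list(numeric(0)), length(cols) - 1L)), cols))
  class(df) <- c("endpoint_table", "data.frame")
  df
}

validate_endpoints <- function(df, tolerance = 0.05) {
  if (!"well_id" %in% names(df)) stop("endpoint table needs a well_id column")
  for (s in SUGARS) {
    for (suffix in c("_initial", "_final")) {
      col <- paste0(s, suffix)
      if (is.null(df[[col]])) df[[col]] <- 0
    }
  }
  if (is.null(df$ethanol)) df$ethanol <- NA_real_
  if (is.null(df$od600_48h)) df$od600_48h <- NA_real_
  conc_cols <- c(paste0(rep(SUGARS, each = 2), c("_initial", "_final")),
                 "ethanol", "od600_48h")
  for (col in conc_cols) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop("negative concentration in endpoint column ", col)
    }
  }
  for (s in SUGARS) {
    excess <- df[[paste0(s, "_final")]] - df[[paste0(s, "_initial")]]
    bad <- which(!is.na(excess) & excess > tolerance)
    if (length(bad) > 0L) {
      warning("final ", s, " exceeds initial by more than ", tolerance,
              " g/L in well(s): ", paste(df$well_id[bad], collapse = ", "))
    }
  }
  if (anyDuplicated(df$well_id)) stop("duplicate well_id in endpoint table")
  class(df) <- unique(c("endpoint_table", class(df)))
  df
}

#' Write a tidy result table to CSV
#'
#' Emits the records in long format preceded by '#' comment lines naming the
#' package version and a hash of the run configuration, so result files are
#' self-describing.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param config Optional list; hashed into the header comment.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path, config = NULL) {
  version <- as.character(utils::packageVersion("phenorobust"))
  hash <- config_hash(config)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# phenorobust %s", version),
    sprintf("# config_hash %s", hash)
  ), con)
  utils::write.csv(records, con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a tidy result table written by [write_table()]
#'
#' @param path Path to the CSV.
#' @return A data frame (comment lines skipped).
#' @export
read_table <- function(path) {
  read_csv_strict(path)
}

#' Read a function table from CSV
#'
#' Columns: `strain`, `fun` (one of mu_max, lag, cdw, biomass_yield,
#' ethanol_yield or a registered extension), `condition_id`, `replicate`,
#' `value`. Missing values are "NA" (e.g. lag of non-growing wells).
#'
#' @param path Path to the CSV.
#' @return A data frame of class `function_table`.
#' @export
read_function_table <- function(path) {
  df <- read_csv_strict(path)
  validate_function_table(df)
}

validate_function_table <- function(df) {
  required <- c("strain", "fun", "condition_id", "replicate", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("function table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$strain, df$fun, df$condition_id, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (strain, fun, condition_id, replicate) keys in function table")
  }
  df$replicate <- as.integer(df$replicate)
  df$value <- as.numeric(df$value)
  class(df) <- unique(c("function_table", class(df)))
  df
}

#' Read a run configuration from YAML
#'
#' Flat keys: calibration constants, QC threshold, metric options, paths and
#' the RNG seed. Unknown keys are preserved.
#'
#' @param path Path to the YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
  cfg
}

# -- internals ---------------------------------------------------------------

read_csv_strict <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                    na.strings = "NA", fileEncoding = "UTF-8"),
    error = function(e) {
      if (allow_empty) return(data.frame())
      stop("failed to read ", path, ": ", conditionMessage(e))
    }
  )
  df
}

# Order-independent FNV-style hash of a flattened config list; good enough to
# fingerprint a run, not cryptographic.
config_hash <- function(config) {
  if (is.null(config)) return("none")
  flat <- unlist(config, use.names = TRUE)
  txt <- paste(sort(paste(names(flat), as.character(flat), sep = "=")),
               collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
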