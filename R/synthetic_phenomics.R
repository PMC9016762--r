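# Synthetic plate experiments with known ground truth: Gompertz growth
# curves in log-signal space, endpoint sugar/ethanol/OD measurements, plate
# layouts, and the effective parameters each well was generated from.

#' Ground-truth strain specification
#'
#' Baseline (control-condition) parameters of a simulated strain. The
#' `sensitivity` exponent scales how strongly perturbation effect
#' multipliers act on this strain (effective multiplier = multiplier ^
#' sensitivity), so strains with lower sensitivity have less dispersed
#' functions across a perturbation space — a built-in robustness ordering
#' that recovery tests can check.
#'
#' @param name Strain name.
#' @param mu_max Baseline maximum specific growth rate, 1/h.
#' @param lag Baseline lag phase, h.
#' @param ethanol_yield,biomass_yield Baseline yields, g/g (< 1).
#' @param cdw_slope CDW calibration slope, g/L per OD unit.
#' @param capacity_gv Carrying capacity of the blank-corrected signal, GV
#'   units.
#' @param sensitivity Perturbation-sensitivity exponent (>= 0).
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(name, mu_max, lag, ethanol_yield, biomass_yield,
                        cdw_slope, capacity_gv, sensitivity = 1) {
  stopifnot(mu_max > 0, lag >= 0, ethanol_yield > 0, biomass_yield > 0,
            ethanol_yield < 1, biomass_yield < 1, cdw_slope > 0,
            capacity_gv > 0, sensitivity >= 0)
  structure(list(name = name, mu_max = mu_max, lag = lag,
                 ethanol_yield = ethanol_yield,
                 biomass_yield = biomass_yield, cdw_slope = cdw_slope,
                 capacity_gv = capacity_gv, sensitivity = sensitivity),
            class = "strain_spec")
}

#' Ground-truth perturbation specification
#'
#' Multiplicative effects of one condition on each baseline parameter
#' (multiplier 1 = unchanged; < 1 degrades rate/capacity/yields; lag
#' multipliers > 1 lengthen the lag), the sugar composition and consumed
#' fraction, and a growth-abolishing flag.
#'
#' @param condition_id Condition label (e.g. "furfural_2gL").
#' @param mu_mult,lag_mult,capacity_mult,ethanol_mult,biomass_mult
#'   Nonnegative effect multipliers.
#' @param sugars Named vector of initial sugar concentrations, g/L (names
#'   among glucose, mannose, xylose, galactose, arabinose).
#' @param consumed_frac Fraction of each sugar consumed by 48 h, in [0, 1].
#' @param abolishes_growth If TRUE the well stays a flat baseline and
#'   nothing is consumed.
#' @param is_control Marks the reference condition (e.g. 20 g/L glucose).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(condition_id, mu_mult = 1, lag_mult = 1,
                              capacity_mult = 1, ethanol_mult = 1,
                              biomass_mult = 1,
                              sugars = c(glucose = 20),
                              consumed_frac = 0.95,
                              abolishes_growth = FALSE, is_control = FALSE) {
  mults <- c(mu_mult, lag_mult, capacity_mult, ethanol_mult, biomass_mult)
  if (any(mults < 0)) stop("effect multipliers must be >= 0")
  if (consumed_frac < 0 || consumed_frac > 1) {
    stop("consumed_frac must lie in [0, 1]")
  }
  if (!all(names(sugars) %in% SUGARS)) {
    stop("unknown sugar(s): ",
         paste(setdiff(names(sugars), SUGARS), collapse = ", "))
  }
  structure(list(condition_id = condition_id, mu_mult = mu_mult,
                 lag_mult = lag_mult, capacity_mult = capacity_mult,
                 ethanol_mult = ethanol_mult, biomass_mult = biomass_mult,
                 sugars = sugars, consumed_frac = consumed_frac,
                 abolishes_growth = abolishes_growth,
                 is_control = is_control),
            class = "perturbation_spec")
}

#' Default three-strain design
#'
#' Emulates the typical design of one laboratory reference strain and two
#' industrial isolates with anaerobic S. cerevisiae-like parameters:
#' baseline growth rates 0.25-0.40 1/h, lags 2-4 h, ethanol yields
#' 0.40-0.46 g/g, biomass yields 0.05-0.09 g/g. The sensitivity exponents
#' (0.6 / 1.0 / 1.4) build in a known robustness ordering: `ind_robust` >
#' `lab_ref` > `ind_perform`, with `ind_perform` trading robustness for a
#' higher baseline ethanol yield.
#'
#' @return Named list of [strain_spec()] objects.
#' @export
default_strains <- function() {
  list(
    lab_ref = strain_spec("lab_ref", mu_max = 0.32, lag = 3.0,
                          ethanol_yield = 0.41, biomass_yield = 0.085,
                          cdw_slope = 0.48, capacity_gv = 140,
                          sensitivity = 1.0),
    ind_robust = strain_spec("ind_robust", mu_max = 0.38, lag = 2.2,
                             ethanol_yield = 0.42, biomass_yield = 0.075,
                             cdw_slope = 0.52, capacity_gv = 160,
                             sensitivity = 0.6),
    ind_perform = strain_spec("ind_perform", mu_max = 0.35, lag = 2.6,
                              ethanol_yield = 0.46, biomass_yield = 0.065,
                              cdw_slope = 0.50, capacity_gv = 150,
                              sensitivity = 1.4)
  )
}

#' Default 29-condition lignocellulosic perturbation space
#'
#' A 20 g/L glucose control plus 28 single-component conditions patterned
#' on lignocellulosic hydrolysates: furanic aldehydes (degrade every
#' function; the harshest abolishes growth), phenolic aldehydes, weak acids
#' (mainly reduce capacity and biomass yield), pentoses (neutral to mildly
#' beneficial), extra hexoses, osmotic salt and ethanol stress.
#'
#' @return Named list of 29 [perturbation_spec()] objects.
#' @export
default_perturbations <- function() {
  p <- list()
  add <- function(...) {
    spec <- perturbation_spec(...)
    p[[spec$condition_id]] <<- spec
  }
  glc <- c(glucose = 20)
  add("glucose_20gL", is_control = TRUE, sugars = glc, consumed_frac = 0.98)
  # furanic aldehydes: hit growth, lag and yields, dose dependently
  add("furfural_1gL", mu_mult = 0.90, lag_mult = 1.3, capacity_mult = 0.95,
      ethanol_mult = 0.97, biomass_mult = 0.95, sugars = glc,
      consumed_frac = 0.95)
  add("furfural_2gL", mu_mult = 0.75, lag_mult = 1.8, capacity_mult = 0.88,
      ethanol_mult = 0.93, biomass_mult = 0.88, sugars = glc,
      consumed_frac = 0.90)
  add("furfural_3gL", mu_mult = 0.55, lag_mult = 2.6, capacity_mult = 0.78,
      ethanol_mult = 0.87, biomass_mult = 0.78, sugars = glc,
      consumed_frac = 0.80)
  add("furfural_4gL", abolishes_growth = TRUE, sugars = glc,
      consumed_frac = 0)
  add("hmf_1gL", mu_mult = 0.93, lag_mult = 1.2, capacity_mult = 0.96,
      ethanol_mult = 0.98, biomass_mult = 0.96, sugars = glc,
      consumed_frac = 0.96)
  add("hmf_2gL", mu_mult = 0.82, lag_mult = 1.5, capacity_mult = 0.90,
      ethanol_mult = 0.95, biomass_mult = 0.90, sugars = glc,
      consumed_frac = 0.92)
  add("hmf_3gL", mu_mult = 0.65, lag_mult = 2.1, capacity_mult = 0.82,
      ethanol_mult = 0.90, biomass_mult = 0.82, sugars = glc,
      consumed_frac = 0.85)
  # phenolic aldehydes
  add("vanillin_0.5gL", mu_mult = 0.92, lag_mult = 1.25,
      capacity_mult = 0.95, ethanol_mult = 0.97, biomass_mult = 0.94,
      sugars = glc, consumed_frac = 0.94)
  add("vanillin_1gL", mu_mult = 0.80, lag_mult = 1.6, capacity_mult = 0.88,
      ethanol_mult = 0.93, biomass_mult = 0.87, sugars = glc,
      consumed_frac = 0.90)
  add("syringaldehyde_1gL", mu_mult = 0.88, lag_mult = 1.35,
      capacity_mult = 0.92, ethanol_mult = 0.95, biomass_mult = 0.91,
      sugars = glc, consumed_frac = 0.93)
  # weak acids: capacity and biomass yield down, growth rate mildly down
  add("acetic_2gL", mu_mult = 0.95, lag_mult = 1.15, capacity_mult = 0.92,
      ethanol_mult = 1.00, biomass_mult = 0.88, sugars = glc,
      consumed_frac = 0.95)
  add("acetic_4gL", mu_mult = 0.88, lag_mult = 1.35, capacity_mult = 0.85,
      ethanol_mult = 0.98, biomass_mult = 0.78, sugars = glc,
      consumed_frac = 0.90)
  add("acetic_6gL", mu_mult = 0.78, lag_mult = 1.7, capacity_mult = 0.76,
      ethanol_mult = 0.95, biomass_mult = 0.68, sugars = glc,
      consumed_frac = 0.84)
  add("formic_1gL", mu_mult = 0.92, lag_mult = 1.2, capacity_mult = 0.90,
      ethanol_mult = 0.99, biomass_mult = 0.85, sugars = glc,
      consumed_frac = 0.93)
  add("formic_2gL", mu_mult = 0.82, lag_mult = 1.5, capacity_mult = 0.82,
      ethanol_mult = 0.96, biomass_mult = 0.74, sugars = glc,
      consumed_frac = 0.88)
  add("levulinic_2gL", mu_mult = 0.94, lag_mult = 1.15,
      capacity_mult = 0.92, ethanol_mult = 0.99, biomass_mult = 0.89,
      sugars = glc, consumed_frac = 0.95)
  add("levulinic_4gL", mu_mult = 0.86, lag_mult = 1.35,
      capacity_mult = 0.84, ethanol_mult = 0.97, biomass_mult = 0.80,
      sugars = glc, consumed_frac = 0.90)
  add("lactic_2gL", mu_mult = 0.96, lag_mult = 1.1, capacity_mult = 0.94,
      ethanol_mult = 1.00, biomass_mult = 0.90, sugars = glc,
      consumed_frac = 0.96)
  add("lactic_4gL", mu_mult = 0.90, lag_mult = 1.25, capacity_mult = 0.88,
      ethanol_mult = 0.98, biomass_mult = 0.82, sugars = glc,
      consumed_frac = 0.92)
  # pentoses: neutral to mildly beneficial (extra carbon, not all consumed)
  add("xylose_10gL", mu_mult = 1.00, lag_mult = 1.0, capacity_mult = 1.02,
      ethanol_mult = 1.03, biomass_mult = 1.02,
      sugars = c(glucose = 20, xylose = 10), consumed_frac = 0.70)
  add("xylose_20gL", mu_mult = 1.00, lag_mult = 1.0, capacity_mult = 1.03,
      ethanol_mult = 1.05, biomass_mult = 1.03,
      sugars = c(glucose = 20, xylose = 20), consumed_frac = 0.60)
  add("arabinose_10gL", mu_mult = 1.00, lag_mult = 1.0,
      capacity_mult = 1.01, ethanol_mult = 1.02, biomass_mult = 1.01,
      sugars = c(glucose = 20, arabinose = 10), consumed_frac = 0.68)
  # extra hexoses
  add("mannose_10gL", mu_mult = 1.02, lag_mult = 0.95,
      capacity_mult = 1.05, ethanol_mult = 1.01, biomass_mult = 1.02,
      sugars = c(glucose = 20, mannose = 10), consumed_frac = 0.95)
  add("galactose_10gL", mu_mult = 0.98, lag_mult = 1.05,
      capacity_mult = 1.02, ethanol_mult = 0.99, biomass_mult = 1.00,
      sugars = c(glucose = 20, galactose = 10), consumed_frac = 0.85)
  add("glucose_50gL", mu_mult = 0.99, lag_mult = 1.05,
      capacity_mult = 1.10, ethanol_mult = 1.02, biomass_mult = 0.98,
      sugars = c(glucose = 50), consumed_frac = 0.90)
  # osmotic / solvent stress
  add("nacl_0.5M", mu_mult = 0.80, lag_mult = 1.5, capacity_mult = 0.85,
      ethanol_mult = 0.95, biomass_mult = 0.85, sugars = glc,
      consumed_frac = 0.88)
  add("ethanol_20gL", mu_mult = 0.90, lag_mult = 1.3, capacity_mult = 0.92,
      ethanol_mult = 0.98, biomass_mult = 0.92, sugars = glc,
      consumed_frac = 0.94)
  add("ethanol_40gL", mu_mult = 0.72, lag_mult = 1.8, capacity_mult = 0.80,
      ethanol_mult = 0.94, biomass_mult = 0.80, sugars = glc,
      consumed_frac = 0.85)
  stopifnot(length(p) == 29L)
  p
}

# effective (post-perturbation) parameters for one strain x condition
effective_params <- function(strain, pert) {
  s <- strain$sensitivity
  list(
    mu = strain$mu_max * pert$mu_mult^s,
    lag = strain$lag * pert$lag_mult^s,
    capacity = strain$capacity_gv * pert$capacity_mult^s,
    ethanol_yield = strain$ethanol_yield * pert$ethanol_mult^s,
    biomass_yield = strain$biomass_yield * pert$biomass_mult^s,
    grew = !pert$abolishes_growth
  )
}

# deterministic per-well substream: a small multiplicative hash of the master
# seed and the well index, kept inside the 32-bit integer range
well_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx * 9973) %% 2147483647)
}

#' Simulate one well's growth curve
#'
#' The log blank-corrected signal follows a modified Gompertz curve
#' \deqn{y(t) = y_0 + A \exp(-\exp(\mu_{max} e / A (\lambda - t) + 1))}
#' whose maximum log-slope is exactly the effective mu_max and whose
#' mu_max-tangent construction yields the lag, so growth-parameter recovery
#' can be checked against closed-form truth. Noise is multiplicative
#' lognormal on the blank-corrected signal (plate readers scale their
#' noise); green values are offset by `gv_blank`. A growth-abolishing
#' condition gives a flat (noisy) baseline.
#'
#' @param strain A [strain_spec()].
#' @param pert A [perturbation_spec()].
#' @param noise_sd Lognormal sigma of the multiplicative signal noise
#'   (0 = noiseless).
#' @param seed Integer seed (NULL leaves the RNG stream untouched).
#' @param times Sampling grid in hours (default 0-48 h, 30-min steps).
#' @param gv_blank Blank green value added to the signal.
#' @param initial_gv Blank-corrected signal at inoculation (GV units).
#' @param well_id Well identifier for the returned series.
#' @param replicate Replicate index recorded on the series.
#' @return A [ts_well()] with attribute `truth`: list(mu, lag_gompertz,
#'   lag_tangent, capacity, grew). `lag_tangent` is the lag the tangent
#'   construction assigns to the noiseless curve observed from `times[1]`
#'   (it exceeds the Gompertz lambda by A exp(-exp(mu e lambda / A + 1))/mu
#'   evaluated at the window start, a correction that matters for slow
#'   growers).
#' @export
simulate_growth_curve <- function(strain, pert, noise_sd = 0, seed = NULL,
                                  times = seq(0, 48, by = 0.5),
                                  gv_blank = 26.3, initial_gv = 2,
                                  well_id = "A1", replicate = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  eff <- effective_params(strain, pert)
  y0 <- log(initial_gv)
  if (!eff$grew) {
    log_signal <- rep(y0, length(times))
    truth <- list(mu = 0, lag_gompertz = NA_real_, lag_tangent = NA_real_,
                  capacity = initial_gv, grew = FALSE)
  } else {
    A <- log(eff$capacity / initial_gv)
    y <- y0 + A * exp(-exp(eff$mu * exp(1) / A * (eff$lag - times) + 1))
    log_signal <- y
    t0 <- times[1]
    y_at_t0 <- y0 + A * exp(-exp(eff$mu * exp(1) / A * (eff$lag - t0) + 1))
    lag_tangent <- eff$lag + (y_at_t0 - y0) / eff$mu
    truth <- list(mu = eff$mu, lag_gompertz = eff$lag,
                  lag_tangent = lag_tangent, capacity = eff$capacity,
                  grew = TRUE)
  }
  noise <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
  gv <- gv_blank + exp(log_signal + noise)
  ts <- ts_well(well_id, times, gv, signal_kind = "GV",
                strain = strain$name, condition_id = pert$condition_id,
                replicate = replicate, is_control = pert$is_control)
  attr(ts, "truth") <- truth
  ts
}

#' Simulate one well's endpoint measurements
#'
#' Sugar finals follow the condition's consumption plan; ethanol is the
#' effective ethanol yield times consumed sugars; the 48-h OD encodes the
#' effective biomass yield on top of the inoculum so that downstream yield
#' computation inverts the generator exactly in the noiseless case.
#' Measurement noise is additive Gaussian on concentrations and OD,
#' truncated at 0.
#'
#' @param strain A [strain_spec()].
#' @param pert A [perturbation_spec()].
#' @param conc_sd Gaussian sd of sugar/ethanol concentration noise, g/L.
#' @param od_sd Gaussian sd of the endpoint OD noise.
#' @param seed Integer seed (NULL leaves the RNG stream untouched).
#' @param inoculum_od Starting OD600.
#' @param well_id Well identifier.
#' @return A one-row endpoint data frame with attribute `truth`:
#'   list(consumed, ethanol_yield, biomass_yield, cdw_final).
#' @export
simulate_endpoints <- function(strain, pert, conc_sd = 0, od_sd = 0,
                               seed = NULL, inoculum_od = 0.02,
                               well_id = "A1") {
  if (!is.null(seed)) set.seed(seed)
  eff <- effective_params(strain, pert)
  frac <- if (eff$grew) pert$consumed_frac else 0
  row <- stats::setNames(as.list(rep(0, 2 * length(SUGARS))),
                         paste0(rep(SUGARS, each = 2),
                                c("_initial", "_final")))
  consumed <- 0
  for (s in names(pert$sugars)) {
    init <- unname(pert$sugars[[s]])
    final <- init * (1 - frac)
    row[[paste0(s, "_initial")]] <- init
    row[[paste0(s, "_final")]] <-
      max(final + if (conc_sd > 0) stats::rnorm(1, 0, conc_sd) else 0, 0)
    consumed <- consumed + (init - final)
  }
  ethanol_true <- eff$ethanol_yield * consumed
  cdw_final_true <- inoculum_od * strain$cdw_slope +
    eff$biomass_yield * consumed
  od_true <- cdw_final_true / strain$cdw_slope
  out <- data.frame(well_id = well_id, stringsAsFactors = FALSE)
  for (nm in names(row)) out[[nm]] <- row[[nm]]
  out$ethanol <- max(ethanol_true +
                       if (conc_sd > 0) stats::rnorm(1, 0, conc_sd) else 0, 0)
  out$od600_48h <- max(od_true +
                         if (od_sd > 0) stats::rnorm(1, 0, od_sd) else 0, 0)
  attr(out, "truth") <- list(consumed = consumed,
                             ethanol_yield = if (consumed > 0) eff$ethanol_yield else NA_real_,
                             biomass_yield = if (consumed > 0) eff$biomass_yield else NA_real_,
                             cdw_final = cdw_final_true)
  out
}

#' Simulate a complete multi-plate experiment
#'
#' One plate per strain (as in a Growth-Profiler campaign), every condition
#' in `n_replicates` technical replicates, with time series, layout,
#' endpoint table and a ground-truth table of every effective parameter.
#' All randomness derives from `seed` through deterministic per-well
#' substreams, so the same seed reproduces the experiment byte for byte.
#'
#' @param strains Named list of [strain_spec()] (default
#'   [default_strains()]).
#' @param perturbations Named list of [perturbation_spec()] (default
#'   [default_perturbations()], 29 conditions).
#' @param n_replicates Technical replicates per condition (default 3).
#' @param noise List with elements `gv_sd` (lognormal signal noise, default
#'   0.02), `conc_sd` (g/L, default 0.1), `od_sd` (default 0.02); use
#'   `noise = NULL` for a fully noiseless experiment.
#' @param seed Master RNG seed.
#' @param times Sampling grid in hours.
#' @param gv_blank Blank green value.
#' @param inoculum_od Starting OD600.
#' @return An object of class `sim_experiment`: list(timeseries, layout,
#'   endpoints, ground_truth, strains, perturbations, seed). Well ids are
#'   "P<plate>_<wellpos>" and globally unique.
#' @export
simulate_experiment <- function(strains = default_strains(),
                                perturbations = default_perturbations(),
                                n_replicates = 3,
                                noise = list(gv_sd = 0.02, conc_sd = 0.1,
                                             od_sd = 0.02),
                                seed = 1, times = seq(0, 48, by = 0.5),
                                gv_blank = 26.3, inoculum_od = 0.02) {
  if (is.null(noise)) noise <- list(gv_sd = 0, conc_sd = 0, od_sd = 0)
  noise <- utils::modifyList(list(gv_sd = 0.02, conc_sd = 0.1, od_sd = 0.02),
                             noise)
  n_wells <- length(perturbations) * n_replicates
  if (n_wells > 96L) stop("design exceeds one 96-well plate per strain")
  positions <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  ts_list <- list()
  layout_rows <- list()
  ep_rows <- list()
  gt_rows <- list()
  idx <- 0L
  for (pi in seq_along(strains)) {
    strain <- strains[[pi]]
    wi <- 0L
    for (pert in perturbations) {
      for (r in seq_len(n_replicates)) {
        idx <- idx + 1L
        wi <- wi + 1L
        wid <- paste0("P", pi, "_", positions[wi])
        ts <- simulate_growth_curve(
          strain, pert, noise_sd = noise$gv_sd,
          seed = well_seed(seed, idx), times = times, gv_blank = gv_blank,
          well_id = wid, replicate = r)
        ep <- simulate_endpoints(
          strain, pert, conc_sd = noise$conc_sd, od_sd = noise$od_sd,
          seed = well_seed(seed, idx + 1000000L),
          inoculum_od = inoculum_od, well_id = wid)
        tr_ts <- attr(ts, "truth")
        tr_ep <- attr(ep, "truth")
        ts_list[[wid]] <- ts
        layout_rows[[wid]] <- data.frame(
          well_id = wid, strain = strain$name,
          condition_id = pert$condition_id, replicate = r,
          is_control = pert$is_control, stringsAsFactors = FALSE)
        ep_rows[[wid]] <- ep
        gt_rows[[wid]] <- data.frame(
          well_id = wid, strain = strain$name,
          condition_id = pert$condition_id, replicate = r,
          mu_max = tr_ts$mu, lag_gompertz = tr_ts$lag_gompertz,
          lag_tangent = tr_ts$lag_tangent, capacity = tr_ts$capacity,
          grew = tr_ts$grew, consumed = tr_ep$consumed,
          ethanol_yield = tr_ep$ethanol_yield,
          biomass_yield = tr_ep$biomass_yield,
          cdw_final = tr_ep$cdw_final, stringsAsFactors = FALSE)
      }
    }
  }
  layout <- validate_layout(do.call(rbind, c(layout_rows,
                                             make.row.names = FALSE)))
  # flag tolerance follows the configured assay noise: a final reading can
  # exceed its initial by a few noise sd without being suspicious
  endpoints <- validate_endpoints(do.call(rbind, c(ep_rows,
                                                   make.row.names = FALSE)),
                                  tolerance = max(0.05, 4 * noise$conc_sd))
  ground_truth <- do.call(rbind, c(gt_rows, make.row.names = FALSE))
  structure(
    list(timeseries = ts_list, layout = layout, endpoints = endpoints,
         ground_truth = ground_truth, strains = strains,
         perturbations = perturbations, seed = seed, gv_blank = gv_blank,
         inoculum_od = inoculum_od),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment  %d strains x %d conditions x %d replicates  (%d wells)  seed=%s>\n",
    length(x$strains), length(x$perturbations),
    max(x$layout$replicate), nrow(x$layout), x$seed))
  invisible(x)
}

#' Write a simulated experiment to CSV files
#'
#' Emits `timeseries.csv` (long format: time_h, well_id, value),
#' `layout.csv`, `endpoints.csv` and `ground_truth.csv` in `outdir` — the
#' same formats the readers consume.
#'
#' @param sim A `sim_experiment`.
#' @param outdir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(sim$timeseries, function(w) {
    data.frame(time_h = w$times, well_id = w$well_id, value = w$values,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  utils::write.csv(long, file.path(outdir, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$layout), file.path(outdir, "layout.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$endpoints),
                   file.path(outdir, "endpoints.csv"), row.names = FALSE)
  utils::write.csv(sim$ground_truth, file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' CDW calibration slopes of a simulated strain set
#'
#' @param strains Named list of [strain_spec()].
#' @return Named numeric vector usable as `cdw_slopes` in
#'   [calibration_model()].
#' @export
sim_cdw_slopes <- function(strains) {
  vapply(strains, function(s) s$cdw_slope, numeric(1))
}
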