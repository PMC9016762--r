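# Robustness metrics: coefficient of variation, Kitano-style control-ratio
# score, and the negative mean-normalized Fano factor, plus the Monte-Carlo
# audit of the three metrics against four consistency criteria.

#' Define a perturbation space
#'
#' The set of conditions over which robustness is scored, with optional
#' frequency weights (equal by default) and an optional control condition
#' (required by the Kitano-style metric).
#'
#' @param conditions Character vector of condition ids, length >= 2.
#' @param weights Optional positive frequencies, one per condition, summing
#'   to 1 (within 1e-9). Default equal.
#' @param control Optional control condition id; must be one of `conditions`
#'   or a designated external reference id.
#' @return An object of class `perturbation_space`.
#' @export
perturbation_space <- function(conditions, weights = NULL, control = NULL) {
  conditions <- as.character(conditions)
  if (length(conditions) < 2L) stop("a perturbation space needs >= 2 conditions")
  if (anyDuplicated(conditions)) stop("duplicate condition ids")
  if (is.null(weights)) {
    weights <- rep(1 / length(conditions), length(conditions))
  }
  if (length(weights) != length(conditions)) {
    stop("weights must match conditions in length")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(
    list(conditions = conditions, weights = stats::setNames(weights, conditions),
         control = control),
    class = "perturbation_space"
  )
}

#' Perturbation space from a plate layout
#'
#' Conditions are the distinct condition ids of the layout; the control is
#' the condition flagged `is_control`, if any.
#'
#' @param layout A `plate_layout`.
#' @return A [perturbation_space()].
#' @export
space_from_layout <- function(layout) {
  layout <- validate_layout(layout)
  conds <- unique(layout$condition_id)
  ctrl <- unique(layout$condition_id[layout$is_control])
  perturbation_space(conds, control = if (length(ctrl) == 1L) ctrl else NULL)
}

new_robustness_result <- function(metric, R, higher_is_more_robust,
                                  n_used, n_missing, sem = NA_real_,
                                  m = NA_real_, strain = NA_character_,
                                  fun = NA_character_, slice_R = NULL,
                                  degenerate = FALSE) {
  structure(
    list(metric = metric, R = R, sem = sem, strain = strain, fun = fun,
         n_perturbations = n_used, n_missing = n_missing, m = m,
         higher_is_more_robust = higher_is_more_robust, slice_R = slice_R,
         degenerate = degenerate),
    class = "robustness_result"
  )
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "<robustness %s  R=%.6g  sem=%s  n=%d (missing %d)%s%s>\n",
    x$metric, x$R,
    if (is.na(x$sem)) "NA" else sprintf("%.3g", x$sem),
    x$n_perturbations, x$n_missing,
    if (is.na(x$m)) "" else sprintf("  m=%.4g", x$m),
    if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

variance_fun <- function(var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  if (var_type == "sample") {
    stats::var
  } else {
    function(x) stats::var(x) * (length(x) - 1) / length(x)
  }
}

drop_missing <- function(values) {
  n_missing <- sum(is.na(values))
  list(values = values[!is.na(values)], n_missing = n_missing)
}

#' Coefficient-of-variation robustness
#'
#' R = sigma / mean of the function values over the perturbation space.
#' Lower is more robust (`higher_is_more_robust` is FALSE in the result).
#' The CV is dimensionless but known to misbehave for means between 0 and 1,
#' where it conflates low mean with high dispersion.
#'
#' @param values Numeric function values over the perturbations (NA dropped,
#'   counted in `n_missing`).
#' @param var_type "sample" (denominator n-1, default) or "population".
#' @return A `robustness_result`.
#' @export
cv_robustness <- function(values, var_type = "sample") {
  d <- drop_missing(values)
  v <- d$values
  if (length(v) < 2L) stop("CV needs >= 2 non-missing values")
  xbar <- mean(v)
  if (xbar == 0) {
    return(new_robustness_result("cv", NA_real_, FALSE, length(v),
                                 d$n_missing, degenerate = TRUE))
  }
  sigma <- sqrt(variance_fun(var_type)(v))
  new_robustness_result("cv", sigma / xbar, FALSE, length(v), d$n_missing)
}

#' Kitano-style control-ratio robustness
#'
#' The frequency-weighted sum of the ratios of the perturbed function values
#' to the control value:
#' \deqn{R = \sum_p \psi(p)\, f(p) / f(0)}
#' With equal frequencies summing to 1 this is the mean ratio; R = 1 when
#' every perturbed value equals the control, and functions performing better
#' than the control push R above 1. Higher is read as more robust. Symmetric
#' deviations about the control cancel (e.g. values {1, 3} against control 2
#' give exactly 1), which is the score's central weakness; see
#' [criteria_audit()].
#'
#' @param values Function values over the perturbations.
#' @param control_value Function value in the control condition (nonzero).
#' @param weights Optional positive frequencies, one per value; default
#'   equal, summing to 1.
#' @param normalize_weights If TRUE (default), weights must sum to 1 within
#'   1e-9 (after NA-dropping they are renormalized over the used values). If
#'   FALSE, weights are taken as fixed per-perturbation frequencies and the
#'   weighted sum is returned as-is, which makes R scale with the number of
#'   perturbations tested.
#' @return A `robustness_result`.
#' @export
kitano_robustness <- function(values, control_value, weights = NULL,
                              normalize_weights = TRUE) {
  if (missing(control_value) || is.null(control_value) || is.na(control_value)) {
    stop("a control condition value is needed for the Kitano-style score")
  }
  if (control_value == 0) stop("control value must be nonzero")
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  if (length(weights) != length(values)) {
    stop("weights must match values in length")
  }
  if (any(weights <= 0, na.rm = TRUE)) stop("weights must be positive")
  keep <- !is.na(values)
  n_missing <- sum(!keep)
  v <- values[keep]
  w <- weights[keep]
  if (length(v) < 1L) stop("no non-missing values")
  if (normalize_weights) {
    if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
    w <- w / sum(w)
  }
  R <- sum(w * v / control_value)
  new_robustness_result("kitano", R, TRUE, length(v), n_missing)
}

#' Negative mean-normalized Fano-factor robustness
#'
#' For function values x over the perturbation space, the Fano factor is
#' sigma^2 / mean(x); robustness is its negative after normalization by `m`,
#' the pooled mean of the same function across all strains in the analyzed
#' dataset:
#' \deqn{R = -\frac{\sigma^2 / \bar{x}}{m}}
#' R has an upper bound of 0 (perfect stability, attained iff the sample
#' variance is zero) and is invariant to positive rescaling of the data when
#' m is recomputed, making scores comparable between functions measured on
#' different scales. Because of m, R is always relative to the dataset it
#' was computed in.
#'
#' @param values Function values over the perturbations (NA dropped).
#' @param m Normalization mean (> 0); see [normalization_mean()].
#' @param var_type "sample" (default) or "population" variance.
#' @return A `robustness_result` with `m` recorded.
#' @export
fano_robustness <- function(values, m, var_type = "sample") {
  d <- drop_missing(values)
  v <- d$values
  if (length(v) < 2L) stop("Fano robustness needs >= 2 non-missing values")
  xbar <- mean(v)
  if (xbar <= 0 || is.na(m) || m <= 0) {
    return(new_robustness_result("fano", NA_real_, TRUE, length(v),
                                 d$n_missing, m = m, degenerate = TRUE))
  }
  fano <- variance_fun(var_type)(v) / xbar
  new_robustness_result("fano", -fano / m, TRUE, length(v), d$n_missing,
                        m = m)
}

#' Pooled normalization mean for a function
#'
#' The mean of all non-missing values of one function pooled over every
#' strain, perturbation and replicate in the dataset (count-weighted, so
#' unbalanced missingness is handled naturally).
#'
#' @param function_table A `function_table` data frame.
#' @param fun Function id (e.g. "mu_max").
#' @return The pooled mean m.
#' @export
normalization_mean <- function(function_table, fun) {
  v <- function_table$value[function_table$fun == fun]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no non-missing values for function ", fun)
  mean(v)
}

#' Robustness with a replicate-slice standard error
#'
#' The headline robustness of one strain x function: R is computed
#' separately on each replicate slice (replicate r's values across all
#' perturbations of the space), and the mean of the slice scores is reported
#' with their standard error of the mean (n = number of usable slices).
#' Perturbations missing within a slice are dropped from that slice and
#' counted. With `pooled = TRUE` all replicates enter one computation and no
#' SEM is available.
#'
#' @param function_table A `function_table`.
#' @param strain Strain name.
#' @param fun Function id.
#' @param space A [perturbation_space()].
#' @param metric "fano" (default), "cv" or "kitano".
#' @param m Normalization mean for the Fano metric; defaults to
#'   [normalization_mean()] over the whole table (all strains).
#' @param var_type "sample" or "population" variance.
#' @param pooled Pool replicates instead of slicing (no SEM).
#' @return A `robustness_result` carrying the slice scores in `slice_R`.
#' @export
robustness_with_sem <- function(function_table, strain, fun, space,
                                metric = c("fano", "cv", "kitano"),
                                m = NULL, var_type = "sample",
                                pooled = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(space, "perturbation_space"))
  if (metric == "fano" && is.null(m)) {
    m <- normalization_mean(function_table, fun)
  }
  sub <- function_table[function_table$strain == strain &
                          function_table$fun == fun &
                          function_table$condition_id %in% space$conditions, ,
                        drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for ", strain, " / ", fun)
  control_of <- function(slice) {
    if (is.null(space$control)) {
      stop("a control condition is needed for the Kitano-style score")
    }
    cv <- slice$value[slice$condition_id == space$control]
    if (length(cv) == 0L || all(is.na(cv))) return(NA_real_)
    mean(cv, na.rm = TRUE)
  }
  score <- function(slice) {
    vals <- slice$value[match(space$conditions, slice$condition_id)]
    switch(metric,
      fano = fano_robustness(vals, m = m, var_type = var_type),
      cv = cv_robustness(vals, var_type = var_type),
      kitano = kitano_robustness(vals, control_of(slice),
                                 weights = as.numeric(space$weights))
    )
  }
  if (pooled) {
    res <- score_pooled(sub, space, metric, m, var_type, control_of)
  } else {
    reps <- sort(unique(sub$replicate))
    slice_res <- list()
    for (r in reps) {
      slice <- sub[sub$replicate == r, , drop = FALSE]
      usable <- sum(!is.na(slice$value[slice$condition_id %in% space$conditions]))
      if (usable < 2L) next
      if (metric == "kitano" && is.na(control_of(slice))) next
      slice_res[[as.character(r)]] <- score(slice)
    }
    if (length(slice_res) == 0L) stop("no usable replicate slice for ",
                                      strain, " / ", fun)
    slice_R <- vapply(slice_res, function(x) x$R, numeric(1))
    n_used <- max(vapply(slice_res, function(x) x$n_perturbations, integer(1)))
    res <- new_robustness_result(
      metric, mean(slice_R), slice_res[[1]]$higher_is_more_robust,
      n_used, length(space$conditions) - n_used,
      sem = if (length(slice_R) >= 2L) {
        stats::sd(slice_R) / sqrt(length(slice_R))
      } else NA_real_,
      m = if (metric == "fano") m else NA_real_,
      slice_R = slice_R
    )
  }
  res$strain <- strain
  res$fun <- fun
  res
}

score_pooled <- function(sub, space, metric, m, var_type, control_of) {
  vals <- sub$value[sub$condition_id %in% space$conditions]
  res <- switch(metric,
    fano = fano_robustness(vals, m = m, var_type = var_type),
    cv = cv_robustness(vals, var_type = var_type),
    kitano = {
      w <- as.numeric(space$weights[match(
        sub$condition_id[sub$condition_id %in% space$conditions],
        space$conditions)])
      kitano_robustness(vals, control_of(sub), weights = w / sum(w))
    })
  n_used <- length(unique(sub$condition_id[!is.na(sub$value)]))
  res$n_perturbations <- n_used
  res$n_missing <- length(space$conditions) - n_used
  res
}

#' Robustness for every strain x function
#'
#' Applies [robustness_with_sem()] to each strain and function present in
#' the table and returns a tidy data frame (the slice scores travel along in
#' a list column for downstream significance testing).
#'
#' @inheritParams robustness_with_sem
#' @param funs Functions to score; default all present.
#' @return Data frame with columns strain, fun, metric, R, sem,
#'   n_perturbations, n_missing, m, higher_is_more_robust, slice_R (list).
#' @export
robustness_table <- function(function_table, space,
                             metric = c("fano", "cv", "kitano"),
                             funs = NULL, var_type = "sample") {
  metric <- match.arg(metric)
  strains <- unique(function_table$strain)
  if (is.null(funs)) funs <- unique(function_table$fun)
  rows <- list()
  for (f in funs) {
    m <- if (metric == "fano") normalization_mean(function_table, f) else NULL
    for (s in strains) {
      res <- robustness_with_sem(function_table, s, f, space, metric = metric,
                                 m = m, var_type = var_type)
      rows[[paste(s, f)]] <- data.frame(
        strain = s, fun = f, metric = metric, R = res$R, sem = res$sem,
        n_perturbations = res$n_perturbations, n_missing = res$n_missing,
        m = res$m, higher_is_more_robust = res$higher_is_more_robust,
        stringsAsFactors = FALSE)
      rows[[paste(s, f)]]$slice_R <- I(list(res$slice_R))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Criteria audit
# ---------------------------------------------------------------------------

#' Monte-Carlo audit of a robustness metric against four criteria
#'
#' A robustness score should satisfy: (1) testing more perturbations should
#' not change R, only its statistical significance; (2) positive and
#' negative deviations from the reference level should both lower R; (3) a
#' higher (orientation-corrected) R should correspond to genuinely lower
#' dispersion; (4) R should be dimensionless and comparable across functions
#' measured at different orders of magnitude.
#'
#' Each criterion is probed by simulation with `n_reps` replicates:
#' \describe{
#'   \item{1}{i.i.d. multiplicative perturbation effects; E[R] over a space
#'     of 8 versus 32 perturbations must agree within 5% relative. The
#'     Kitano-style score is evaluated in its frequency-weighted-sum form
#'     with the per-perturbation frequency fixed when the baseline space is
#'     defined, so its value scales with the number of perturbations
#'     assayed.}
#'   \item{2}{paired datasets {c-d, c+d} versus {c, c}: the dispersed pair
#'     must score strictly less robust. For the Kitano score the symmetric
#'     deviations cancel (values {1, 3} against control 2 give exactly 1.0),
#'     which the audit demonstrates.}
#'   \item{3}{one-sided degradation effects at two dispersion widths; the
#'     lower-dispersion dataset must be ranked more robust in >= 95% of
#'     replicates (after orientation).}
#'   \item{4}{(a) rescaling all values by k in {1e-3, 1, 1e3} (normalization
#'     mean and control rescaled along) must leave R unchanged to 1e-9
#'     relative; (b) under Poisson-like dispersion (variance proportional to
#'     the mean), a dataset with a lower variance-to-mean ratio but mean in
#'     (0, 1) must still be ranked more robust than one with a higher ratio
#'     and mean in (1, 10), in >= 95% of replicates. The CV fails (b): it
#'     divides by the mean once, so small-mean functions look spuriously
#'     fragile.}
#' }
#'
#' @param metric "fano", "cv" or "kitano".
#' @param n_reps Monte-Carlo replicates per criterion (default 1000).
#' @param seed RNG seed.
#' @return An object of class `criteria_audit`: a data frame with columns
#'   criterion, description, statistic, threshold, pass, plus attributes
#'   `metric` and `examples`.
#' @export
criteria_audit <- function(metric = c("fano", "cv", "kitano"),
                           n_reps = 1000, seed = 1) {
  metric <- match.arg(metric)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # oriented score: larger = more robust, whatever the metric's native scale
  oriented <- function(R, higher) if (higher) R else -R

  # m (Fano normalization) defaults to the dataset's own mean; probes that
  # compare two datasets representing strains of the same function pass the
  # pooled mean of both, as normalization_mean() would.
  score <- function(values, control = NULL, weights = NULL,
                    normalize = TRUE, m = mean(values)) {
    switch(metric,
      fano = fano_robustness(values, m = m),
      cv = cv_robustness(values),
      kitano = kitano_robustness(values, control, weights = weights,
                                 normalize_weights = normalize)
    )
  }

  # criterion 1: size independence under i.i.d. effects
  n1 <- 8L; n2 <- 32L
  c0 <- 2
  r_small <- numeric(n_reps); r_large <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    v1 <- c0 * stats::rlnorm(n1, meanlog = 0.1, sdlog = 0.25)
    v2 <- c0 * stats::rlnorm(n2, meanlog = 0.1, sdlog = 0.25)
    if (metric == "kitano") {
      psi0 <- 1 / n1  # frequency fixed when the baseline space was defined
      r_small[i] <- score(v1, control = c0, weights = rep(psi0, n1),
                          normalize = FALSE)$R
      r_large[i] <- score(v2, control = c0, weights = rep(psi0, n2),
                          normalize = FALSE)$R
    } else {
      r_small[i] <- score(v1)$R
      r_large[i] <- score(v2)$R
    }
  }
  drift <- abs(mean(r_large) - mean(r_small)) /
    max(abs(mean(r_small)), 1e-12)
  crit1 <- list(stat = drift, threshold = 0.05, pass = drift <= 0.05)

  # criterion 2: symmetric deviations must penalize
  penalized <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cc <- stats::runif(1, 1, 10)
    dd <- stats::runif(1, 0.1, 0.9) * cc
    disp <- c(cc - dd, cc + dd)
    flat <- c(cc, cc)
    if (metric == "kitano") {
      ra <- score(disp, control = cc)$R
      rb <- score(flat, control = cc)$R
      penalized[i] <- oriented(ra, TRUE) < oriented(rb, TRUE)
    } else {
      mm <- mean(c(disp, flat))
      ra <- score(disp, m = mm); rb <- score(flat, m = mm)
      penalized[i] <- oriented(ra$R, ra$higher_is_more_robust) <
        oriented(rb$R, rb$higher_is_more_robust)
    }
  }
  frac2 <- mean(penalized)
  crit2 <- list(stat = frac2, threshold = 0.99, pass = frac2 >= 0.99)
  # the canonical cancellation example, recorded alongside the verdict
  kit13 <- kitano_robustness(c(1, 3), control_value = 2)$R

  # criterion 3: orientation-corrected ranking under increasing dispersion
  n3 <- 12L
  ranked3 <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cc <- stats::runif(1, 1, 10)
    lo <- cc * stats::runif(n3, 0.9, 1)    # narrow one-sided degradation
    hi <- cc * stats::runif(n3, 0.6, 1)    # wide one-sided degradation
    if (metric == "kitano") {
      ra <- score(lo, control = cc)$R
      rb <- score(hi, control = cc)$R
      ranked3[i] <- ra > rb
    } else {
      mm <- mean(c(lo, hi))
      ra <- score(lo, m = mm); rb <- score(hi, m = mm)
      ranked3[i] <- oriented(ra$R, ra$higher_is_more_robust) >
        oriented(rb$R, rb$higher_is_more_robust)
    }
  }
  frac3 <- mean(ranked3)
  crit3 <- list(stat = frac3, threshold = 0.95, pass = frac3 >= 0.95)

  # criterion 4a: invariance under unit rescaling
  rel_change <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cc <- stats::runif(1, 1, 10)
    v <- cc * stats::rlnorm(10, sdlog = 0.2)
    base <- if (metric == "kitano") score(v, control = cc)$R else score(v)$R
    worst <- 0
    for (k in c(1e-3, 1e3)) {
      rk <- if (metric == "kitano") {
        score(k * v, control = k * cc)$R
      } else {
        score(k * v)$R
      }
      worst <- max(worst, abs(rk - base) / max(abs(base), 1e-300))
    }
    rel_change[i] <- worst
  }
  stat4a <- max(rel_change)

  # criterion 4b: dispersion ranking across magnitude regimes under
  # Poisson-like (variance ~ mean) noise
  n4 <- 20L
  phi_lo <- 0.005; phi_hi <- 0.02
  ranked4 <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    mu_a <- stats::runif(1, 0.2, 1)    # small-mean regime, low dispersion
    mu_b <- stats::runif(1, 1, 10)     # large-mean regime, high dispersion
    a <- pmax(mu_a + sqrt(phi_lo * mu_a) * stats::rnorm(n4), 1e-6)
    b <- pmax(mu_b + sqrt(phi_hi * mu_b) * stats::rnorm(n4), 1e-6)
    if (metric == "kitano") {
      ra <- score(a, control = mu_a)$R
      rb <- score(b, control = mu_b)$R
      ranked4[i] <- ra > rb
    } else {
      mm <- mean(c(a, b))  # the two datasets are strains of one function
      ra <- score(a, m = mm); rb <- score(b, m = mm)
      ranked4[i] <- oriented(ra$R, ra$higher_is_more_robust) >
        oriented(rb$R, rb$higher_is_more_robust)
    }
  }
  frac4 <- mean(ranked4)
  crit4 <- list(stat = min(1 - stat4a, frac4),
                pass = stat4a <= 1e-9 && frac4 >= 0.95)

  out <- data.frame(
    criterion = 1:4,
    description = c(
      "R stable as the number of tested perturbations grows",
      "symmetric deviations from the reference lower R",
      "higher (oriented) R tracks genuinely lower dispersion",
      "dimensionless; comparable across orders of magnitude"
    ),
    statistic = c(crit1$stat, crit2$stat, crit3$stat, frac4),
    threshold = c(0.05, 0.99, 0.95, 0.95),
    pass = c(crit1$pass, crit2$pass, crit3$pass, crit4$pass),
    stringsAsFactors = FALSE
  )
  attr(out, "metric") <- metric
  attr(out, "examples") <- list(
    kitano_symmetric_example = kit13,
    rescale_max_rel_change = stat4a,
    size_drift = crit1$stat
  )
  class(out) <- c("criteria_audit", "data.frame")
  out
}

#' @export
print.criteria_audit <- function(x, ...) {
  cat("Criteria audit for metric:", attr(x, "metric"), "\n")
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  cat(if (all(x$pass)) "-> meets all criteria\n" else
    paste0("-> violates criteria ",
           paste(x$criterion[!x$pass], collapse = ", "), "\n"))
  invisible(x)
}
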