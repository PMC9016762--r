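# Strain-pairwise significance testing of robustness differences and
# robustness-performance trade-off assembly.

#' Pairwise strain comparison of replicate-slice robustness
#'
#' For each function and each pair of strains, an unpaired two-sided t test
#' on the replicate-slice robustness scores (Welch by default; the
#' equal-variance Student variant via `var_equal = TRUE`), with
#' Holm-Bonferroni adjustment applied within each function's family of
#' strain pairs.
#'
#' Degenerate inputs are handled explicitly rather than erroring: when both
#' groups have zero variance, equal means give t = 0 and p = 1, unequal
#' means give p = 0 as the limiting value, and the row is flagged
#' `degenerate`.
#'
#' @param robustness A data frame from [robustness_table()] (needs columns
#'   strain, fun and the list column slice_R), or a data frame with columns
#'   strain, fun, replicate, R.
#' @param var_equal FALSE (Welch, default) or TRUE (Student).
#' @return Data frame with one row per function x strain pair: fun,
#'   strain_a, strain_b, n_a, n_b, t, df, p_value, p_adjusted, degenerate.
#' @export
pairwise_strain_test <- function(robustness, var_equal = FALSE) {
  slices <- extract_slices(robustness)
  funs <- unique(slices$fun)
  rows <- list()
  for (f in funs) {
    sub <- slices[slices$fun == f, , drop = FALSE]
    strains <- unique(sub$strain)
    if (length(strains) < 2L) next
    pairs <- utils::combn(strains, 2, simplify = FALSE)
    fam <- lapply(pairs, function(pr) {
      x <- sub$R[sub$strain == pr[1]]
      y <- sub$R[sub$strain == pr[2]]
      tt <- welch_or_student(x, y, var_equal = var_equal)
      data.frame(fun = f, strain_a = pr[1], strain_b = pr[2],
                 n_a = length(x), n_b = length(y), t = tt$t, df = tt$df,
                 p_value = tt$p, degenerate = tt$degenerate,
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, fam)
    fam$p_adjusted <- holm_bonferroni(fam$p_value)
    rows[[f]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

extract_slices <- function(robustness) {
  if (!is.null(robustness$slice_R)) {
    rows <- lapply(seq_len(nrow(robustness)), function(i) {
      r <- robustness$slice_R[[i]]
      if (is.null(r) || length(r) == 0L) return(NULL)
      data.frame(strain = robustness$strain[i], fun = robustness$fun[i],
                 replicate = seq_along(r), R = as.numeric(r),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (all(c("strain", "fun", "R") %in% names(robustness))) {
    return(robustness)
  }
  stop("robustness input needs either a slice_R list column or ",
       "(strain, fun, R) columns")
}

# Two-sided unpaired t test with explicit degenerate handling; delegates to
# stats::t.test in the regular case.
welch_or_student <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 replicate-slice values")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal, paired = FALSE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error control: order the p-values ascending,
#' multiply the i-th by (n - i + 1), enforce monotonicity cumulatively and
#' cap at 1. Adjusted values never fall below the raw ones and the result is
#' invariant to the input order.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Robustness-performance trade-off table
#'
#' Pairs, for every strain x function, the mean performance (function value
#' averaged over all perturbations and replicates of the same records that
#' entered the robustness computation, missing dropped) with the robustness
#' score, each with its SEM (performance SEM over replicate-slice means).
#' The output is tidy and ready for scatter plotting of trade-offs.
#'
#' @param function_table A `function_table`.
#' @param robustness A data frame from [robustness_table()].
#' @param space Optional [perturbation_space()] restricting the conditions
#'   used for the performance mean (defaults to all conditions present,
#'   which must match what robustness used).
#' @return Data frame: strain, fun, performance, performance_sem,
#'   robustness, robustness_sem, n_perturbations.
#' @export
tradeoff_table <- function(function_table, robustness, space = NULL) {
  rows <- list()
  for (i in seq_len(nrow(robustness))) {
    s <- robustness$strain[i]
    f <- robustness$fun[i]
    sub <- function_table[function_table$strain == s &
                            function_table$fun == f, , drop = FALSE]
    if (!is.null(space)) {
      sub <- sub[sub$condition_id %in% space$conditions, , drop = FALSE]
    }
    v <- sub$value[!is.na(sub$value)]
    if (length(v) == 0L) {
      warning("no performance values for ", s, " / ", f, "; omitted")
      next
    }
    rep_means <- tapply(sub$value, sub$replicate,
                        function(x) mean(x, na.rm = TRUE))
    rep_means <- rep_means[!is.na(rep_means)]
    perf_sem <- if (length(rep_means) >= 2L) {
      stats::sd(rep_means) / sqrt(length(rep_means))
    } else NA_real_
    rows[[paste(s, f)]] <- data.frame(
      strain = s, fun = f, performance = mean(v), performance_sem = perf_sem,
      robustness = robustness$R[i], robustness_sem = robustness$sem[i],
      n_perturbations = robustness$n_perturbations[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
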