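# Shared fixture builders: tiny layouts, wells and function tables built in
# code at test time.

tiny_layout <- function(n_strains = 1, n_cond = 2, n_rep = 3,
                        control = TRUE) {
  strains <- paste0("S", seq_len(n_strains))
  conds <- paste0("cond", seq_len(n_cond))
  grid <- expand.grid(replicate = seq_len(n_rep), condition_id = conds,
                      strain = strains, stringsAsFactors = FALSE)
  grid$well_id <- paste0("W", seq_len(nrow(grid)))
  plate_layout(grid$well_id, grid$strain, grid$condition_id, grid$replicate,
               is_control = control & grid$condition_id == "cond1")
}

# deterministic exponential-phase well: v(t) = v0 * exp(mu t) + blank
exp_well <- function(mu = 0.3, v0 = 0.02, times = seq(0, 10, length.out = 50),
                     blank = 0, well_id = "A1", signal_kind = "OD") {
  ts_well(well_id, times, v0 * exp(mu * times) + blank, signal_kind)
}

# function table from a named list: values[[strain]] is a numeric vector over
# conditions (one replicate), or a matrix conditions x replicates
make_function_table <- function(values, fun = "mu_max",
                                conditions = NULL) {
  rows <- list()
  for (s in names(values)) {
    v <- values[[s]]
    if (is.null(dim(v))) v <- matrix(v, ncol = 1)
    conds <- if (is.null(conditions)) paste0("p", seq_len(nrow(v))) else conditions
    for (r in seq_len(ncol(v))) {
      rows[[paste(s, r)]] <- data.frame(
        strain = s, fun = fun, condition_id = conds,
        replicate = r, value = v[, r], stringsAsFactors = FALSE)
    }
  }
  validate_function_table(do.call(rbind, rows))
}

# brute-force oracles, written from the definitions, independent of the
# package implementations
brute_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
brute_var <- function(x) {
  m <- brute_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}
brute_cv <- function(x) sqrt(brute_var(x)) / brute_mean(x)
brute_kitano <- function(x, control) brute_mean(x / control)
brute_fano_R <- function(x, m) -(brute_var(x) / brute_mean(x)) / m

brute_holm <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_max <- 0
  for (i in seq_len(n)) {
    val <- min((n - i + 1) * p[ord[i]], 1)
    running_max <- max(running_max, val)
    adj[ord[i]] <- running_max
  }
  adj
}

# all permutations of 1..n (n <= 5 here, at most 120)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_perms(n - 1)
    for (r in rest) {
      tail <- setdiff(seq_len(n), i)[r]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}

brute_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- brute_var(x); vy <- brute_var(y)
  se2 <- vx / nx + vy / ny
  t <- (brute_mean(x) - brute_mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}
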