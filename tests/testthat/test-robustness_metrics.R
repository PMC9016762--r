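# The three robustness metrics, their invariants, and the criteria audit.

test_that("CV matches its hand computation and handles edge cases", {
  expect_equal(cv_robustness(c(2, 4, 6))$R, 0.5)  # sample sd 2, mean 4
  expect_equal(cv_robustness(c(3, 3, 3))$R, 0)
  # sigma > mean gives CV > 1
  expect_gt(cv_robustness(c(0.1, 0.1, 5))$R, 1)
  zero_mean <- cv_robustness(c(-1, 1))
  expect_true(is.na(zero_mean$R))
  expect_true(zero_mean$degenerate)
  expect_error(cv_robustness(c(1, NA)), ">= 2 non-missing")
})

test_that("Kitano score is the weighted mean ratio to the control", {
  expect_equal(kitano_robustness(c(2, 2, 2), 2)$R, 1)
  # symmetric deviations cancel: the canonical counterexample
  expect_identical(kitano_robustness(c(1, 3), 2)$R, 1)
  expect_gt(kitano_robustness(c(2.5, 3, 2.2), 2)$R, 1)
  expect_error(kitano_robustness(c(1, 2), 0), "nonzero")
  expect_error(kitano_robustness(c(1, 2)), "control")
  expect_error(kitano_robustness(c(1, 2), 2, weights = c(0.5, 0.6)),
               "sum to 1")
  # unnormalized frequency-sum form scales with the number of perturbations
  r8 <- kitano_robustness(rep(2, 8), 2, weights = rep(1 / 8, 8),
                          normalize_weights = FALSE)$R
  r16 <- kitano_robustness(rep(2, 16), 2, weights = rep(1 / 8, 16),
                           normalize_weights = FALSE)$R
  expect_equal(r16 / r8, 2)
})

test_that("Fano robustness matches hand computation and pools m correctly", {
  # strain A {1,2,3}, strain B {2,2,2}; pooled m = 2
  ft <- make_function_table(list(A = c(1, 2, 3), B = c(2, 2, 2)))
  m <- normalization_mean(ft, "mu_max")
  expect_equal(m, 2)
  expect_equal(fano_robustness(c(1, 2, 3), m)$R, -0.25)  # var 1, mean 2
  expect_equal(fano_robustness(c(2, 2, 2), m)$R, 0)
  # single strain: m is that strain's mean
  ft1 <- make_function_table(list(A = c(1, 2, 3)))
  expect_equal(normalization_mean(ft1, "mu_max"), 2)
  # unbalanced missingness: count-weighted pooled mean
  ft2 <- make_function_table(list(A = c(1, 2, NA), B = c(4, 4, 4)))
  expect_equal(normalization_mean(ft2, "mu_max"), mean(c(1, 2, 4, 4, 4)))
  expect_error(normalization_mean(ft2, "cdw"), "no non-missing")
})

test_that("Fano R is bounded above by 0, equal iff zero dispersion", {
  set.seed(101)
  for (i in 1:50) {
    v <- rlnorm(sample(3:12, 1), meanlog = runif(1, -2, 2), sdlog = 1)
    r <- fano_robustness(v, m = mean(v))$R
    if (var(v) > 0) expect_lt(r, 0) else expect_equal(r, 0)
  }
  expect_equal(fano_robustness(rep(7, 5), m = 7)$R, 0)
})

test_that("CV and mean-normalized Fano are invariant to positive rescaling", {
  set.seed(5)
  v <- rlnorm(10, sdlog = 0.4)
  for (k in c(1e-3, 1, 1e3, 17.3)) {
    expect_equal(fano_robustness(k * v, m = mean(k * v))$R,
                 fano_robustness(v, m = mean(v))$R, tolerance = 1e-12)
    expect_equal(cv_robustness(k * v)$R, cv_robustness(v)$R,
                 tolerance = 1e-12)
  }
})

test_that("duplicating every perturbation leaves Fano R almost unchanged", {
  set.seed(9)
  v <- rlnorm(10, sdlog = 0.3)
  m <- mean(v)
  r1 <- fano_robustness(v, m)$R
  r2 <- fano_robustness(c(v, v), m)$R
  # exact with population variance; sample variance drifts O(1/n)
  expect_equal(fano_robustness(c(v, v), m, var_type = "population")$R,
               fano_robustness(v, m, var_type = "population")$R,
               tolerance = 1e-12)
  n <- length(v)
  expect_equal(r2 / r1, ((n - 1) / n) * (2 * n) / (2 * n - 1),
               tolerance = 1e-12)
  expect_equal(r2, r1, tolerance = 0.06)
})

test_that("all three metrics match brute-force formulas on short vectors", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    v <- as.numeric(sample(1:9, n, replace = TRUE))
    ctrl <- as.numeric(sample(1:9, 1))
    m <- mean(v)
    expect_equal(cv_robustness(v)$R, brute_cv(v), tolerance = 1e-12)
    expect_equal(kitano_robustness(v, ctrl)$R, brute_kitano(v, ctrl),
                 tolerance = 1e-12)
    expect_equal(fano_robustness(v, m)$R, brute_fano_R(v, m),
                 tolerance = 1e-12)
  }
})

test_that("perturbation space validates weights and control", {
  expect_error(perturbation_space("p1"), ">= 2")
  expect_error(perturbation_space(c("p1", "p2"), weights = c(0.5, 0.4)),
               "sum to 1")
  expect_error(perturbation_space(c("p1", "p2"), weights = c(1.1, -0.1)),
               "positive")
  sp <- perturbation_space(c("p1", "p2", "p3"), control = "p1")
  expect_equal(unname(sp$weights), rep(1 / 3, 3))
})

test_that("replicate-slice R and SEM follow the slice scheme", {
  conds <- paste0("p", 1:5)
  # three identical replicate slices: sem 0
  vals <- matrix(rep(c(1, 2, 3, 2, 2), 3), ncol = 3)
  ft <- make_function_table(list(A = vals), conditions = conds)
  sp <- perturbation_space(conds)
  res <- robustness_with_sem(ft, "A", "mu_max", sp)
  expect_equal(res$sem, 0)
  expect_length(res$slice_R, 3)
  expect_equal(res$n_perturbations + res$n_missing, 5)

  # slices engineered to give R = {-0.2, -0.3, -0.4}: slice r holds
  # {1 - d_r, 1, 1 + d_r} over three conditions, so var = d_r^2, mean = 1,
  # pooled m = 1 and R_r = -d_r^2
  d <- sqrt(c(0.2, 0.3, 0.4))
  eng <- sapply(d, function(dr) c(1 - dr, 1, 1 + dr))
  ft_eng <- make_function_table(list(A = eng), conditions = paste0("q", 1:3))
  res_eng <- robustness_with_sem(ft_eng, "A", "mu_max",
                                 perturbation_space(paste0("q", 1:3)))
  expect_equal(unname(res_eng$slice_R), c(-0.2, -0.3, -0.4),
               tolerance = 1e-12)
  expect_equal(res_eng$R, -0.3, tolerance = 1e-12)
  expect_equal(res_eng$sem, 0.05773503, tolerance = 1e-6)

  # one replicate entirely missing: 2 usable slices
  vals2 <- vals
  vals2[, 3] <- NA
  ft2 <- make_function_table(list(A = vals2), conditions = conds)
  res2 <- robustness_with_sem(ft2, "A", "mu_max", sp)
  expect_length(res2$slice_R, 2)
  expect_false(is.na(res2$sem))
  # a single usable slice: sem missing
  vals3 <- vals
  vals3[, 2:3] <- NA
  ft3 <- make_function_table(list(A = vals3), conditions = conds)
  res3 <- robustness_with_sem(ft3, "A", "mu_max", sp)
  expect_true(is.na(res3$sem))
})

test_that("slice values agree with direct metric computation", {
  conds <- paste0("p", 1:6)
  set.seed(77)
  vals <- matrix(rlnorm(18, meanlog = 0, sdlog = 0.3), ncol = 3)
  ft <- make_function_table(list(A = vals, B = vals * 0.5),
                            conditions = conds)
  sp <- perturbation_space(conds, control = "p1")
  m <- normalization_mean(ft, "mu_max")
  res <- robustness_with_sem(ft, "A", "mu_max", sp, metric = "fano")
  for (r in 1:3) {
    expect_equal(unname(res$slice_R[r]),
                 brute_fano_R(vals[, r], m), tolerance = 1e-12)
  }
  res_cv <- robustness_with_sem(ft, "A", "mu_max", sp, metric = "cv")
  expect_equal(unname(res_cv$slice_R[2]), brute_cv(vals[, 2]),
               tolerance = 1e-12)
  res_k <- robustness_with_sem(ft, "A", "mu_max", sp, metric = "kitano")
  expect_equal(unname(res_k$slice_R[1]),
               brute_kitano(vals[, 1], vals[1, 1]), tolerance = 1e-12)
})

test_that("criteria audit reproduces the qualitative metric verdicts", {
  fano <- criteria_audit("fano", n_reps = 300, seed = 4)
  expect_true(all(fano$pass))
  cv <- criteria_audit("cv", n_reps = 300, seed = 4)
  expect_true(all(cv$pass[1:3]))
  expect_false(cv$pass[4])
  kit <- criteria_audit("kitano", n_reps = 300, seed = 4)
  expect_false(kit$pass[1])
  expect_false(kit$pass[2])
  expect_true(kit$pass[3])
  expect_false(kit$pass[4])
  expect_identical(attr(kit, "examples")$kitano_symmetric_example, 1)
})
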