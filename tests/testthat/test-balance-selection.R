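test_that("balance_score matches the normalized log-contrast definition", {
  expect_equal(balance_score(c(a = exp(1) * 3, b = 3), "a", "b"), sqrt(1 / 2))
  # equal parts give zero
  expect_equal(balance_score(c(a = 2, b = 2, c = 2, d = 2), c("a", "b"), c("c", "d")), 0)
  # scale invariance (pre-closure constant) and part-permutation invariance
  set.seed(20)
  gp <- random_composition()
  n <- c("GP3", "GP7", "GP12"); d <- c("GP20", "GP31")
  b0 <- balance_score(gp, n, d)
  expect_equal(balance_score(gp * 7.3, n, d), b0, tolerance = 1e-12)
  expect_equal(balance_score(gp, rev(n), d), b0)
  # swap antisymmetry
  expect_equal(balance_score(gp, d, n), -b0)
  # general p, q normalization against a direct computation
  direct <- sqrt(3 * 2 / 5) * (mean(log(gp[n])) - mean(log(gp[d])))
  expect_equal(b0, direct)
  expect_error(balance_score(gp, c("GP1", "GP2"), c("GP2", "GP3")), "disjoint")
  gp0 <- gp; gp0["GP3"] <- 0
  expect_error(balance_score(gp0, n, d), "zero_replace")
})

test_that("zero_replace produces positive closed vectors and preserves ratios", {
  gp <- close_to_percent(c(rep(1, 44), 0, 0))
  # identity on positive input
  pos <- close_to_percent(runif(46, 0.1, 2))
  expect_identical(zero_replace(pos), pos)
  ps <- zero_replace(gp, "pseudocount")
  expect_true(all(ps > 0))
  expect_lt(abs(sum(ps) - 100), 1e-9)
  delta <- min(gp[gp > 0]) / 2
  expect_equal(unname(ps[45]), 100 * delta / (sum(gp) + 2 * delta))
  mult <- zero_replace(gp, "multiplicative")
  expect_true(all(mult > 0))
  expect_lt(abs(sum(mult) - 100), 1e-9)
  # ratios among originally positive cells exactly preserved
  r0 <- gp[1:44] / gp[2]
  expect_equal(mult[1:44] / mult[2], r0, tolerance = 1e-12)
  expect_error(zero_replace(rep(0, 46)), "all-zero")
})

test_that("evaluate_candidate returns the adjusted in-sample AUC", {
  set.seed(21)
  y <- rep(0:1, each = 50)
  expect_equal(as.numeric(evaluate_candidate(rep(1, 100), y)), 0.5)
  sep <- evaluate_candidate(y + 0.0, y)
  expect_equal(as.numeric(sep), 1.0)
  expect_true(isTRUE(attr(sep, "separation")))
  # informative score beats noise
  s <- y + rnorm(100, 0, 0.8)
  expect_gt(evaluate_candidate(s, y), 0.7)
  expect_error(evaluate_candidate(rnorm(10), rep(1, 10)), "both")
})

test_that("planted pair criterion exceeds random pairs", {
  set.seed(22)
  d <- planted_pair_cohort(n = 400)
  true_crit <- evaluate_candidate(balance_score(d$x, d$a, d$b), d$y)
  rand <- replicate(60, {
    ij <- sample(colnames(d$x), 2)
    evaluate_candidate(balance_score(d$x, ij[1], ij[2]), d$y)
  })
  expect_gte(mean(true_crit > rand), 0.95)
})

test_that("forward_select is reproducible and respects max_size bounds", {
  set.seed(23)
  d <- planted_pair_cohort(n = 150, p = 8)
  a <- forward_select(d$x, d$y, max_size = 3, cv_folds = 3, cv_repeats = 2, seed = 5)
  b <- forward_select(d$x, d$y, max_size = 3, cv_folds = 3, cv_repeats = 2, seed = 5)
  expect_identical(a[c("numerator", "denominator", "chosen_size", "cv_table")],
                   b[c("numerator", "denominator", "chosen_size", "cv_table")])
  expect_equal(a$chosen_size, length(a$numerator) + length(a$denominator))
  expect_error(forward_select(d$x, d$y, max_size = 9, seed = 1), "max_size")
  expect_error(forward_select(d$x, d$y, max_size = 3, cv_folds = 3,
                              cv_repeats = 1), "seed")
})

test_that("max_size=2 equals the brute-force exhaustive-pair oracle", {
  set.seed(24)
  for (rep_i in 1:3) {
    d <- planted_pair_cohort(n = 120, p = 12, a = sample(12, 1),
                             b = sample(11, 1))
    sel <- forward_select(d$x, d$y, max_size = 2, seed = 2)
    # oracle: independent brute force over all ordered pairs
    labels <- colnames(d$x)
    best <- c(NA, NA); best_crit <- -Inf
    for (i in labels) for (j in labels) {
      if (i == j) next
      cr <- as.numeric(evaluate_candidate(balance_score(d$x, i, j), d$y))
      if (cr > best_crit + 1e-12) { best_crit <- cr; best <- c(i, j) }
    }
    expect_equal(sel$numerator, best[1])
    expect_equal(sel$denominator, best[2])
    expect_equal(sel$criterion_trace[1], best_crit, tolerance = 1e-10)
  }
})

test_that("swapping numerator and denominator leaves the criterion unchanged", {
  set.seed(25)
  d <- planted_pair_cohort(n = 200)
  b <- balance_score(d$x, c(d$a, "P05"), d$b)
  expect_equal(as.numeric(evaluate_candidate(b, d$y)),
               as.numeric(evaluate_candidate(-b, d$y)))
})

test_that("covariates enter the selection model additively", {
  set.seed(26)
  d <- planted_pair_cohort(n = 200, p = 6, a = 2, b = 5)
  z <- data.frame(age = rnorm(200, 50, 10), smoker = rbinom(200, 1, 0.3))
  sel <- forward_select(d$x, d$y, covariates = z, max_size = 2, seed = 4)
  expect_equal(sel$covariates_used, c("age", "smoker"))
  expect_equal(sel$chosen_size, 2)
})
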