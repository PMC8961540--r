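# Oracle construction: ladders generated exactly from known polynomials,
# peak lists composed from known per-window areas.

true_poly <- c(2, 0.9, 0.05, 0.002, 1e-4, 5e-6)  # increasing on [1, 25]
eval_poly <- function(coefs, x) drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)

test_that("fit_gu_curve recovers a noiseless degree-5 ladder exactly", {
  rt <- seq(2, 24, length.out = 15)
  ladder <- dextran_ladder(rt, eval_poly(true_poly, rt))
  cal <- fit_gu_curve(ladder)
  expect_lt(max(abs(predict_gu(cal, rt) - ladder$gu)), 1e-9)
})

test_that("identity ladder is reproduced (degree 1 nested in degree 5)", {
  rt <- seq(3, 12, length.out = 10)
  cal <- fit_gu_curve(dextran_ladder(rt, rt))
  expect_lt(max(abs(predict_gu(cal, rt) - rt)), 1e-9)
})

test_that("short or non-monotone ladders are rejected", {
  expect_error(dextran_ladder(1:6, 1:6), "at least 7")
  expect_error(dextran_ladder(c(1, 2, 3, 4, 5, 7, 6), 1:7), "increasing")
  # a staircase ladder is monotone but its degree-5 fit oscillates
  gu <- c(1, 1.01, 1.02, 1.03, 1.04, 8, 8.01, 8.02, 8.03, 8.04)
  expect_error(fit_gu_curve(dextran_ladder(1:10, gu)), "not strictly increasing")
})

test_that("least-squares residuals never exceed a lower-degree fit", {
  set.seed(7)
  rt <- seq(2, 20, length.out = 12)
  gu <- eval_poly(true_poly, rt) + rnorm(12, 0, 0.05)
  cal <- fit_gu_curve(dextran_ladder(rt, gu))
  rss5 <- sum((predict_gu(cal, rt) - gu)^2)
  for (deg in 1:4) {
    fit <- lm(gu ~ poly(rt, deg, raw = TRUE))
    expect_lte(rss5, sum(residuals(fit)^2) + 1e-12)
  }
})

test_that("assign_peaks honors containment and the half-open convention", {
  # exact identity calibration (boundary semantics need exact GU values;
  # a least-squares identity fit is only identity to ~1e-12)
  cal <- structure(list(coefficients = c(0, 1, 0, 0, 0, 0),
                        valid_range = c(0, 30)),
                   class = "gu_calibration")
  win <- default_gu_windows()
  # peak at the midpoint of GP19
  mid <- (win$lo[19] + win$hi[19]) / 2
  v <- assign_peaks(data.frame(rt = mid, area = 5), cal, win)
  expect_equal(unname(v[19]), 5)
  expect_equal(sum(v), 5)
  # boundary hi_i belongs to window i+1
  v <- assign_peaks(data.frame(rt = win$hi[19], area = 2), cal, win)
  expect_equal(unname(v[20]), 2)
  expect_equal(unname(v[19]), 0)
  # one peak per window, areas 1..46
  mids <- (win$lo + win$hi) / 2
  v <- assign_peaks(data.frame(rt = mids, area = 1:46), cal, win)
  expect_equal(as.numeric(v), as.numeric(1:46))
  expect_equal(attr(v, "unassigned"), 0)
})

test_that("out-of-range peaks are warned about and counted unassigned", {
  rt <- seq(4, 13, length.out = 10)
  cal <- fit_gu_curve(dextran_ladder(rt, rt))
  win <- default_gu_windows()
  expect_warning(
    v <- assign_peaks(data.frame(rt = c(5, 100), area = c(3, 7)), cal, win),
    "unassigned")
  expect_equal(sum(v), 3)
  expect_equal(attr(v, "unassigned"), 7)
})

test_that("close_to_percent closes, rejects degenerate input, is scale invariant", {
  expect_equal(close_to_percent(rep(1, 46)), rep(100 / 46, 46))
  expect_equal(close_to_percent(c(2, rep(0, 45)))[1], 100)
  expect_error(close_to_percent(rep(0, 46)), "positive")
  expect_error(close_to_percent(c(-1, rep(1, 45))), "non-negative")
  set.seed(1)
  for (i in 1:20) {
    v <- runif(46, 0, 10)
    c1 <- close_to_percent(v)
    expect_lt(abs(sum(c1) - 100), 1e-9)
    expect_equal(c1, close_to_percent(v * runif(1, 0.01, 100)), tolerance = 1e-9)
  }
})

test_that("round trip: compose, calibrate, assign, close recovers the composition", {
  set.seed(42)
  rt <- seq(1, 30, length.out = 15)
  cal <- fit_gu_curve(dextran_ladder(rt, eval_poly(c(0, 0.45, 0.001), rt)))
  win <- default_gu_windows()
  known <- close_to_percent(runif(46, 0.2, 6))
  # place each window's area at a random GU inside the window, invert the
  # (monotone) calibration numerically to get a retention time
  gu_target <- win$lo + runif(46) * (win$hi - win$lo) * 0.98
  rt_peaks <- vapply(gu_target, function(g)
    uniroot(function(r) predict_gu(cal, r) - g, c(1, 30), tol = 1e-12)$root,
    numeric(1))
  out <- reduce_chromatogram(data.frame(rt = rt_peaks, area = known), cal, win)
  expect_lt(max(abs(out - known) / known), 1e-6)
})

test_that("integrate_trace recovers well-separated gaussian peak areas", {
  rt <- seq(0, 20, by = 0.005)
  sig <- 3 * dnorm(rt, 5, 0.1) + 7 * dnorm(rt, 12, 0.1)
  pk <- integrate_trace(rt, sig)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$rt, c(5, 12), tolerance = 0.01)
  expect_equal(pk$area, c(3, 7), tolerance = 0.01)
})

test_that("calibration and window CSV readers round-trip", {
  d <- tempfile(fileext = ".csv"); on.exit(unlink(d), add = TRUE)
  rt <- seq(2, 16, length.out = 8)
  write.csv(data.frame(rt = rt, gu = rt), d, row.names = FALSE)
  expect_equal(read_dextran_ladder_csv(d)$rt, rt)
  w <- tempfile(fileext = ".csv"); on.exit(unlink(w), add = TRUE)
  write.csv(as.data.frame(default_gu_windows()), w, row.names = FALSE)
  expect_equal(read_gu_windows_csv(w)$hi, default_gu_windows()$hi)
})
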