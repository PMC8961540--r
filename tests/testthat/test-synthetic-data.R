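test_that("classify_risk applies the sex-specific OR rule with strict inequalities", {
  expect_equal(classify_risk("F", 21, 0), "risk")        # > 20 g/day
  expect_equal(classify_risk("F", 20, 5), "non-risk")    # both at boundary
  expect_equal(classify_risk("M", 40, 7), "non-risk")    # both at boundary
  expect_equal(classify_risk("M", 0, 8), "risk")         # AUDIT > 7
  expect_equal(classify_risk("F", 0, 6), "risk")         # AUDIT > 5
  expect_equal(classify_risk(c("M", "F"), c(41, 0), c(0, 0)),
               c("risk", "non-risk"))
  expect_error(classify_risk("X", 10, 0), "sex")
  expect_error(classify_risk("M", -1, 0), "alcohol")
  expect_error(classify_risk("M", 0, 41), "audit")
})

test_that("generate_cohort is deterministic, closed, and label-consistent", {
  spec <- small_male_spec(n = 30, seed = 11)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_identical(coh1, coh2)
  expect_equal(nrow(coh1), 60)
  gp <- as.matrix(coh1[, GP_COLS])
  expect_true(all(gp >= 0))
  expect_lt(max(abs(rowSums(gp) - 100)), 1e-9)
  expect_true(all(coh1$age >= 18 & coh1$age <= 91))
  # stratum labels agree with the risk rule applied to the drawn values
  expect_equal(classify_risk(coh1$sex, coh1$alcohol_gweek / 7, coh1$audit),
               coh1$risk)
})

test_that("zero dispersion with equal medians gives the uniform closed profile", {
  spec <- small_male_spec(n = 5, seed = 2)
  spec$peak_medians[] <- 1
  spec$log_dispersion[] <- 1e-12  # dispersion must be positive; effectively zero
  coh <- generate_cohort(spec)
  expect_equal(as.numeric(as.matrix(coh[, GP_COLS])),
               rep(100 / 46, 5 * 2 * 46), tolerance = 1e-6)
})

test_that("stratum medians and planted effects are recovered at n=500", {
  coh <- generate_cohort(default_cohort_spec("M", c("non-risk" = 500, risk = 500),
                                             seed = 1))
  nonrisk <- coh[coh$risk == "non-risk", ]
  risk <- coh[coh$risk == "risk", ]
  # large peak absolute tolerance
  expect_lt(abs(median(nonrisk$GP25) - 31.8), 1.5)
  # planted GP9 decrease in risk drinkers
  expect_lt(median(risk$GP9), median(nonrisk$GP9))
  # sign recovery for every peak with >= 5% relative median shift
  ref <- glycan_peak_reference()
  ref <- ref[ref$sex == "M", ]
  for (pk in GP_COLS) {
    m_nr <- ref$median[ref$risk == "non-risk" & ref$peak == pk]
    m_r <- ref$median[ref$risk == "risk" & ref$peak == pk]
    if (abs(m_r - m_nr) / m_nr >= 0.05) {
      expect_equal(sign(median(risk[[pk]]) - median(nonrisk[[pk]])),
                   sign(m_r - m_nr), label = pk)
    }
  }
})

test_that("marker draws match target medians within 5% at n=2000", {
  coh <- generate_cohort(default_cohort_spec("F", c("non-risk" = 2000, risk = 2000),
                                             seed = 9))
  st <- glycorisk:::stratum_reference()
  for (r in c("non-risk", "risk")) {
    tgt <- st[st$sex == "F" & st$risk == r, ]
    sub <- coh[coh$risk == r, ]
    expect_lt(abs(median(sub$GGT) / tgt$ggt_med - 1), 0.05)
    expect_lt(abs(median(sub$MCV) / tgt$mcv_med - 1), 0.05)
    expect_lt(abs(median(sub$CDT) / tgt$cdt_med - 1), 0.05)
  }
})

test_that("spec validation rejects bad inputs", {
  expect_error(small_male_spec(n = 40, seed = NULL), "seed")
  spec <- small_male_spec()
  bad <- spec$peak_medians; bad[3, 1] <- -1
  expect_error(cohort_spec(c("non-risk" = 10, risk = 10), "M", bad,
                           spec$log_dispersion,
                           covariate_params = spec$covariate_params,
                           marker_params = spec$marker_params, seed = 1),
               "positive")
  expect_error(cohort_spec(c("non-risk" = 1, risk = 10), "M", spec$peak_medians,
                           spec$log_dispersion,
                           covariate_params = spec$covariate_params,
                           marker_params = spec$marker_params, seed = 1),
               ">= 2")
})

test_that("table2_fixtures returns the published 2x2 counts", {
  fx <- table2_fixtures()
  expect_named(fx, c("GGT_men", "MCV_men", "CDT_men",
                     "GGT_women", "MCV_women", "CDT_women"))
  expect_equal(unlist(fx$GGT_men[c("tp", "fn", "fp", "tn")]),
               c(tp = 26L, fn = 117L, fp = 48L, tn = 487L))
  expect_equal(unlist(fx$CDT_men[c("tp", "fn", "fp", "tn")]),
               c(tp = 37L, fn = 106L, fp = 30L, tn = 505L))
  expect_equal(unlist(fx$GGT_women[c("tp", "fn", "fp", "tn")]),
               c(tp = 16L, fn = 34L, fp = 69L, tn = 719L))
  # stratum totals: 143/535 men, 50/788 women (MCV short by its missing)
  expect_equal(fx$CDT_women$tp + fx$CDT_women$fn, 50L)
  expect_equal(fx$MCV_men$tp + fx$MCV_men$fn, 143L - 2L)
  expect_equal(attr(fx$MCV_men, "missing"), c(risk = 2L, nonrisk = 9L))
})

test_that("cohort CSV round-trips", {
  coh <- generate_cohort(small_male_spec(n = 5, seed = 3))
  path <- tempfile(fileext = ".csv"); on.exit(unlink(path))
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$GP25, coh$GP25, tolerance = 1e-12)
  expect_equal(back$risk, coh$risk)
})
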