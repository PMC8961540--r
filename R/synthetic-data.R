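# Synthetic cohort generation.
#
# The generator draws each subject's 46-peak glycan profile from a
# logistic-normal-style model: per-stratum log-normal marginals matched to
# the reference medians, an optional one-factor correlation structure on
# the log scale, then closure to 100%. Standard markers (GGT, MCV, CDT)
# are log-normal with dispersion implied by the published IQRs, so marker
# positivity arises from the distribution tails against the clinical
# cut-offs rather than being planted directly.

RISK_LEVELS <- c("non-risk", "risk")

#' Construct a cohort-generation specification
#'
#' @param n_per_stratum Named integer vector of subjects per risk stratum,
#'   names `"non-risk"` and `"risk"`, each at least 2.
#' @param sex `"M"` or `"F"`; risk-drinking thresholds and reference
#'   ranges are sex-specific, so a spec describes one sex.
#' @param peak_medians 46 x 2 matrix (columns `"non-risk"`, `"risk"`) of
#'   strictly positive target medians on the percent scale.
#' @param log_dispersion 46 x 2 matrix of positive per-peak standard
#'   deviations on the natural-log scale.
#' @param correlation_model `"independent"` or `"one-factor"`.
#' @param loading Factor loading in (0, 1) for the one-factor model; each
#'   log-scale deviation is `sigma * (loading * f + sqrt(1 - loading^2) * e)`
#'   with shared `f` and idiosyncratic `e`, both standard normal.
#' @param covariate_params,marker_params Data frames with one row per risk
#'   stratum (see [default_cohort_spec()] for the layout).
#' @param seed Integer seed; mandatory, reproducibility is part of the
#'   generator's contract.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_stratum, sex, peak_medians, log_dispersion,
                        correlation_model = c("one-factor", "independent"),
                        loading = 0.3,
                        covariate_params, marker_params, seed) {
  correlation_model <- match.arg(correlation_model)
  abort_if(missing(seed) || is.null(seed) || !is_count(seed),
           "seed is mandatory and must be a single integer")
  abort_if(!sex %in% c("M", "F"), "sex must be 'M' or 'F'")
  n_per_stratum <- n_per_stratum[RISK_LEVELS]
  abort_if(anyNA(n_per_stratum) || any(n_per_stratum < 2),
           "n_per_stratum must name 'non-risk' and 'risk', each >= 2")
  peak_medians <- as.matrix(peak_medians)
  log_dispersion <- as.matrix(log_dispersion)
  abort_if(!all(dim(peak_medians) == c(N_PEAKS, 2L)) ||
           !all(dim(log_dispersion) == c(N_PEAKS, 2L)),
           "peak_medians and log_dispersion must be %d x 2 matrices", N_PEAKS)
  abort_if(any(peak_medians <= 0), "all peak medians must be positive")
  abort_if(any(log_dispersion <= 0), "all log dispersions must be positive")
  abort_if(correlation_model == "one-factor" && (loading <= 0 || loading >= 1),
           "loading must be in (0, 1)")
  for (df in list(covariate_params, marker_params)) {
    abort_if(!is.data.frame(df) || nrow(df) != 2L ||
             !all(RISK_LEVELS %in% df$risk),
             "covariate_params and marker_params need one row per risk stratum")
  }
  structure(list(
    n_per_stratum = as.integer(n_per_stratum), sex = sex,
    peak_medians = peak_medians, log_dispersion = log_dispersion,
    correlation_model = correlation_model, loading = loading,
    covariate_params = covariate_params, marker_params = marker_params,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default cohort specification matched to the reference cohort
#'
#' Builds a [cohort_spec()] whose per-stratum peak medians, log-scale
#' dispersions (from the published IQRs under a log-normal model),
#' covariate distributions and marker distributions reproduce the summary
#' statistics of the source general-population study for the given sex.
#'
#' @param sex `"M"` or `"F"`.
#' @param n_per_stratum Optional stratum sizes; defaults to the source
#'   cohort sizes (men 535/143, women 788/50 non-risk/risk).
#' @param seed Integer seed (mandatory).
#' @param correlation_model,loading Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
#' @examples
#' spec <- default_cohort_spec("M", seed = 1)
#' spec$peak_medians["GP25", "non-risk"]  # 31.8
default_cohort_spec <- function(sex, n_per_stratum = NULL, seed,
                                correlation_model = "one-factor",
                                loading = 0.3) {
  abort_if(!sex %in% c("M", "F"), "sex must be 'M' or 'F'")
  ref <- glycan_peak_reference()
  ref <- ref[ref$sex == sex, ]
  med <- sig <- matrix(NA_real_, N_PEAKS, 2,
                       dimnames = list(gp_labels(), RISK_LEVELS))
  for (r in RISK_LEVELS) {
    s <- ref[ref$risk == r, ]
    s <- s[match(gp_labels(), s$peak), ]
    med[, r] <- s$median
    sig[, r] <- lognormal_sigma(s$q1, s$q3)
  }
  st <- stratum_reference()
  st <- st[st$sex == sex, ]
  st <- st[match(RISK_LEVELS, st$risk), ]
  if (is.null(n_per_stratum)) {
    n_per_stratum <- stats::setNames(st$n, RISK_LEVELS)
  }
  cov_par <- data.frame(
    risk = RISK_LEVELS,
    age_med = st$age_med, age_q1 = st$age_q1, age_q3 = st$age_q3,
    alcohol_med = st$alcohol_med, alcohol_q1 = st$alcohol_q1,
    alcohol_q3 = st$alcohol_q3,
    smoking_prev = st$smoking_prev,
    stringsAsFactors = FALSE
  )
  mark_par <- data.frame(
    risk = RISK_LEVELS,
    ggt_med = st$ggt_med, ggt_sd = lognormal_sigma(st$ggt_q1, st$ggt_q3),
    mcv_med = st$mcv_med, mcv_sd = lognormal_sigma(st$mcv_q1, st$mcv_q3),
    cdt_med = st$cdt_med, cdt_sd = lognormal_sigma(st$cdt_q1, st$cdt_q3),
    stringsAsFactors = FALSE
  )
  cohort_spec(n_per_stratum = n_per_stratum, sex = sex,
              peak_medians = med, log_dispersion = sig,
              correlation_model = correlation_model, loading = loading,
              covariate_params = cov_par, marker_params = mark_par,
              seed = seed)
}

#' Classify a subject as risk or non-risk drinker
#'
#' Risk drinking is defined, by sex, as habitual consumption above a daily
#' threshold OR an AUDIT questionnaire score above a cut-off: more than
#' 40 g/day or AUDIT above 7 for men; more than 20 g/day or AUDIT above 5
#' for women. Both inequalities are strict.
#'
#' @param sex `"M"` or `"F"` (vectorised).
#' @param alcohol_gday Mean daily alcohol intake in grams.
#' @param audit_score AUDIT score, 0-40.
#' @return Character vector, `"risk"` or `"non-risk"`.
#' @export
#' @examples
#' classify_risk("F", 21, 0)  # "risk"
#' classify_risk("M", 40, 7)  # "non-risk"
classify_risk <- function(sex, alcohol_gday, audit_score) {
  abort_if(!all(sex %in% c("M", "F")), "sex must be 'M' or 'F'")
  abort_if(any(alcohol_gday < 0), "alcohol_gday must be non-negative")
  abort_if(any(audit_score < 0 | audit_score > 40), "audit_score must be in [0, 40]")
  gday_thr <- ifelse(sex == "M", 40, 20)
  audit_thr <- ifelse(sex == "M", 7, 5)
  ifelse(alcohol_gday > gday_thr | audit_score > audit_thr, "risk", "non-risk")
}

# Draw log-scale deviations for one stratum: n x 46 matrix.
draw_log_deviations <- function(n, sigma, model, loading) {
  z <- matrix(stats::rnorm(n * N_PEAKS), n, N_PEAKS)
  if (model == "one-factor") {
    f <- stats::rnorm(n)
    z <- loading * f + sqrt(1 - loading^2) * z
  }
  sweep(z, 2, sigma, `*`)
}

# Alcohol (g/week) and AUDIT draws, resampled until consistent with the
# stratum label under the sex-specific risk definition.
draw_alcohol_audit <- function(n, sex, risk, cov) {
  sd_week <- (cov$alcohol_q3 - cov$alcohol_q1) / (2 * stats::qnorm(0.75))
  audit_gen <- if (risk == "risk") {
    function(k) pmin(40, 3 + stats::rpois(k, 4))
  } else {
    function(k) pmin(40, stats::rpois(k, 1.5))
  }
  gweek <- rep(NA_real_, n)
  audit <- rep(NA_integer_, n)
  todo <- seq_len(n)
  for (iter in 1:1000) {
    k <- length(todo)
    if (k == 0) break
    a <- pmax(0, stats::rnorm(k, cov$alcohol_med, sd_week))
    s <- audit_gen(k)
    ok <- classify_risk(rep(sex, k), a / 7, s) == risk
    gweek[todo[ok]] <- a[ok]
    audit[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  abort_if(length(todo) > 0,
           "could not draw label-consistent alcohol/AUDIT values; check covariate_params")
  list(alcohol_gweek = gweek, audit = audit)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `spec$seed`. Per stratum, each subject's 46-part
#' peak vector is `exp(log(median) + eps)` with `eps` multivariate normal
#' per the correlation model, closed to sum 100. Ages are drawn normal
#' (IQR-matched) truncated to 18-91 years; alcohol and AUDIT draws are
#' resampled until consistent with the stratum's risk label; markers are
#' log-normal with median and IQR-implied dispersion per stratum.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame (class `glycan_cohort`) with columns `subject_id`,
#'   `sex`, `risk`, `age`, `smoker`, `alcohol_gweek`, `audit`,
#'   `GP1`..`GP46`, `GGT`, `MCV`, `CDT`. Peak columns sum to 100 per row.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_spec("M", c("non-risk" = 20, risk = 20), seed = 1))
#' range(rowSums(coh[, paste0("GP", 1:46)]))
generate_cohort <- function(spec) {
  abort_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  strata <- lapply(RISK_LEVELS, function(r) {
    n <- spec$n_per_stratum[[match(r, RISK_LEVELS)]]
    dev <- draw_log_deviations(n, spec$log_dispersion[, r],
                               spec$correlation_model, spec$loading)
    gp <- exp(sweep(dev, 2, log(spec$peak_medians[, r]), `+`))
    gp <- t(apply(gp, 1, close_to_percent))
    colnames(gp) <- gp_labels()

    cov <- spec$covariate_params[spec$covariate_params$risk == r, ]
    age_sd <- (cov$age_q3 - cov$age_q1) / (2 * stats::qnorm(0.75))
    age <- round(pmin(91, pmax(18, stats::rnorm(n, cov$age_med, age_sd))))
    smoker <- stats::runif(n) < cov$smoking_prev
    aa <- draw_alcohol_audit(n, spec$sex, r, cov)

    mk <- spec$marker_params[spec$marker_params$risk == r, ]
    data.frame(
      sex = spec$sex, risk = r, age = age, smoker = smoker,
      alcohol_gweek = aa$alcohol_gweek, audit = aa$audit,
      gp,
      GGT = rlnorm_median(n, mk$ggt_med, mk$ggt_sd),
      MCV = rlnorm_median(n, mk$mcv_med, mk$mcv_sd),
      CDT = rlnorm_median(n, mk$cdt_med, mk$cdt_sd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, strata)
  out <- cbind(subject_id = sprintf("%s%04d", spec$sex, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("glycan_cohort", "data.frame")
  out
}

#' Write / read a cohort as delimited text
#'
#' Plain CSV with one header line, decimal point, UTF-8; columns as
#' produced by [generate_cohort()].
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame (unvalidated; see
#'   [validate_cohort_csv()] for checked ingestion).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  # sex must never be sniffed: a column of "F" values parses as logical
  cols <- utils::read.csv(path, nrows = 1, check.names = TRUE)
  cc <- rep(NA, ncol(cols))
  names(cc) <- names(cols)
  cc[names(cc) %in% c("subject_id", "sex", "risk")] <- "character"
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = cc)
}
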