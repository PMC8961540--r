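# Diagnostic-marker evaluation: clinical threshold rules for the standard
# alcohol markers, 2x2 diagnostic metrics with likelihood-ratio confidence
# intervals, and covariate-adjusted ROC/AUC.

#' 2x2 diagnostic contingency table
#'
#' Cell convention: `tp` = risk drinkers with a positive marker, `fn` =
#' risk drinkers with a negative marker, `fp` = non-risk drinkers with a
#' positive marker, `tn` = non-risk drinkers with a negative marker.
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  abort_if(any(cells < 0) || any(cells != floor(cells)),
           "cells must be non-negative integers")
  cells <- stats::setNames(as.integer(cells), names(cells))
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(c("risk", "non-risk"), c("positive", "negative")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
         dimnames = list(c("risk", "non-risk"), c("positive", "negative")))
}

#' Diagnostic metrics from a 2x2 table
#'
#' Sensitivity and specificity on the percent scale, the positive
#' likelihood ratio LR+ = sens / (1 - spec), and its 95% confidence
#' interval by the log method:
#'   exp( ln LR +/- 1.96 * sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)) ).
#' With `fp = 0` the LR+ is infinite (flagged, CI undefined); with
#' `tp = 0` it is 0 (CI undefined).
#'
#' @param t A [contingency_table()].
#' @param conf_z Normal quantile for the CI (1.96 for 95%).
#' @return List: `sensitivity`, `specificity` (percent), `lr_plus`,
#'   `lr_ci` (length-2), `flags` (character).
#' @export
#' @examples
#' diagnostic_metrics(table2_fixtures()$GGT_men)
diagnostic_metrics <- function(t, conf_z = stats::qnorm(0.975)) {
  abort_if(!inherits(t, "contingency_table"), "t must be a contingency_table")
  n_pos <- t$tp + t$fn
  n_neg <- t$fp + t$tn
  abort_if(n_pos == 0 || n_neg == 0, "both diseased and non-diseased totals must be positive")
  sens <- t$tp / n_pos
  spec <- t$tn / n_neg
  flags <- character(0)
  if (t$fp == 0) {
    lr <- Inf
    ci <- c(NA_real_, NA_real_)
    flags <- c(flags, "lr_infinite")
  } else if (t$tp == 0) {
    lr <- 0
    ci <- c(NA_real_, NA_real_)
    flags <- c(flags, "lr_zero")
  } else {
    lr <- sens / (t$fp / n_neg)
    se <- sqrt(1 / t$tp - 1 / n_pos + 1 / t$fp - 1 / n_neg)
    ci <- exp(log(lr) + c(-1, 1) * conf_z * se)
  }
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       lr_plus = lr, lr_ci = ci, flags = flags)
}

#' Marker positivity per clinical reference limits
#'
#' GGT is positive above the sex-specific upper reference limit (73 IU/L
#' men, 38 IU/L women); MCV above 100 fL; CDT above 1.6%. All
#' inequalities are strict. A missing MCV yields `NA`.
#'
#' @param sex `"M"`/`"F"` (vectorised with the marker values).
#' @param ggt,mcv,cdt Marker values (IU/L, fL, %); `mcv` may be `NA`.
#' @return data.frame of logicals `ggt_pos`, `mcv_pos`, `cdt_pos`.
#' @export
apply_marker_thresholds <- function(sex, ggt, mcv, cdt) {
  abort_if(!all(sex %in% c("M", "F")), "sex must be 'M' or 'F'")
  data.frame(
    ggt_pos = ggt > ifelse(sex == "M", 73, 38),
    mcv_pos = mcv > 100,
    cdt_pos = cdt > 1.6
  )
}

#' Tabulate marker positivity against risk status
#'
#' @param positive Logical marker positivity (NA dropped with its subject).
#' @param risk Character `"risk"`/`"non-risk"` per subject.
#' @return A [contingency_table()].
#' @export
tabulate_marker <- function(positive, risk) {
  keep <- !is.na(positive)
  positive <- positive[keep]; risk <- risk[keep]
  contingency_table(
    tp = sum(positive & risk == "risk"),
    fn = sum(!positive & risk == "risk"),
    fp = sum(positive & risk == "non-risk"),
    tn = sum(!positive & risk == "non-risk")
  )
}

#' Covariate-adjusted predictor scores
#'
#' Fits the logistic model `outcome ~ predictors + covariates` and
#' returns the fitted probabilities, the standard logistic-score reading
#' of "ROC adjusted for age and smoking". Separation is flagged but the
#' scores are still returned.
#'
#' @param predictors Numeric matrix / data.frame (may be NULL for an
#'   intercept-only model).
#' @param outcome Binary outcome.
#' @param covariates Optional numeric matrix / data.frame.
#' @return Numeric vector of fitted probabilities, attribute
#'   `separation` if quasi-separated.
#' @export
adjusted_scores <- function(predictors, outcome, covariates = NULL) {
  y <- as.integer(outcome)
  abort_if(!all(y %in% 0:1), "outcome must be binary")
  X <- cbind(as_covariate_matrix(predictors, length(y)),
             as_covariate_matrix(covariates, length(y)))
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(rep(1, length(y)), X), y, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  out <- fit$fitted.values
  if (any(out > 1 - 1e-10) && any(out < 1e-10)) attr(out, "separation") <- TRUE
  out
}

#' Empirical ROC AUC with DeLong confidence interval
#'
#' AUC via the rank statistic (tied scores count one half); the 95% CI
#' uses DeLong's structural-components variance estimator, truncated to
#' [0, 1].
#'
#' @param scores Numeric predictor scores.
#' @param outcome Binary outcome with both classes present.
#' @param conf_z Normal quantile (1.96 for 95%).
#' @return List of class `roc_result`: `auc`, `ci95`, `se`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, outcome, conf_z = stats::qnorm(0.975)) {
  y <- as.integer(outcome)
  abort_if(!all(y %in% 0:1), "outcome must be binary")
  abort_if(length(unique(y)) < 2, "both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  auc <- auc_rank(scores, y)
  # DeLong structural components via midranks
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0          # placement of each pos
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1 # placement of each neg
  s <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(s)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * conf_z * se))
  structure(list(auc = auc, ci95 = ci, se = se, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), n = %d/%d pos/neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare a standard marker with a glycan balance, adjusted
#'
#' Three covariate-adjusted ROC analyses on the same subjects: marker
#' alone, balance alone, and marker plus balance combined, each scored by
#' a logistic model with the given covariates.
#'
#' @param marker Numeric marker values.
#' @param balance_scores Numeric per-subject balance scores.
#' @param outcome Binary outcome.
#' @param covariates Optional covariates (e.g. age, smoker).
#' @return List of `roc_result`: `marker`, `balance`, `combined`.
#' @export
compare_marker_vs_balance <- function(marker, balance_scores, outcome,
                                      covariates = NULL) {
  list(
    marker = roc_auc(adjusted_scores(cbind(marker = marker), outcome, covariates),
                     outcome),
    balance = roc_auc(adjusted_scores(cbind(balance = balance_scores), outcome,
                                      covariates), outcome),
    combined = roc_auc(adjusted_scores(cbind(marker = marker,
                                             balance = balance_scores),
                                       outcome, covariates), outcome)
  )
}
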