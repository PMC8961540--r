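# Compositional log-contrast balance selection.
#
# A balance between two disjoint subsets of compositional parts
# (numerator N, |N| = p; denominator D, |D| = q) is the normalized
# log-contrast
#     B = sqrt(pq / (p + q)) * (mean(ln x_N) - mean(ln x_D)),
# which is invariant to the closure constant. Forward selection searches
# for the balance most predictive of a binary outcome: the first step is
# an exhaustive search over all ordered part pairs, each later step tries
# every unused part on either side, and the final model size is chosen by
# repeated stratified k-fold cross-validation (highest mean test
# criterion; ties go to the smaller, more parsimonious size). The
# criterion is the AUC of a logistic model outcome ~ balance + covariates.

#' Normalized log-contrast balance score
#'
#' @param gp Closed composition: a positive numeric vector with named
#'   parts, or a matrix / data.frame of such rows.
#' @param numerator,denominator Disjoint non-empty sets of part labels
#'   (or column indices).
#' @return Balance score(s): a scalar for a vector input, a vector with
#'   one score per row otherwise.
#' @export
#' @examples
#' balance_score(c(a = exp(1), b = 1), "a", "b")  # sqrt(1/2)
balance_score <- function(gp, numerator, denominator) {
  if (is.data.frame(gp)) gp <- as.matrix(gp)
  single <- is.null(dim(gp))
  if (single) gp <- matrix(gp, nrow = 1, dimnames = list(NULL, names(gp)))
  num_idx <- resolve_parts(numerator, colnames(gp), ncol(gp))
  den_idx <- resolve_parts(denominator, colnames(gp), ncol(gp))
  abort_if(length(intersect(num_idx, den_idx)) > 0,
           "numerator and denominator must be disjoint")
  abort_if(length(num_idx) < 1 || length(den_idx) < 1,
           "numerator and denominator must be non-empty")
  abort_if(any(gp[, c(num_idx, den_idx)] <= 0),
           "balance parts must be strictly positive; apply zero_replace() first")
  p <- length(num_idx); q <- length(den_idx)
  lg <- log(gp)
  b <- sqrt(p * q / (p + q)) *
    (rowMeans(lg[, num_idx, drop = FALSE]) - rowMeans(lg[, den_idx, drop = FALSE]))
  if (single) b[[1]] else unname(b)
}

resolve_parts <- function(parts, labels, p) {
  if (is.character(parts)) {
    idx <- match(parts, labels)
    abort_if(anyNA(idx), "unknown part label: %s",
             paste(parts[is.na(idx)], collapse = ", "))
    idx
  } else {
    abort_if(any(parts < 1 | parts > p), "part index out of range")
    as.integer(parts)
  }
}

#' Replace zeros in a closed composition
#'
#' Log-contrasts require strictly positive parts. `pseudocount` adds
#' delta = half the smallest observed positive value to zero cells and
#' re-closes. `multiplicative` sets zero cells to delta and shrinks the
#' positive cells multiplicatively, exactly preserving their ratios.
#'
#' @param gp Non-negative vector summing to 100 (or matrix of rows).
#' @param method `"pseudocount"` or `"multiplicative"`.
#' @return Strictly positive composition re-closed to 100.
#' @export
zero_replace <- function(gp, method = c("pseudocount", "multiplicative")) {
  method <- match.arg(method)
  if (is.data.frame(gp)) gp <- as.matrix(gp)
  if (!is.null(dim(gp))) {
    return(t(apply(gp, 1, zero_replace, method = method)))
  }
  abort_if(any(gp < 0), "composition must be non-negative")
  abort_if(all(gp == 0), "all-zero composition")
  if (!any(gp == 0)) return(gp)
  delta <- min(gp[gp > 0]) / 2
  z <- gp == 0
  out <- gp
  if (method == "pseudocount") {
    out[z] <- delta
    out <- close_to_percent(out)
  } else {
    out[z] <- delta
    out[!z] <- gp[!z] * (100 - sum(z) * delta) / 100
  }
  out
}

# In-sample AUC of fitted probabilities from a logistic model
# outcome ~ predictors. Separation is tolerated (glm warnings are
# suppressed; the fitted order, hence the AUC, is still well defined).
logit_auc <- function(y, X) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial())
  )
  auc_rank(fit$fitted.values, y)
}

# Rank-statistic AUC with ties counted 1/2.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Criterion for a candidate balance
#'
#' Fits the additive logistic model `outcome ~ score + covariates` and
#' returns the in-sample AUC of its fitted probabilities. Perfect
#' separation does not error: the AUC (1.0) is returned with a
#' `separation` attribute set.
#'
#' @param score Per-subject balance score.
#' @param outcome Binary outcome (0/1 or logical), both classes present.
#' @param covariates Optional numeric matrix / data.frame of adjustment
#'   covariates.
#' @return AUC in [0, 1].
#' @export
evaluate_candidate <- function(score, outcome, covariates = NULL) {
  y <- as.integer(outcome)
  abort_if(!all(y %in% 0:1), "outcome must be binary")
  abort_if(length(unique(y)) < 2, "both outcome classes must be present")
  X <- cbind(score = score, as_covariate_matrix(covariates, length(y)))
  auc <- logit_auc(y, X)
  if (auc >= 1 - 1e-12) attr(auc, "separation") <- TRUE
  auc
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  m <- as.matrix(as.data.frame(covariates))
  storage.mode(m) <- "double"
  abort_if(nrow(m) != n, "covariates must have one row per subject")
  m
}

# One forward-selection path on (lg = log composition, y, Z covariates).
# Returns cumulative numerator/denominator index sets of size 2..max_size
# and the training criterion trace. Tie-break: smallest column label,
# numerator side first.
forward_path <- function(lg, y, Z, max_size) {
  P <- ncol(lg)
  labels <- colnames(lg)
  ord <- order(labels)  # lexicographic preference
  crit_of <- function(num, den) {
    p <- length(num); q <- length(den)
    b <- sqrt(p * q / (p + q)) *
      (rowMeans(lg[, num, drop = FALSE]) - rowMeans(lg[, den, drop = FALSE]))
    logit_auc(y, cbind(b, Z))
  }
  # step 1: exhaustive ordered pairs, visited in lexicographic order so
  # that the first maximum is the lexicographically smallest tie
  best <- list(crit = -Inf, num = NULL, den = NULL)
  for (i in ord) for (j in ord) {
    if (i == j) next
    cr <- crit_of(i, j)
    if (cr > best$crit + 1e-12) best <- list(crit = cr, num = i, den = j)
  }
  num <- best$num; den <- best$den
  trace <- best$crit
  steps <- list(list(num = num, den = den))
  while (length(num) + length(den) < max_size) {
    used <- c(num, den)
    cand <- setdiff(ord, used)
    if (length(cand) == 0) break
    best <- list(crit = -Inf, num = NULL, den = NULL)
    for (k in cand) {
      cr <- crit_of(c(num, k), den)
      if (cr > best$crit + 1e-12) best <- list(crit = cr, num = c(num, k), den = den)
      cr <- crit_of(num, c(den, k))
      if (cr > best$crit + 1e-12) best <- list(crit = cr, num = num, den = c(den, k))
    }
    num <- best$num; den <- best$den
    trace <- c(trace, best$crit)
    steps[[length(steps) + 1]] <- list(num = num, den = den)
  }
  list(steps = steps, trace = trace)
}

# Stratified fold assignment: both outcome classes represented in every
# training set; folds are re-drawn per repeat.
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

#' Forward selection of a predictive balance
#'
#' Searches for the balance of compositional parts most predictive of a
#' binary outcome, with covariate adjustment. The first step is an
#' exhaustive search over all ordered part pairs; each later step tries
#' every unused part on each side of the balance and keeps the best. The
#' model size (total number of parts, 2..`max_size`) is chosen by
#' repeated stratified k-fold cross-validation: the full forward path is
#' re-run on every training fold and the test-fold criterion (AUC of the
#' logistic model outcome ~ balance + covariates, refitted on the
#' training fold) is averaged per size; the highest mean wins, ties going
#' to the smaller size. The final balance is the full-data forward path
#' truncated at the chosen size. Fully reproducible given `seed`.
#'
#' @param x Composition matrix / data.frame (subjects x parts, named
#'   columns), rows closed to 100. Zeros are replaced via [zero_replace()].
#' @param outcome Binary outcome (0/1 or logical).
#' @param covariates Optional covariate matrix / data.frame (e.g. age in
#'   years and smoker 0/1), entered additively and untransformed.
#' @param max_size Maximum total number of parts (>= 2).
#' @param cv_folds,cv_repeats Cross-validation folds and repeats.
#' @param seed Integer seed (mandatory).
#' @param one_se_rule Choose the smallest size whose mean criterion is
#'   within one standard error of the best, instead of the best mean.
#' @param zero_method Passed to [zero_replace()].
#' @return Object of class `balance_selection`: `numerator`,
#'   `denominator` (labels), `scores` (per subject, from the re-closed
#'   data), `chosen_size`, `cv_table` (size, mean, sd of test criterion),
#'   `criterion_trace` (full-data training criterion per size),
#'   `covariates_used`, `seed`.
#' @export
forward_select <- function(x, outcome, covariates = NULL, max_size = 12,
                           cv_folds = 5, cv_repeats = 10, seed,
                           one_se_rule = FALSE,
                           zero_method = "pseudocount") {
  abort_if(missing(seed) || !is_count(seed), "seed is mandatory")
  if (is.data.frame(x)) x <- as.matrix(x)
  abort_if(is.null(colnames(x)), "x must have named part columns")
  abort_if(ncol(x) < 2, "need at least 2 parts")
  abort_if(max_size > ncol(x), "max_size cannot exceed the number of parts")
  abort_if(max_size < 2, "max_size must be at least 2")
  y <- as.integer(outcome)
  abort_if(!all(y %in% 0:1) || length(unique(y)) < 2,
           "outcome must be binary with both classes present")
  x <- zero_replace(x, method = zero_method)
  lg <- log(x)
  Z <- as_covariate_matrix(covariates, length(y))

  sizes <- 2:max_size
  cv_mat <- NULL
  if (length(sizes) > 1) {
    cv_mat <- matrix(NA_real_, cv_folds * cv_repeats, length(sizes))
    withr_seed(seed, {
      row <- 0
      for (rep_i in seq_len(cv_repeats)) {
        folds <- stratified_folds(y, cv_folds)
        for (f in seq_len(cv_folds)) {
          row <- row + 1
          tr <- folds != f
          path <- forward_path(lg[tr, , drop = FALSE], y[tr],
                               if (is.null(Z)) NULL else Z[tr, , drop = FALSE],
                               max_size)
          for (s in seq_along(path$steps)) {
            st <- path$steps[[s]]
            p <- length(st$num); q <- length(st$den)
            b <- sqrt(p * q / (p + q)) *
              (rowMeans(lg[, st$num, drop = FALSE]) -
               rowMeans(lg[, st$den, drop = FALSE]))
            fit <- suppressWarnings(stats::glm.fit(
              cbind(1, b[tr], if (is.null(Z)) NULL else Z[tr, , drop = FALSE]),
              y[tr], family = stats::binomial()))
            eta <- cbind(1, b[!tr], if (is.null(Z)) NULL else Z[!tr, , drop = FALSE]) %*%
              fit$coefficients
            cv_mat[row, s] <- auc_rank(drop(eta), y[!tr])
          }
        }
      }
    })
  }

  full <- forward_path(lg, y, Z, max_size)
  if (is.null(cv_mat)) {
    chosen <- max_size
    cv_table <- NULL
  } else {
    means <- colMeans(cv_mat, na.rm = TRUE)
    sds <- apply(cv_mat, 2, stats::sd, na.rm = TRUE)
    cv_table <- data.frame(size = sizes, mean = means, sd = sds)
    reachable <- sizes <= (1 + length(full$trace))
    if (one_se_rule) {
      best_i <- which.max(means)
      thr <- means[best_i] - sds[best_i] / sqrt(nrow(cv_mat))
      chosen <- sizes[which(means >= thr & reachable)[1]]
    } else {
      chosen <- sizes[which(means >= max(means[reachable]) - 1e-12 & reachable)[1]]
    }
  }
  step <- full$steps[[min(chosen - 1, length(full$steps))]]
  chosen <- length(step$num) + length(step$den)
  labels <- colnames(x)
  res <- list(
    numerator = labels[step$num],
    denominator = labels[step$den],
    scores = balance_score(x, labels[step$num], labels[step$den]),
    chosen_size = chosen,
    cv_table = cv_table,
    criterion_trace = full$trace,
    covariates_used = colnames(Z) %||% character(0),
    seed = as.integer(seed)
  )
  class(res) <- "balance_selection"
  res
}

#' @export
print.balance_selection <- function(x, ...) {
  cat("Balance selection (size ", x$chosen_size, ")\n", sep = "")
  cat("  numerator:  ", paste(x$numerator, collapse = ", "), "\n", sep = "")
  cat("  denominator:", paste(x$denominator, collapse = ", "), "\n")
  invisible(x)
}
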