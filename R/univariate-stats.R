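# Univariate toolkit: two-group rank-sum test, 2x2 proportion test,
# ordered-group trend test, and sequential Bonferroni (Holm) adjustment.
# All p-values are two-sided.

test_result <- function(statistic, p_raw, method, n_per_group,
                        p_adjusted = NULL) {
  structure(list(statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, method = method,
                 n_per_group = n_per_group),
            class = "glyco_test")
}

#' @export
print.glyco_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_raw), "\n", sep = "")
  invisible(x)
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n, n_x) group
# assignments of the pooled sample (valid under ties). Two-sided p is the
# probability of a U at least as far from the null mean n_x*n_y/2 as observed.
rank_sum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  combos <- utils::combn(n, nx)
  u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Two-group rank-sum (Mann-Whitney) test
#'
#' U statistic for the first sample. For combined n of 20 or fewer the
#' two-sided p is exact, by enumeration of all group assignments (valid
#' under ties); otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return A test-result list: `statistic` (U), `p_raw`, `method`,
#'   `n_per_group`.
#' @export
#' @examples
#' rank_sum(c(1, 2), c(3, 4))$p_raw  # exact: 1/3
rank_sum <- function(x, y) {
  abort_if(length(x) < 1 || length(y) < 1, "both groups must be non-empty")
  abort_if(anyNA(x) || anyNA(y), "NA values not allowed")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n <= 20) {
    p <- rank_sum_exact_p(x, y)
    method <- "Mann-Whitney (exact)"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "Mann-Whitney (normal approximation)"
  }
  test_result(u, p, method, c(nx, ny))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom, no continuity correction by default (Yates
#' available via `correct = TRUE`).
#'
#' @param table 2x2 matrix of non-negative counts; both row and column
#'   margins must be positive.
#' @param correct Apply the Yates continuity correction.
#' @return Test-result list.
#' @export
proportion_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  abort_if(!all(dim(table) == 2L), "need a 2x2 table")
  abort_if(any(table < 0), "counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  abort_if(any(rs == 0) || any(cs == 0), "zero margin")
  expected <- outer(rs, cs) / n
  d <- abs(table - expected)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / expected)
  test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              if (correct) "Chi-squared (Yates)" else "Chi-squared",
              rs)
}

# J statistic: over ordered group pairs k < l, concordant cross-pairs plus
# half the tied cross-pairs.
jt_statistic <- function(groups) {
  j <- 0
  k <- length(groups)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      d <- outer(groups[[a]], groups[[b]], `-`)
      j <- j + sum(d < 0) + 0.5 * sum(d == 0)
    }
  }
  j
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend in a numeric response across three or more
#' ordered groups. The two-sided p uses the normal approximation with the
#' standard no-tie null variance; when more than 10% of cross-group pairs
#' are tied, a seeded Monte-Carlo permutation null is used instead.
#'
#' @param groups List of numeric vectors in increasing category order.
#' @param n_perm Number of permutations for the Monte-Carlo fallback.
#' @param seed Seed for the permutation draw (local RNG state).
#' @param force_permutation Use the permutation null regardless of ties.
#' @return Test-result list; `statistic` is J.
#' @export
jonckheere_terpstra <- function(groups, n_perm = 10000, seed = 1,
                                force_permutation = FALSE) {
  abort_if(!is.list(groups) || length(groups) < 3,
           "need at least 3 ordered groups")
  abort_if(any(vapply(groups, length, 1L) == 0), "empty group")
  nk <- vapply(groups, length, 1L)
  n <- sum(nk)
  j <- jt_statistic(groups)
  mu <- (n^2 - sum(nk^2)) / 4
  n_cross <- (n^2 - sum(nk^2)) / 2
  pooled <- unlist(groups)
  # tied cross-pairs fraction
  tied <- 0
  k <- length(groups)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    tied <- tied + sum(outer(groups[[a]], groups[[b]], `==`))
  }
  use_perm <- force_permutation || tied > 0.1 * n_cross
  if (use_perm) {
    labels <- rep(seq_along(groups), nk)
    j_null <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- sample(pooled)
        jt_statistic(split(perm, labels))
      }, numeric(1))
    })
    p <- (1 + sum(abs(j_null - mu) >= abs(j - mu) - 1e-9)) / (1 + n_perm)
    method <- "Jonckheere-Terpstra (permutation)"
  } else {
    sigma2 <- (n^2 * (2 * n + 3) - sum(nk^2 * (2 * nk + 3))) / 72
    z <- (j - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    method <- "Jonckheere-Terpstra (normal approximation)"
  }
  test_result(j, p, method, nk)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Step-down Holm: the i-th smallest p is multiplied by (m - i + 1), a
#' running maximum enforces monotonicity, values are capped at 1, and the
#' result is returned in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_adjust <- function(p_values) {
  abort_if(anyNA(p_values) || any(p_values < 0 | p_values > 1),
           "p-values must be in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, cummax(p_values[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Sex-stratified univariate screen of cohort columns
#'
#' For each requested numeric column, compares risk against non-risk
#' drinkers within each sex (medians, IQRs, two-sided rank-sum p), with
#' Holm adjustment across the columns of each sex stratum.
#'
#' @param cohort Cohort data.frame with `sex` and `risk` columns.
#' @param columns Character vector of numeric column names to screen
#'   (default: the 46 peak columns).
#' @return data.frame: `sex`, `variable`, group medians/IQRs, `p_raw`,
#'   `p_holm`.
#' @export
univariate_screen <- function(cohort, columns = gp_labels()) {
  abort_if(!all(columns %in% names(cohort)), "unknown column in manifest")
  out <- list()
  for (sx in unique(cohort$sex)) {
    sel <- cohort$sex == sx
    grp <- cohort$risk[sel]
    rows <- lapply(columns, function(cl) {
      x <- cohort[[cl]][sel]
      a <- x[grp == "non-risk"]; b <- x[grp == "risk"]
      qa <- stats::quantile(a, c(.25, .5, .75), names = FALSE)
      qb <- stats::quantile(b, c(.25, .5, .75), names = FALSE)
      data.frame(sex = sx, variable = cl,
                 nonrisk_median = qa[2], nonrisk_q1 = qa[1], nonrisk_q3 = qa[3],
                 risk_median = qb[2], risk_q1 = qb[1], risk_q3 = qb[3],
                 p_raw = rank_sum(a, b)$p_raw, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$p_holm <- holm_adjust(res$p_raw)
    out[[sx]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
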