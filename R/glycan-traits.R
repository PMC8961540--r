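# Derived glycan traits.
#
# Each trait is a fixed linear aggregate of the 46 glycan peaks sharing a
# structural feature: degree of sialylation (S0-S4), galactosylation
# (G0-G4), antennarity (A1-A4), oligomannose content (OM), and core /
# outer-arm fucosylation (CF, OF). Peaks containing a mixture of two
# structures contribute fractionally: GP6, GP12, GP21 and GP44 split 1/2,
# GP41 and GP46 split 1/3. Three exact partition identities follow from
# the definitions on any closed profile:
#   S0+S1+S2+S3+S4 = 100,  G0+..+G4+OM = 100,  A1+..+A4+OM = 100.
# CF and OF are not a partition of anything and may overlap.

TRAIT_NAMES <- c("S0", "S1", "S2", "S3", "S4",
                 "G0", "G1", "G2", "G3", "G4",
                 "A1", "A2", "A3", "A4", "OM", "CF", "OF")

# Trait definitions as data: for each trait, the contributing peak numbers
# and their coefficients. This table is the contract; derive_traits() does
# nothing but apply it.
trait_definition_list <- function() {
  w <- function(peaks, coef = 1) stats::setNames(rep(coef, length(peaks)), peaks)
  list(
    S0 = w(1:15),
    S1 = c(w(16:23), w(30)),
    S2 = c(w(24:29), w(31)),
    S3 = w(32:40),
    S4 = w(41:46),
    G0 = c(w(1:2), w(4:5), w(6, 1/2), w(12, 1/2)),
    G1 = c(w(3), w(7:10), w(12, 1/2), w(16:18), w(21, 1/2)),
    G2 = c(w(13:15), w(19:20), w(21, 1/2), w(22:28)),
    G3 = c(w(29), w(31:37)),
    G4 = c(w(30), w(38:46)),
    A1 = c(w(1:3), w(12, 1/2), w(21, 1/2)),
    A2 = c(w(4:5), w(6, 1/2), w(7:10), w(12, 1/2), w(13:20), w(21, 1/2), w(22:28)),
    A3 = c(w(29), w(31:37)),
    A4 = c(w(30), w(38:46)),
    OM = c(w(6, 1/2), w(11)),
    CF = c(w(2), w(5), w(6, 1/2), w(8:10), w(14:15), w(17:18), w(22:23),
           w(27:28), w(36), w(44, 1/2)),
    OF = c(w(37), w(40), w(41, 1/3), w(45), w(46, 1/3))
  )
}

#' Trait aggregation coefficient matrix
#'
#' The 46 x 17 matrix of coefficients mapping a closed glycan peak vector
#' to the derived traits; `derive_traits(gp)` is `gp %*% trait_matrix()`.
#'
#' @return Numeric matrix, rows `GP1..GP46`, columns the 17 traits.
#' @export
trait_matrix <- function() {
  defs <- trait_definition_list()
  m <- matrix(0, N_PEAKS, length(TRAIT_NAMES),
              dimnames = list(gp_labels(), TRAIT_NAMES))
  for (tr in TRAIT_NAMES) {
    d <- defs[[tr]]
    idx <- as.integer(names(d))
    for (i in seq_along(d)) m[idx[i], tr] <- m[idx[i], tr] + d[i]
  }
  m
}

#' Compute derived glycan traits from a 46-peak profile
#'
#' @param gp Numeric 46-vector (single profile) or matrix / data.frame
#'   with 46 peak columns, each row a closed profile summing to 100.
#' @param tol Tolerance on the closure check.
#' @return Named 17-vector, or a matrix with one row per profile.
#' @export
#' @examples
#' derive_traits(rep(100 / 46, 46))[c("S0", "OM", "G0")]
derive_traits <- function(gp, tol = 1e-6) {
  if (is.data.frame(gp)) gp <- as.matrix(gp)
  single <- is.null(dim(gp))
  if (single) gp <- matrix(gp, nrow = 1)
  abort_if(ncol(gp) != N_PEAKS, "expected %d peak columns", N_PEAKS)
  abort_if(any(gp < 0), "peak values must be non-negative")
  abort_if(any(abs(rowSums(gp) - 100) > tol),
           "each profile must sum to 100 within %g", tol)
  out <- gp %*% trait_matrix()
  if (single) out[1, ] else out
}

#' Two-group trait comparison, stratified by sex
#'
#' For each derived trait, compares risk against non-risk drinkers within
#' each sex by medians, interquartile ranges and the two-sided rank-sum
#' test, with sequential Bonferroni (Holm) adjustment across the traits of
#' each sex stratum.
#'
#' @param cohort Cohort data.frame with `sex`, `risk` and `GP1..GP46`.
#' @param traits Traits to report (default all 17).
#' @return data.frame: `sex`, `trait`, per-group `median`/`q1`/`q3`,
#'   `p_raw`, `p_holm`.
#' @export
trait_group_compare <- function(cohort, traits = TRAIT_NAMES) {
  abort_if(!all(traits %in% TRAIT_NAMES), "unknown trait name")
  tv <- derive_traits(cohort[, gp_labels()])
  out <- list()
  for (sx in unique(cohort$sex)) {
    sel <- cohort$sex == sx
    grp <- cohort$risk[sel]
    abort_if(sum(grp == "risk") < 2 || sum(grp == "non-risk") < 2,
             "need at least 2 subjects per risk group in sex stratum %s", sx)
    rows <- lapply(traits, function(tr) {
      x <- tv[sel, tr]
      a <- x[grp == "non-risk"]; b <- x[grp == "risk"]
      qa <- stats::quantile(a, c(.25, .5, .75), names = FALSE, type = 7)
      qb <- stats::quantile(b, c(.25, .5, .75), names = FALSE, type = 7)
      data.frame(sex = sx, trait = tr,
                 nonrisk_median = qa[2], nonrisk_q1 = qa[1], nonrisk_q3 = qa[3],
                 risk_median = qb[2], risk_q1 = qb[1], risk_q3 = qb[3],
                 p_raw = rank_sum(a, b)$p_raw,
                 stringsAsFactors = FALSE)
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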