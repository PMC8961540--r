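#' glycorisk: serum N-glycome analysis of alcohol risk drinking
#'
#' @keywords internal
#' @importFrom jsonlite write_json
"_PACKAGE"

# Number of chromatographic glycan peaks in the standard serum profile.
N_PEAKS <- 46L

gp_labels <- function() paste0("GP", seq_len(N_PEAKS))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x)
}

#' Rescale a non-negative vector to sum to 100
#'
#' Closure is the defining operation of compositional data: only relative
#' information is retained. Used both by the chromatogram reduction (percent
#' of total integrated area) and by the synthetic cohort generator.
#'
#' @param areas Numeric vector of non-negative values with a positive sum.
#' @return Numeric vector of the same length summing to 100.
#' @export
#' @examples
#' close_to_percent(rep(1, 46))[1]  # 100/46
close_to_percent <- function(areas) {
  abort_if(!is.numeric(areas) || anyNA(areas), "areas must be numeric without NA")
  abort_if(any(areas < 0), "areas must be non-negative")
  s <- sum(areas)
  abort_if(s <= 0, "cannot close a vector with non-positive total area")
  100 * areas / s
}

# Dispersion on the natural-log scale implied by a reported median and
# interquartile range under a log-normal model: sigma = (ln q3 - ln q1) / 1.349
# (1.349 = 2 * qnorm(0.75)).
lognormal_sigma <- function(q1, q3) {
  abort_if(any(q1 <= 0) || any(q3 <= q1), "need 0 < q1 < q3 for log-normal dispersion")
  (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
}

# Draw from a log-normal with given median and log-sd.
rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}
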