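# Chromatogram reduction: dextran-ladder calibration of retention time to
# glucose units (GU), binning of integrated peaks into the 46 standard GU
# windows, and closure to percent of total area.

#' Dextran ladder calibration points
#'
#' @param rt Retention times in minutes, strictly increasing with `gu`.
#' @param gu Glucose-unit values (positive integers for a hydrolysed
#'   glucose oligomer ladder).
#' @return Object of class `dextran_ladder`.
#' @export
dextran_ladder <- function(rt, gu) {
  abort_if(length(rt) != length(gu), "rt and gu must have equal length")
  abort_if(length(rt) < 7, "a dextran ladder needs at least 7 points")
  o <- order(gu)
  rt <- rt[o]; gu <- gu[o]
  abort_if(any(diff(rt) <= 0),
           "retention times must be strictly increasing with GU")
  abort_if(any(gu <= 0), "GU values must be positive")
  structure(list(rt = rt, gu = gu), class = "dextran_ladder")
}

#' Fit the retention-time to glucose-unit calibration curve
#'
#' Least-squares fifth-order polynomial mapping retention time (minutes)
#' to GU, fitted to a dextran ladder. The fit is rejected if the
#' polynomial is not strictly increasing over the ladder's retention-time
#' range (a non-monotone calibration cannot assign peak identities).
#'
#' @param ladder A [dextran_ladder()].
#' @return Object of class `gu_calibration`: `coefficients` (length 6,
#'   ascending powers), `valid_range` (min/max ladder rt).
#' @export
fit_gu_curve <- function(ladder) {
  abort_if(!inherits(ladder, "dextran_ladder"), "ladder must be a dextran_ladder")
  fit <- stats::lm(gu ~ poly(rt, 5, raw = TRUE),
                   data = data.frame(rt = ladder$rt, gu = ladder$gu))
  coefs <- unname(stats::coef(fit))
  rng <- range(ladder$rt)
  cal <- structure(list(coefficients = coefs, valid_range = rng),
                   class = "gu_calibration")
  # derivative sign on a fine grid over the calibrated range
  grid <- seq(rng[1], rng[2], length.out = 2048)
  dcoef <- coefs[-1] * seq_len(5)
  deriv <- outer(grid, 0:4, `^`) %*% dcoef
  abort_if(any(deriv <= 0),
           "fitted calibration polynomial is not strictly increasing on [%.3f, %.3f]",
           rng[1], rng[2])
  cal
}

#' Evaluate a calibration curve
#'
#' @param cal A `gu_calibration`.
#' @param rt Retention times (minutes).
#' @return GU values.
#' @export
predict_gu <- function(cal, rt) {
  abort_if(!inherits(cal, "gu_calibration"), "cal must be a gu_calibration")
  drop(outer(rt, 0:5, `^`) %*% cal$coefficients)
}

#' Standard 46-window GU binning table
#'
#' The published 46-peak integration scheme does not print its GU window
#' boundaries (they live in the cited prior integration protocol), so the
#' package ships a configurable table. The default is a placeholder of 46
#' contiguous equal-width half-open windows spanning GU 4.4-12.0; any
#' analysis of real chromatograms should supply the laboratory's own
#' boundaries via `gu_windows()` or a three-column CSV
#' (label, lo, hi; see [read_gu_windows_csv()]).
#'
#' @param lo,hi Vectors of 46 window bounds; windows `[lo, hi)` must be
#'   contiguous (`hi[i] == lo[i+1]`) and increasing.
#' @return Object of class `gu_windows`: data.frame `label`, `lo`, `hi`.
#' @export
gu_windows <- function(lo, hi) {
  abort_if(length(lo) != N_PEAKS || length(hi) != N_PEAKS,
           "need %d windows", N_PEAKS)
  abort_if(any(hi <= lo), "each window needs lo < hi")
  abort_if(any(abs(lo[-1] - hi[-N_PEAKS]) > 1e-9),
           "windows must be contiguous: hi[i] == lo[i+1]")
  structure(data.frame(label = gp_labels(), lo = lo, hi = hi,
                       stringsAsFactors = FALSE),
            class = c("gu_windows", "data.frame"))
}

#' @rdname gu_windows
#' @export
default_gu_windows <- function() {
  b <- seq(4.4, 12.0, length.out = N_PEAKS + 1)
  gu_windows(b[-(N_PEAKS + 1)], b[-1])
}

#' Bin integrated peaks into the 46 GU windows
#'
#' Each peak's retention time is converted to GU through the calibration;
#' its area is added to the half-open window `[lo, hi)` containing that GU
#' (a GU exactly at a boundary belongs to the upper window). Peaks whose
#' retention time falls outside the calibration's valid range, or whose GU
#' falls outside all windows, are not assigned: their total is returned in
#' the `unassigned` attribute and a warning is emitted.
#'
#' @param peaks data.frame with columns `rt` (minutes) and `area`
#'   (fluorescence units, non-negative, at least one positive).
#' @param cal A `gu_calibration`.
#' @param windows A `gu_windows` table (default [default_gu_windows()]).
#' @return Named 46-vector of summed areas, attribute `unassigned`.
#' @export
assign_peaks <- function(peaks, cal, windows = default_gu_windows()) {
  abort_if(!all(c("rt", "area") %in% names(peaks)),
           "peaks needs columns rt and area")
  abort_if(any(peaks$area < 0), "peak areas must be non-negative")
  abort_if(!any(peaks$area > 0), "at least one peak area must be positive")
  out <- stats::setNames(numeric(N_PEAKS), windows$label)
  in_range <- peaks$rt >= cal$valid_range[1] & peaks$rt <= cal$valid_range[2]
  if (any(!in_range)) {
    warning(sprintf("%d peak(s) outside calibration range treated as unassigned",
                    sum(!in_range)), call. = FALSE)
  }
  gu <- rep(NA_real_, nrow(peaks))
  gu[in_range] <- predict_gu(cal, peaks$rt[in_range])
  # findInterval with left-closed intervals: boundary GU goes to upper window
  edges <- c(windows$lo, windows$hi[N_PEAKS])
  idx <- findInterval(gu, edges, left.open = FALSE, rightmost.closed = FALSE)
  idx[!is.na(gu) & (gu >= windows$hi[N_PEAKS])] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  assigned <- !is.na(idx)
  for (i in which(assigned)) out[idx[i]] <- out[idx[i]] + peaks$area[i]
  attr(out, "unassigned") <- sum(peaks$area[!assigned])
  out
}

#' Reduce a peak list to a closed 46-peak percent table
#'
#' Convenience composition of [assign_peaks()] and [close_to_percent()].
#'
#' @inheritParams assign_peaks
#' @return Named 46-vector summing to 100, attribute `unassigned`
#'   (percent of total raw area not assigned to any window).
#' @export
reduce_chromatogram <- function(peaks, cal, windows = default_gu_windows()) {
  areas <- assign_peaks(peaks, cal, windows)
  un <- attr(areas, "unassigned")
  out <- close_to_percent(as.numeric(areas))
  names(out) <- names(areas)
  attr(out, "unassigned") <- 100 * un / (sum(areas) + un)
  out
}

#' Integrate a raw trace into a peak list (fixture convenience)
#'
#' A minimal valley-to-valley integrator for synthetic traces: local
#' maxima above a threshold become peak apexes; peak area is the trapezoid
#' sum between the flanking local minima. Not intended for real
#' chromatograms (no baseline correction or alignment).
#'
#' @param rt,signal Equal-length numeric vectors; `rt` increasing.
#' @param min_height Apex threshold as a fraction of the signal maximum.
#' @return data.frame with columns `rt` (apex) and `area`.
#' @export
integrate_trace <- function(rt, signal, min_height = 0.01) {
  abort_if(length(rt) != length(signal) || length(rt) < 3,
           "rt and signal must be equal-length vectors of length >= 3")
  n <- length(signal)
  apex <- which(diff(sign(diff(signal))) < 0) + 1L
  apex <- apex[signal[apex] >= min_height * max(signal)]
  if (length(apex) == 0) {
    return(data.frame(rt = numeric(0), area = numeric(0)))
  }
  valleys <- c(1L,
               vapply(seq_len(length(apex) - 1), function(i) {
                 seg <- apex[i]:apex[i + 1]
                 seg[which.min(signal[seg])]
               }, integer(1)),
               n)
  area <- vapply(seq_along(apex), function(i) {
    seg <- valleys[i]:valleys[i + 1]
    sum(diff(rt[seg]) * (signal[seg][-1] + signal[seg][-length(seg)]) / 2)
  }, numeric(1))
  data.frame(rt = rt[apex], area = area)
}

#' Read helpers for calibration inputs
#'
#' Two-column CSVs `rt, gu` (ladder) and `rt, area` (peak list); a
#' three-column CSV `label, lo, hi` for the window table.
#'
#' @param path File path.
#' @return The corresponding object.
#' @export
read_dextran_ladder_csv <- function(path) {
  x <- utils::read.csv(path)
  dextran_ladder(x$rt, x$gu)
}

#' @rdname read_dextran_ladder_csv
#' @export
read_peak_list_csv <- function(path) {
  x <- utils::read.csv(path)
  abort_if(!all(c("rt", "area") %in% names(x)), "peak list needs rt, area columns")
  x[, c("rt", "area")]
}

#' @rdname read_dextran_ladder_csv
#' @export
read_gu_windows_csv <- function(path) {
  x <- utils::read.csv(path)
  gu_windows(x$lo, x$hi)
}
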