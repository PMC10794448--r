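# Longitudinal signal construction: uniform resampling of frame-wise
# features onto the 60 frames/mm grid, BL/FU co-registration, and
# differentiation.

#' Interpolate irregular frame samples onto the uniform 60 frames/mm grid
#'
#' Linear interpolation of (position, value) samples onto the grid
#' \code{origin + i/60} mm, where the origin is the first sample position and
#' the last grid point does not exceed the last sample position (no
#' extrapolation).
#'
#' @param positions strictly increasing axial positions in mm.
#' @param values feature values at those positions.
#' @param name feature identifier carried by the resulting signal.
#' @return a [LongitudinalSignal-class].
#' @examples
#' s <- interpolateUniform(c(0, 1), c(0, 60))
#' signalValues(s)[1:5]  # 0 1 2 3 4: one unit per interpolated frame
#' @export
interpolateUniform <- function(positions, values, name = "f") {
  if (length(positions) < 2L)
    ptStop("too_few_samples", "need at least 2 samples to interpolate")
  if (length(positions) != length(values))
    ptStop("too_few_samples", "positions and values must have equal length")
  if (any(diff(positions) <= 0))
    ptStop("ordering_error", "sample positions must be strictly increasing")
  span <- positions[length(positions)] - positions[1L]
  n <- floor(span * 60 + 1e-9) + 1L
  grid <- positions[1L] + (seq_len(n) - 1L) / 60
  # rule = 2: the 1e-9 tolerance can put the last grid point a rounding error
  # past the last sample; constant extension there is exact to that error
  v <- approx(positions, values, xout = grid, ties = "ordered", rule = 2)$y
  LongitudinalSignal(v, originMm = positions[1L], name = name)
}

.pearson <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  cor(a, b)
}

#' Co-register baseline and follow-up pullback signals
#'
#' The reference workflow is manual: an operator shifts and clips the
#' signals until local extrema match. The automated surrogate searches the
#' integer shift that maximises the mean Pearson correlation of the
#' plaque-burden and vessel-area signals over the overlap, over all shifts
#' leaving at least \code{minOverlap} interpolated frames (default 300 = 5
#' mm). \code{manualShift} bypasses the search and preserves the manual
#' workflow. Ties (including constant, correlation-free signals) resolve to
#' the smallest |shift|, negative before positive.
#'
#' @param blPB,blVA [LongitudinalSignal-class]: baseline plaque burden and
#'   vessel area.
#' @param fuPB,fuVA follow-up counterparts.
#' @param manualShift optional integer shift to apply verbatim.
#' @param minOverlap minimum retained overlap, in interpolated frames.
#' @return a [RegistrationResult-class]; BL frame \code{i} aligns with FU
#'   frame \code{i + shiftFrames}, and the retained half-open ranges are
#'   0-based.
#' @export
coregister <- function(blPB, blVA, fuPB, fuVA, manualShift = NULL,
                       minOverlap = 300L) {
  pb <- signalValues(blPB); va <- signalValues(blVA)
  qb <- signalValues(fuPB); qa <- signalValues(fuVA)
  if (length(pb) != length(va) || length(qb) != length(qa))
    ptStop("alignment_error", "PB and vessel-area signals differ in length")
  nb <- length(pb); nf <- length(qb)

  overlapIdx <- function(s) {
    i0 <- max(0L, -s); i1 <- min(nb, nf - s)
    if (i1 - i0 < 1L) return(NULL)
    list(bl = (i0 + 1L):i1, fu = (i0 + s + 1L):(i1 + s), i0 = i0, i1 = i1)
  }
  scoreShift <- function(s) {
    ov <- overlapIdx(s)
    cs <- c(.pearson(pb[ov$bl], qb[ov$fu]), .pearson(va[ov$bl], qa[ov$fu]))
    if (all(is.na(cs))) 0 else mean(cs, na.rm = TRUE)
  }

  if (!is.null(manualShift)) {
    s <- as.integer(manualShift)
    ov <- overlapIdx(s)
    if (is.null(ov))
      ptStop("no_overlap", "manual shift leaves no overlap")
    return(new("RegistrationResult", shiftFrames = s,
               blRange = c(ov$i0, ov$i1),
               fuRange = c(ov$i0 + s, ov$i1 + s), score = scoreShift(s)))
  }

  minOverlap <- max(2L, as.integer(minOverlap))
  sMax <- nf - minOverlap
  sMin <- minOverlap - nb
  if (sMax < sMin)
    ptStop("no_overlap", sprintf(
      "no shift leaves the minimum overlap of %d frames", minOverlap))
  shifts <- sMin:sMax
  shifts <- shifts[order(abs(shifts), shifts)]  # tie-break: smallest |shift|
  scores <- vapply(shifts, scoreShift, numeric(1))
  best <- shifts[which.max(scores)]
  ov <- overlapIdx(best)
  new("RegistrationResult", shiftFrames = as.integer(best),
      blRange = c(ov$i0, ov$i1), fuRange = c(ov$i0 + best, ov$i1 + best),
      score = max(scores))
}

#' Clip a signal to a registration range
#'
#' @param signal a [LongitudinalSignal-class].
#' @param range half-open 0-based frame interval \code{c(start, end)}.
#' @return the clipped [LongitudinalSignal-class].
#' @export
clipSignal <- function(signal, range) {
  v <- signalValues(signal)
  if (range[1L] < 0L || range[2L] > length(v))
    ptStop("range_error", "clip range outside signal support")
  LongitudinalSignal(v[(range[1L] + 1L):range[2L]],
                     originMm = signal@originMm + range[1L] / 60,
                     name = signal@name)
}

#' First derivative of a longitudinal signal
#'
#' Central finite differences at interior frames, first-order one-sided
#' differences at the endpoints; spacing 1/60 mm, so units are per mm. The
#' result is named \code{"d<name>"}.
#'
#' @param signal a [LongitudinalSignal-class] with >= 3 frames.
#' @return a [LongitudinalSignal-class] of equal length.
#' @export
signalDerivative <- function(signal) {
  v <- signalValues(signal)
  n <- length(v)
  if (n < 3L)
    ptStop("too_short", "derivative needs at least 3 frames")
  h <- signal@spacing
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * h)
  d[1L] <- (v[2L] - v[1L]) / h
  d[n] <- (v[n] - v[n - 1L]) / h
  LongitudinalSignal(d, originMm = signal@originMm,
                     name = paste0("d", signal@name))
}

#' Optional moving-average smoothing
#'
#' Off by default everywhere in the pipeline (no smoothing precedes
#' differentiation); provided for exploratory use.
#'
#' @param signal a [LongitudinalSignal-class].
#' @param window odd window width in frames.
#' @return the smoothed [LongitudinalSignal-class].
#' @export
smoothSignal <- function(signal, window = 5L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  v <- signalValues(signal)
  k <- (window - 1L) %/% 2L
  padded <- c(rep(v[1L], k), v, rep(v[length(v)], k))
  sm <- stats::filter(padded, rep(1 / window, window), sides = 2L)
  LongitudinalSignal(as.numeric(sm[(k + 1L):(k + length(v))]),
                     originMm = signal@originMm, name = signal@name)
}
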