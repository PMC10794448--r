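# ROI partitioning of co-registered pullbacks and the dPAV target.
#
# ROIs are half-open intervals [start, end) of 0-based interpolated frames on
# the aligned grid. Six criteria: FP (full pullback), ChPAV (sign-pure runs
# of the PB change), PBR (baseline PB bins), and fixed windows W30O10,
# W60O20, W120O20 pooled over their offsets.

.MIN_RUN <- 15L  # runs under 15 interpolated frames (0.25 mm) are discarded

.roiRow <- function(pullbackId, criterion, offsetId, start, end) {
  data.frame(pullback_id = pullbackId, criterion = criterion,
             offset_id = offsetId, start = as.integer(start),
             end = as.integer(end),
             length_mm = (end - start) / 60,
             stringsAsFactors = FALSE)
}

.emptyRoiTable <- function() {
  data.frame(pullback_id = character(0), criterion = character(0),
             offset_id = integer(0), start = integer(0), end = integer(0),
             length_mm = numeric(0), stringsAsFactors = FALSE)
}

# maximal runs of a constant integer code; code NA breaks runs
.runs <- function(code) {
  n <- length(code)
  brk <- which(code[-1L] != code[-n] | is.na(code[-1L]) != is.na(code[-n]))
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  keep <- !is.na(code[starts])
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             code = code[starts[keep]])
}

#' ROIs from the sign of the plaque-burden change (ChPAV criterion)
#'
#' Forms maximal runs where the difference d = PB_FU - PB_BL keeps a constant
#' sign on every interpolated frame (d = 0 breaks runs), then discards runs
#' whose maximum |d| stays below \code{minDelta} (default 0.5 percentage
#' points) and runs spanning fewer than 15 interpolated frames (0.25 mm).
#' Requires follow-up data, so it is a reference criterion, not a clinically
#' applicable one.
#'
#' @param pbBL,pbFU aligned baseline/follow-up plaque-burden signals
#'   ([LongitudinalSignal-class]) of equal length.
#' @param pullbackId identifier copied into the ROI table.
#' @param minDelta discard threshold on max |d| within a run, in percentage
#'   points; set \code{deltaRule = "mean"} to threshold the run mean instead.
#' @param deltaRule \code{"max"} (default) or \code{"mean"}.
#' @return ROI table (data.frame): \code{pullback_id, criterion, offset_id,
#'   start, end, length_mm}.
#' @export
partitionChPAV <- function(pbBL, pbFU, pullbackId = "pb",
                           minDelta = 0.5, deltaRule = c("max", "mean")) {
  deltaRule <- match.arg(deltaRule)
  b <- signalValues(pbBL); f <- signalValues(pbFU)
  if (length(b) != length(f))
    ptStop("alignment_error", "BL and FU signals differ in length")
  d <- f - b
  code <- ifelse(d > 0, 1L, ifelse(d < 0, -1L, NA_integer_))
  runs <- .runs(code)
  if (!nrow(runs)) return(.emptyRoiTable())
  stat <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- abs(d[(runs$start[i] + 1L):runs$end[i]])
    if (deltaRule == "max") max(seg) else mean(seg)
  }, numeric(1))
  keep <- (runs$end - runs$start >= .MIN_RUN) & (stat >= minDelta)
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(.emptyRoiTable())
  .roiRow(pullbackId, "ChPAV", 0L, runs$start, runs$end)
}

#' ROIs from baseline plaque-burden bins (PBR criterion)
#'
#' The baseline PB signal is binned into [0, 30), [30, 60) and [60, 100]
#' (half-open lower bins, closed top bin, exactly as defined); maximal
#' constant-category runs become ROIs and runs under 15 interpolated frames
#' are discarded. Uses baseline data only, so it is clinically applicable.
#'
#' @param pbBL baseline plaque-burden signal.
#' @inheritParams partitionChPAV
#' @return ROI table with a \code{category} column (0 = low, 1 = mid,
#'   2 = high).
#' @export
partitionPBR <- function(pbBL, pullbackId = "pb") {
  b <- signalValues(pbBL)
  if (any(b < 0 | b > 100))
    ptStop("invalid_signal", "PB outside [0, 100]")
  code <- findInterval(b, c(30, 60))  # 0, 1, 2; edges go to the upper bin
  runs <- .runs(code)
  keep <- runs$end - runs$start >= .MIN_RUN
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(.emptyRoiTable())
  out <- .roiRow(pullbackId, "PBR", 0L, runs$start, runs$end)
  out$category <- as.integer(runs$code)
  out
}

.WINDOW_OFFSETS <- list(`30` = c(0L, 10L, 20L),
                        `60` = c(0L, 20L, 40L),
                        `120` = c(0L, 20L, 40L, 60L, 80L, 100L))

#' Fixed-size sliding-window ROIs (W30O10, W60O20, W120O20 criteria)
#'
#' For each offset o, non-overlapping windows \code{[o + k*w, o + (k+1)*w)}
#' are placed over the pullback; trailing partial windows are dropped and the
#' ROIs of all offsets are pooled (tagged by \code{offset_id}).
#'
#' @param pullbackLength pullback length in interpolated frames.
#' @param window window size in frames: 30, 60 or 120.
#' @param offsets integer offsets; defaults to the per-window convention
#'   (30: 0/10/20; 60: 0/20/40; 120: 0/20/.../100).
#' @inheritParams partitionChPAV
#' @return ROI table.
#' @export
partitionWindows <- function(pullbackLength, window, offsets = NULL,
                             pullbackId = "pb") {
  window <- as.integer(window)
  if (window <= 0L)
    ptStop("config_error", "window size must be positive")
  if (is.null(offsets)) {
    offsets <- .WINDOW_OFFSETS[[as.character(window)]]
    if (is.null(offsets))
      ptStop("config_error",
             "no default offsets for this window size; pass `offsets`")
  }
  crit <- sprintf("W%dO%d", window,
                  if (length(offsets) > 1L) diff(offsets)[1L] else 0L)
  rows <- lapply(seq_along(offsets), function(j) {
    o <- as.integer(offsets[j])
    k <- seq.int(0L, length.out = max(0L, (pullbackLength - o) %/% window))
    if (!length(k)) return(NULL)
    .roiRow(pullbackId, crit, j - 1L, o + k * window, o + (k + 1L) * window)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .emptyRoiTable() else out
}

#' Full-pullback ROI (FP criterion)
#'
#' @inheritParams partitionWindows
#' @return a single-row ROI table spanning \code{[0, pullbackLength)}.
#' @export
partitionFullPullback <- function(pullbackLength, pullbackId = "pb") {
  if (pullbackLength < .MIN_RUN)
    ptStop("config_error", "pullback shorter than 15 interpolated frames")
  .roiRow(pullbackId, "FP", 0L, 0L, pullbackLength)
}

#' Partition a pullback under any criterion
#'
#' Dispatch wrapper over [partitionFullPullback()], [partitionChPAV()],
#' [partitionPBR()] and [partitionWindows()].
#'
#' @param criterion one of \code{"FP", "ChPAV", "PBR", "W30O10", "W60O20",
#'   "W120O20"}.
#' @param pbBL,pbFU aligned plaque-burden signals (FU needed for ChPAV only).
#' @inheritParams partitionChPAV
#' @return ROI table.
#' @export
partitionROIs <- function(criterion, pbBL, pbFU = NULL, pullbackId = "pb") {
  switch(criterion,
    FP = partitionFullPullback(length(signalValues(pbBL)), pullbackId),
    ChPAV = {
      if (is.null(pbFU))
        ptStop("config_error", "ChPAV partitioning needs the FU PB signal")
      partitionChPAV(pbBL, pbFU, pullbackId)
    },
    PBR = partitionPBR(pbBL, pullbackId),
    W30O10 = partitionWindows(length(signalValues(pbBL)), 30L,
                              pullbackId = pullbackId),
    W60O20 = partitionWindows(length(signalValues(pbBL)), 60L,
                              pullbackId = pullbackId),
    W120O20 = partitionWindows(length(signalValues(pbBL)), 120L,
                               pullbackId = pullbackId),
    ptStop("config_error", sprintf("unknown ROI criterion '%s'", criterion))
  )
}

# Trapezoidal integral of an area signal over the half-open frame interval
# [start, end): sampled at frames start..min(end, n-1), step 1/60 mm. The
# right edge of an interior ROI is shared with its successor, so integrals
# over a disjoint exhaustive partition sum exactly to the whole-pullback
# integral.
.roiIntegral <- function(values, start, end) {
  n <- length(values)
  hi <- min(end, n - 1L)
  idx <- (start + 1L):(hi + 1L)
  v <- values[idx]
  if (length(v) < 2L) return(v[1L] / 60)  # degenerate single-sample cell
  sum((v[-1L] + v[-length(v)]) / 2) / 60
}

#' Volumes, PAV and the dPAV target of one ROI
#'
#' Total lumen/vessel/atheroma volumes by trapezoidal integration of the
#' aligned area signals over the ROI (step 1/60 mm), percent atheroma volume
#' PAV = 100 * TAV / TVV per phase, the change dPAV = PAV_FU - PAV_BL, and
#' the progression/regression class with threshold epsilon = 0 (the
#' measure-zero tie dPAV = 0 is assigned to regression so the two classes
#' partition outcomes).
#'
#' @param roi one ROI-table row (or any list with \code{start}, \code{end}).
#' @param blAreas,fuAreas named lists of aligned
#'   [LongitudinalSignal-class]s \code{lumenA}, \code{vesselA},
#'   \code{plaqueA} for each phase.
#' @return list with \code{TLV_BL, TVV_BL, TAV_BL, PAV_BL} (and FU
#'   counterparts), \code{dPAV} (%) and \code{class}
#'   (\code{"progression"}/\code{"regression"}).
#' @export
roiTarget <- function(roi, blAreas, fuAreas) {
  start <- roi$start; end <- roi$end
  nBL <- length(signalValues(blAreas$lumenA))
  nFU <- length(signalValues(fuAreas$lumenA))
  if (start < 0L || end > nBL || end > nFU)
    ptStop("range_error", "ROI outside the aligned signal support")
  vol <- function(areas) {
    tlv <- .roiIntegral(signalValues(areas$lumenA), start, end)
    tvv <- .roiIntegral(signalValues(areas$vesselA), start, end)
    tav <- .roiIntegral(signalValues(areas$plaqueA), start, end)
    list(TLV = tlv, TVV = tvv, TAV = tav, PAV = 100 * tav / tvv)
  }
  b <- vol(blAreas); f <- vol(fuAreas)
  dPAV <- f$PAV - b$PAV
  list(TLV_BL = b$TLV, TVV_BL = b$TVV, TAV_BL = b$TAV, PAV_BL = b$PAV,
       TLV_FU = f$TLV, TVV_FU = f$TVV, TAV_FU = f$TAV, PAV_FU = f$PAV,
       dPAV = dPAV,
       class = if (dPAV > 0) "progression" else "regression")
}
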