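# Condensation of frame-wise signals into ROI-wise features, and assembly of
# the Sa / Sb / Sd feature sets.
#
# Feature-set arithmetic (asserted at assembly): Sa = 20 patient-level
# clinical covariates; Sb = Sa + {TLV, TVV, TAV, PAV} at baseline over the
# ROI (24); Sd = Sb + 6 condensations x 36 signals (18 features and their 18
# derivatives) + arterial label + ROI length = 24 + 216 + 2 = 242.

.CLINICAL_VARS <- c("AGE", "MSX", "BMI", "HDL", "LDL", "DIA", "HYT", "HYC",
                    "CSK", "FHC", "RFL", "PMI", "PPI", "STA", "ASP", "PRA",
                    "CLO", "DAPT", "BB", "ACE")

.CONDENSATIONS <- c("MED", "IQR", "ICR", "H", "FFTm", "FFTp")

#' Order-statistic condensations of a segment
#'
#' Median, interquartile range (percentile 75 - 25) and central-80% range
#' (percentile 90 - 10); percentiles by linear interpolation between order
#' statistics.
#'
#' @param segment non-empty numeric vector.
#' @return list with \code{MED}, \code{IQR}, \code{ICR}.
#' @export
condenseStatistics <- function(segment) {
  if (!length(segment))
    ptStop("empty_input", "cannot condense an empty segment")
  q <- unname(quantile(segment, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  list(MED = q[3L], IQR = q[4L] - q[2L], ICR = q[5L] - q[1L])
}

#' Shannon entropy of a segment (bits)
#'
#' Histogram approximation of the discrete probability function: nBins
#' equal-width bins spanning the segment's own [min, max]; H = -sum p log2 p
#' with 0 log 0 = 0. A constant segment occupies one bin and has H = 0.
#'
#' @param segment non-empty numeric vector.
#' @param nBins number of histogram bins (default 16).
#' @return entropy in bits, in [0, log2(nBins)].
#' @export
shannonEntropy <- function(segment, nBins = 16L) {
  if (!length(segment))
    ptStop("empty_input", "cannot condense an empty segment")
  lo <- min(segment); hi <- max(segment)
  if (hi == lo) return(0)
  bin <- pmin(nBins, floor((segment - lo) / (hi - lo) * nBins) + 1L)
  p <- tabulate(bin, nbins = nBins) / length(segment)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Magnitude and phase of the first Fourier harmonic
#'
#' X1 = sum_t v_t exp(-2 pi i t / N) over t = 0..N-1; magnitude normalised
#' as 2|X1|/N so a unit-amplitude single-cycle sinusoid has magnitude 1;
#' phase arg(X1) in (-pi, pi], defined as 0 when the magnitude vanishes.
#'
#' @param segment numeric vector of length >= 2.
#' @return list with \code{FFTm}, \code{FFTp}.
#' @export
fftFirstHarmonic <- function(segment) {
  n <- length(segment)
  if (n < 2L)
    ptStop("too_short", "first harmonic needs at least 2 samples")
  x1 <- sum(segment * exp(-2i * pi * (seq_len(n) - 1L) / n))
  m <- 2 * Mod(x1) / n
  list(FFTm = m, FFTp = if (m < 1e-12) 0 else Arg(x1))
}

#' All six condensations of one segment
#'
#' @inheritParams shannonEntropy
#' @return named list \code{MED, IQR, ICR, H, FFTm, FFTp}.
#' @export
condenseSegment <- function(segment, nBins = 16L) {
  cs <- condenseStatistics(segment)
  fh <- fftFirstHarmonic(segment)
  list(MED = cs$MED, IQR = cs$IQR, ICR = cs$ICR,
       H = shannonEntropy(segment, nBins), FFTm = fh$FFTm, FFTp = fh$FFTp)
}

#' Names of the Sd condensed-feature columns
#'
#' 6 condensations x 36 signals (the 18 frame-wise features and their
#' derivatives), named \code{<stat>_<signal>}, e.g. \code{MED_PB},
#' \code{FFTp_dPB}.
#'
#' @return character vector of length 216.
#' @export
condensedFeatureNames <- function() {
  signals <- c(.FRAME_FEATURES, paste0("d", .FRAME_FEATURES))
  as.vector(outer(.CONDENSATIONS, signals, paste, sep = "_"))
}

#' Assemble the feature vector of one ROI
#'
#' Builds the Sa, Sb or Sd feature set for one ROI from the patient's
#' clinical record, the ROI's baseline volumes, and (for Sd) the six
#' condensations of all 36 baseline signals plus the arterial label and ROI
#' length. Condensations use BASELINE signals only; follow-up data enters
#' solely through the dPAV target (and the ChPAV partition).
#'
#' @param roi one ROI-table row (needs \code{start}, \code{end},
#'   \code{length_mm}).
#' @param blSignals named list of 36 aligned baseline
#'   [LongitudinalSignal-class]s: the 18 frame-wise features and their
#'   derivatives (\code{d}-prefixed names).
#' @param clinical single-row data.frame (or list) with the 20 patient-level
#'   covariates \code{AGE, MSX, BMI, HDL, LDL, DIA, HYT, HYC, CSK, FHC, RFL,
#'   PMI, PPI, STA, ASP, PRA, CLO, DAPT, BB, ACE}.
#' @param volumes list with baseline \code{TLV_BL, TVV_BL, TAV_BL, PAV_BL}
#'   (as from [roiTarget()]); required for Sb and Sd.
#' @param artery arterial label (categorical; required for Sd).
#' @param setId \code{"Sa"}, \code{"Sb"} or \code{"Sd"}.
#' @param nBins entropy histogram bins.
#' @return named list: 20 (Sa), 24 (Sb) or 242 (Sd) features, in a stable
#'   order; the arterial label is the only non-numeric entry.
#' @export
assembleFeatures <- function(roi, blSignals = NULL, clinical, volumes = NULL,
                             artery = NULL, setId = c("Sd", "Sa", "Sb"),
                             nBins = 16L) {
  setId <- match.arg(setId)
  missing <- setdiff(.CLINICAL_VARS, names(clinical))
  if (length(missing))
    ptStop("missing_data", paste0("missing clinical variables: ",
                                  paste(missing, collapse = ", ")))
  out <- lapply(.CLINICAL_VARS, function(v) {
    x <- clinical[[v]]
    if (is.na(x))
      ptStop("missing_data", sprintf(
        "clinical variable %s is NA (no imputation is performed)", v))
    as.numeric(x)
  })
  names(out) <- .CLINICAL_VARS
  if (setId == "Sa") {
    stopifnot(length(out) == 20L)
    return(out)
  }
  if (is.null(volumes))
    ptStop("missing_data", "Sb/Sd need the ROI's baseline volumes")
  out$TLV <- volumes$TLV_BL
  out$TVV <- volumes$TVV_BL
  out$TAV <- volumes$TAV_BL
  out$PAV <- volumes$PAV_BL
  if (setId == "Sb") {
    stopifnot(length(out) == 24L)
    return(out)
  }
  if (is.null(blSignals) || is.null(artery))
    ptStop("missing_data", "Sd needs the baseline signals and artery label")
  idx <- (roi$start + 1L):roi$end
  signals <- c(.FRAME_FEATURES, paste0("d", .FRAME_FEATURES))
  for (sig in signals) {
    v <- signalValues(blSignals[[sig]])
    if (roi$end > length(v))
      ptStop("range_error", "ROI outside baseline signal support")
    cond <- condenseSegment(v[idx], nBins)
    for (stat in .CONDENSATIONS)
      out[[paste(stat, sig, sep = "_")]] <- cond[[stat]]
  }
  out$artery <- as.character(artery)
  out$len_mm <- roi$length_mm
  stopifnot(length(out) == 242L)  # 20 + 4 + 216 + 2
  out
}
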