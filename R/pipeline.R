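# Driver: contour records -> longitudinal signals -> registration -> ROIs ->
# condensed feature matrix ready for the learning stage.

#' Frame-wise features of a pullback as longitudinal signals
#'
#' Computes the 18 geometric descriptors on every annotated frame of both
#' phases, interpolates each onto the uniform 60 frames/mm grid, and appends
#' the 18 derivative signals.
#'
#' @param record a [PullbackRecord-class].
#' @param anchor catheter position in image coordinates (default the origin).
#' @param M ray-casting directions per feature.
#' @param nResample arclength resampling resolution for curvature.
#' @return list with elements \code{bl} and \code{fu}, each a named list of
#'   36 [LongitudinalSignal-class]s.
#' @export
pullbackSignals <- function(record, anchor = c(0, 0), M = 360L,
                            nResample = 256L) {
  onePhase <- function(frames) {
    pos <- vapply(frames, `[[`, numeric(1), "position")
    feat <- lapply(frames, function(fr)
      computeFrameFeatures(fr$lumen, fr$vessel, anchor, M, nResample))
    sigs <- lapply(.FRAME_FEATURES, function(nm)
      interpolateUniform(pos, vapply(feat, `[[`, numeric(1), nm), name = nm))
    names(sigs) <- .FRAME_FEATURES
    der <- lapply(sigs, signalDerivative)
    names(der) <- paste0("d", .FRAME_FEATURES)
    c(sigs, der)
  }
  list(bl = onePhase(record@bl), fu = onePhase(record@fu))
}

#' Co-register and clip the signals of one pullback
#'
#' Registers BL against FU on the plaque-burden and vessel-area signals and
#' clips every signal of both phases to the retained aligned ranges.
#'
#' @param signals output of [pullbackSignals()].
#' @param manualShift optional operator-provided shift (frames).
#' @param minOverlap minimum retained overlap (frames).
#' @return list with \code{bl}, \code{fu} (aligned signal lists of equal
#'   length) and \code{registration} (a [RegistrationResult-class]).
#' @export
registerPullback <- function(signals, manualShift = NULL, minOverlap = 300L) {
  reg <- coregister(signals$bl$PB, signals$bl$vesselA,
                    signals$fu$PB, signals$fu$vesselA,
                    manualShift = manualShift, minOverlap = minOverlap)
  list(bl = lapply(signals$bl, clipSignal, range = reg@blRange),
       fu = lapply(signals$fu, clipSignal, range = reg@fuRange),
       registration = reg)
}

#' Build the ROI-wise dataset of a cohort
#'
#' Runs the full data-preparation pipeline for every pullback: frame-wise
#' features, interpolation, co-registration, ROI partitioning under the
#' chosen criterion, dPAV targets, and feature condensation (baseline
#' signals only).
#'
#' @param cohort an [IvusCohort-class].
#' @param criterion ROI criterion: \code{"FP", "ChPAV", "PBR", "W30O10",
#'   "W60O20", "W120O20"}.
#' @param setId feature set: \code{"Sa"}, \code{"Sb"} or \code{"Sd"}.
#' @param anchor catheter position.
#' @param minOverlap registration overlap floor (frames).
#' @param manualShifts optional named integer vector of operator shifts per
#'   pullback.
#' @param M,nResample geometry resolutions.
#' @param nBins entropy histogram bins.
#' @return list with:
#'   \item{features}{data.frame, one row per ROI: \code{roi_id, pullback_id,
#'     patient_id, dPAV} + feature columns.}
#'   \item{rois}{ROI table with targets and classes.}
#'   \item{pullbacks}{data.frame \code{pullback_id, patient_id, dPAV_fp}
#'     (full-pullback target, used for fold stratification).}
#'   \item{registrations}{named list of [RegistrationResult-class].}
#' @export
buildRoiDataset <- function(cohort, criterion = "ChPAV", setId = "Sd",
                            anchor = c(0, 0), minOverlap = 300L,
                            manualShifts = NULL, M = 360L, nResample = 256L,
                            nBins = 16L) {
  clin <- clinicalData(cohort)
  featRows <- list(); roiRows <- list(); pbRows <- list(); regs <- list()
  for (rec in pullbacks(cohort)) {
    id <- rec@pullbackId
    sig <- pullbackSignals(rec, anchor, M, nResample)
    aligned <- registerPullback(
      sig, manualShift = if (!is.null(manualShifts)) manualShifts[[id]],
      minOverlap = minOverlap)
    regs[[id]] <- aligned$registration
    blAreas <- aligned$bl[c("lumenA", "vesselA", "plaqueA")]
    fuAreas <- aligned$fu[c("lumenA", "vesselA", "plaqueA")]
    n <- length(signalValues(aligned$bl$PB))

    fpRoi <- partitionFullPullback(n, id)
    fpTarget <- roiTarget(fpRoi[1L, ], blAreas, fuAreas)
    pbRows[[id]] <- data.frame(pullback_id = id, patient_id = rec@patientId,
                               dPAV_fp = fpTarget$dPAV,
                               stringsAsFactors = FALSE)

    rois <- partitionROIs(criterion, aligned$bl$PB, aligned$fu$PB, id)
    if (!nrow(rois)) next
    clinRow <- clin[clin$patient_id == rec@patientId, , drop = FALSE]
    for (i in seq_len(nrow(rois))) {
      roi <- rois[i, ]
      tgt <- roiTarget(roi, blAreas, fuAreas)
      roiId <- sprintf("%s_%s_o%d_%d_%d", id, roi$criterion, roi$offset_id,
                       roi$start, roi$end)
      fv <- assembleFeatures(roi, blSignals = aligned$bl, clinical = clinRow,
                             volumes = tgt, artery = rec@artery,
                             setId = setId, nBins = nBins)
      featRows[[roiId]] <- data.frame(
        roi_id = roiId, pullback_id = id, patient_id = rec@patientId,
        dPAV = tgt$dPAV, as.data.frame(fv, stringsAsFactors = FALSE),
        stringsAsFactors = FALSE)
      roi$roi_id <- roiId
      roi$dPAV <- tgt$dPAV
      roi$class <- tgt$class
      roi$PAV_BL <- tgt$PAV_BL
      roi$artery <- rec@artery
      roiRows[[roiId]] <- roi
    }
  }
  if (!length(featRows))
    ptStop("data_error", "no ROIs produced under this criterion")
  list(features = do.call(rbind, c(featRows, list(make.row.names = FALSE))),
       rois = do.call(rbind, c(roiRows, list(make.row.names = FALSE))),
       pullbacks = do.call(rbind, c(pbRows, list(make.row.names = FALSE))),
       registrations = regs)
}
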