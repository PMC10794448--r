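#' Contour: a closed planar cross-sectional boundary
#'
#' A simple (non-self-intersecting) closed polygon in catheter-centred image
#' coordinates (mm), delineating either the lumen or the vessel (external
#' elastic membrane) on one IVUS frame. Vertices are stored as an open ring
#' and the orientation is normalised to counter-clockwise on construction.
#'
#' @slot points numeric matrix (n x 2), vertex coordinates in mm, CCW.
#' @slot role character, \code{"lumen"} or \code{"vessel"}.
#' @slot framePosition numeric, axial position of the frame along the
#'   pullback, in mm.
#'
#' @seealso [Contour()] for the validating constructor.
#' @export
setClass("Contour",
  representation(points = "matrix", role = "character",
                 framePosition = "numeric"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 2L)
      return("points must be a numeric n x 2 matrix")
    if (nrow(p) < 3L)
      return("a contour needs at least 3 vertices")
    if (!all(is.finite(p)))
      return("contour vertices must be finite")
    if (!object@role %in% c("lumen", "vessel"))
      return("role must be 'lumen' or 'vessel'")
    if (polySignedArea(p) <= 0)
      return("contour must have positive area and CCW orientation")
    TRUE
  }
)

#' Construct a Contour
#'
#' Validates the vertex ring (>= 3 vertices, finite, simple polygon) and
#' normalises the orientation to counter-clockwise.
#'
#' @param points numeric n x 2 matrix of vertices in mm (open ring: the
#'   closing edge is implicit).
#' @param role \code{"lumen"} or \code{"vessel"}.
#' @param framePosition axial position in mm (default 0).
#' @param checkSimple logical; run the O(n^2) self-intersection test.
#'   Generators that construct provably simple (star-shaped) rings may skip
#'   it; file readers always run it.
#' @return a [Contour-class] object.
#' @examples
#' sq <- Contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), role = "lumen")
#' contourMetrics(sq)
#' @export
Contour <- function(points, role = c("lumen", "vessel"), framePosition = 0,
                    checkSimple = TRUE) {
  role <- match.arg(role)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) >= 2L &&
      all(points[1L, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]  # drop duplicated closer
  if (nrow(points) < 3L)
    ptStop("invalid_contour", "a contour needs at least 3 vertices")
  if (!all(is.finite(points)))
    ptStop("invalid_contour", "contour vertices must be finite")
  a <- polySignedArea(points)
  if (a == 0)
    ptStop("invalid_contour", "degenerate contour: zero area")
  if (a < 0)
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (checkSimple && !isSimplePolygon(points))
    ptStop("invalid_contour", "contour polygon is self-intersecting")
  new("Contour", points = points, role = role,
      framePosition = as.numeric(framePosition))
}

#' @describeIn Contour-class vertex matrix accessor
#' @param object,x a \code{Contour}
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))

#' @rdname Contour-class
#' @export
setMethod("contourPoints", "Contour", function(object) object@points)

#' @describeIn Contour-class role accessor ("lumen"/"vessel")
#' @export
setGeneric("contourRole", function(object) standardGeneric("contourRole"))

#' @rdname Contour-class
#' @export
setMethod("contourRole", "Contour", function(object) object@role)

#' @describeIn Contour-class axial frame position (mm)
#' @export
setGeneric("framePosition", function(object) standardGeneric("framePosition"))

#' @rdname Contour-class
#' @export
setMethod("framePosition", "Contour", function(object) object@framePosition)

setMethod("show", "Contour", function(object) {
  m <- contourMetrics(object)
  cat(sprintf("Contour(%s) with %d vertices at %.3f mm: A = %.3f mm^2, P = %.3f mm\n",
              object@role, nrow(object@points), object@framePosition,
              m$A, m$P))
})

#' LongitudinalSignal: one frame-wise feature on the uniform axial grid
#'
#' A single geometric feature sampled at 60 interpolated frames per mm along
#' the pullback (grid spacing 1/60 mm), as produced by
#' [interpolateUniform()]. Derivative signals carry a \code{"d"}-prefixed
#' name (e.g. \code{"dPB"}).
#'
#' @slot values numeric vector of samples (finite, length >= 2).
#' @slot spacing grid spacing in mm (always 1/60).
#' @slot originMm axial position of frame 0, in mm.
#' @slot name feature identifier.
#' @export
setClass("LongitudinalSignal",
  representation(values = "numeric", spacing = "numeric",
                 originMm = "numeric", name = "character"),
  validity = function(object) {
    if (length(object@values) < 2L)
      return("a longitudinal signal needs at least 2 samples")
    if (!all(is.finite(object@values)))
      return("signal values must be finite")
    if (abs(object@spacing - 1 / 60) > 1e-12)
      return("grid spacing must be 1/60 mm")
    TRUE
  }
)

LongitudinalSignal <- function(values, originMm = 0, name = "f") {
  new("LongitudinalSignal", values = as.numeric(values), spacing = 1 / 60,
      originMm = as.numeric(originMm), name = as.character(name))
}

#' @describeIn LongitudinalSignal-class sample values
#' @param object a \code{LongitudinalSignal}
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname LongitudinalSignal-class
#' @export
setMethod("signalValues", "LongitudinalSignal", function(object) object@values)

setMethod("show", "LongitudinalSignal", function(object) {
  cat(sprintf("LongitudinalSignal '%s': %d frames from %.3f mm (spacing 1/60 mm)\n",
              object@name, length(object@values), object@originMm))
})

setMethod("length", "LongitudinalSignal", function(x) length(x@values))

#' RegistrationResult: BL/FU alignment of one pullback pair
#'
#' The integer shift (in interpolated frames) applied to the follow-up grid,
#' the equal-length half-open frame ranges retained on each side, and the
#' alignment score (mean Pearson correlation of the plaque-burden and
#' vessel-area signals over the overlap).
#'
#' @slot shiftFrames signed integer shift: BL frame i aligns with FU frame
#'   \code{i + shiftFrames}.
#' @slot blRange,fuRange integer length-2 vectors, half-open retained ranges
#'   \code{[start, end)} in 0-based interpolated frames.
#' @slot score alignment similarity in [-1, 1].
#' @export
setClass("RegistrationResult",
  representation(shiftFrames = "integer", blRange = "integer",
                 fuRange = "integer", score = "numeric"),
  validity = function(object) {
    if (diff(object@blRange) != diff(object@fuRange))
      return("retained BL and FU ranges must have equal length")
    if (diff(object@blRange) < 1L)
      return("retained overlap must be non-empty")
    TRUE
  }
)

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult: shift %+d frames, overlap %d frames, score %.3f\n",
    object@shiftFrames, diff(object@blRange), object@score))
})

#' PullbackRecord: paired BL/FU contour series for one artery
#'
#' @slot pullbackId,patientId,artery character identifiers; \code{artery} is
#'   the arterial label (e.g. LAD, LCx, RCA).
#' @slot bl,fu lists of frames; each frame is a list with elements
#'   \code{position} (mm), \code{lumen} and \code{vessel} ([Contour-class]),
#'   ordered by strictly increasing position.
#' @export
setClass("PullbackRecord",
  representation(pullbackId = "character", patientId = "character",
                 artery = "character", bl = "list", fu = "list"),
  validity = function(object) {
    for (phase in c("bl", "fu")) {
      frames <- slot(object, phase)
      if (length(frames) < 2L)
        return(sprintf("phase %s needs at least 2 annotated frames", phase))
      pos <- vapply(frames, `[[`, numeric(1), "position")
      if (any(diff(pos) <= 0))
        return("frame positions must be strictly increasing")
    }
    TRUE
  }
)

setMethod("show", "PullbackRecord", function(object) {
  cat(sprintf(
    "PullbackRecord %s (patient %s, %s): %d BL / %d FU annotated frames\n",
    object@pullbackId, object@patientId, object@artery,
    length(object@bl), length(object@fu)))
})

#' @describeIn PullbackRecord-class arterial label accessor
#' @param object a \code{PullbackRecord}
#' @export
setGeneric("arteryLabel", function(object) standardGeneric("arteryLabel"))

#' @rdname PullbackRecord-class
#' @export
setMethod("arteryLabel", "PullbackRecord", function(object) object@artery)

#' IvusCohort: a set of pullbacks plus the patient-level clinical table
#'
#' @slot pullbacks named list of [PullbackRecord-class] objects.
#' @slot clinical data.frame of patient-level covariates, one row per
#'   patient, with a \code{patient_id} column.
#' @export
setClass("IvusCohort",
  representation(pullbacks = "list", clinical = "data.frame"),
  validity = function(object) {
    if (!all(vapply(object@pullbacks, is, logical(1), "PullbackRecord")))
      return("pullbacks must be PullbackRecord objects")
    if (!"patient_id" %in% names(object@clinical))
      return("clinical table needs a patient_id column")
    pid <- vapply(object@pullbacks, function(p) p@patientId, character(1))
    if (!all(pid %in% object@clinical$patient_id))
      return("every pullback's patient must appear in the clinical table")
    TRUE
  }
)

setMethod("show", "IvusCohort", function(object) {
  cat(sprintf("IvusCohort: %d pullbacks from %d patients\n",
              length(object@pullbacks), nrow(object@clinical)))
})

#' @describeIn IvusCohort-class list of pullback records
#' @param object an \code{IvusCohort}
#' @export
setGeneric("pullbacks", function(object) standardGeneric("pullbacks"))

#' @rdname IvusCohort-class
#' @export
setMethod("pullbacks", "IvusCohort", function(object) object@pullbacks)

#' @describeIn IvusCohort-class patient-level covariate table
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname IvusCohort-class
#' @export
setMethod("clinicalData", "IvusCohort", function(object) object@clinical)

#' ExperimentResult: one repeated cross-validated experiment
#'
#' Holds everything produced by [runExperiment()]: per-model test
#' predictions, per-model metrics, fold assignments, selected-feature
#' records, and (optionally) SHAP attributions.
#'
#' @slot config list of experiment settings (folds, repeats, seed, k, ...).
#' @slot folds data.frame of fold assignments (repeat_id, fold_id,
#'   pullback_id, role).
#' @slot predictions data.frame with one row per (model, test ROI).
#' @slot metrics data.frame with one row per model.
#' @slot selection list: per model, the selected feature names.
#' @slot shap list: per model, mean |SHAP| per selected feature over the
#'   model's test set (empty when SHAP was not requested).
#' @slot featureNames character: columns of the model matrix.
#' @export
setClass("ExperimentResult",
  representation(config = "list", folds = "data.frame",
                 predictions = "data.frame", metrics = "data.frame",
                 selection = "list", shap = "list",
                 featureNames = "character"))

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf(
    "ExperimentResult: %d models (%d folds x %d repeats), %d ROIs, %d features\n",
    nrow(object@metrics), object@config$nFolds, object@config$nRepeats,
    length(unique(object@predictions$roi_id)), length(object@featureNames)))
  ms <- metricsSummary(object)
  cat(sprintf("  mean ACC %.3f, mean MCC %.3f, mean MAE %.3f\n",
              ms$mean[ms$metric == "ACC"], ms$mean[ms$metric == "MCC"],
              ms$mean[ms$metric == "MAE"]))
})

#' @describeIn ExperimentResult-class per-model metric table
#' @param object an \code{ExperimentResult}
#' @export
setGeneric("modelMetrics", function(object) standardGeneric("modelMetrics"))

#' @rdname ExperimentResult-class
#' @export
setMethod("modelMetrics", "ExperimentResult", function(object) object@metrics)

#' @describeIn ExperimentResult-class per-model test predictions
#' @export
setGeneric("modelPredictions",
           function(object) standardGeneric("modelPredictions"))

#' @rdname ExperimentResult-class
#' @export
setMethod("modelPredictions", "ExperimentResult",
          function(object) object@predictions)
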