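# Plain-text interchange: contour CSVs with per-pullback JSON sidecars, the
# clinical table, ROI tables and registration reports. Numeric columns are
# written with 17 significant digits so finite doubles round-trip bit-exact.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write one pullback's contours as CSV + JSON sidecar
#'
#' CSV columns: \code{pullback_id, phase, frame_index, position_mm, role,
#' vertex_index, x_mm, y_mm}; the sidecar \code{<id>.json} carries
#' \code{artery_label} and \code{patient_id}.
#'
#' @param record a [PullbackRecord-class].
#' @param dir output directory (created if needed).
#' @return the CSV path, invisibly.
#' @export
writePullbackContours <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (phase in c("BL", "FU")) {
    frames <- if (phase == "BL") record@bl else record@fu
    for (i in seq_along(frames)) {
      for (role in c("lumen", "vessel")) {
        pts <- contourPoints(frames[[i]][[role]])
        rows[[length(rows) + 1L]] <- data.frame(
          pullback_id = record@pullbackId, phase = phase,
          frame_index = i - 1L, position_mm = .fmtNum(frames[[i]]$position),
          role = role, vertex_index = seq_len(nrow(pts)) - 1L,
          x_mm = .fmtNum(pts[, 1L]), y_mm = .fmtNum(pts[, 2L]),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  csv <- file.path(dir, paste0(record@pullbackId, ".csv"))
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(pullback_id = record@pullbackId, artery_label = record@artery,
         patient_id = record@patientId),
    file.path(dir, paste0(record@pullbackId, ".json")), auto_unbox = TRUE)
  invisible(csv)
}

#' Read one pullback from its CSV + JSON sidecar
#'
#' Validates every contour (>= 3 vertices, finite, simple polygon) and
#' normalises orientation to counter-clockwise.
#'
#' @param csvPath path to the contour CSV; the sidecar is looked up next to
#'   it.
#' @return a [PullbackRecord-class].
#' @export
readPullbackContours <- function(csvPath) {
  df <- read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("pullback_id", "phase", "frame_index", "position_mm", "role",
            "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    ptStop("invalid_contour", "contour CSV is missing required columns")
  side <- jsonlite::read_json(sub("\\.csv$", ".json", csvPath))
  phases <- list()
  for (phase in c("BL", "FU")) {
    sub <- df[df$phase == phase, ]
    frames <- lapply(split(sub, sub$frame_index), function(fr) {
      out <- list(position = fr$position_mm[1L])
      for (role in c("lumen", "vessel")) {
        g <- fr[fr$role == role, ]
        g <- g[order(g$vertex_index), ]
        if (!nrow(g))
          ptStop("invalid_contour",
                 sprintf("frame without a %s contour", role))
        out[[role]] <- Contour(cbind(g$x_mm, g$y_mm), role = role,
                               framePosition = fr$position_mm[1L],
                               checkSimple = TRUE)
      }
      out
    })
    frames <- frames[order(vapply(frames, `[[`, numeric(1), "position"))]
    phases[[phase]] <- unname(frames)
  }
  new("PullbackRecord", pullbackId = as.character(side$pullback_id),
      patientId = as.character(side$patient_id),
      artery = as.character(side$artery_label),
      bl = phases$BL, fu = phases$FU)
}

#' Write a cohort to a directory
#'
#' One contour CSV + JSON sidecar per pullback and a \code{clinical.csv}.
#'
#' @param cohort an [IvusCohort-class].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in pullbacks(cohort)) writePullbackContours(rec, dir)
  write.csv(clinicalData(cohort), file.path(dir, "clinical.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory produced by [writeCohort()].
#' @return an [IvusCohort-class].
#' @export
readCohort <- function(dir) {
  csvs <- sort(list.files(dir, "\\.csv$", full.names = TRUE))
  csvs <- csvs[file.exists(sub("\\.csv$", ".json", csvs))]  # sidecar = contours
  recs <- lapply(csvs, readPullbackContours)
  names(recs) <- vapply(recs, function(r) r@pullbackId, character(1))
  clin <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  new("IvusCohort", pullbacks = recs, clinical = clin)
}

#' Write a ROI table as CSV
#'
#' Columns: \code{pullback_id, criterion, offset_id, start_frame, end_frame,
#' length_mm, artery, dPAV, class}.
#'
#' @param rois ROI table from [buildRoiDataset()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeRoiTable <- function(rois, path) {
  out <- data.frame(pullback_id = rois$pullback_id,
                    criterion = rois$criterion,
                    offset_id = rois$offset_id,
                    start_frame = rois$start, end_frame = rois$end,
                    length_mm = .fmtNum(rois$length_mm),
                    artery = rois$artery,
                    dPAV = .fmtNum(rois$dPAV), class = rois$class,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a registration report as JSON
#'
#' @param registrations named list of [RegistrationResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeRegistrationReport <- function(registrations, path) {
  rep <- lapply(registrations, function(r)
    list(shift_frames = r@shiftFrames,
         bl_range = r@blRange, fu_range = r@fuRange, score = r@score))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
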