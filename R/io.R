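## Tidy text export of stimuli, spectra, profiles and reports.

#' Write trial stimulus timecourses as tidy CSV
#'
#' One row per trial, side and frame with the instantaneous frequency and
#' luminance (columns: trial, side, frame, time_s, freq_hz,
#' luminance_cdm2).
#'
#' @param trials list of [TrialSpec-class]
#' @param path output CSV path
#' @export
writeTrialsCSV <- function(trials, path) {
  rows <- lapply(seq_along(trials), function(k) {
    tr <- trials[[k]]
    do.call(rbind, lapply(c("left", "right"), function(side) {
      fm <- if (side == "left") tr@fmLeft else tr@fmRight
      cmf <- if (side == "left") tr@cmfLeft else tr@cmfRight
      data.frame(trial = k, side = side, frame = seq_along(fm@t),
                 time_s = fm@t, freq_hz = fm@freq,
                 luminance_cdm2 = cmf@luminance)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a power spectrum as tidy CSV
#'
#' Columns: channel, freq_hz, power, scale.
#'
#' @param ps a [PowerSpectrum-class]
#' @param path output CSV path
#' @export
writeSpectrumCSV <- function(ps, path) {
  df <- data.frame(channel = rep(ps@channels, times = length(ps@freqs)),
                   freq_hz = rep(ps@freqs, each = length(ps@channels)),
                   power = as.vector(ps@values), scale = ps@scale)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an alpha-profile table as tidy CSV
#'
#' Columns: subject, condition, iaf_hz, iap_db, lateralization_db.
#'
#' @param profiles data.frame as produced in a [StudyReport-class]
#' @param path output CSV path
#' @export
writeAlphaProfilesCSV <- function(profiles, path) {
  out <- data.frame(subject = profiles$subject,
                    condition = profiles$condition,
                    iaf_hz = profiles$iaf, iap_db = profiles$iap,
                    lateralization_db = profiles$lateralization)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a recording as tidy CSV with a ground-truth JSON sidecar
#'
#' The sample matrix goes to `<path>` (columns: channel labels; one row
#' per sample) and the generating subject parameters, sampling rate,
#' trial onsets and segment kind to `<path>.json`.
#'
#' @param rec a [Recording-class]
#' @param path output CSV path
#' @export
writeRecordingCSV <- function(rec, path) {
  df <- as.data.frame(t(rec@data))
  names(df) <- rec@montage@labels
  utils::write.csv(df, path, row.names = FALSE)
  s <- rec@subject
  sidecar <- list(
    fs = rec@fs, segmentKind = rec@segmentKind, onsets = rec@onsets,
    subject = list(iafTrue = s@iafTrue, alphaAmp = s@alphaAmp,
                   attnModulation = s@attnModulation,
                   noiseExponent = s@noiseExponent, noiseAmp = s@noiseAmp,
                   driveSnr = s@driveSnr,
                   entrainCoupling = s@entrainCoupling,
                   behaviorIntercept = s@behaviorIntercept,
                   behaviorSlope = s@behaviorSlope))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write electrode positions as .sfp-style text
#'
#' One line per channel: label, x, y, z on the unit sphere.
#'
#' @param montage a [Montage-class]
#' @param path output path
#' @export
writeMontageSFP <- function(montage, path) {
  lines <- sprintf("%s\t%.6f\t%.6f\t%.6f", montage@labels,
                   montage@positions[, 1], montage@positions[, 2],
                   montage@positions[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Write a study report summary as JSON
#'
#' Serializes the inference results (cluster table, ANOVA, Bayes factors,
#' regression table, slope differences, Friedman test) plus the full
#' configuration for provenance.
#'
#' @param report a [StudyReport-class]
#' @param path output JSON path
#' @export
writeReportJSON <- function(report, path) {
  x <- list(
    config = report@config@params,
    clusters = report@clusterTest@clusters,
    anova = report@anova@table,
    bayesAnova = report@bayesAnova@table,
    contrasts = report@contrasts,
    regressions = compareRegressionTables(report),
    slopeDiffs = report@slopeDiffs,
    friedman = report@friedman[c("statistic", "df", "p.value")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
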