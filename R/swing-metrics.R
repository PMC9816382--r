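# The nine candidate rotational metrics of one swing.

#' Canonical metric names
#'
#' The nine candidate rotational metrics: for each of the pelvis, upper torso
#' and X-prime, the signed peak rotational velocity pre-impact (downswing),
#' the velocity at impact, and the signed peak post-impact (follow-through).
#' Order is segment-major (pelvis, torso, xprime) then phase (pre, at, post).
#'
#' @return Character vector of the nine metric names.
#' @export
#' @examples
#' metricNames()
metricNames <- function() {
  as.vector(outer(c("peak_pre_impact", "at_impact", "peak_post_impact"),
                  c("pelvis", "torso", "xprime"),
                  function(p, s) paste(s, p, sep = ".")))
}

#' Signed peak of a velocity series
#'
#' The value of largest absolute magnitude within a frame window, sign
#' preserved (follow-through X-prime peaks are large negative values, so
#' peaks must be magnitude extrema, not maxima). Ties resolve to the
#' earliest frame.
#'
#' @param values Numeric velocity series.
#' @param window Integer frame indices to search.
#' @return The signed peak value.
#' @export
#' @examples
#' signedPeak(c(3, -7, 5), 1:3)  # -7
signedPeak <- function(values, window) {
  if (!length(window)) stop("empty window for signed peak")
  v <- values[window]
  if (anyNA(v)) stop("window contains missing values")
  v[which.max(abs(v))]
}

#' Extract the nine rotational metrics of a swing
#'
#' For each of pelvis, upper-torso and X-prime rotational velocity:
#' the signed peak over the downswing window `[top, impact]` (the backswing
#' is excluded so backswing-direction extrema cannot masquerade as downswing
#' peaks), the value at the impact frame, and the signed peak over the
#' follow-through window `(impact, followthroughEnd]` (half-open at impact).
#'
#' @param rec A [SwingRecording-class].
#' @param phases A [SwingPhases-class]; detected with [detectPhases()] when
#'   omitted.
#' @param swingId,subjectId,group Identifier columns carried into the output.
#' @param cutoffHz Optional low-pass cutoff forwarded to
#'   [swingKinematics()].
#' @return One-row `data.frame` with columns `swing`, `subject`, `group` and
#'   the nine metrics of [metricNames()] (deg/s).
#' @export
extractMetrics <- function(rec, phases = NULL, swingId = "swing1",
                           subjectId = "subject1", group = NA_character_,
                           cutoffHz = NULL) {
  stopifnot(is(rec, "SwingRecording"))
  if (is.null(phases)) phases <- detectPhases(rec)
  kin <- swingKinematics(rec, cutoffHz = cutoffHz)
  f <- phaseFrames(phases)
  if (f[["followthroughEnd"]] > nrow(kin))
    stop("phases exceed recording length")
  pre <- f[["top"]]:f[["impact"]]
  post <- (f[["impact"]] + 1L):f[["followthroughEnd"]]
  series <- list(pelvis = kin$pelvis_dps, torso = kin$torso_dps,
                 xprime = kin$xprime_dps)
  out <- data.frame(swing = swingId, subject = subjectId, group = group,
                    stringsAsFactors = FALSE)
  for (seg in names(series)) {
    s <- series[[seg]]
    out[[paste0(seg, ".peak_pre_impact")]] <- signedPeak(s, pre)
    out[[paste0(seg, ".at_impact")]] <- s[f[["impact"]]]
    out[[paste0(seg, ".peak_post_impact")]] <- signedPeak(s, post)
  }
  out
}

#' Metric table for several recordings
#'
#' Runs phase detection and [extractMetrics()] over a list of recordings and
#' binds the rows; this table (written as CSV) is the interchange format
#' consumed by the SPI fitting functions.
#'
#' @param recordings List of [SwingRecording-class] objects.
#' @param swingIds,subjectIds,groups Per-recording identifiers, recycled if
#'   length 1.
#' @param cutoffHz Optional low-pass cutoff forwarded to [extractMetrics()].
#' @return `data.frame` with one row per recording.
#' @export
swingMetricsTable <- function(recordings,
                              swingIds = paste0("swing", seq_along(recordings)),
                              subjectIds = swingIds,
                              groups = NA_character_, cutoffHz = NULL) {
  n <- length(recordings)
  subjectIds <- rep_len(subjectIds, n)
  groups <- rep_len(groups, n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    extractMetrics(recordings[[i]], swingId = swingIds[i],
                   subjectId = subjectIds[i], group = groups[i],
                   cutoffHz = cutoffHz)
  }))
}
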