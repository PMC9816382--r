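# Transverse-plane segment kinematics: orientations, rotational velocities
# and X-prime (pelvis minus upper-torso velocity).

#' Transverse-plane orientation of a two-marker segment
#'
#' Per frame, the left-minus-right marker vector is projected onto the
#' horizontal (transverse) plane and its atan2 angle taken in degrees, then
#' unwrapped over time so no between-frame jump exceeds 180 degrees.
#' Degenerate frames (projected norm below 1e-9 m, or missing samples)
#' inherit the previous frame's angle; leading degenerate frames inherit the
#' first valid angle.
#'
#' @param left,right Frames-by-3 position matrices (metres) of the left and
#'   right segment markers.
#' @param verticalAxis Up-direction token (see [SwingRecording-class]).
#' @return Numeric vector of unwrapped angles in degrees, one per frame.
#' @export
segmentOrientation <- function(left, right, verticalAxis = "z+") {
  left <- as.matrix(left); right <- as.matrix(right)
  stopifnot(nrow(left) == nrow(right))
  v <- left - right
  bc <- horizontalAxes(verticalAxis)
  b <- v[, bc[1L]]; cc <- v[, bc[2L]]
  ok <- is.finite(b) & is.finite(cc) & sqrt(b^2 + cc^2) >= 1e-9
  if (!any(ok)) stop("all frames degenerate: segment has no horizontal extent")
  raw <- atan2(cc, b) * 180 / pi
  raw[!ok] <- NA_real_
  # carry last valid angle forward; backfill the leading run
  idx <- cummax(ifelse(ok, seq_along(raw), 0L))
  idx[idx == 0L] <- which(ok)[1L]
  unwrapDeg(raw[idx])
}

#' Rotational velocity of an angle series
#'
#' Rate of change by central finite differences,
#' `w[t] = (theta[t+1] - theta[t-1]) * rate / 2`, with one-sided differences
#' at the two endpoints.
#'
#' @param angles Unwrapped angle series in degrees.
#' @param rate Sampling rate (Hz).
#' @return Velocity series in deg/s, same length as `angles`.
#' @export
rotationalVelocity <- function(angles, rate) {
  if (length(angles) < 3L)
    stop("need at least 3 frames to differentiate an angle series")
  centralDiff(angles, rate)
}

#' X-prime velocity
#'
#' The pelvis-minus-upper-torso rotational velocity at each time point: the
#' rate of change of the relative transverse-plane orientation of the two
#' segments. During the downswing the torso outpaces the pelvis, so X-prime
#' is negative there.
#'
#' @param pelvis,torso Velocity series (deg/s) of equal length.
#' @return Numeric velocity series `pelvis - torso`.
#' @export
xprimeVelocity <- function(pelvis, torso) {
  if (length(pelvis) != length(torso))
    stop("pelvis and torso velocity series differ in length (",
         length(pelvis), " vs ", length(torso), ")")
  pelvis - torso
}

#' Optional zero-lag low-pass filter
#'
#' Forward-backward (zero phase lag) Butterworth low-pass, 2nd order per
#' pass, i.e. 4th-order magnitude response. No filtering is applied anywhere
#' by default; this is provided for noisy recordings, where unfiltered
#' finite-difference velocities amplify marker noise.
#'
#' @param x Numeric series.
#' @param rate Sampling rate (Hz).
#' @param cutoffHz Cutoff frequency (Hz), must be below `rate / 2`.
#' @return Filtered series of the same length.
#' @export
lowpassZeroLag <- function(x, rate, cutoffHz) {
  stopifnot(cutoffHz > 0, cutoffHz < rate / 2)
  bf <- signal::butter(2, cutoffHz / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

handednessSign <- function(rec) if (handedness(rec) == "right") 1 else -1

#' Per-frame kinematics table of a recording
#'
#' Computes pelvis and upper-torso transverse-plane orientations (from the
#' bilateral ASIS and acromion markers), their rotational velocities, and
#' X-prime. The handedness flag flips the rotation sign so that downswing
#' pelvis/torso velocities are positive for either handedness.
#'
#' @param rec A [SwingRecording-class] (gaps filled; see
#'   [interpolateGaps()]).
#' @param cutoffHz Optional low-pass cutoff (Hz) applied to the angle series
#'   before differentiation; default `NULL` (no filtering).
#' @return `data.frame` with columns `frame`, `pelvis_deg`, `torso_deg`,
#'   `pelvis_dps`, `torso_dps`, `xprime_dps`.
#' @export
swingKinematics <- function(rec, cutoffHz = NULL) {
  stopifnot(is(rec, "SwingRecording"))
  s <- handednessSign(rec)
  pelvis <- s * segmentOrientation(markerPositions(rec, "LASIS"),
                                   markerPositions(rec, "RASIS"),
                                   verticalAxis(rec))
  torso <- s * segmentOrientation(markerPositions(rec, "LACR"),
                                  markerPositions(rec, "RACR"),
                                  verticalAxis(rec))
  if (!is.null(cutoffHz)) {
    pelvis <- lowpassZeroLag(pelvis, samplingRate(rec), cutoffHz)
    torso <- lowpassZeroLag(torso, samplingRate(rec), cutoffHz)
  }
  pv <- rotationalVelocity(pelvis, samplingRate(rec))
  tv <- rotationalVelocity(torso, samplingRate(rec))
  data.frame(frame = seq_along(pelvis), pelvis_deg = pelvis,
             torso_deg = torso, pelvis_dps = pv, torso_dps = tv,
             xprime_dps = xprimeVelocity(pv, tv))
}
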