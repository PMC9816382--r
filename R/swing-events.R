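# Swing-phase event detection and clubhead speed at impact.
#
# Event rules operate on vertical clubhead displacement and ball velocity:
# backswing start = first sustained vertical clubhead speed above 0.2 m/s,
# impact = frame immediately preceding the initial increase in ball velocity,
# follow-through end = first local minimum of vertical clubhead displacement
# after impact.

verticalSeries <- function(rec, role) {
  vc <- verticalComponent(verticalAxis(rec))
  markerPositions(rec, role)[, vc$index] * vc$sign
}

#' Detect the start of the backswing
#'
#' First frame whose absolute vertical clubhead speed exceeds `threshold`
#' and stays above it for at least `minHold` consecutive frames. The absolute
#' value is used because a takeaway may dip before rising; the sustain
#' requirement rejects single-frame noise spikes. Vertical speed is computed
#' by central differences.
#'
#' @param rec A [SwingRecording-class]; the club trajectory must be gap-free.
#' @param threshold Vertical speed threshold (m/s), default 0.2 (strict
#'   inequality).
#' @param minHold Number of consecutive qualifying frames required, default 5
#'   (about 21 ms at 240 Hz).
#' @return Frame index of the detected takeaway.
#' @export
detectBackswingStart <- function(rec, threshold = 0.2, minHold = 5L) {
  h <- verticalSeries(rec, "CLUB")
  if (anyNA(h)) stop("club trajectory has missing samples; fill gaps first")
  v <- abs(centralDiff(h, samplingRate(rec)))
  above <- v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= minHold)
  if (!length(ok)) stop("no swing detected: vertical clubhead speed never exceeds ",
                        threshold, " m/s for ", minHold, " frames")
  ends[ok[1L]] - r$lengths[ok[1L]] + 1L
}

#' Detect ball impact
#'
#' Returns the frame immediately preceding the initial increase in ball
#' velocity: with `t*` the first frame after `start` whose ball speed exceeds
#' `launchThreshold`, impact is `t* - 1`. Ball speed uses the backward
#' difference `||pos[t] - pos[t-1]|| * rate`, so the first moving frame - not
#' the last static one - crosses the threshold. The ball must be quasi-static
#' (speed below `staticTol`) before `start`.
#'
#' @param rec A [SwingRecording-class].
#' @param start Backswing-start frame (see [detectBackswingStart()]).
#' @param launchThreshold Ball speed (m/s) marking launch; default 0.5, far
#'   above marker noise and far below any real launch speed.
#' @param staticTol Pre-swing ball speed tolerance (m/s), default 0.05.
#' @return Impact frame index.
#' @export
detectImpact <- function(rec, start, launchThreshold = 0.5,
                         staticTol = 0.05) {
  p <- markerPositions(rec, "BALL")
  if (anyNA(p)) stop("ball trajectory has missing samples; fill gaps first")
  n <- nrow(p)
  sp <- c(0, rowNorms(p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]) *
               samplingRate(rec))
  if (start > 1L && any(sp[2:start] > staticTol))
    stop("ball moving at recording start (speed exceeds ", staticTol,
         " m/s before the backswing)")
  cand <- which(sp > launchThreshold)
  cand <- cand[cand > start]
  if (!length(cand)) stop("ball never moves: no impact detected")
  cand[1L] - 1L
}

#' Detect the top of the backswing
#'
#' Frame of maximum vertical clubhead position within `[start, impact]`;
#' ties resolve to the latest such frame (the club lingers at the top).
#'
#' @param rec A [SwingRecording-class].
#' @param start,impact Bounding frames, `start < impact`.
#' @return Frame index of the top of the backswing.
#' @export
detectTop <- function(rec, start, impact) {
  stopifnot(start < impact)
  h <- verticalSeries(rec, "CLUB")[start:impact]
  start + max(which(h == max(h))) - 1L
}

#' Detect the end of the follow-through
#'
#' First local minimum of vertical clubhead displacement after impact:
#' the first `t > impact` with `h[t] <= h[t-1]` and `h[t] <= h[t+1]`
#' (for plateaus this is the first frame of the minimal plateau). If the
#' height decreases monotonically to the end of the recording, the last
#' frame is returned with a warning.
#'
#' @param rec A [SwingRecording-class].
#' @param impact Impact frame; at least 3 frames must follow it.
#' @return Frame index of the follow-through end.
#' @export
detectFollowthroughEnd <- function(rec, impact) {
  h <- verticalSeries(rec, "CLUB")
  n <- length(h)
  stopifnot(impact + 3L <= n)
  for (t in (impact + 1L):(n - 1L)) {
    if (h[t] <= h[t - 1L] && h[t] <= h[t + 1L]) return(t)
  }
  warning("no local minimum of clubhead height after impact; using last frame")
  n
}

#' Detect all swing phases
#'
#' Convenience wrapper running [detectBackswingStart()], [detectImpact()],
#' [detectTop()] and [detectFollowthroughEnd()] in order.
#'
#' @param rec A [SwingRecording-class].
#' @param threshold,minHold Passed to [detectBackswingStart()].
#' @param launchThreshold,staticTol Passed to [detectImpact()].
#' @return A [SwingPhases-class].
#' @export
detectPhases <- function(rec, threshold = 0.2, minHold = 5L,
                         launchThreshold = 0.5, staticTol = 0.05) {
  start <- detectBackswingStart(rec, threshold, minHold)
  impact <- detectImpact(rec, start, launchThreshold, staticTol)
  top <- detectTop(rec, start, impact)
  ftEnd <- detectFollowthroughEnd(rec, impact)
  SwingPhases(start, top, impact, ftEnd)
}

#' Least-squares circle through 3D points
#'
#' Fits the best plane by total least squares (centroid plus
#' smallest-variance direction of the point cloud), projects the points into
#' that plane, and fits a planar circle by algebraic (Kasa) least squares.
#' Exact for noiseless circular arcs in any 3D orientation; for three
#' non-collinear points it returns the circumscribed circle.
#'
#' @param points Matrix (n x 3) of 3D points, n >= 3, not collinear.
#' @return A [CircleFit-class].
#' @export
fitCircle3d <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3L) stop("need at least 3 points to fit a circle")
  c0 <- colMeans(p)
  m <- sweep(p, 2L, c0)
  sv <- svd(m)
  if (sv$d[2L] <= 1e-10 * max(sv$d[1L], .Machine$double.eps))
    stop("points are collinear: no circle fit")
  u <- sv$v[, 1L]; vv <- sv$v[, 2L]; normal <- sv$v[, 3L]
  x <- as.numeric(m %*% u); y <- as.numeric(m %*% vv)
  w <- as.numeric(m %*% normal)
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  r2 <- sol[3L] + sol[1L]^2 + sol[2L]^2
  if (!is.finite(r2) || r2 <= 0) stop("degenerate circle fit")
  r <- sqrt(r2)
  rho <- sqrt((x - sol[1L])^2 + (y - sol[2L])^2)
  new("CircleFit",
      center = as.numeric(c0 + sol[1L] * u + sol[2L] * vv),
      radius = r, normal = as.numeric(normal),
      rmsResidual = sqrt(mean((rho - r)^2 + w^2)))
}

#' Clubhead speed at impact
#'
#' The distal-shaft marker speed at impact is the displacement between the
#' impact frame and the next frame times the sampling rate. Because the
#' marker sits 5 cm from the clubface centre, the clubhead speed is
#' approximated by fitting a circle to the marker trajectory in the `window`
#' frames on each side of impact and scaling the marker speed by
#' `(r + 0.05) / r`. If fewer than `window` frames are available on a side,
#' all available frames are used (with a warning below `minFrames`); a
#' degenerate circle fit falls back to the raw marker speed with a warning.
#'
#' @param rec A [SwingRecording-class].
#' @param phases A [SwingPhases-class] for the recording.
#' @param window Frames on each side of impact for the circle fit,
#'   default 50.
#' @param minFrames Minimum total frames for attempting the fit, default 10.
#' @return Clubhead speed at impact (m/s) with attributes `markerSpeed`
#'   (m/s) and `radius` (m, `NA` on fallback).
#' @export
clubheadSpeedAtImpact <- function(rec, phases, window = 50L,
                                  minFrames = 10L) {
  stopifnot(is(rec, "SwingRecording"), is(phases, "SwingPhases"))
  p <- markerPositions(rec, "CLUB")
  n <- nrow(p)
  imp <- phases@impact
  vm <- sqrt(sum((p[imp + 1L, ] - p[imp, ])^2)) * samplingRate(rec)
  lo <- max(1L, imp - window); hi <- min(n, imp + window)
  fit <- NULL
  if (hi - lo + 1L < minFrames) {
    warning("fewer than ", minFrames,
            " frames around impact; using raw marker speed")
  } else {
    if (imp - lo < window || hi - imp < window)
      warning("fewer than ", window,
              " frames on one side of impact; circle fit uses all available")
    fit <- tryCatch(fitCircle3d(p[lo:hi, , drop = FALSE]),
                    error = function(e) {
                      warning("degenerate circle fit (", conditionMessage(e),
                              "); using raw marker speed")
                      NULL
                    })
  }
  csi <- if (is.null(fit)) vm else vm * (fit@radius + 0.05) / fit@radius
  structure(csi, markerSpeed = vm,
            radius = if (is.null(fit)) NA_real_ else fit@radius)
}
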