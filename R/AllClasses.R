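#' @import methods
NULL

#' Marker roles of a swing recording
#'
#' The six marker roles a validated recording must carry: bilateral anterior
#' superior iliac spines (pelvis segment), bilateral acromia (upper-torso
#' segment), the distal club-shaft marker, and the ball.
#'
#' @return Character vector of the six role names in canonical order.
#' @export
#' @examples
#' markerRoles()
markerRoles <- function() c("LASIS", "RASIS", "LACR", "RACR", "CLUB", "BALL")

#' SwingRecording: marker trajectories of one golf swing
#'
#' Container for time-synchronised 3D marker trajectories sampled at a fixed
#' rate. Positions are stored in metres as frames-by-3 matrices keyed by role
#' (see [markerRoles()]); missing samples are `NA` rows, exposed through
#' [missingFrames()]. `handedness` fixes the sign convention so that downswing
#' pelvis/torso rotational velocities are positive for either handedness;
#' `verticalAxis` names the up direction (e.g. `"z+"`) that the transverse
#' plane and all vertical-displacement event rules refer to.
#'
#' @slot markers Named list of numeric matrices (frames x 3, metres), one per
#'   role in [markerRoles()].
#' @slot rate Sampling rate in Hz.
#' @slot handedness `"right"` or `"left"`.
#' @slot verticalAxis One of `"x+"`, `"x-"`, `"y+"`, `"y-"`, `"z+"`, `"z-"`.
#' @export
setClass("SwingRecording",
  representation(markers = "list", rate = "numeric",
                 handedness = "character", verticalAxis = "character"))

setValidity("SwingRecording", function(object) {
  msgs <- character()
  missing <- setdiff(markerRoles(), names(object@markers))
  if (length(missing))
    msgs <- c(msgs, paste0("missing marker roles: ",
                           paste(missing, collapse = ", ")))
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a single positive number")
  if (!object@handedness %in% c("right", "left"))
    msgs <- c(msgs, "handedness must be 'right' or 'left'")
  if (!object@verticalAxis %in% c("x+", "x-", "y+", "y-", "z+", "z-"))
    msgs <- c(msgs, "verticalAxis must be one of x+/x-/y+/y-/z+/z-")
  ns <- vapply(object@markers, nrow, integer(1))
  if (length(unique(ns)) > 1L)
    msgs <- c(msgs, "all marker trajectories must have the same frame count")
  if (any(vapply(object@markers, ncol, integer(1)) != 3L))
    msgs <- c(msgs, "marker trajectories must have 3 columns (x, y, z)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SwingRecording
#'
#' @param markers Named list of frames-by-3 numeric matrices in metres, one
#'   per role in [markerRoles()]. `NA` rows mark missing samples.
#' @param rate Sampling rate (Hz).
#' @param handedness `"right"` (default) or `"left"`.
#' @param verticalAxis Up direction, default `"z+"`.
#' @return A [SwingRecording-class] object.
#' @export
SwingRecording <- function(markers, rate, handedness = "right",
                           verticalAxis = "z+") {
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  new("SwingRecording", markers = markers[markerRoles()], rate = rate,
      handedness = handedness, verticalAxis = verticalAxis)
}

#' @describeIn SwingRecording-class Number of frames.
#' @param x,object A `SwingRecording`.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname SwingRecording-class
#' @export
setMethod("nFrames", "SwingRecording", function(x) nrow(x@markers[[1L]]))

#' @describeIn SwingRecording-class Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname SwingRecording-class
#' @export
setMethod("samplingRate", "SwingRecording", function(x) x@rate)

#' @describeIn SwingRecording-class Positions of one marker role
#'   (frames x 3 matrix, metres).
#' @param role One of [markerRoles()].
#' @export
setGeneric("markerPositions", function(x, role) standardGeneric("markerPositions"))

#' @rdname SwingRecording-class
#' @export
setMethod("markerPositions", "SwingRecording", function(x, role) {
  role <- match.arg(role, markerRoles())
  x@markers[[role]]
})

#' @describeIn SwingRecording-class Logical mask of frames with a missing
#'   sample for `role`.
#' @export
setGeneric("missingFrames", function(x, role) standardGeneric("missingFrames"))

#' @rdname SwingRecording-class
#' @export
setMethod("missingFrames", "SwingRecording", function(x, role) {
  rowSums(is.na(markerPositions(x, role))) > 0L
})

#' @describeIn SwingRecording-class Handedness flag.
#' @export
setGeneric("handedness", function(x) standardGeneric("handedness"))

#' @rdname SwingRecording-class
#' @export
setMethod("handedness", "SwingRecording", function(x) x@handedness)

#' @describeIn SwingRecording-class Vertical-axis token.
#' @export
setGeneric("verticalAxis", function(x) standardGeneric("verticalAxis"))

#' @rdname SwingRecording-class
#' @export
setMethod("verticalAxis", "SwingRecording", function(x) x@verticalAxis)

setMethod("show", "SwingRecording", function(object) {
  miss <- sum(vapply(markerRoles(),
                     function(r) sum(missingFrames(object, r)), integer(1)))
  cat(sprintf(
    "SwingRecording: %d frames @ %g Hz (%.2f s), %s-handed, vertical %s\n",
    nFrames(object), object@rate, nFrames(object) / object@rate,
    object@handedness, object@verticalAxis))
  cat(sprintf("  markers: %s; missing samples: %d\n",
              paste(markerRoles(), collapse = " "), miss))
})

#' SwingPhases: frame indices of the swing-cycle boundaries
#'
#' Frame indices (1-based) of the four detected swing events, strictly ordered
#' backswing start < top of backswing < impact < follow-through end.
#'
#' @slot backswingStart,top,impact,followthroughEnd Integer frame indices.
#' @export
setClass("SwingPhases",
  representation(backswingStart = "integer", top = "integer",
                 impact = "integer", followthroughEnd = "integer"))

setValidity("SwingPhases", function(object) {
  v <- c(object@backswingStart, object@top, object@impact,
         object@followthroughEnd)
  if (length(v) != 4L || anyNA(v)) return("all four phase indices required")
  if (any(diff(v) <= 0L))
    return("phase indices must be strictly ordered: backswingStart < top < impact < followthroughEnd")
  if (v[1L] < 1L) return("phase indices must be >= 1")
  TRUE
})

#' Construct a SwingPhases object
#'
#' @param backswingStart,top,impact,followthroughEnd Frame indices (1-based),
#'   strictly increasing.
#' @return A [SwingPhases-class] object.
#' @export
SwingPhases <- function(backswingStart, top, impact, followthroughEnd) {
  new("SwingPhases", backswingStart = as.integer(backswingStart),
      top = as.integer(top), impact = as.integer(impact),
      followthroughEnd = as.integer(followthroughEnd))
}

#' @describeIn SwingPhases-class Extract the four indices as a named integer
#'   vector.
#' @param x,object A `SwingPhases`.
#' @export
setGeneric("phaseFrames", function(x) standardGeneric("phaseFrames"))

#' @rdname SwingPhases-class
#' @export
setMethod("phaseFrames", "SwingPhases", function(x) {
  c(backswingStart = x@backswingStart, top = x@top, impact = x@impact,
    followthroughEnd = x@followthroughEnd)
})

setMethod("show", "SwingPhases", function(object) {
  f <- phaseFrames(object)
  cat("SwingPhases:", paste(names(f), f, sep = "=", collapse = " "), "\n")
})

#' CircleFit: least-squares circle through 3D points
#'
#' Result of fitting a plane (total least squares) and a circle (algebraic
#' least squares in the plane) to a 3D point cloud, as used for clubhead-speed
#' estimation around impact.
#'
#' @slot center Circle centre (3-vector, metres).
#' @slot radius Radius (metres), positive.
#' @slot normal Unit normal of the fitted plane.
#' @slot rmsResidual Root-mean-square 3D distance of the points from the
#'   fitted circle (metres).
#' @export
setClass("CircleFit",
  representation(center = "numeric", radius = "numeric", normal = "numeric",
                 rmsResidual = "numeric"))

setValidity("CircleFit", function(object) {
  msgs <- character()
  if (length(object@center) != 3L) msgs <- c(msgs, "center must be a 3-vector")
  if (object@radius <= 0) msgs <- c(msgs, "radius must be positive")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    msgs <- c(msgs, "normal must be unit length")
  if (object@rmsResidual < 0) msgs <- c(msgs, "rmsResidual must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CircleFit", function(object) {
  cat(sprintf("CircleFit: radius %.4f m, rms residual %.2e m, normal (%.3f, %.3f, %.3f)\n",
              object@radius, object@rmsResidual,
              object@normal[1], object@normal[2], object@normal[3]))
})

#' SPIModel: fitted Swing Performance Index model
#'
#' Everything needed to score new swings: the metric subset, the professional
#' cohort's normalization statistics, the pro-fitted PCA rotation, the pro
#' principal-component centroid, and the log-distance scaling constants that
#' anchor professionals at 100 +/- 10 (population SD). The score of a swing
#' with principal components p is
#' \code{100 - 10 * (log(max(||p - center||, epsilon)) - mu) / sigma}.
#'
#' @slot subset Metric names the model consumes, in order.
#' @slot proMean,proSd Pro normalization statistics per metric (deg/s);
#'   population SD.
#' @slot pcaCenter Mean of the pro z-scores (analytically zero; stored as
#'   computed).
#' @slot pcaComponents Orthonormal k x k loading matrix, columns ordered by
#'   decreasing eigenvalue, sign fixed so each column's largest-|loading|
#'   entry is positive.
#' @slot proPcCenter Mean pro principal-component vector.
#' @slot logDistMean,logDistSd Pro population mean/SD of the log distances.
#' @slot epsilon Distance floor keeping the logarithm finite.
#' @slot logBase Base of the logarithm (default natural; scores are invariant
#'   to the choice).
#' @slot seed Integer seed recorded at fit time (`NA` when no randomness was
#'   consumed).
#' @slot provenance Free-form list of creation metadata.
#' @export
setClass("SPIModel",
  representation(subset = "character", proMean = "numeric", proSd = "numeric",
                 pcaCenter = "numeric", pcaComponents = "matrix",
                 proPcCenter = "numeric", logDistMean = "numeric",
                 logDistSd = "numeric", epsilon = "numeric",
                 logBase = "numeric", seed = "integer", provenance = "list"))

setValidity("SPIModel", function(object) {
  msgs <- character()
  k <- length(object@subset)
  if (k < 1L) msgs <- c(msgs, "subset must contain at least one metric")
  if (any(object@proSd <= 0))
    msgs <- c(msgs, paste0("non-positive pro SD for metric(s): ",
      paste(object@subset[object@proSd <= 0], collapse = ", ")))
  if (object@logDistSd <= 0) msgs <- c(msgs, "logDistSd must be positive")
  if (object@epsilon <= 0) msgs <- c(msgs, "epsilon must be positive")
  W <- object@pcaComponents
  if (nrow(W) != k || ncol(W) != k)
    msgs <- c(msgs, "pcaComponents must be k x k")
  else if (max(abs(crossprod(W) - diag(k))) > 1e-10)
    msgs <- c(msgs, "pcaComponents must be orthonormal to 1e-10")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SPIModel", function(object) {
  cat("SPIModel\n")
  cat("  metrics:", paste(object@subset, collapse = ", "), "\n")
  cat(sprintf("  log-distance scaling: mu=%.4f sigma=%.4f (base %g), epsilon=%g\n",
              object@logDistMean, object@logDistSd, object@logBase,
              object@epsilon))
  cat(sprintf("  seed: %s\n",
              if (is.na(object@seed)) "none" else as.character(object@seed)))
})

#' @describeIn SPIModel-class Metric subset of a fitted model.
#' @param x,object An `SPIModel`.
#' @export
setGeneric("modelSubset", function(x) standardGeneric("modelSubset"))

#' @rdname SPIModel-class
#' @export
setMethod("modelSubset", "SPIModel", function(x) x@subset)
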