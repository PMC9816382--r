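# Seeded synthetic-swing generator with analytically known ground truth.
#
# Pelvis and torso transverse-plane velocity profiles are piecewise
# raised-cosine pulses hitting designed signed peaks at designed phases
# (backswing negative, downswing positive), so every designed metric has a
# closed form on the frame grid. Bilateral markers are placed at +/- half
# the segment width perpendicular to each segment's orientation about fixed
# centres (rigid segments); the club marker rides a tilted circular arc
# whose angular profile realises the designed takeaway, top-of-backswing
# height maximum, post-impact height minimum and impact speed; the ball is
# static until the impact frame and then departs at constant velocity.

halfCosRise <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2
fullCosBump <- function(s) (1 - cos(2 * pi * pmin(pmax(s, 0), 1))) / 2

#' Synthetic swing parameters
#'
#' Designed signed peak rotational velocities (deg/s), event times (s),
#' segment geometry (m) and capture settings for one synthetic swing. Event
#' times are snapped to the frame grid at generation. Defaults place the
#' designed velocities at professional magnitudes.
#'
#' @param pelvisDown,pelvisImpact,pelvisPost Designed pelvis velocities:
#'   downswing peak, value at impact, follow-through peak (deg/s).
#' @param torsoDown,torsoImpact,torsoPost Same for the upper torso.
#' @param backswingFrac Backswing peak magnitude as a fraction of the
#'   downswing peak (negative direction), default 0.35.
#' @param pelvisPeakFrac,torsoPeakFrac Position of the downswing velocity
#'   peak between top of backswing (0) and impact (1); the pelvis peaking
#'   before the torso reproduces proximal-to-distal sequencing.
#' @param postPeakFrac Position of the follow-through peak between impact
#'   and follow-through end.
#' @param tTakeaway,tTop,tImpact,tFtEnd,duration Event times (s), strictly
#'   increasing, all below `duration`.
#' @param pelvisWidth,shoulderWidth Inter-marker segment widths (m).
#' @param clubRadius Radius of the club-marker arc (m).
#' @param csiTarget Designed clubhead speed at impact (m/s); the marker
#'   speed is `csiTarget * r / (r + 0.05)`.
#' @param noiseSd Gaussian marker noise SD (m), default 0.
#' @param rate Sampling rate (Hz), default 240.
#' @param seed Optional RNG seed used when `noiseSd > 0`.
#' @return A validated `SwingParams` list.
#' @export
swingParams <- function(pelvisDown = 415.2, pelvisImpact = 288.8,
                        pelvisPost = 309.8, torsoDown = 551.7,
                        torsoImpact = 458.5, torsoPost = 929.2,
                        backswingFrac = 0.35, pelvisPeakFrac = 0.55,
                        torsoPeakFrac = 0.75, postPeakFrac = 0.6,
                        tTakeaway = 0.30, tTop = 1.10, tImpact = 1.40,
                        tFtEnd = 1.50, duration = 2.00,
                        pelvisWidth = 0.30, shoulderWidth = 0.40,
                        clubRadius = 1.4, csiTarget = 33.15,
                        noiseSd = 0, rate = 240, seed = NULL) {
  p <- list(pelvisDown = pelvisDown, pelvisImpact = pelvisImpact,
            pelvisPost = pelvisPost, torsoDown = torsoDown,
            torsoImpact = torsoImpact, torsoPost = torsoPost,
            backswingFrac = backswingFrac, pelvisPeakFrac = pelvisPeakFrac,
            torsoPeakFrac = torsoPeakFrac, postPeakFrac = postPeakFrac,
            tTakeaway = tTakeaway, tTop = tTop, tImpact = tImpact,
            tFtEnd = tFtEnd, duration = duration,
            pelvisWidth = pelvisWidth, shoulderWidth = shoulderWidth,
            clubRadius = clubRadius, csiTarget = csiTarget,
            noiseSd = noiseSd, rate = rate, seed = seed)
  times <- c(0, tTakeaway, tTop, tImpact, tFtEnd, duration)
  if (any(diff(times) <= 0))
    stop("event times must satisfy 0 < takeaway < top < impact < followthrough end < duration")
  if (pelvisWidth <= 0 || shoulderWidth <= 0 || clubRadius <= 0 || rate <= 0)
    stop("widths, club radius and sampling rate must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  stopifnot(pelvisPeakFrac > 0, pelvisPeakFrac < 1,
            torsoPeakFrac > 0, torsoPeakFrac < 1,
            postPeakFrac > 0, postPeakFrac <= 1)
  class(p) <- "SwingParams"
  p
}

## Closed-form segment velocity profile (deg/s) on a time grid.
segmentVelocityProfile <- function(t, tTk, tTop, tImp, tFt, duration,
                                   down, impact, post, peakFrac,
                                   backswingFrac, postPeakFrac) {
  tPk <- tTop + peakFrac * (tImp - tTop)
  tPost <- tImp + postPeakFrac * (tFt - tImp)
  vFt <- 0.3 * post
  w <- numeric(length(t))
  i <- t >= tTk & t < tTop
  w[i] <- -backswingFrac * down * fullCosBump((t[i] - tTk) / (tTop - tTk))
  i <- t >= tTop & t < tPk
  w[i] <- down * halfCosRise((t[i] - tTop) / (tPk - tTop))
  i <- t >= tPk & t < tImp
  w[i] <- down + (impact - down) * halfCosRise((t[i] - tPk) / (tImp - tPk))
  i <- t >= tImp & t < tPost
  w[i] <- impact + (post - impact) * halfCosRise((t[i] - tImp) / (tPost - tImp))
  i <- t >= tPost & t < tFt
  w[i] <- post + (vFt - post) * halfCosRise((t[i] - tPost) / (tFt - tPost))
  i <- t >= tFt
  w[i] <- vFt * (1 - halfCosRise((t[i] - tFt) / (duration - tFt)))
  w
}

cumTrapz <- function(x, rate) c(0, cumsum((x[-1L] + x[-length(x)]) / 2)) / rate

## Club arc angle (rad from the bottom of the arc) on the time grid.
## The impact-to-bottom segment is a cubic Hermite whose end slope is chosen
## so the angular acceleration at impact is exactly zero: the one-frame
## marker displacement after impact then measures the designed impact speed
## to well under 0.1 percent. With psiImp = c*omega*dt and end slope
## omega*(2 - 3c), c = 0.8 keeps the segment monotone (both endpoint slopes
## within 3x the secant slope) and the end slope negative, so the arc
## crosses its bottom - the height minimum - exactly at tFt.
clubArcProfile <- function(t, tTk, tTop, tImp, tFt, duration, omegaImp) {
  psiAddr <- 0.08
  psiTop <- 2.75
  dtFt <- tFt - tImp
  cImp <- 0.8
  psiImp <- cImp * omegaImp * dtFt
  mFt <- omegaImp * (2 - 3 * cImp)      # = -0.4 * omegaImp
  if (psiImp >= 0.85 * psiTop)
    stop("club arc profile infeasible: impact speed too high for the follow-through duration")
  a <- omegaImp * (tImp - tTop) / (psiTop - psiImp)
  if (a <= 1)
    stop("club arc profile infeasible: impact speed too low for the downswing duration")
  psi <- numeric(length(t))
  psi[t < tTk] <- psiAddr
  i <- t >= tTk & t < tTop
  psi[i] <- psiAddr + (psiTop - psiAddr) * halfCosRise((t[i] - tTk) / (tTop - tTk))
  i <- t >= tTop & t < tImp
  s <- (t[i] - tTop) / (tImp - tTop)
  psi[i] <- psiImp + (psiTop - psiImp) * (1 - s^a)
  i <- t >= tImp & t < tFt
  s <- (t[i] - tImp) / dtFt
  h00 <- 2 * s^3 - 3 * s^2 + 1; h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2;    h11 <- s^3 - s^2
  psi[i] <- h00 * psiImp + h10 * dtFt * (-omegaImp) + h11 * dtFt * mFt
  i <- t >= tFt
  b <- 2.5
  psiEnd <- mFt * (duration - tFt) / b
  s <- (t[i] - tFt) / (duration - tFt)
  psi[i] <- psiEnd * (1 - (1 - s)^b)
  psi
}

#' Generate one synthetic swing with ground truth
#'
#' Builds a noise-free [SwingRecording-class] from closed-form velocity and
#' club-arc profiles (optionally adding seeded Gaussian marker noise) plus a
#' one-row ground-truth table: the designed phase frames and the nine
#' designed metrics, computed by applying the metric window rules to the
#' noiseless analytic velocity profiles on the frame grid - independent of
#' the marker-processing pipeline under test.
#'
#' @param params A [swingParams()] list.
#' @return List with `recording` (a [SwingRecording-class]) and `truth`
#'   (one-row `data.frame`).
#' @export
generateSwing <- function(params) {
  stopifnot(inherits(params, "SwingParams"))
  p <- params
  rate <- p$rate
  n <- floor(p$duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  snap <- function(x) (round(x * rate)) / rate
  tTk <- snap(p$tTakeaway); tTop <- snap(p$tTop)
  tImp <- snap(p$tImpact); tFt <- snap(p$tFtEnd)
  fTk <- as.integer(round(tTk * rate)) + 1L
  fTop <- as.integer(round(tTop * rate)) + 1L
  fImp <- as.integer(round(tImp * rate)) + 1L
  fFt <- as.integer(round(tFt * rate)) + 1L

  wPel <- segmentVelocityProfile(t, tTk, tTop, tImp, tFt, p$duration,
                                 p$pelvisDown, p$pelvisImpact, p$pelvisPost,
                                 p$pelvisPeakFrac, p$backswingFrac,
                                 p$postPeakFrac)
  wTor <- segmentVelocityProfile(t, tTk, tTop, tImp, tFt, p$duration,
                                 p$torsoDown, p$torsoImpact, p$torsoPost,
                                 p$torsoPeakFrac, p$backswingFrac,
                                 p$postPeakFrac)
  wXp <- wPel - wTor
  # integrate on a 4x supersampled grid so the angle series carries the
  # closed-form profile to well beyond central-difference accuracy
  ss <- 4L
  tFine <- (seq_len((n - 1L) * ss + 1L) - 1L) / (rate * ss)
  integrateFine <- function(down, impact, post, peakFrac) {
    wf <- segmentVelocityProfile(tFine, tTk, tTop, tImp, tFt, p$duration,
                                 down, impact, post, peakFrac,
                                 p$backswingFrac, p$postPeakFrac)
    cumTrapz(wf, rate * ss)[seq(1L, length(tFine), by = ss)] * pi / 180
  }
  thPel <- integrateFine(p$pelvisDown, p$pelvisImpact, p$pelvisPost,
                         p$pelvisPeakFrac)
  thTor <- integrateFine(p$torsoDown, p$torsoImpact, p$torsoPost,
                         p$torsoPeakFrac)

  seg <- function(theta, center, width) {
    u <- cbind(cos(theta), sin(theta), 0)
    list(left = sweep(u * (width / 2), 2L, center, "+"),
         right = sweep(-u * (width / 2), 2L, center, "+"))
  }
  pel <- seg(thPel, c(0, 0, 1.00), p$pelvisWidth)
  tor <- seg(thTor, c(0, 0, 1.45), p$shoulderWidth)

  r <- p$clubRadius
  vMarker <- p$csiTarget * r / (r + 0.05)
  psi <- clubArcProfile(t, tTk, tTop, tImp, tFt, p$duration, vMarker / r)
  beta <- 0.4
  cc <- c(0.8, 0, 1.3)
  u1 <- c(0, 1, 0); u2 <- c(sin(beta), 0, cos(beta))
  club <- matrix(cc, n, 3L, byrow = TRUE) +
    outer(sin(psi) * r, u1) - outer(cos(psi) * r, u2)

  ballSpeed <- max(1.4 * p$csiTarget, 2)
  pb <- cc - r * u2 + c(0, 0.05, 0.02)
  ball <- matrix(pb, n, 3L, byrow = TRUE)
  moving <- t > tImp
  ball[moving, 2L] <- pb[2L] + ballSpeed * (t[moving] - tImp)

  markers <- list(LASIS = pel$left, RASIS = pel$right,
                  LACR = tor$left, RACR = tor$right,
                  CLUB = club, BALL = ball)
  if (p$noiseSd > 0) {
    addNoise <- function(m) m + matrix(rnorm(length(m), 0, p$noiseSd),
                                       nrow(m), ncol(m))
    markers <- if (is.null(p$seed)) lapply(markers, addNoise)
               else withSeed(p$seed, lapply(markers, addNoise))
  }
  rec <- SwingRecording(markers, rate = rate, handedness = "right",
                        verticalAxis = "z+")

  # ground truth: takeaway and top are defined operationally on the
  # noiseless club trajectory (0.2 m/s sustained vertical-speed crossing;
  # height maximum with latest-tie rule), metric values from the analytic
  # velocity profiles and the designed window rules
  vClub <- abs(centralDiff(club[, 3L], rate))
  runs <- rle(vClub > 0.2)
  ends <- cumsum(runs$lengths)
  ok <- which(runs$values & runs$lengths >= 5L)
  if (!length(ok))
    stop("generated swing never exceeds the takeaway speed threshold")
  fTk <- ends[ok[1L]] - runs$lengths[ok[1L]] + 1L
  hWin <- club[fTk:fImp, 3L]
  fTop <- fTk + max(which(hWin == max(hWin))) - 1L
  pre <- fTop:fImp; post <- (fImp + 1L):fFt
  truth <- data.frame(
    takeaway = fTk, top = fTop, impact = fImp, followthroughEnd = fFt,
    pelvis.peak_pre_impact = signedPeak(wPel, pre),
    pelvis.at_impact = wPel[fImp],
    pelvis.peak_post_impact = signedPeak(wPel, post),
    torso.peak_pre_impact = signedPeak(wTor, pre),
    torso.at_impact = wTor[fImp],
    torso.peak_post_impact = signedPeak(wTor, post),
    xprime.peak_pre_impact = signedPeak(wXp, pre),
    xprime.at_impact = wXp[fImp],
    xprime.peak_post_impact = signedPeak(wXp, post),
    csiTarget = p$csiTarget, markerSpeed = vMarker)
  list(recording = rec, truth = truth)
}

#' Professional and amateur swing-parameter presets
#'
#' Distributions from which per-swing [swingParams()] are drawn. The
#' professional preset centres the designed velocities on published
#' professional peak magnitudes (pelvis 415.2 / 288.8 / 309.8 deg/s, torso
#' 551.7 / 458.5 / 929.2 deg/s for downswing / impact / follow-through) with
#' the corresponding SDs. The amateur preset is a documented degradation -
#' velocity means scaled by 0.75 with doubled SDs, a delayed pelvis peak,
#' and lower clubhead speed - claiming only separability from the pros, not
#' amateur realism.
#'
#' @return List with `mean` and `sd` sub-lists over the velocity targets,
#'   clubhead speed, and downswing peak-timing fractions.
#' @export
proPreset <- function() {
  list(mean = list(pelvisDown = 415.2, pelvisImpact = 288.8,
                   pelvisPost = 309.8, torsoDown = 551.7,
                   torsoImpact = 458.5, torsoPost = 929.2,
                   csiTarget = 33.15, pelvisPeakFrac = 0.55,
                   torsoPeakFrac = 0.75),
       sd = list(pelvisDown = 32.9, pelvisImpact = 70.9, pelvisPost = 42.1,
                 torsoDown = 47.6, torsoImpact = 73.0, torsoPost = 185.1,
                 csiTarget = 5.91, pelvisPeakFrac = 0.03,
                 torsoPeakFrac = 0.03))
}

#' @rdname proPreset
#' @export
amateurPreset <- function() {
  pro <- proPreset()
  vel <- c("pelvisDown", "pelvisImpact", "pelvisPost",
           "torsoDown", "torsoImpact", "torsoPost")
  mean <- pro$mean; sd <- pro$sd
  for (v in vel) { mean[[v]] <- 0.75 * mean[[v]]; sd[[v]] <- 2 * sd[[v]] }
  mean$csiTarget <- 30.58; sd$csiTarget <- 3.33
  mean$pelvisPeakFrac <- 0.85; sd$pelvisPeakFrac <- 0.06
  sd$torsoPeakFrac <- 0.06
  list(mean = mean, sd = sd)
}

## One parameter draw from a preset (consumes the current RNG stream).
drawParams <- function(preset, noiseSd = 0) {
  draw <- function(field, lo = -Inf, hi = Inf) {
    min(max(rnorm(1L, preset$mean[[field]], preset$sd[[field]]), lo), hi)
  }
  vel <- function(field) draw(field, lo = 0.2 * preset$mean[[field]])
  swingParams(
    pelvisDown = vel("pelvisDown"), pelvisImpact = vel("pelvisImpact"),
    pelvisPost = vel("pelvisPost"), torsoDown = vel("torsoDown"),
    torsoImpact = vel("torsoImpact"), torsoPost = vel("torsoPost"),
    pelvisPeakFrac = draw("pelvisPeakFrac", 0.3, 0.92),
    torsoPeakFrac = draw("torsoPeakFrac", 0.3, 0.92),
    csiTarget = draw("csiTarget", lo = 18, hi = 40),
    noiseSd = noiseSd)
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-swing parameters from the professional and amateur presets and
#' generates one recording per participant. Deterministic given `seed`.
#'
#' @param nPro,nAmateur Cohort sizes, each at least 2.
#' @param seed Integer RNG seed.
#' @param noiseSd Gaussian marker noise SD (m) applied to every recording,
#'   default 0.
#' @return List with `recordings` (named list of [SwingRecording-class])
#'   and `truth` (`data.frame` with `swing`, `subject`, `group`, designed
#'   phase frames and designed metrics).
#' @export
generateCohort <- function(nPro, nAmateur, seed, noiseSd = 0) {
  stopifnot(nPro >= 2L, nAmateur >= 2L)
  withSeed(seed, {
    ids <- c(sprintf("pro%02d", seq_len(nPro)),
             sprintf("am%02d", seq_len(nAmateur)))
    groups <- rep(c("pro", "amateur"), c(nPro, nAmateur))
    recordings <- vector("list", length(ids))
    names(recordings) <- ids
    truths <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      preset <- if (groups[i] == "pro") proPreset() else amateurPreset()
      params <- drawParams(preset, noiseSd = noiseSd)
      sw <- generateSwing(params)
      recordings[[i]] <- sw$recording
      truths[[i]] <- cbind(data.frame(swing = ids[i], subject = ids[i],
                                      group = groups[i],
                                      stringsAsFactors = FALSE),
                           sw$truth)
    }
    list(recordings = recordings, truth = do.call(rbind, truths))
  })
}
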