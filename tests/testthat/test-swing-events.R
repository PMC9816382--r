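test_that("backswing start triggers on sustained 0.2 m/s vertical club speed", {
  rate <- 240
  # 1 s stationary, then rising at 0.5 m/s
  clubZ <- c(rep(0.1, 240), 0.1 + cumsum(rep(0.5 / rate, 200)))
  rec <- makeEventRecording(clubZ)
  start <- detectBackswingStart(rec)
  expect_true(abs(start - 240L) <= 5L)

  # a takeaway that dips first still triggers (absolute value rule)
  dip <- c(rep(0.1, 240), 0.1 - cumsum(rep(0.5 / rate, 200)))
  expect_true(abs(detectBackswingStart(makeEventRecording(dip)) - 240L) <= 5L)

  # 0.19 m/s forever: threshold is strict
  slow <- 0.1 + cumsum(rep(0.19 / rate, 400))
  expect_error(detectBackswingStart(makeEventRecording(slow)),
               "no swing detected")

  # single-frame spike is rejected by the sustain requirement
  spiky <- rep(0.1, 400); spiky[200] <- 0.2
  expect_error(detectBackswingStart(makeEventRecording(spiky)),
               "no swing detected")
})

test_that("impact is the frame immediately preceding ball launch", {
  rate <- 240; n <- 500L
  clubZ <- c(rep(0.5, 100), 0.5 + cumsum(rep(0.6 / rate, n - 100)))
  ball <- constMat(n, c(1, 0, 0.02))
  # ball first displaced at frame 400 (30 m/s)
  moving <- 400:n
  ball[moving, 2L] <- 0.02 + 30 / rate * (moving - 399)
  rec <- makeEventRecording(clubZ, ball)
  start <- detectBackswingStart(rec)
  expect_identical(detectImpact(rec, start), 399L)

  # 0.01 m/s drift never false-triggers; never-launching ball errors
  drift <- constMat(n, c(1, 0, 0.02))
  drift[, 2L] <- 0.02 + cumsum(rep(0.01 / rate, n))
  expect_error(detectImpact(makeEventRecording(clubZ, drift), start),
               "never moves")

  # ball already moving before the swing -> error
  early <- constMat(n, c(1, 0, 0.02))
  early[, 2L] <- 0.02 + cumsum(rep(0.2 / rate, n))
  expect_error(detectImpact(makeEventRecording(clubZ, early), start),
               "moving at recording start")
})

test_that("top of backswing takes the latest maximal-height frame", {
  up <- c(seq(0, 1, length.out = 100), seq(0.99, 0.2, length.out = 100))
  rec <- makeEventRecording(c(rep(0, 10), up))
  expect_identical(detectTop(rec, 10L, 200L), 110L)
  plateau <- c(seq(0, 1, length.out = 50), rep(1, 20),
               seq(0.98, 0, length.out = 50))
  rec2 <- makeEventRecording(plateau)
  expect_identical(detectTop(rec2, 1L, 120L), 70L)  # last plateau frame
})

test_that("follow-through ends at the first height minimum after impact", {
  v <- c(rep(1, 50), seq(1, 0.2, length.out = 40),
         seq(0.2, 0.8, length.out = 40))
  rec <- makeEventRecording(v)
  expect_identical(detectFollowthroughEnd(rec, 60L), 90L)

  mono <- c(rep(1, 50), seq(1, 0, length.out = 80))
  expect_warning(ft <- detectFollowthroughEnd(makeEventRecording(mono), 60L),
                 "last frame")
  expect_identical(ft, 130L)

  # plateau minimum: first frame of the minimal plateau
  plat <- c(rep(1, 10), seq(1, 0.3, length.out = 20), rep(0.3, 5),
            seq(0.3, 1, length.out = 20))
  expect_identical(detectFollowthroughEnd(makeEventRecording(plat), 12L), 30L)
})

test_that("3D circle fit is exact on noiseless arcs in any orientation", {
  for (seed in 1:5) {
    for (arc in c(15, 60, 180, 360)) {
      pts <- circlePoints3d(100L, 1.4, c(2, -1, 3), arcDeg = arc,
                            seed = seed)
      fit <- fitCircle3d(pts)
      expect_lt(abs(fit@radius - 1.4), 1e-9)
      expect_lt(fit@rmsResidual, 1e-9)
    }
  }
  # three points: circumscribed circle of the triangle (closed form)
  tri <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0))
  a <- 5; b <- 3; cc <- 4                     # side lengths
  area <- 6
  circumR <- a * b * cc / (4 * area)
  expect_equal(fitCircle3d(tri)@radius, circumR, tolerance = 1e-12)
  # collinear points refuse to fit
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fitCircle3d(line), "collinear")
})

test_that("circle fit tolerates millimetre noise", {
  set.seed(99)
  pts <- circlePoints3d(100L, 1.4, c(0, 0, 1), arcDeg = 120)
  noisy <- pts + matrix(rnorm(300, 0, 0.001), 100L)
  expect_lt(abs(fitCircle3d(noisy)@radius - 1.4), 0.005)
})

test_that("clubhead speed applies the 5 cm radius correction", {
  rate <- 240; r <- 1; omega <- 20           # rad/s on a circle of 1 m
  t <- (0:299) / rate
  phi <- omega * (t - t[150])
  alpha <- 0.3     # plane tilt
  club <- cbind(r * cos(phi), r * sin(phi) * cos(alpha),
                1 + r * sin(phi) * sin(alpha))
  n <- 300L
  rec <- SwingRecording(list(
    LASIS = constMat(n, c(0.15, 0, 1)), RASIS = constMat(n, c(-0.15, 0, 1)),
    LACR = constMat(n, c(0.2, 0, 1.45)), RACR = constMat(n, c(-0.2, 0, 1.45)),
    CLUB = club, BALL = constMat(n, c(1, 0, 0))), rate = rate)
  phases <- SwingPhases(10L, 100L, 150L, 200L)
  csi <- clubheadSpeedAtImpact(rec, phases)
  expect_equal(as.numeric(csi), 1.05 * omega * r, tolerance = 0.01)
  expect_equal(attr(csi, "radius"), r, tolerance = 1e-6)

  # straight-line path: guarded fallback to the raw marker speed
  straight <- cbind(seq(0, 3, length.out = n), 0, 1)
  rec2 <- SwingRecording(modifyList(rec@markers, list(CLUB = straight)),
                         rate = rate)
  expect_warning(csi2 <- clubheadSpeedAtImpact(rec2, phases),
                 "marker speed")
  vm <- 3 / (n - 1) * rate
  expect_equal(as.numeric(csi2), vm, tolerance = 1e-9)
})

test_that("synthetic swings are segmented at their designed frames", {
  for (seed in c(1, 2)) {
    params <- drawProParams(seed)
    sw <- generateSwing(params)
    tr <- sw$truth
    ph <- detectPhases(sw$recording)
    f <- phaseFrames(ph)
    expect_true(abs(f[["backswingStart"]] - tr$takeaway) <= 5L)
    expect_true(abs(f[["top"]] - tr$top) <= 3L)
    expect_identical(f[["impact"]], tr$impact)
    expect_true(abs(f[["followthroughEnd"]] - tr$followthroughEnd) <= 2L)
    expect_true(all(diff(f) > 0))
    # invariant to rigid horizontal translation of the whole scene
    shifted <- SwingRecording(
      lapply(sw$recording@markers, function(m)
        sweep(m, 2L, c(5, -3, 0), "+")), 240)
    expect_identical(phaseFrames(detectPhases(shifted)), f)
  }
})

test_that("synthetic pro swing hits its designed clubhead speed", {
  sw <- generateSwing(swingParams(csiTarget = 33))
  csi <- clubheadSpeedAtImpact(sw$recording, detectPhases(sw$recording))
  expect_equal(as.numeric(csi), 33, tolerance = 0.02)
})
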