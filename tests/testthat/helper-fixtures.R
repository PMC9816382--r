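# Fixtures are built in code: small TRC/CSV files written to tempdirs, and
# hand-constructed recordings where only one marker's motion matters.

trcLabels <- function() unname(defaultRoleMap())

# Write a minimal TRC file (5-line header + data). `data` is a named list of
# n x 3 matrices, one per label, in the file's declared units; NA -> blank.
writeTrcFixture <- function(path, data, units = "mm", rate = 240) {
  labels <- names(data)
  n <- nrow(data[[1L]])
  header <- c(
    "PathFileType\t4\t(X/Y/Z)\tfixture.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    paste(rate, rate, n, length(labels), units, rate, 1, n, sep = "\t"),
    paste(c("Frame#", "Time", as.vector(rbind(labels, "", ""))),
          collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(labels)),
                           rep(seq_along(labels), each = 3L))),
          collapse = "\t"))
  rows <- vapply(seq_len(n), function(i) {
    vals <- unlist(lapply(data, function(m) m[i, ]))
    vals <- ifelse(is.na(vals), "", format(vals, trim = TRUE))
    paste(c(i, (i - 1) / rate, vals), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

constMat <- function(n, xyz) matrix(xyz, n, 3L, byrow = TRUE)

# Recording whose body markers are static and whose club/ball trajectories
# are supplied; used by event-detection tests where only one marker matters.
makeEventRecording <- function(clubZ, ball = NULL, rate = 240) {
  n <- length(clubZ)
  club <- cbind(0.8, 0, clubZ)
  if (is.null(ball)) ball <- constMat(n, c(1, 0, 0.02))
  SwingRecording(list(
    LASIS = constMat(n, c(0.15, 0, 1)), RASIS = constMat(n, c(-0.15, 0, 1)),
    LACR = constMat(n, c(0.2, 0, 1.45)), RACR = constMat(n, c(-0.2, 0, 1.45)),
    CLUB = club, BALL = ball), rate = rate)
}

# Recording with both segments rotating at constant angular velocity
# (deg/s); club and ball static.
makeRotatingRecording <- function(omegaPelvis, omegaTorso, n = 200,
                                  rate = 240) {
  t <- (seq_len(n) - 1L) / rate
  seg <- function(omega, width, center) {
    th <- omega * t * pi / 180
    u <- cbind(cos(th), sin(th), 0)
    list(left = sweep(u * width / 2, 2L, center, "+"),
         right = sweep(-u * width / 2, 2L, center, "+"))
  }
  p <- seg(omegaPelvis, 0.3, c(0, 0, 1))
  s <- seg(omegaTorso, 0.4, c(0, 0, 1.45))
  SwingRecording(list(LASIS = p$left, RASIS = p$right,
                      LACR = s$left, RACR = s$right,
                      CLUB = constMat(n, c(0.8, 0, 0.1)),
                      BALL = constMat(n, c(1, 0, 0.02))), rate = rate)
}

# Points on a circle of given radius in a random 3D orientation.
circlePoints3d <- function(n, radius, center, arcDeg = 360, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(9), 3L)))
  phi <- seq(0, arcDeg * pi / 180, length.out = n)
  sweep(outer(cos(phi) * radius, basis[, 1L]) +
        outer(sin(phi) * radius, basis[, 2L]), 2L, center, "+")
}

# Labeled metric dataset with a designed group difference, for model tests.
makeLabeledDataset <- function(nPro = 10L, nAm = 4L, seed = 1L,
                               shift = c(3, 2, 1.5, 0, 0, 0, 0, 0, 0)) {
  set.seed(seed)
  mets <- metricNames()
  pro <- matrix(rnorm(nPro * 9L), nPro)
  am <- sweep(matrix(rnorm(nAm * 9L), nAm), 2L, shift)
  x <- rbind(pro, am) * 50 + 300
  colnames(x) <- mets
  data.frame(swing = sprintf("sw%02d", seq_len(nPro + nAm)),
             subject = sprintf("subj%02d", seq_len(nPro + nAm)),
             group = rep(c("pro", "amateur"), c(nPro, nAm)),
             x, check.names = FALSE, stringsAsFactors = FALSE)
}

refPcCols <- c("pc1", "pc2", "pc3")

# Seeded parameter draw from the professional preset.
drawProParams <- function(seed, noiseSd = 0) {
  golfSPI:::withSeed(seed, golfSPI:::drawParams(proPreset(), noiseSd))
}
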