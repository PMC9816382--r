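test_that("TRC reading converts units, maps roles, and masks blanks", {
  n <- 10L
  data <- setNames(lapply(trcLabels(), function(l) constMat(n, c(1000, 0, 500))),
                   trcLabels())
  data[["CLUB"]][4L, ] <- NA          # dropout frame -> blank cells
  path <- withr::local_tempfile(fileext = ".trc")
  writeTrcFixture(path, data, units = "mm")
  rec <- readTrc(path)
  expect_s4_class(rec, "SwingRecording")
  expect_equal(nFrames(rec), n)
  expect_equal(samplingRate(rec), 240)
  expect_equal(markerPositions(rec, "LASIS")[1L, ],
               c(x = 1, y = 0, z = 0.5))  # mm -> m
  expect_equal(which(missingFrames(rec, "CLUB")), 4L)
  expect_false(any(missingFrames(rec, "BALL")))

  # metres declared as metres stay untouched
  pathM <- withr::local_tempfile(fileext = ".trc")
  writeTrcFixture(pathM, data, units = "m")
  expect_equal(markerPositions(readTrc(pathM), "LASIS")[1L, 1L],
               c(x = 1000))
})

test_that("TRC validation names absent roles and bad columns", {
  n <- 5L
  labels <- setdiff(trcLabels(), "BALL")
  data <- setNames(lapply(labels, function(l) constMat(n, c(1, 2, 3))),
                   labels)
  path <- withr::local_tempfile(fileext = ".trc")
  writeTrcFixture(path, data)
  expect_error(readTrc(path), "BALL")

  full <- setNames(lapply(trcLabels(), function(l) constMat(n, c(1, 2, 3))),
                   trcLabels())
  path2 <- withr::local_tempfile(fileext = ".trc")
  writeTrcFixture(path2, full)
  lines <- readLines(path2)
  lines[8L] <- paste(lines[8L], "99", sep = "\t")   # extra field in frame 3
  writeLines(lines, path2)
  expect_error(readTrc(path2), "line 8")
})

test_that("CSV dialect round-trips recordings to below 1e-9 m", {
  sw <- generateSwing(swingParams(noiseSd = 0.002, seed = 3))
  rec <- sw$recording
  # punch a hole so the mask round-trips too
  m <- rec@markers; m$RACR[17L, ] <- NA
  rec <- SwingRecording(m, samplingRate(rec), handedness = "left",
                        verticalAxis = "z+")
  path <- withr::local_tempfile(fileext = ".csv")
  writeMarkerCsv(rec, path)
  back <- readMarkerCsv(path)
  expect_equal(samplingRate(back), samplingRate(rec))
  expect_identical(handedness(back), "left")
  expect_identical(verticalAxis(back), "z+")
  for (role in markerRoles()) {
    a <- markerPositions(rec, role); b <- markerPositions(back, role)
    expect_identical(is.na(a), is.na(b))
    expect_lt(max(abs(a - b), na.rm = TRUE), 1e-9)
  }
})

test_that("CSV reader enforces its dialect", {
  sw <- generateSwing(swingParams())
  path <- withr::local_tempfile(fileext = ".csv")
  writeMarkerCsv(sw$recording, path)
  lines <- readLines(path)

  expect_equal(samplingRate(readMarkerCsv(path)), 240)  # '#rate=240'

  bad <- sub("^#units=m$", "#units=furlong", lines)
  writeLines(bad, path)
  expect_error(readMarkerCsv(path), "units")

  # drop one role's columns entirely -> validation error naming it
  hdr <- strsplit(lines[5L], ",")[[1L]]
  keep <- !grepl("^BALL_", hdr)
  body <- vapply(lines[-(1:5)], function(l)
    paste(strsplit(l, ",")[[1L]][keep], collapse = ","), character(1),
    USE.NAMES = FALSE)
  writeLines(c(lines[1:4], paste(hdr[keep], collapse = ","), body), path)
  expect_error(readMarkerCsv(path), "BALL")

  # duplicated role columns -> error
  dup <- c(lines[1:4],
           paste(c(hdr, "CLUB_x", "CLUB_y", "CLUB_z"), collapse = ","),
           vapply(lines[-(1:5)], function(l) paste(l, "1,2,3", sep = ","),
                  character(1), USE.NAMES = FALSE))
  writeLines(dup, path)
  expect_error(readMarkerCsv(path), "duplicate")
})

test_that("gap interpolation fills short interior runs linearly", {
  sw <- generateSwing(swingParams())
  m <- sw$recording@markers
  # single-frame gap between known neighbours
  m$CLUB[100L, ] <- NA
  # run of 4 (> maxGap) left alone; leading run never extrapolated
  m$BALL[20:23, ] <- NA
  m$LACR[1:2, ] <- NA
  rec <- SwingRecording(m, 240)
  expect_message(filled <- interpolateGaps(rec, maxGap = 3L),
                 "unfilled")
  expect_equal(markerPositions(filled, "CLUB")[100L, ],
               (markerPositions(rec, "CLUB")[99L, ] +
                markerPositions(rec, "CLUB")[101L, ]) / 2)
  expect_true(all(missingFrames(filled, "BALL")[20:23]))
  expect_true(all(missingFrames(filled, "LACR")[1:2]))

  # midpoint example: 0 m and 2 m around a 1-frame hole -> 1 m
  m2 <- rec@markers
  m2$CLUB[1:3, ] <- rbind(c(0, 0, 0), NA, c(2, 2, 2))
  filled2 <- suppressMessages(interpolateGaps(SwingRecording(m2, 240), 1L))
  expect_equal(markerPositions(filled2, "CLUB")[2L, ],
               c(x = 1, y = 1, z = 1))

  # idempotent, and identity when nothing is missing
  again <- suppressMessages(interpolateGaps(filled, maxGap = 3L))
  expect_identical(again@markers, filled@markers)
  clean <- generateSwing(swingParams())$recording
  expect_identical(interpolateGaps(clean, 5L)@markers, clean@markers)
})
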