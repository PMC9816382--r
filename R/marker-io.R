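# Reading, validating and writing marker-trajectory recordings.
# Canonical internal units are metres; TRC files declaring Units=mm are
# converted on read (single conversion site).

#' Default marker-label to role mapping
#'
#' Lab marker naming varies; the reader maps file labels onto the six
#' canonical roles through this mapping, which callers can override.
#'
#' @return Named character vector `role = label` covering [markerRoles()].
#' @export
#' @examples
#' defaultRoleMap()
defaultRoleMap <- function() {
  c(LASIS = "L.ASIS", RASIS = "R.ASIS", LACR = "L.ACR", RACR = "R.ACR",
    CLUB = "CLUB", BALL = "BALL")
}

checkRoleMap <- function(roleMap) {
  missing <- setdiff(markerRoles(), names(roleMap))
  if (length(missing))
    stop("role mapping lacks roles: ", paste(missing, collapse = ", "))
  roleMap[markerRoles()]
}

#' Read a TRC marker file
#'
#' Parses the tab-separated TRC dialect (5-line header: file type line,
#' metadata field names, metadata values, marker-name row, coordinate-label
#' row, then one row per frame). Positions declared in millimetres are
#' converted to metres; blank cells become missing samples (`NA`).
#'
#' @param path Path to a `.trc` file.
#' @param roleMap Named character vector mapping roles to the marker labels
#'   used in the file; default [defaultRoleMap()].
#' @param handedness,verticalAxis Recording metadata not carried by TRC;
#'   defaults `"right"` and `"z+"`.
#' @return A [SwingRecording-class].
#' @export
readTrc <- function(path, roleMap = defaultRoleMap(), handedness = "right",
                    verticalAxis = "z+") {
  if (!file.exists(path)) stop("file not found: ", path)
  roleMap <- checkRoleMap(roleMap)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("truncated TRC file: ", path)
  fields <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  values <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
  meta <- as.list(values)
  names(meta) <- fields[seq_along(values)]
  if (is.null(meta$DataRate)) stop("TRC header lacks DataRate")
  rate <- as.numeric(meta$DataRate)
  units <- meta$Units
  if (is.null(units) || !units %in% c("m", "mm"))
    stop("TRC Units must be 'm' or 'mm', got: ",
         if (is.null(units)) "<absent>" else units)
  scale <- if (units == "mm") 1e-3 else 1
  labels <- strsplit(lines[[4L]], "\t", fixed = TRUE)[[1L]]
  labels <- labels[-(1:2)]
  labels <- labels[labels != ""]
  dataLines <- lines[-(1:5)]
  dataLines <- dataLines[trimws(dataLines) != ""]
  nExpected <- 2L + 3L * length(labels)
  rows <- strsplit(dataLines, "\t", fixed = TRUE)
  n <- length(rows)
  mat <- matrix(NA_real_, n, 3L * length(labels))
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (length(f) > nExpected)
      stop(sprintf("inconsistent column count at line %d: %d fields, expected %d",
                   i + 5L, length(f), nExpected))
    length(f) <- nExpected       # short rows: trailing blanks -> missing
    f[f == ""] <- NA_character_
    mat[i, ] <- suppressWarnings(as.numeric(f[-(1:2)]))
  }
  markers <- list()
  for (role in markerRoles()) {
    j <- match(roleMap[[role]], labels)
    if (is.na(j)) next
    markers[[role]] <- mat[, (3L * (j - 1L) + 1L):(3L * j), drop = FALSE] * scale
  }
  absent <- setdiff(markerRoles(), names(markers))
  if (length(absent))
    stop("recording lacks marker(s) for role(s): ",
         paste(absent, collapse = ", "))
  SwingRecording(markers, rate = rate, handedness = handedness,
                 verticalAxis = verticalAxis)
}

#' Read a marker CSV file
#'
#' Documented CSV dialect: metadata comment rows `#rate=<Hz>`, `#units=m|mm`,
#' `#vertical=<axis><sign>` (and optional `#handedness=right|left`), followed
#' by a header `frame,<ROLE>_x,<ROLE>_y,<ROLE>_z,...` and one row per frame.
#' Empty cells mark missing samples.
#'
#' @param path Path to the CSV file.
#' @return A [SwingRecording-class].
#' @seealso [writeMarkerCsv()]
#' @export
readMarkerCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  if (is.null(meta$rate)) stop("missing '#rate=' metadata row")
  rate <- as.numeric(meta$rate)
  units <- if (is.null(meta$units)) "m" else meta$units
  if (!units %in% c("m", "mm")) stop("unknown units token: ", units)
  scale <- if (units == "mm") 1e-3 else 1
  verticalAxis <- if (is.null(meta$vertical)) "z+" else meta$vertical
  hand <- if (is.null(meta$handedness)) "right" else meta$handedness
  body <- lines[!grepl("^#", lines)]
  body <- body[trimws(body) != ""]
  df <- read.csv(text = paste(body, collapse = "\n"), check.names = FALSE)
  markers <- list()
  for (role in markerRoles()) {
    cols <- paste0(role, "_", c("x", "y", "z"))
    hits <- lapply(cols, function(cn) which(colnames(df) == cn))
    if (any(lengths(hits) > 1L))
      stop("duplicate columns for role ", role)
    if (all(lengths(hits) == 1L)) {
      markers[[role]] <- as.matrix(df[, cols, drop = FALSE]) * scale
    }
  }
  absent <- setdiff(markerRoles(), names(markers))
  if (length(absent))
    stop("recording lacks marker(s) for role(s): ",
         paste(absent, collapse = ", "))
  SwingRecording(markers, rate = rate, handedness = hand,
                 verticalAxis = verticalAxis)
}

#' Write a marker CSV file
#'
#' Writes the dialect read by [readMarkerCsv()], always in metres, with full
#' double precision so that a read/write round trip preserves positions to
#' well below 1e-9 m. Missing samples become empty cells.
#'
#' @param rec A [SwingRecording-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMarkerCsv <- function(rec, path) {
  stopifnot(is(rec, "SwingRecording"))
  n <- nFrames(rec)
  cols <- list(frame = seq_len(n))
  for (role in markerRoles()) {
    p <- markerPositions(rec, role)
    for (j in 1:3)
      cols[[paste0(role, "_", c("x", "y", "z")[j])]] <- p[, j]
  }
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- c(sprintf("#rate=%.17g", samplingRate(rec)),
              "#units=m",
              paste0("#vertical=", verticalAxis(rec)),
              paste0("#handedness=", handedness(rec)))
  rows <- do.call(paste, c(lapply(cols[-1L], fmt), list(sep = ",")))
  writeLines(c(header, paste(names(cols), collapse = ","),
               paste(cols$frame, rows, sep = ",")), path)
  invisible(path)
}

#' Fill short marker dropouts by linear interpolation
#'
#' Interior runs of at most `maxGap` consecutive missing frames are filled by
#' per-coordinate linear interpolation between the flanking samples. Longer
#' runs, and leading/trailing runs (which would require extrapolation), are
#' left missing and reported via a message. The operation is idempotent.
#'
#' @param rec A [SwingRecording-class].
#' @param maxGap Maximum run length (frames) that will be filled.
#' @return A new [SwingRecording-class] with gaps filled.
#' @export
interpolateGaps <- function(rec, maxGap) {
  stopifnot(is(rec, "SwingRecording"), maxGap >= 0)
  markers <- rec@markers
  unfilled <- character()
  for (role in markerRoles()) {
    p <- markers[[role]]
    miss <- rowSums(is.na(p)) > 0L
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      interior <- starts[k] > 1L && ends[k] < nrow(p)
      if (interior && r$lengths[k] <= maxGap) {
        i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
        for (j in 1:3) {
          p[starts[k]:ends[k], j] <-
            approx(c(i0, i1), p[c(i0, i1), j],
                   xout = starts[k]:ends[k])$y
        }
      } else {
        unfilled <- c(unfilled,
          sprintf("%s frames %d-%d (%d)", role, starts[k], ends[k],
                  r$lengths[k]))
      }
    }
    markers[[role]] <- p
  }
  if (length(unfilled))
    message("gaps left unfilled: ", paste(unfilled, collapse = "; "))
  SwingRecording(markers, rate = samplingRate(rec),
                 handedness = handedness(rec),
                 verticalAxis = verticalAxis(rec))
}
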