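# Bundled reference cohort: per-swing principal-component vectors and
# published integer SPI scores from a study of 11 professional (two swings
# each) and 5 amateur golfers whose amateur rows were SMOTE-oversampled to
# 22. Serves as the package's validation fixture: refitting the scaling
# stage on the professional rows must reproduce the published scores.

#' Reference cohort of principal-component vectors with published SPIs
#'
#' Forty-four swing rows - 22 professional (11 participants, two swings
#' each) and 22 amateur (5 original swings plus 17 SMOTE oversamples) -
#' expressed as three principal components, together with the published
#' integer SPI of each row. Fitting the log-distance scaling stage on the
#' professional rows (see [fitSpiScaling()]) reproduces every published
#' score within one point.
#'
#' @return `data.frame` with columns `swing`, `subject`, `group`
#'   (`"pro"`/`"amateur"`), `origin` (`"original"`/`"synthetic"`), `pc1`,
#'   `pc2`, `pc3`, and `publishedSpi`.
#' @export
#' @examples
#' ref <- referenceCohort()
#' model <- fitSpiScaling(as.matrix(ref[ref$group == "pro", c("pc1", "pc2", "pc3")]))
#' round(spiScore(as.matrix(ref[, c("pc1", "pc2", "pc3")]), model))
referenceCohort <- function() {
  pro <- matrix(c(
     2.16, -0.47, -0.49,   2.36, -0.65,  0.16,
     0.22, -1.47, -0.80,   0.23, -1.42, -0.54,
     0.98,  1.02,  0.25,   1.27,  0.78,  1.12,
    -1.22, -0.60, -0.68,  -1.24, -0.59, -1.12,
    -1.09, -0.72,  0.44,  -0.64, -1.37,  1.11,
    -0.16,  1.68,  0.13,   0.10,  2.50, -0.30,
    -0.52, -0.02,  2.00,  -0.52, -0.21,  2.09,
     0.82, -0.09, -1.58,  -0.64,  0.07, -0.74,
    -0.56,  0.61,  1.02,  -0.18, -0.17,  0.17,
    -0.96,  0.87, -0.92,  -0.72,  0.94, -1.38,
     0.21, -0.19,  0.05,   0.09, -0.48,  0.00), ncol = 3L, byrow = TRUE)
  proSpi <- c(92, 90, 97, 98, 99, 95, 99, 96, 100, 95, 97, 90,
              93, 93, 96, 106, 101, 126, 98, 95, 126, 118)
  am <- matrix(c(
    -2.61, -0.36, -2.48,  -3.14, -1.66, -4.28,
    -1.20, -2.19, -3.84,  -1.27,  2.13,  4.37,
    -1.10,  2.09,  1.65,  -1.64,  1.23,  0.20,
    -2.18,  0.35, -1.29,  -1.90, -2.00, -4.00,
    -2.49, -0.52, -2.60,  -1.63, -1.63, -3.42,
    -2.20, -0.89, -2.88,  -1.70,  1.13,  0.02,
    -2.72, -0.61, -2.83,  -2.76, -0.71, -2.98,
    -1.13,  2.10,  2.01,  -2.71, -0.59, -2.81,
    -1.28, -2.08, -3.76,  -2.72, -0.62, -2.84,
    -1.54, -1.75, -3.51,  -2.68, -0.51, -2.69,
    -1.91, -1.27, -3.16,  -2.85, -0.95, -3.30), ncol = 3L, byrow = TRUE)
  amSpi <- c(84, 77, 80, 78, 88, 93, 90, 79, 84, 82, 83,
             94, 82, 82, 86, 82, 80, 82, 81, 83, 83, 80)
  proSubj <- rep(sprintf("pro%02d", 1:11), each = 2L)
  df <- data.frame(
    swing = c(paste0(proSubj, c("a", "b")), sprintf("am_sw%02d", 1:22)),
    subject = c(proSubj,
                c(sprintf("am%02d", 1:5), rep("synthetic", 17L))),
    group = rep(c("pro", "amateur"), each = 22L),
    origin = c(rep("original", 22L),
               rep(c("original", "synthetic"), c(5L, 17L))),
    stringsAsFactors = FALSE)
  pcs <- rbind(pro, am)
  df$pc1 <- pcs[, 1L]; df$pc2 <- pcs[, 2L]; df$pc3 <- pcs[, 3L]
  df$publishedSpi <- c(proSpi, amSpi)
  df
}
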