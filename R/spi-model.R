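# Construction and application of the Swing Performance Index for a fixed
# metric subset: pro-referenced normalization, KMO factorability, SMOTE class
# balancing, pro-fitted PCA, and log-Euclidean-distance scoring anchored at
# pro mean 100, population SD 10.

#' Professional-cohort normalization statistics
#'
#' Column means and population standard deviations of the professional rows;
#' metrics are z-scored against the professional distribution, never the
#' pooled one, so amateur deviations show up as non-zero z-scores.
#'
#' @param proMatrix Numeric matrix of professional metric rows.
#' @return List with named vectors `mean` and `sd`.
#' @export
proStats <- function(proMatrix) {
  m <- as.matrix(proMatrix)
  if (nrow(m) < 2L) stop("need at least 2 professional rows")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, popSd)
  bad <- which(sdv <= 0)
  if (length(bad))
    stop("zero professional variance in metric(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  list(mean = mu, sd = sdv)
}

#' Normalize metrics by professional statistics
#'
#' @param x Numeric matrix (rows x metrics).
#' @param stats Result of [proStats()] (or the corresponding slots of a
#'   fitted [SPIModel-class]).
#' @return Matrix of z-scores `(x - mean) / sd` per column.
#' @export
normalizeMetrics <- function(x, stats) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, stats$mean), 2L, stats$sd, "/")
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' From the correlation matrix `R` and the anti-image partial correlations
#' `A` derived from its inverse (`a_ij = -Rinv_ij / sqrt(Rinv_ii Rinv_jj)`),
#' the per-variable measure is
#' `KMO_j = sum_{i != j} r_ij^2 / (sum r_ij^2 + sum a_ij^2)` and the overall
#' measure is the analogous ratio over all pairs. Values lie in [0, 1];
#' sets below 0.6 are conventionally considered unsuitable for factor
#' analysis. The measure is exactly scale-invariant (correlation-based).
#'
#' @param data Numeric matrix or data.frame (rows x variables), >= 2
#'   variables, no constant column. A singular correlation matrix is handled
#'   with the Moore-Penrose pseudo-inverse (with a warning), as is having
#'   fewer rows than variables.
#' @return List with `overall` (scalar) and `perVariable` (named vector).
#' @export
kmo <- function(data) {
  x <- as.matrix(data)
  if (ncol(x) < 2L) stop("KMO needs at least 2 variables")
  if (any(apply(x, 2L, function(col) popSd(col) == 0)))
    stop("constant column: KMO undefined")
  if (nrow(x) < ncol(x))
    warning("fewer rows than variables; correlation matrix is singular")
  R <- cor(x)
  Rinv <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; using pseudo-inverse")
    MASS::ginv(R)
  })
  d <- sqrt(diag(Rinv))
  A <- -Rinv / tcrossprod(d)
  diag(A) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; a2 <- A^2
  perVar <- rowSums(r2) / (rowSums(r2) + rowSums(a2))
  names(perVar) <- colnames(x)
  list(overall = sum(r2) / (sum(r2) + sum(a2)), perVariable = perVar)
}

## Core SMOTE step: create nNew synthetic rows from the original minority
## rows. Each draw picks a random original row, takes its single nearest
## neighbor among the other original rows (Euclidean; ties -> first), and
## places a point uniformly on the connecting segment.
smoteRows <- function(x, nNew) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("SMOTE needs at least 2 minority rows")
  D <- as.matrix(dist(x))
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min)
  out <- matrix(NA_real_, nNew, ncol(x), dimnames = list(NULL, colnames(x)))
  for (i in seq_len(nNew)) {
    j <- sample.int(n, 1L)
    u <- runif(1L)
    out[i, ] <- x[j, ] + u * (x[nn[j], ] - x[j, ])
  }
  out
}

#' Balance group sizes by SMOTE
#'
#' Oversamples the minority group until both groups are equally large:
#' repeatedly, a random original minority row and its single nearest
#' neighbor (Euclidean, among the original minority rows) are chosen and a
#' uniformly random point on the segment between them is added. Synthetic
#' rows are flagged in the returned `origin` vector. Deterministic given
#' `seed`.
#'
#' @param x Numeric feature matrix (rows x features).
#' @param group Factor/character vector of two group labels, one per row.
#' @param seed Integer RNG seed (required for reproducibility).
#' @return List with the augmented `x`, `group`, and `origin`
#'   (`"original"`/`"synthetic"`).
#' @export
smoteBalance <- function(x, group, seed) {
  x <- as.matrix(x)
  group <- as.character(group)
  stopifnot(nrow(x) == length(group))
  counts <- table(group)
  if (length(counts) != 2L) stop("need exactly 2 groups")
  if (counts[1L] == counts[2L])
    return(list(x = x, group = group,
                origin = rep("original", nrow(x))))
  minority <- names(counts)[which.min(counts)]
  nNew <- abs(diff(as.integer(counts)))
  if (min(counts) < 2L) stop("minority group of 1: SMOTE undefined")
  synth <- withSeed(seed, smoteRows(x[group == minority, , drop = FALSE],
                                    nNew))
  list(x = rbind(x, synth),
       group = c(group, rep(minority, nNew)),
       origin = c(rep("original", nrow(x)), rep("synthetic", nNew)))
}

#' Fit a PCA on professional z-scores
#'
#' Eigen-decomposition of the population covariance of the professional
#' z-score rows; all k components are retained, ordered by decreasing
#' eigenvalue, with each component's sign fixed so its largest-|loading|
#' entry is positive (making stored models reproducible across linear
#' algebra backends; distances, hence scores, are sign-invariant anyway).
#'
#' @param z Professional z-score matrix (rows x k), >= 2 rows.
#' @return List with `components` (orthonormal k x k, columns = components),
#'   `center` (column means of `z`), `eigenvalues`, and `rankDeficient`
#'   (logical flag for zero eigenvalues).
#' @export
fitProPca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 professional rows for PCA")
  center <- colMeans(z)
  zc <- sweep(z, 2L, center)
  C <- crossprod(zc) / nrow(z)
  e <- eigen(C, symmetric = TRUE)
  W <- e$vectors
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  rankDeficient <- any(e$values < 1e-12 * max(e$values, .Machine$double.eps))
  if (rankDeficient)
    warning("rank-deficient professional covariance: zero eigenvalue(s)")
  list(components = W, center = center, eigenvalues = e$values,
       rankDeficient = rankDeficient)
}

buildSpiModel <- function(subset, stats, pca, proPcs, epsilon, logBase,
                          seed, provenance = list()) {
  center <- unname(colMeans(proPcs))
  d <- rowNorms(sweep(proPcs, 2L, center))
  l <- log(pmax(d, epsilon), base = logBase)
  sdl <- popSd(l)
  if (sdl <= 0) stop("zero spread of professional log distances; cannot scale")
  new("SPIModel", subset = subset, proMean = stats$mean, proSd = stats$sd,
      pcaCenter = unname(pca$center), pcaComponents = unname(pca$components),
      proPcCenter = center, logDistMean = mean(l), logDistSd = sdl,
      epsilon = epsilon, logBase = logBase,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      provenance = provenance)
}

#' Fit the scaling stage on principal-component vectors
#'
#' Builds an [SPIModel-class] directly from professional principal-component
#' vectors, with identity normalization and PCA stages: the logarithm of the
#' Euclidean distance to the professional centroid is standardized by the
#' professional population mean/SD and mapped through `100 - 10 * z`. Used
#' to score data already expressed as principal components (e.g. the bundled
#' reference cohort).
#'
#' @param proPcs Matrix of professional PC vectors (rows x k).
#' @param epsilon Distance floor, default 1e-6.
#' @param logBase Logarithm base, default natural; scores are invariant to
#'   the choice.
#' @return An [SPIModel-class] whose [spiScore()] consumes raw PC vectors.
#' @export
fitSpiScaling <- function(proPcs, epsilon = 1e-6, logBase = exp(1)) {
  proPcs <- as.matrix(proPcs)
  k <- ncol(proPcs)
  nm <- colnames(proPcs)
  if (is.null(nm)) nm <- paste0("pc", seq_len(k))
  stats <- list(mean = stats::setNames(rep(0, k), nm),
                sd = stats::setNames(rep(1, k), nm))
  pca <- list(components = diag(k), center = rep(0, k))
  buildSpiModel(nm, stats, pca, proPcs, epsilon, logBase, seed = NULL,
                provenance = list(kind = "scaling-only"))
}

#' Score principal-component vectors
#'
#' `SPI = 100 - 10 * (log(max(d, epsilon)) - mu) / sigma` with `d` the
#' Euclidean distance to the professional PC centroid. The slope is
#' negative: swings farther from the average professional swing score lower.
#'
#' @param pcs Numeric vector (one swing) or matrix (rows = swings) of
#'   principal components.
#' @param model A fitted [SPIModel-class].
#' @return Numeric SPI scores.
#' @export
spiScore <- function(pcs, model) {
  stopifnot(is(model, "SPIModel"))
  if (is.null(dim(pcs))) pcs <- matrix(pcs, nrow = 1L)
  d <- rowNorms(sweep(as.matrix(pcs), 2L, model@proPcCenter))
  l <- log(pmax(d, model@epsilon), base = model@logBase)
  100 - 10 * (l - model@logDistMean) / model@logDistSd
}

#' Score new swings from their metrics
#'
#' Applies the full scoring path of a fitted model: professional z-scoring,
#' PCA transform, log-distance scaling.
#'
#' @param model A fitted [SPIModel-class].
#' @param metrics `data.frame` or matrix containing the model's metric
#'   columns.
#' @return Numeric SPI scores, one per row.
#' @export
predictSpi <- function(model, metrics) {
  stopifnot(is(model, "SPIModel"))
  x <- as.matrix(as.data.frame(metrics)[, model@subset, drop = FALSE])
  z <- normalizeMetrics(x, list(mean = model@proMean, sd = model@proSd))
  pcs <- sweep(z, 2L, model@pcaCenter) %*% model@pcaComponents
  spiScore(pcs, model)
}

#' Fit the Swing Performance Index for a metric subset
#'
#' The full pipeline, in order: (1) z-score the subset metrics against the
#' professional rows (population SD); (2) SMOTE-balance the amateur group in
#' the normalized subset space; (3) fit a PCA on the professional rows;
#' (4) transform all rows - original and synthetic - to principal
#' components; (5) take the logarithm of each row's Euclidean distance to
#' the professional PC centroid; (6) standardize by the professional
#' population mean/SD of those logs; (7) map through `100 - 10 * z`. By
#' construction the professional scores have mean exactly 100 and population
#' SD exactly 10.
#'
#' @param ds `data.frame` with identifier columns `swing`, `subject`,
#'   `group` (`"pro"`/`"amateur"`), optional `origin`, and the metric
#'   columns.
#' @param subset Character vector of 1-3 metric names (see
#'   [metricNames()]).
#' @param seed Integer RNG seed for the SMOTE stage (required).
#' @param epsilon Distance floor, default 1e-6.
#' @param logBase Logarithm base, default natural.
#' @return List with `model` (an [SPIModel-class]) and `scored` (the input
#'   rows plus synthetic rows, with principal-component columns and an
#'   `spi` column).
#' @export
fitSpiModel <- function(ds, subset, seed, epsilon = 1e-6,
                        logBase = exp(1)) {
  ds <- as.data.frame(ds)
  if (length(subset) < 1L || length(subset) > 3L)
    stop("subset must contain 1-3 metrics")
  if (!all(subset %in% colnames(ds)))
    stop("missing metric column(s): ",
         paste(setdiff(subset, colnames(ds)), collapse = ", "))
  if (!all(c("group") %in% colnames(ds))) stop("dataset lacks 'group' column")
  if (is.null(ds$origin)) ds$origin <- "original"
  proMask <- ds$group == "pro"
  if (sum(proMask) < 2L) stop("need at least 2 professional rows")
  x <- as.matrix(ds[, subset, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite metric values")

  stats <- proStats(x[proMask, , drop = FALSE])
  z <- normalizeMetrics(x, stats)

  bal <- smoteBalance(z, ds$group, seed = seed)
  nNew <- sum(bal$origin == "synthetic")
  scored <- ds[, c("swing", "subject", "group", "origin"), drop = FALSE]
  if (nNew > 0L) {
    synthMetrics <- sweep(sweep(bal$x[bal$origin == "synthetic", ,
                                      drop = FALSE],
                                2L, stats$sd, "*"), 2L, stats$mean, "+")
    extra <- data.frame(swing = paste0("synth", seq_len(nNew)),
                        subject = "synthetic",
                        group = bal$group[bal$origin == "synthetic"],
                        origin = "synthetic", stringsAsFactors = FALSE)
    scored <- rbind(scored, extra)
    x <- rbind(x, synthMetrics)
  }
  scored[, subset] <- x

  proZ <- z[proMask, , drop = FALSE]
  pca <- fitProPca(proZ)
  pcs <- sweep(bal$x, 2L, pca$center) %*% pca$components
  colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))

  model <- buildSpiModel(subset, stats, pca,
                         pcs[bal$group == "pro" &
                             bal$origin == "original", , drop = FALSE],
                         epsilon, logBase, seed,
                         provenance = list(kind = "metric-pipeline",
                                           nOriginal = nrow(ds),
                                           nSynthetic = nNew))
  scored[, colnames(pcs)] <- pcs
  scored$spi <- spiScore(pcs, model)
  list(model = model, scored = scored)
}

modelSchemaVersion <- "golfSPI-model/1"

modelFields <- c("schema", "subset", "proMean", "proSd", "pcaCenter",
                 "pcaComponents", "proPcCenter", "logDistMean", "logDistSd",
                 "epsilon", "logBase", "seed", "provenance")

#' Save / load a fitted SPI model
#'
#' Lossless structured-text (JSON) serialization of every model field,
#' schema-versioned; loading a file with a different schema version or an
#' unexpected field set is an explicit error, and a load/score cycle
#' reproduces pre-save scores bit-identically.
#'
#' @param model A fitted [SPIModel-class].
#' @param path File path.
#' @return `saveSpiModel`: `path`, invisibly. `loadSpiModel`: the restored
#'   [SPIModel-class].
#' @export
saveSpiModel <- function(model, path) {
  stopifnot(is(model, "SPIModel"))
  obj <- list(schema = modelSchemaVersion,
              subset = model@subset,
              proMean = as.list(model@proMean),
              proSd = as.list(model@proSd),
              pcaCenter = model@pcaCenter,
              pcaComponents = apply(model@pcaComponents, 1L, identity,
                                    simplify = FALSE),
              proPcCenter = model@proPcCenter,
              logDistMean = model@logDistMean,
              logDistSd = model@logDistSd,
              epsilon = model@epsilon,
              logBase = model@logBase,
              seed = model@seed,
              provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname saveSpiModel
#' @export
loadSpiModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || !identical(obj$schema, modelSchemaVersion))
    stop("model schema version mismatch: expected '", modelSchemaVersion,
         "', found '", if (is.null(obj$schema)) "<none>" else obj$schema, "'")
  if (!setequal(names(obj), modelFields))
    stop("model file schema error: unexpected fields ",
         paste(setdiff(names(obj), modelFields), collapse = ", "),
         if (length(setdiff(modelFields, names(obj))))
           paste0("; missing fields ",
                  paste(setdiff(modelFields, names(obj)), collapse = ", "))
         else "")
  subset <- as.character(unlist(obj$subset))
  k <- length(subset)
  W <- matrix(as.numeric(unlist(obj$pcaComponents)), k, k, byrow = TRUE)
  num <- function(x) as.numeric(unlist(x))
  new("SPIModel", subset = subset,
      proMean = stats::setNames(num(obj$proMean), names(obj$proMean)),
      proSd = stats::setNames(num(obj$proSd), names(obj$proSd)),
      pcaCenter = num(obj$pcaCenter), pcaComponents = W,
      proPcCenter = num(obj$proPcCenter),
      logDistMean = num(obj$logDistMean), logDistSd = num(obj$logDistSd),
      epsilon = num(obj$epsilon), logBase = num(obj$logBase),
      seed = {
        sv <- suppressWarnings(num(obj$seed))
        if (length(sv) != 1L || is.na(sv)) NA_integer_ else as.integer(sv)
      },
      provenance = lapply(obj$provenance, function(v)
        if (is.list(v)) unlist(v) else v))
}
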