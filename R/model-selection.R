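# Exhaustive metric-subset search: KMO screening, SPI fitting, and
# leave-one-out cross-validated logistic-regression AUC.

#' Enumerate candidate metric subsets
#'
#' All subsets of size 1 to `maxSize` in canonical order: by size, then by
#' the order of `names`. For the nine candidate metrics with `maxSize = 3`
#' this yields 9 + 36 + 84 = 129 subsets.
#'
#' @param names Character vector of metric names (canonical order).
#' @param maxSize Largest subset size, default 3.
#' @return List of character vectors.
#' @export
enumerateSubsets <- function(names = metricNames(), maxSize = 3L) {
  stopifnot(maxSize >= 1L)
  out <- list()
  for (k in seq_len(min(maxSize, length(names)))) {
    out <- c(out, combn(names, k, simplify = FALSE))
  }
  out
}

## Mann-Whitney AUC of predictions p against binary labels y (1 = positive);
## ties counted one half, computed via average ranks.
aucMW <- function(p, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Single-feature logistic fit returning held-out probabilities for xout.
## With complete separation IRLS still returns finite coefficients monotone
## in the score, which preserves the held-out ranking (all the AUC uses).
logisticPredict <- function(xtrain, ytrain, xout) {
  if (length(unique(ytrain)) < 2L) return(rep(mean(ytrain), length(xout)))
  fit <- suppressWarnings(
    glm.fit(cbind(1, xtrain), ytrain, family = binomial()))
  b <- fit$coefficients
  as.numeric(plogis(b[1L] + b[2L] * xout))
}

#' Leave-one-out cross-validated logistic-regression AUC
#'
#' For each fold (one row by default, or one level of `folds`), a
#' single-feature logistic regression (intercept + slope, maximum
#' likelihood) is fitted on the remaining rows and the held-out predicted
#' probability recorded; the AUC is the Mann-Whitney statistic of the pooled
#' held-out probabilities, with ties counted one half. A fold missing one
#' class predicts the training prior. Deterministic.
#'
#' @param scores Numeric score per row (e.g. SPI).
#' @param labels Group label per row; `positive` names the positive class.
#' @param folds Optional fold identifier per row (e.g. subject) for
#'   leave-one-subject-out; default one fold per row.
#' @param positive Positive-class label, default `"pro"`.
#' @return AUC in [0, 1].
#' @export
loocvLogisticAuc <- function(scores, labels, folds = NULL,
                             positive = "pro") {
  labels <- as.character(labels)
  n <- length(scores)
  stopifnot(n == length(labels), n >= 3L)
  y <- as.integer(labels == positive)
  if (all(y == 1L) || all(y == 0L)) stop("both classes must be present")
  if (is.null(folds)) folds <- seq_len(n)
  p <- numeric(n)
  for (f in unique(folds)) {
    hold <- folds == f
    p[hold] <- logisticPredict(scores[!hold], y[!hold], scores[hold])
  }
  aucMW(p, y)
}

#' Select the best metric subset
#'
#' For every subset of up to `maxSize` metrics: the overall KMO is computed
#' (on the original rows by default); subsets whose overall KMO falls below
#' `kmoThreshold` are screened out (the threshold is inclusive - 0.60 is
#' retained - and applies to the overall measure only). Single-metric
#' subsets bypass the screen, since sampling adequacy is defined only for
#' sets of two or more variables. Each surviving subset gets an SPI model
#' (fitted with the shared `seed`) and a LOOCV logistic-regression AUC over
#' all scored rows, originals and oversamples. Subsets are ranked by AUC
#' descending, ties broken by smaller size then canonical order.
#'
#' @param ds Labeled metric dataset as for [fitSpiModel()].
#' @param seed Integer RNG seed shared by every subset's SMOTE stage.
#' @param kmoThreshold Overall-KMO screening threshold, default 0.6
#'   (inclusive).
#' @param maxSize Largest subset size, default 3.
#' @param kmoPopulation Rows entering the KMO: `"original"` (both groups,
#'   pre-SMOTE; default), `"balanced"` (after oversampling, computed in the
#'   normalized subset space), or `"pro_only"`.
#' @param nested If `TRUE`, the SPI model is refitted inside each LOOCV fold
#'   (stricter; slower). Default `FALSE`: the model is fitted once on the
#'   full dataset and only the classifier is cross-validated.
#' @param groupBy Optional column name (e.g. `"subject"`) defining LOOCV
#'   folds; default one fold per swing row.
#' @return List with `ranking` (a `data.frame` of subset, size, overall
#'   KMO, AUC, rank) and `best` (the winning subset's
#'   [fitSpiModel()] result).
#' @export
selectBest <- function(ds, seed, kmoThreshold = 0.6, maxSize = 3L,
                       kmoPopulation = c("original", "balanced", "pro_only"),
                       nested = FALSE, groupBy = NULL) {
  ds <- as.data.frame(ds)
  kmoPopulation <- match.arg(kmoPopulation)
  if (is.null(ds$origin)) ds$origin <- "original"
  mets <- intersect(metricNames(), colnames(ds))
  if (!length(mets)) stop("dataset contains no recognized metric columns")
  subsets <- enumerateSubsets(mets, maxSize)
  m <- length(subsets)
  kmoVal <- rep(NA_real_, m)
  auc <- rep(NA_real_, m)
  screened <- logical(m)
  fits <- vector("list", m)
  orig <- ds[ds$origin == "original", , drop = FALSE]
  for (i in seq_len(m)) {
    sub <- subsets[[i]]
    if (length(sub) >= 2L) {
      kmoRows <- switch(kmoPopulation,
        original = as.matrix(orig[, sub, drop = FALSE]),
        pro_only = as.matrix(orig[orig$group == "pro", sub, drop = FALSE]),
        balanced = {
          st <- proStats(as.matrix(orig[orig$group == "pro", sub,
                                        drop = FALSE]))
          z <- normalizeMetrics(as.matrix(orig[, sub, drop = FALSE]), st)
          smoteBalance(z, orig$group, seed = seed)$x
        })
      kmoVal[i] <- kmo(kmoRows)$overall
      if (kmoVal[i] < kmoThreshold) { screened[i] <- TRUE; next }
    }
    fit <- fitSpiModel(ds, sub, seed = seed)
    folds <- if (is.null(groupBy)) NULL else fit$scored[[groupBy]]
    auc[i] <- if (nested) {
      nestedLoocvAuc(ds, sub, seed = seed, groupBy = groupBy)
    } else {
      loocvLogisticAuc(fit$scored$spi, fit$scored$group, folds = folds)
    }
    fits[[i]] <- fit
  }
  if (all(screened | is.na(auc)))
    stop("nothing factorable: every subset screened out by KMO < ",
         kmoThreshold)
  ranking <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets), kmo_overall = kmoVal, auc = auc,
    screened = screened, stringsAsFactors = FALSE)
  ord <- order(-ranking$auc, ranking$size, seq_len(m), na.last = TRUE)
  ranking$rank <- NA_integer_
  ranking$rank[ord[!is.na(ranking$auc[ord])]] <-
    seq_len(sum(!is.na(ranking$auc)))
  best <- which(ranking$rank == 1L)
  list(ranking = ranking[order(ranking$rank, na.last = TRUE), ,
                         drop = FALSE],
       best = fits[[best]])
}

#' Nested LOOCV AUC for one subset
#'
#' Sensitivity variant in which the whole SPI pipeline (normalization,
#' SMOTE, PCA, scaling) is refitted with the held-out fold removed, the
#' held-out rows are scored by the fold's model, and the logistic classifier
#' is trained on the fold's training scores.
#'
#' @inheritParams fitSpiModel
#' @param groupBy Optional fold column name as in [selectBest()].
#' @return AUC in [0, 1].
#' @export
nestedLoocvAuc <- function(ds, subset, seed, groupBy = NULL) {
  ds <- as.data.frame(ds)
  if (is.null(ds$origin)) ds$origin <- "original"
  full <- fitSpiModel(ds, subset, seed = seed)$scored
  n <- nrow(full)
  folds <- if (is.null(groupBy)) seq_len(n) else full[[groupBy]]
  y <- as.integer(full$group == "pro")
  p <- numeric(n)
  for (f in unique(folds)) {
    hold <- folds == f
    train <- full[!hold & full$origin == "original", , drop = FALSE]
    refit <- fitSpiModel(train, subset, seed = seed)
    sHold <- predictSpi(refit$model, full[hold, , drop = FALSE])
    p[hold] <- logisticPredict(refit$scored$spi,
                               as.integer(refit$scored$group == "pro"),
                               sHold)
  }
  aucMW(p, y)
}
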