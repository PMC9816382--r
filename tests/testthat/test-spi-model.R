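proPcMatrix <- function(ref = referenceCohort()) {
  as.matrix(ref[ref$group == "pro", refPcCols])
}

test_that("professional z-scoring gives mean 0, population SD 1", {
  set.seed(31)
  pro <- matrix(rnorm(40, 300, 60), 20L, 2L,
                dimnames = list(NULL, c("a", "b")))
  st <- proStats(pro)
  z <- normalizeMetrics(pro, st)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2L, function(x) sqrt(mean(x^2))), c(a = 1, b = 1))

  # an amateur at the pro mean lands at the origin
  expect_equal(as.numeric(normalizeMetrics(rbind(st$mean), st)), c(0, 0))

  # direct-formula oracle on random data
  x <- matrix(rnorm(30, 5, 2), 15L, 2L, dimnames = list(NULL, c("a", "b")))
  expect_equal(normalizeMetrics(x, st),
               sweep(sweep(x, 2L, st$mean), 2L, st$sd, "/"))

  # zero pro variance names the metric
  pro[, 2L] <- 7
  expect_error(proStats(pro), "b")
})

test_that("KMO matches a brute-force anti-image computation", {
  bruteKmo <- function(x) {
    R <- cor(x); Ri <- solve(R); p <- ncol(x)
    A <- matrix(0, p, p)
    for (i in 1:p) for (j in 1:p)
      A[i, j] <- -Ri[i, j] / sqrt(Ri[i, i] * Ri[j, j])
    r2 <- 0; a2 <- 0; per <- numeric(p)
    for (j in 1:p) {
      rj <- 0; aj <- 0
      for (i in 1:p) if (i != j) {
        rj <- rj + R[i, j]^2; aj <- aj + A[i, j]^2
      }
      per[j] <- rj / (rj + aj); r2 <- r2 + rj; a2 <- a2 + aj
    }
    list(overall = r2 / (r2 + a2), per = per)
  }
  set.seed(42)
  for (p in 3:5) {
    x <- matrix(rnorm(40 * p), 40L) %*% matrix(runif(p * p, -1, 1), p)
    got <- kmo(x); want <- bruteKmo(x)
    expect_equal(got$overall, want$overall, tolerance = 1e-10)
    expect_equal(unname(got$perVariable), want$per, tolerance = 1e-10)
    # exactly scale-invariant
    scaled <- sweep(sweep(x, 2L, colMeans(x)), 2L, apply(x, 2L, sd), "/")
    expect_equal(kmo(scaled * 7 + 3)$overall, got$overall)
  }
  # two variables: anti-image partial equals the raw correlation -> 0.5
  set.seed(5)
  x2 <- matrix(rnorm(60), 30L); x2[, 2L] <- x2[, 2L] + 0.8 * x2[, 1L]
  expect_equal(kmo(x2)$overall, 0.5)
  # population-independent variables: partials ~ raw correlations, so the
  # ratio converges to one half - below the 0.6 adequacy screen
  set.seed(7)
  xi <- matrix(rnorm(5000 * 4), 5000L)
  expect_lt(abs(kmo(xi)$overall - 0.5), 0.05)
  expect_lt(kmo(xi)$overall, 0.6)
  expect_error(kmo(cbind(rnorm(10), rep(1, 10))), "constant")
})

test_that("SMOTE equalizes groups with synthetics on nearest-neighbor segments", {
  set.seed(13)
  x <- rbind(matrix(rnorm(40, 0), 20L), matrix(rnorm(10, 4), 5L))
  group <- rep(c("pro", "amateur"), c(20L, 5L))
  bal <- smoteBalance(x, group, seed = 77)
  expect_equal(unname(table(bal$group)["pro"]),
               unname(table(bal$group)["amateur"]))
  expect_equal(sum(bal$origin == "synthetic"), 15L)
  # determinism
  expect_identical(smoteBalance(x, group, seed = 77), bal)
  expect_false(identical(smoteBalance(x, group, seed = 78)$x, bal$x))

  # membership: every synthetic row lies on the segment between some
  # original minority row and that row's nearest neighbor
  minority <- x[group == "amateur", , drop = FALSE]
  D <- as.matrix(dist(minority)); diag(D) <- Inf
  nn <- apply(D, 1L, which.min)
  onSegment <- function(s) {
    any(vapply(seq_len(nrow(minority)), function(j) {
      p <- minority[j, ]; q <- minority[nn[j], ]
      dir <- q - p
      u <- sum((s - p) * dir) / sum(dir * dir)
      u >= -1e-9 && u <= 1 + 1e-9 &&
        sqrt(sum((s - (p + u * dir))^2)) < 1e-9
    }, logical(1)))
  }
  synth <- bal$x[bal$origin == "synthetic", , drop = FALSE]
  expect_true(all(apply(synth, 1L, onSegment)))

  # segment property in the 2-point example
  two <- smoteBalance(rbind(c(0, 0), c(1, 0), matrix(rnorm(6), 3L)),
                      rep(c("amateur", "pro"), c(2L, 3L)), seed = 3)
  s <- two$x[two$origin == "synthetic", , drop = FALSE]
  expect_equal(unname(s[, 2L]), 0)
  expect_true(all(s[, 1L] >= 0 & s[, 1L] <= 1))

  # identity when groups are equal; error on a singleton minority
  eq <- smoteBalance(x[1:10, ], rep(c("pro", "amateur"), each = 5L),
                     seed = 1)
  expect_identical(eq$x, x[1:10, ])
  expect_error(smoteBalance(x[1:6, ], rep(c("pro", "amateur"), c(5L, 1L)),
                            seed = 1), "minority")
})

test_that("professional PCA is orthonormal, ordered, and reconstructive", {
  # data stretched along x -> first component (1, 0)
  set.seed(17)
  z <- cbind(rnorm(30, 0, 5), rnorm(30, 0, 0.5))
  z <- sweep(z, 2L, colMeans(z))
  pca <- fitProPca(z)
  expect_equal(abs(pca$components[, 1L]), c(1, 0), tolerance = 0.05)
  expect_true(all(diff(pca$eigenvalues) <= 0))

  # transformed pros have diagonal covariance; full-rank reconstruction
  z3 <- matrix(rnorm(60), 20L) %*% matrix(runif(9, -1, 1), 3L)
  p3 <- fitProPca(z3)
  pcs <- sweep(z3, 2L, p3$center) %*% p3$components
  cv <- crossprod(pcs) / nrow(pcs)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_equal(pcs %*% t(p3$components),
               sweep(z3, 2L, p3$center), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(p3$components) - diag(3))), 1e-10)
  # sign convention: largest-|loading| entry positive
  for (j in 1:3)
    expect_gt(p3$components[which.max(abs(p3$components[, j])), j], 0)
})

test_that("PC scoring reproduces published reference scores", {
  ref <- referenceCohort()
  model <- fitSpiScaling(proPcMatrix(ref))
  expect_equal(round(spiScore(c(2.16, -0.47, -0.49), model)), 92)
  expect_equal(round(spiScore(c(-0.18, -0.17, 0.17), model)), 126)
  # centroid swing: distance floored at epsilon -> maximal finite score
  atCenter <- spiScore(model@proPcCenter, model)
  expect_true(is.finite(atCenter))
  expect_gt(atCenter, max(spiScore(as.matrix(ref[, refPcCols]), model)))
})

test_that("fitted models anchor professionals at exactly 100 +/- 10", {
  ds <- makeLabeledDataset()
  fit <- fitSpiModel(ds, c("pelvis.peak_pre_impact", "pelvis.at_impact",
                           "torso.peak_post_impact"), seed = 17)
  pro <- fit$scored$spi[fit$scored$group == "pro"]
  expect_equal(mean(pro), 100, tolerance = 1e-9)
  expect_equal(sqrt(mean((pro - mean(pro))^2)), 10, tolerance = 1e-9)
  # oversampling balanced the groups
  expect_equal(sum(fit$scored$group == "amateur"),
               sum(fit$scored$group == "pro"))
  # predictSpi reproduces the training scores
  expect_equal(predictSpi(fit$model, ds), fit$scored$spi[1:nrow(ds)],
               tolerance = 1e-9)
})

test_that("the model is invariant to duplicated professional rows", {
  ds <- makeLabeledDataset()
  f1 <- fitSpiModel(ds, c("pelvis.peak_pre_impact", "torso.at_impact"),
                    seed = 5)
  dup <- rbind(ds, ds[ds$group == "pro", ])
  f2 <- fitSpiModel(dup, c("pelvis.peak_pre_impact", "torso.at_impact"),
                    seed = 5)
  for (slot in c("proMean", "proSd", "pcaComponents", "proPcCenter",
                 "logDistMean", "logDistSd"))
    expect_equal(methods::slot(f1$model, slot),
                 methods::slot(f2$model, slot), tolerance = 1e-9)
})

test_that("scores are invariant to log base and PC-space rotation", {
  ds <- makeLabeledDataset(seed = 3)
  sub <- c("pelvis.peak_pre_impact", "pelvis.at_impact",
           "torso.peak_post_impact")
  fe <- fitSpiModel(ds, sub, seed = 9)
  f10 <- fitSpiModel(ds, sub, seed = 9, logBase = 10)
  expect_equal(fe$scored$spi, f10$scored$spi, tolerance = 1e-9)

  # joint orthogonal rotation of all PC vectors preserves distances
  ref <- referenceCohort()
  pro <- proPcMatrix(ref)
  all <- as.matrix(ref[, refPcCols])
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  base <- spiScore(all, fitSpiScaling(pro))
  rotated <- spiScore(all %*% Q, fitSpiScaling(pro %*% Q))
  expect_equal(rotated, base, tolerance = 1e-9)

  # strictly decreasing in distance beyond the floor
  m <- fitSpiScaling(pro)
  d <- c(0.01, 0.1, 1, 2, 5)
  s <- vapply(d, function(dd)
    spiScore(m@proPcCenter + c(dd, 0, 0), m), numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("models survive a save/load round trip bit-faithfully", {
  ds <- makeLabeledDataset(seed = 6)
  fit <- fitSpiModel(ds, c("pelvis.peak_pre_impact", "xprime.at_impact"),
                     seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  saveSpiModel(fit$model, path)
  back <- loadSpiModel(path)
  for (slot in c("subset", "proMean", "proSd", "pcaCenter", "pcaComponents",
                 "proPcCenter", "logDistMean", "logDistSd", "epsilon",
                 "logBase", "seed"))
    expect_equal(methods::slot(back, slot), methods::slot(fit$model, slot),
                 tolerance = 1e-12)
  # load-then-score reproduces pre-save scores bit-identically
  expect_identical(predictSpi(back, ds), predictSpi(fit$model, ds))

  # tampered field -> schema error; wrong version -> explicit error
  obj <- jsonlite::read_json(path)
  names(obj)[names(obj) == "logDistMean"] <- "logarithmMean"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(loadSpiModel(path), "schema")
  obj2 <- jsonlite::read_json(path)
  names(obj2)[names(obj2) == "logarithmMean"] <- "logDistMean"
  obj2$schema <- "golfSPI-model/99"
  jsonlite::write_json(obj2, path, auto_unbox = TRUE, digits = NA)
  expect_error(loadSpiModel(path), "version")
})
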