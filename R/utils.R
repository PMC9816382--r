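# Internal numerical helpers shared across modules.

#' @importFrom stats approx cor rnorm runif sd var plogis binomial glm.fit
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

## Population (divide-by-n) standard deviation. The SPI scaling stage uses the
## population convention throughout; the sample variant shifts scores by ~1 SPI
## point and no longer matches the published worked example.
popSd <- function(x) sqrt(mean((x - mean(x))^2))

## Unwrap a degree series so no between-frame jump exceeds 180 deg.
unwrapDeg <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- ((d + 180) %% 360) - 180
  theta[1L] + cumsum(c(0, d))
}

## Central finite difference with one-sided endpoints, in units/second.
centralDiff <- function(x, rate) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 frames for differentiation")
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * rate / 2
  v[1L] <- (x[2L] - x[1L]) * rate
  v[n] <- (x[n] - x[n - 1L]) * rate
  v
}

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## Horizontal-plane component columns for a given vertical axis token, ordered
## so that atan2(v[, cc], v[, bb]) increases counter-clockwise when viewed from
## the up direction (right-handed frames).
horizontalAxes <- function(verticalAxis) {
  ax <- match.arg(verticalAxis, c("x+", "x-", "y+", "y-", "z+", "z-"))
  switch(ax,
    "x+" = c(2L, 3L), "x-" = c(3L, 2L),
    "y+" = c(3L, 1L), "y-" = c(1L, 3L),
    "z+" = c(1L, 2L), "z-" = c(2L, 1L))
}

## Index (1..3) and sign of the vertical coordinate.
verticalComponent <- function(verticalAxis) {
  ax <- match.arg(verticalAxis, c("x+", "x-", "y+", "y-", "z+", "z-"))
  list(index = match(substr(ax, 1L, 1L), c("x", "y", "z")),
       sign = if (substr(ax, 2L, 2L) == "+") 1 else -1)
}

rowNorms <- function(m) sqrt(rowSums(m^2))
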