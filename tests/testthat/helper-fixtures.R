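# shared fixtures: small deterministic images, oracle models, brute-force
# oracles used across test files

# deterministic smooth test image (H x W x 3 in [0,1])
testImage <- function(h = 8L, w = h) {
  r <- outer(seq_len(h), seq_len(w), function(i, j) (i + j) / (h + w))
  g <- outer(seq_len(h), seq_len(w), function(i, j) i / (h + 1))
  b <- outer(seq_len(h), seq_len(w), function(i, j) j / (w + 1))
  array(c(r, g, b) * 0.8 + 0.1, c(h, w, 3))
}

# epsilon model that returns a captured noise array: the "oracle" that knows
# exactly which noise corrupted the sample
oracleModel <- function(noise) function(x, t) noise

# zero predictor
zeroModel <- function(x, t) array(0, dim = if (is.null(dim(x))) length(x)
                                  else dim(x))

# independent brute-force Otsu: evaluate the between-class variance of every
# candidate split of the sorted unique pixel values directly
bruteForceOtsuPartition <- function(v) {
  u <- sort(unique(v))
  best <- -Inf; bestCut <- u[1]
  for (k in seq_len(length(u) - 1L)) {
    cut <- (u[k] + u[k + 1L]) / 2
    lo <- v[v <= cut]; hi <- v[v > cut]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bestCut <- cut }
  }
  v > bestCut
}

# identity generator for translation losses
identityGenerator <- function(image, masks) list(image = image, masks = masks)

# additive-shift generator (no clipping; caller keeps values in range)
shiftGenerator <- function(delta) function(image, masks)
  list(image = image + delta, masks = masks)

# constant-output generator
constantGenerator <- function(value) function(image, masks)
  list(image = array(value, dim = dim(image)), masks = masks)

# permutation-invariant toy discriminator: depends on the image mean and the
# mask-set sum only
setDiscriminator <- function(bias = 0) function(image, masks)
  mean(image) + mean(Reduce(`+`, masks)) + bias

# tiny instance pair on a 4x4 raster with two instances per domain
toyPair <- function(val = 0.5) {
  mk <- function(cells) {
    g <- matrix(0, 4, 4); g[cells] <- 1
    binaryMask(g, "instance-marks-1")
  }
  x <- array(val, c(4, 4, 3)); y <- array(val + 0.1, c(4, 4, 3))
  instancePair(x, list(mk(1:2), mk(5:6)), y, list(mk(3:4), mk(7:8)))
}

# features with exact first two sample moments (mean 0, covariance I)
whitenedFeatures <- function(n, d, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  X <- sweep(X, 2, colMeans(X))
  S <- cov(X)
  e <- eigen(S, symmetric = TRUE)
  X %*% (e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors))
}
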