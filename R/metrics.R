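#' Peak signal-to-noise ratio
#'
#' \eqn{20 \log_{10}(MAX / \sqrt{MSE})} in decibels; identical images
#' (MSE = 0) return \code{Inf}.
#'
#' @param x,y numeric arrays of the same shape.
#' @param maxValue dynamic range MAX of the images (default 1).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, maxValue = 1) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("'x' and 'y' must share a shape", call. = FALSE)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  20 * log10(maxValue / sqrt(mse))
}

#' Global structural similarity index
#'
#' The single-window SSIM computed from whole-image means, variances and
#' covariance:
#' \eqn{\frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#' {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}.
#' Defaults follow the usual stabilisers \eqn{c_1 = (0.01 L)^2},
#' \eqn{c_2 = (0.03 L)^2} for dynamic range \eqn{L}. With
#' \code{windowSize} set, the image is instead scanned with non-overlapping
#' square windows and the mean local SSIM is returned.
#'
#' @param x,y numeric arrays of the same shape.
#' @param dynamicRange value range L of the data (default 1).
#' @param c1,c2 positive stabilising constants.
#' @param windowSize optional integer side of the local-window variant.
#' @return SSIM in [-1, 1].
#' @export
ssimGlobal <- function(x, y, dynamicRange = 1, c1 = (0.01 * dynamicRange)^2,
                       c2 = (0.03 * dynamicRange)^2, windowSize = NULL) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("'x' and 'y' must share a shape", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  one <- function(u, v) {
    mx <- mean(u); my <- mean(v)
    vx <- mean((u - mx)^2); vy <- mean((v - my)^2)
    cxy <- mean((u - mx) * (v - my))
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (is.null(windowSize)) return(one(x, y))
  xm <- if (length(dim(x)) == 3L) apply(x, c(1, 2), mean) else x
  ym <- if (length(dim(y)) == 3L) apply(y, c(1, 2), mean) else y
  w <- as.integer(windowSize)
  ri <- seq(1L, nrow(xm) - w + 1L, by = w)
  ci <- seq(1L, ncol(xm) - w + 1L, by = w)
  vals <- outer(ri, ci, Vectorize(function(r, cc)
    one(xm[r:(r + w - 1L), cc:(cc + w - 1L)],
        ym[r:(r + w - 1L), cc:(cc + w - 1L)])))
  mean(vals)
}

#' Inception score from class-posterior rows
#'
#' \eqn{\exp(E_x D_{KL}(p(y \mid x) \,\|\, p(y)))}, computed per split with
#' the marginal \eqn{p(y)} estimated within the split; returns the mean and
#' standard deviation across splits. Confident, diverse posteriors score
#' near the class count k; posteriors equal to the marginal score 1.
#'
#' @param probs n x k matrix; rows are nonnegative and sum to 1 (within
#'   1e-6).
#' @param nSplits number of equal splits (default 10, capped at n).
#' @return list with \code{mean} and \code{sd}.
#' @export
inceptionScore <- function(probs, nSplits = 10L) {
  probs <- as.matrix(probs)
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("rows of 'probs' must be probability vectors summing to 1",
         call. = FALSE)
  n <- nrow(probs)
  nSplits <- max(1L, min(as.integer(nSplits), n))
  splitId <- ceiling(seq_len(n) / (n / nSplits))
  scores <- vapply(seq_len(nSplits), function(s) {
    p <- probs[splitId == s, , drop = FALSE]
    marg <- colMeans(p)
    kl <- rowSums(ifelse(p > 0, p * (log(p) - rep(log(marg),
                                                  each = nrow(p))), 0))
    exp(mean(kl))
  }, numeric(1))
  list(mean = mean(scores), sd = if (nSplits > 1L) stats::sd(scores) else 0)
}

# symmetric positive-semidefinite matrix square root via eigendecomposition;
# eigenvalues in [-tol, 0) are zeroed, below -tol is an error
.sqrtmPSD <- function(S, tol = 1e-6) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -tol))
    stop("matrix is not positive semidefinite within tolerance",
         call. = FALSE)
  ev[ev < 0] <- 0
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

.checkFeatures <- function(m, nm) {
  m <- as.matrix(m)
  if (any(!is.finite(m)))
    stop(sprintf("'%s' contains non-finite features", nm), call. = FALSE)
  if (nrow(m) < 2L)
    stop(sprintf("'%s' needs at least 2 samples", nm), call. = FALSE)
  m
}

#' Frechet distance between two feature distributions
#'
#' Fits a Gaussian to each embedding set and returns
#' \eqn{\|\mu_r - \mu_f\|^2 + \mathrm{Tr}(\Sigma_r + \Sigma_f -
#' 2(\Sigma_r \Sigma_f)^{1/2})}. The matrix square root is taken as the
#' symmetrised product \eqn{\Sigma_r^{1/2} \Sigma_f \Sigma_r^{1/2}} via
#' eigendecomposition, with small negative eigenvalues (>= -1e-6) clipped
#' to zero. Zero iff the two sets share their first two moments; symmetric
#' in its arguments.
#'
#' @param real,fake numeric feature matrices (n x d) with matching d.
#' @return nonnegative scalar (tiny negatives from round-off are clamped).
#' @export
fid <- function(real, fake) {
  real <- .checkFeatures(real, "real"); fake <- .checkFeatures(fake, "fake")
  if (ncol(real) != ncol(fake))
    stop("feature dimensions differ", call. = FALSE)
  muR <- colMeans(real); muF <- colMeans(fake)
  sR <- stats::cov(real); sF <- stats::cov(fake)
  sqR <- .sqrtmPSD(sR)
  covMean <- .sqrtmPSD(sqR %*% sF %*% sqR)
  val <- sum((muR - muF)^2) + sum(diag(sR)) + sum(diag(sF)) -
    2 * sum(diag(covMean))
  max(val, 0)
}

#' Kernel distance between two feature distributions
#'
#' Unbiased squared maximum-mean-discrepancy estimate under the polynomial
#' kernel \eqn{\kappa(x, y) = (x \cdot y / d + 1)^3}, averaged over random
#' subsets; reported as mean and standard deviation across subsets (the
#' "mean (+- sd)" convention). Unlike the Frechet distance the estimator is
#' unbiased, so its null distribution is centred on zero. Uses the global
#' RNG for subset draws.
#'
#' @param real,fake numeric feature matrices (n x d) with matching d.
#' @param nSubsets number of subset repetitions (default 100).
#' @param subsetSize samples per subset (default \code{min(n, 1000)}); must
#'   be at least 2 and at most the smaller sample count.
#' @return list with \code{mean} and \code{sd}.
#' @export
kid <- function(real, fake, nSubsets = 100L,
                subsetSize = min(nrow(real), nrow(fake), 1000L)) {
  real <- .checkFeatures(real, "real"); fake <- .checkFeatures(fake, "fake")
  d <- ncol(real)
  if (ncol(fake) != d) stop("feature dimensions differ", call. = FALSE)
  if (subsetSize < 2L)
    stop("'subsetSize' must be at least 2", call. = FALSE)
  if (subsetSize > min(nrow(real), nrow(fake)))
    stop("'subsetSize' exceeds the available samples", call. = FALSE)
  kpoly <- function(A, B) (A %*% t(B) / d + 1)^3
  est <- vapply(seq_len(nSubsets), function(i) {
    X <- real[sample.int(nrow(real), subsetSize), , drop = FALSE]
    Y <- fake[sample.int(nrow(fake), subsetSize), , drop = FALSE]
    Kxx <- kpoly(X, X); Kyy <- kpoly(Y, Y); Kxy <- kpoly(X, Y)
    m <- subsetSize
    (sum(Kxx) - sum(diag(Kxx))) / (m * (m - 1)) +
      (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) -
      2 * mean(Kxy)
  }, numeric(1))
  list(mean = mean(est), sd = if (nSubsets > 1L) stats::sd(est) else 0)
}

#' Embed a batch of images with a pluggable extractor
#'
#' Applies an embedding callable row-wise to a batch. An extractor is any
#' \code{function(image)} returning a fixed-length numeric vector, with its
#' output dimension declared in the attribute \code{"featureDim"} (checked
#' against every output). The bundled [toyExtractor()] is a deterministic
#' offline default; a pretrained classifier can be plugged in through the
#' same contract.
#'
#' @param images list of numeric arrays.
#' @param extractor embedding callable with a \code{featureDim} attribute.
#' @return n x d feature matrix, one row per image, in batch order.
#' @export
extractFeatures <- function(images, extractor) {
  d <- attr(extractor, "featureDim")
  if (is.null(d))
    stop("extractor must declare its output size in attr 'featureDim'",
         call. = FALSE)
  t(vapply(images, function(im) {
    f <- extractor(im)
    if (length(f) != d)
      stop(sprintf("extractor returned %d values, declared featureDim is %d",
                   length(f), d), call. = FALSE)
    as.numeric(f)
  }, numeric(d)))
}

#' Deterministic offline feature extractor
#'
#' A fixed seeded random projection over 4 x 4 average-pooled channel
#' planes: cheap, deterministic, needs no download, and separates image
#' distributions well enough for distribution-level testing. Not a
#' perceptual embedding; distances computed over it are not comparable to
#' published scores from pretrained classifier features.
#'
#' @param dim output embedding size (default 64).
#' @param seed seed fixing the projection (default 42).
#' @param pool pooled grid side (default 4).
#' @return extractor \code{function(image)} with attribute
#'   \code{featureDim}.
#' @export
toyExtractor <- function(dim = 64L, seed = 42L, pool = 4L) {
  dim <- as.integer(dim); pool <- as.integer(pool)
  proj <- new.env(parent = emptyenv())
  fn <- function(image) {
    if (length(base::dim(image)) == 2L)
      image <- array(image, c(base::dim(image), 1L))
    pooled <- vapply(seq_len(base::dim(image)[3]), function(ch) {
      pl <- image[, , ch]
      ri <- ceiling(seq_len(nrow(pl)) / nrow(pl) * pool)
      ci <- ceiling(seq_len(ncol(pl)) / ncol(pl) * pool)
      as.vector(rowsum(t(rowsum(pl, ri)), ci) /
                  tcrossprod(tabulate(ci, pool), tabulate(ri, pool)))
    }, numeric(pool * pool))
    v <- as.vector(pooled)
    key <- as.character(length(v))
    if (is.null(proj[[key]])) {
      rs <- .seededRNG(seed + length(v))
      proj[[key]] <- matrix(rs$rnorm(length(v) * dim) / sqrt(length(v)),
                            length(v), dim)
    }
    as.numeric(v %*% proj[[key]])
  }
  attr(fn, "featureDim") <- dim
  fn
}

#' Softmax class-posterior head over an extractor
#'
#' Turns any feature extractor into a k-class probability model by a seeded
#' linear map plus softmax; the stand-in classifier used to compute
#' inception-style scores without pretrained weights.
#'
#' @param extractor a feature extractor (see [extractFeatures()]).
#' @param k number of classes (default 8).
#' @param seed seed fixing the linear head.
#' @return \code{function(image)} returning a length-k probability vector,
#'   with attribute \code{nClasses}.
#' @export
toyClassifier <- function(extractor = toyExtractor(), k = 8L, seed = 7L) {
  d <- attr(extractor, "featureDim")
  rs <- .seededRNG(seed)
  W <- matrix(rs$rnorm(d * k) / sqrt(d), d, k)
  fn <- function(image) {
    z <- as.numeric(extractor(image) %*% W)
    e <- exp(z - max(z))
    e / sum(e)
  }
  attr(fn, "nClasses") <- as.integer(k)
  fn
}

# draw from a private RNG stream without touching the global .Random.seed
.seededRNG <- function(seed) {
  list(rnorm = function(n) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old))
      rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::rnorm(n)
  })
}
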