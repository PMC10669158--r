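test_that("binary masks validate values and convention tags", {
  expect_error(binaryMask(matrix(0.5, 2, 2)), "0 or 1")
  m <- binaryMask(matrix(c(1, 0, 0, 1), 2), "known-marks-1")
  expect_equal(maskConvention(m), "known-marks-1")
  expect_equal(maskGrid(binaryMask(matrix(TRUE, 2, 2))), matrix(1, 2, 2))
})

test_that("Otsu threshold separates a two-level image exactly", {
  v <- c(rep(0.2, 40), rep(0.8, 60))
  thr <- otsuThreshold(v)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  expect_identical(v > thr, v == 0.8)
  # swapping the proportions leaves the partition identical
  v2 <- c(rep(0.2, 60), rep(0.8, 40))
  thr2 <- otsuThreshold(v2)
  expect_identical(v2 > thr2, v2 == 0.8)
  expect_error(otsuThreshold(rep(0.3, 10)), "constant")
})

test_that("Otsu equals brute-force between-class-variance maximisation", {
  set.seed(1)
  levels <- seq(0.05, 0.95, length.out = 32)
  for (i in 1:20) {
    w <- rgamma(32, shape = runif(1, 0.2, 2))
    v <- sample(levels, 500, replace = TRUE, prob = w / sum(w))
    if (length(unique(v)) < 2) next
    thr <- otsuThreshold(v, nBins = 256)
    expect_identical(v > thr, bruteForceOtsuPartition(v))
  }
})

test_that("Otsu misclassifies under 1% of a well-separated mixture", {
  set.seed(2)
  n <- 1e4
  lab <- rbinom(n, 1, 0.5)
  v <- rnorm(n, mean = ifelse(lab == 1, 0.75, 0.25), sd = 0.05)
  thr <- otsuThreshold(v)
  expect_lt(mean((v > thr) != lab), 0.01)
})

test_that("leaf extraction recovers the ground-truth mask", {
  set.seed(3)
  leaf <- generateLeaf(leafSpec())
  m <- leafMaskOtsu(leaf$image)
  expect_equal(maskConvention(m), "instance-marks-1")
  expect_gte(iou(m, leaf$mask), 0.95)
  expect_error(leafMaskOtsu(array(0.5, c(8, 8, 3))), "constant")
})

test_that("largest-component cleanup removes a detached shadow blob", {
  img <- array(0.9, c(32, 32, 3))                  # bright background
  truth <- matrix(0, 32, 32)
  truth[8:24, 8:20] <- 1                           # dark "leaf"
  shadow <- matrix(0, 32, 32)
  shadow[27:30, 26:30] <- 1                        # smaller dark blob
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[truth == 1] <- 0.2; pl[shadow == 1] <- 0.25
    img[, , ch] <- pl
  }
  m <- leafMaskOtsu(img, foregroundPolarity = "dark")
  expect_equal(maskGrid(m), truth)
})

test_that("dilation uses the documented disk and nests monotonically", {
  g <- matrix(0, 7, 7); g[4, 4] <- 1
  m <- binaryMask(g, "instance-marks-1")
  expect_identical(maskGrid(dilateMask(m, 0)), g)     # radius 0 identity
  d1 <- maskGrid(dilateMask(m, 1))
  expect_equal(sum(d1), 5)                            # plus shape
  expect_equal(d1[3:5, 3:5],
               matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3))
  d2 <- maskGrid(dilateMask(m, 2))
  expect_true(all(d2[d1 == 1] == 1))                  # nested
  expect_gte(sum(d2), sum(d1))
  expect_equal(maskConvention(dilateMask(m, 2)), "instance-marks-1")
  expect_error(dilateMask(m, -1), "nonnegative")
})

test_that("inversion is an involution that swaps the convention", {
  g <- matrix(c(1, 0, 1, 0), 2)
  m <- binaryMask(g, "instance-marks-1")
  inv <- invertMask(m)
  expect_equal(maskConvention(inv), "known-marks-1")
  expect_equal(maskGrid(inv), 1 - g)
  back <- invertMask(inv)
  expect_equal(maskGrid(back), g)
  expect_equal(maskConvention(back), "instance-marks-1")
  # whole-leaf instance mask inverts to the no-context configuration
  allLeaf <- binaryMask(matrix(1, 3, 3), "instance-marks-1")
  expect_equal(sum(maskGrid(invertMask(allLeaf))), 0)
  expect_equal(sum(g) + sum(maskGrid(inv)), length(g))
})

test_that("split-mask catalogue templates are sane and complement-paired", {
  cat10 <- splitMaskCatalogue()
  expect_length(cat10, 10)
  grids <- lapply(cat10, function(f) f(16, 16))
  for (g in grids) {
    expect_gt(sum(g), 0)                 # nonempty known region
    expect_lt(sum(g), 256)               # nonempty unknown region
  }
  # any two templates' unknown regions jointly cover the raster
  for (i in seq_along(grids)) {
    covered <- vapply(seq_along(grids), function(j)
      all((1 - grids[[i]]) + (1 - grids[[j]]) > 0), logical(1))
    expect_true(any(covered[-i]))
  }
  # named complements are exact
  expect_equal(grids[["left-half"]] + grids[["right-half"]],
               matrix(1, 16, 16))
  expect_equal(grids[["center-window"]] + grids[["border-band"]],
               matrix(1, 16, 16))
})

test_that("split masks are drawn uniformly and reproducibly", {
  one <- list(only = function(nr, nc) { g <- matrix(1, nr, nc); g[1] <- 0; g })
  set.seed(4)
  m <- sampleSplitMask(c(8, 8), one)
  expect_equal(attr(m, "template"), "only")
  expect_equal(maskConvention(m), "known-marks-1")
  set.seed(5); a <- sampleSplitMask(c(8, 8))
  set.seed(5); b <- sampleSplitMask(c(8, 8))
  expect_identical(maskGrid(a), maskGrid(b))
  # frequencies across 8000 draws within 4 sigma of uniform over 10
  set.seed(6)
  draws <- replicate(8000, attr(sampleSplitMask(c(8, 8)), "template"))
  counts <- table(factor(draws, levels = names(splitMaskCatalogue())))
  expected <- 8000 / 10
  sigma <- sqrt(8000 * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < 4 * sigma))
  expect_error(sampleSplitMask(c(8, 8), list()), "empty")
})

test_that("IoU matches hand counts and is a proper similarity", {
  g <- function(cells) { m <- matrix(0, 3, 3); m[cells] <- 1
    binaryMask(m, "instance-marks-1") }
  expect_equal(iou(g(1:4), g(1:4)), 1)
  expect_equal(iou(g(1:2), g(3:4)), 0)
  expect_equal(iou(g(1:4), g(2:7)), 3 / 7)          # overlap 3, union 7
  expect_equal(iou(g(2:7), g(1:4)), 3 / 7)          # symmetric
  empty <- binaryMask(matrix(0, 3, 3), "instance-marks-1")
  expect_equal(iou(empty, empty), 1)                # both empty
  expect_error(iou(g(1:2), invertMask(g(1:2))), "conventions differ")
  expect_equal(meanIOU(list(g(1:4), g(1:2)), list(g(1:4), g(3:4))),
               mean(c(1, 0)))
})

test_that("mask PNGs round-trip with their convention sidecar", {
  g <- matrix(rbinom(64, 1, 0.4), 8)
  m <- binaryMask(g, "known-marks-1")
  path <- tempfile(fileext = ".png")
  writeMaskPNG(m, path, provenance = "test")
  back <- readMaskPNG(path)
  expect_equal(maskGrid(back), g)
  expect_equal(maskConvention(back), "known-marks-1")
  file.remove(paste0(path, ".json"))
  expect_error(readMaskPNG(path), "sidecar")
  expect_equal(maskConvention(readMaskPNG(path, "instance-marks-1")),
               "instance-marks-1")
})
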