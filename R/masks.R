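#' Create a binary mask
#'
#' @param grid numeric, integer or logical matrix; values must be 0/1
#'   (logicals are coerced).
#' @param convention \code{"instance-marks-1"} (1 = object pixels, the
#'   segmentation convention) or \code{"known-marks-1"} (1 = pixels kept as
#'   context during inpainting).
#' @return a [BinaryMask-class].
#' @examples
#' m <- binaryMask(matrix(c(1, 1, 0, 0), 2), "instance-marks-1")
#' maskConvention(invertMask(m))
#' @export
binaryMask <- function(grid, convention = c("instance-marks-1",
                                            "known-marks-1")) {
  convention <- match.arg(convention)
  if (is.logical(grid)) grid <- grid + 0
  storage.mode(grid) <- "double"
  new("BinaryMask", grid = grid, convention = convention)
}

#' @rdname maskGrid
#' @export
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @rdname maskConvention
#' @export
setMethod("maskConvention", "BinaryMask", function(x) x@convention)

setMethod("show", "BinaryMask", function(object) {
  g <- object@grid
  cat(sprintf("BinaryMask %dx%d [%s], %d/%d pixels set\n",
              nrow(g), ncol(g), object@convention, sum(g), length(g)))
})

#' @rdname invertMask
#' @export
setMethod("invertMask", "BinaryMask", function(x) {
  new("BinaryMask", grid = 1 - x@grid,
      convention = setdiff(.maskConventions, x@convention))
})

# discrete disk: offsets with dx^2 + dy^2 <= r^2 (radius 1 => 5-pixel plus)
.diskKernel <- function(radius) {
  r <- as.integer(radius)
  off <- seq(-r, r)
  k <- outer(off, off, function(i, j) (i * i + j * j) <= radius^2) + 0
  k
}

#' @rdname dilateMask
#' @export
setMethod("dilateMask", "BinaryMask", function(x, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius < 0)
    stop("'radius' must be a nonnegative number", call. = FALSE)
  if (radius < 1) return(x)
  g <- EBImage::dilate(x@grid, .diskKernel(radius))
  new("BinaryMask", grid = (g > 0) + 0, convention = x@convention)
})

.assertConvention <- function(mask, expected) {
  if (maskConvention(mask) != expected)
    stop(sprintf("mask convention must be '%s' but received '%s'",
                 expected, maskConvention(mask)), call. = FALSE)
  invisible(mask)
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustively searches the histogram cut that maximises the between-class
#' variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over \code{nBins}
#' equal-width bins spanning the observed value range.
#'
#' @param gray numeric matrix or vector of pixel values.
#' @param nBins number of histogram bins (default 256).
#' @return the threshold level (a value strictly between the two classes;
#'   pixels \code{> threshold} form the upper class).
#' @export
otsuThreshold <- function(gray, nBins = 256L) {
  v <- as.vector(gray)
  if (any(!is.finite(v))) stop("non-finite pixel values", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate input: image is constant, no threshold exists",
         call. = FALSE)
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("'nBins' must be at least 2", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              nBins)
  cnt <- tabulate(bin, nBins)
  # class means use the actual per-bin value sums (exact-level Otsu)
  sums <- numeric(nBins)
  rs <- rowsum(v, bin)
  sums[as.integer(rownames(rs))] <- rs
  w0 <- cumsum(cnt) / length(v)
  m0 <- cumsum(sums) / length(v)
  mT <- m0[nBins]
  # between-class variance at each candidate cut (threshold after bin k)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nBins)
  bcv[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv[-nBins])
  # threshold strictly between the two classes' observed values
  (max(v[bin <= k]) + min(v[bin > k])) / 2
}

#' Extract a leaf mask by Otsu thresholding
#'
#' Automatic leaf segmentation: luminance conversion, Otsu threshold,
#' polarity resolution, then optional cleanup (retain the largest connected
#' component, fill interior holes). In \code{"auto"} polarity the
#' foreground is the threshold side that dominates the central quarter of
#' the frame, matching single-leaf-centred imagery. Simple thresholding is
#' known to admit shadows and miss diseased regions on heterogeneous data;
#' the cleanup switches encode the standard fixes.
#'
#' @param image numeric array H x W x 3 in [0, 1].
#' @param foregroundPolarity \code{"auto"}, \code{"dark"} or
#'   \code{"bright"}: which threshold side is the leaf.
#' @param largestComponent keep only the largest connected foreground
#'   component (default TRUE).
#' @param fillHoles fill enclosed background holes (default TRUE).
#' @param nBins histogram bins for [otsuThreshold()].
#' @return a [BinaryMask-class] with convention \code{instance-marks-1}.
#' @export
leafMaskOtsu <- function(image,
                         foregroundPolarity = c("auto", "dark", "bright"),
                         largestComponent = TRUE, fillHoles = TRUE,
                         nBins = 256L) {
  foregroundPolarity <- match.arg(foregroundPolarity)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be an H x W x 3 array", call. = FALSE)
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  thr <- otsuThreshold(gray, nBins = nBins)
  upper <- gray > thr
  fg <- switch(foregroundPolarity,
    bright = upper,
    dark = !upper,
    auto = {
      nr <- nrow(gray); nc <- ncol(gray)
      ri <- seq(floor(nr * 3 / 8) + 1L, ceiling(nr * 5 / 8))
      ci <- seq(floor(nc * 3 / 8) + 1L, ceiling(nc * 5 / 8))
      if (mean(upper[ri, ci]) >= 0.5) upper else !upper
    })
  g <- fg + 0
  if (largestComponent && any(g > 0)) {
    lab <- EBImage::bwlabel(g)
    sizes <- tabulate(lab[lab > 0])
    g <- (lab == which.max(sizes)) + 0
  }
  if (fillHoles && any(g > 0)) g <- (EBImage::fillHull(g) > 0) + 0
  if (!any(g > 0))
    stop("leaf mask extraction failed: empty foreground after cleanup",
         call. = FALSE)
  binaryMask(g, "instance-marks-1")
}

#' Catalogue of simple split masks
#'
#' The default set of partial context masks used to spread synthetic
#' symptoms over every part of the leaf, including boundaries and edges:
#' four half-frame masks, four single-quadrant-context masks, a centre
#' window and its border-band complement. In each template 1 marks known
#' (kept) pixels and 0 the region to regenerate; every template keeps both
#' regions nonempty, and any two templates' unknown regions jointly cover
#' the raster.
#'
#' @return named list of template functions \code{function(nrow, ncol)}
#'   returning a 0/1 matrix (known-marks-1).
#' @seealso [sampleSplitMask()]
#' @export
splitMaskCatalogue <- function() {
  half <- function(side) function(nr, nc) {
    g <- matrix(1, nr, nc)
    switch(side,
      left = g[, seq_len(ncol(g) %/% 2)] <- 0,
      right = g[, (ncol(g) %/% 2 + 1L):ncol(g)] <- 0,
      top = g[seq_len(nrow(g) %/% 2), ] <- 0,
      bottom = g[(nrow(g) %/% 2 + 1L):nrow(g), ] <- 0)
    g
  }
  quadrantKnown <- function(vert, horiz) function(nr, nc) {
    g <- matrix(0, nr, nc)
    ri <- if (vert == "top") seq_len(nr %/% 2) else (nr %/% 2 + 1L):nr
    ci <- if (horiz == "left") seq_len(nc %/% 2) else (nc %/% 2 + 1L):nc
    g[ri, ci] <- 1
    g
  }
  centerWindow <- function(nr, nc) {
    g <- matrix(1, nr, nc)
    g[seq(nr %/% 4 + 1L, nr %/% 4 + nr %/% 2),
      seq(nc %/% 4 + 1L, nc %/% 4 + nc %/% 2)] <- 0
    g
  }
  list(
    `left-half` = half("left"), `right-half` = half("right"),
    `top-half` = half("top"), `bottom-half` = half("bottom"),
    `quadrant-tl` = quadrantKnown("top", "left"),
    `quadrant-tr` = quadrantKnown("top", "right"),
    `quadrant-bl` = quadrantKnown("bottom", "left"),
    `quadrant-br` = quadrantKnown("bottom", "right"),
    `center-window` = centerWindow,
    `border-band` = function(nr, nc) 1 - centerWindow(nr, nc))
}

#' Draw one split mask uniformly at random
#'
#' Samples a template uniformly from the catalogue and instantiates it for
#' the given raster; over many draws each template appears with frequency
#' 1/|catalogue|. Uses the global RNG.
#'
#' @param shape integer length-2, raster (rows, cols).
#' @param catalogue named list of template functions, by default
#'   [splitMaskCatalogue()].
#' @return a [BinaryMask-class] (known-marks-1); attribute
#'   \code{"template"} names the drawn variant.
#' @export
sampleSplitMask <- function(shape, catalogue = splitMaskCatalogue()) {
  if (length(catalogue) < 1L)
    stop("split-mask catalogue is empty", call. = FALSE)
  if (length(shape) != 2L || any(shape < 2))
    stop("'shape' must be two raster dimensions >= 2", call. = FALSE)
  k <- sample.int(length(catalogue), 1L)
  m <- binaryMask(catalogue[[k]](shape[1], shape[2]), "known-marks-1")
  attr(m, "template") <- names(catalogue)[k]
  m
}

#' Intersection over union of two masks
#'
#' \eqn{|A \cap B| / |A \cup B|}; when both masks are empty the union is
#' empty and the score is defined as 1. Masks must share raster dimensions
#' and convention tag.
#'
#' @param pred,truth [BinaryMask-class] objects.
#' @return numeric in [0, 1].
#' @export
iou <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  if (!identical(dim(maskGrid(pred)), dim(maskGrid(truth))))
    stop("masks must share raster dimensions", call. = FALSE)
  if (maskConvention(pred) != maskConvention(truth))
    stop(sprintf("mask conventions differ: '%s' vs '%s'",
                 maskConvention(pred), maskConvention(truth)), call. = FALSE)
  a <- maskGrid(pred); b <- maskGrid(truth)
  uni <- sum(a + b > 0)
  if (uni == 0) return(1)
  sum(a * b) / uni
}

#' Mean IoU over paired masks
#'
#' @param preds,truths parallel lists of [BinaryMask-class] objects.
#' @return mean of pairwise [iou()] scores.
#' @export
meanIOU <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1L)
  mean(mapply(iou, preds, truths))
}

#' Read and write mask PNGs with a convention sidecar
#'
#' Masks are stored as single-channel 0/255 PNG files; the convention tag
#' and provenance travel in a JSON sidecar (\code{<path>.json}). On read,
#' pixel values are thresholded at 128 (0.5 in the [0, 1] PNG range).
#'
#' @param mask a [BinaryMask-class].
#' @param path PNG file path.
#' @param provenance optional string recorded in the sidecar.
#' @return \code{writeMaskPNG} invisibly returns \code{path};
#'   \code{readMaskPNG} returns a [BinaryMask-class].
#' @export
writeMaskPNG <- function(mask, path, provenance = "leafdiffuse") {
  stopifnot(is(mask, "BinaryMask"))
  png::writePNG(maskGrid(mask), path)
  jsonlite::write_json(
    list(convention = maskConvention(mask), provenance = provenance),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @param convention fallback convention when no sidecar exists.
#' @export
readMaskPNG <- function(path, convention = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    convention <- jsonlite::read_json(sidecar)$convention
  } else if (is.null(convention)) {
    stop("no sidecar JSON found; supply 'convention' explicitly",
         call. = FALSE)
  }
  binaryMask((px >= 0.5) + 0, convention)
}
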