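#' Construct a leaf specification
#'
#' Defaults render a mid-green elliptical blade with a tapered tip and a
#' gently noisy margin on a light uniform background, occupying roughly a
#' third of a 64 x 64 raster -- the single-leaf, controlled-background
#' composition of curated leaf-disease image collections. 64 pixels keeps
#' test arithmetic fast; 256 matches the full-scale imaging size used by
#' the generative experiments this package emulates.
#'
#' @param size raster side length in pixels (default 64).
#' @param axes ellipse semi-axes as fractions of \code{size}.
#' @param taper tip taper in [0, 1).
#' @param marginAmplitude relative margin-noise amplitude in [0, 0.3].
#' @param leafColor,backgroundColor RGB triples in [0, 1].
#' @param venationDensity secondary veins per side.
#' @param occupancy admissible leaf-area fraction range.
#' @return a [LeafSpec-class].
#' @export
leafSpec <- function(size = 64L, axes = c(0.38, 0.26), taper = 0.25,
                     marginAmplitude = 0.06,
                     leafColor = c(0.20, 0.55, 0.22),
                     backgroundColor = c(0.82, 0.80, 0.76),
                     venationDensity = 4L, occupancy = c(0.2, 0.8)) {
  new("LeafSpec", size = as.integer(size), axes = axes, taper = taper,
      marginAmplitude = marginAmplitude, leafColor = leafColor,
      backgroundColor = backgroundColor,
      venationDensity = as.integer(venationDensity), occupancy = occupancy)
}

#' Construct a disease style
#'
#' @param style one of \code{"concentric-ring-blight"}, \code{"dark-spot"},
#'   \code{"edge-blight"}, \code{"mosaic-mottle"},
#'   \code{"curl-yellowing-tint"}.
#' @param intensity symptom intensity in [0, 1] (default 0.7).
#' @param maxSpots lesion-count ceiling for spotting styles (default 12).
#' @param spotRadius lesion radius range in pixels, scaled to the raster at
#'   render time (defaults suit a 64-pixel raster).
#' @param edgeBias in [0, 1]; 1 confines symptoms to the leaf-boundary
#'   band (default 0.3).
#' @return a [DiseaseStyle-class].
#' @export
diseaseStyle <- function(style, intensity = 0.7, maxSpots = 12L,
                         spotRadius = c(1.5, 3.5), edgeBias = 0.3) {
  new("DiseaseStyle", style = style, intensity = intensity,
      maxSpots = as.integer(maxSpots), spotRadius = spotRadius,
      edgeBias = edgeBias)
}

setMethod("show", "DiseaseStyle", function(object) {
  cat(sprintf("DiseaseStyle '%s' (intensity %.2f, edgeBias %.2f)\n",
              object@style, object@intensity, object@edgeBias))
})

#' Render a healthy synthetic leaf with its ground-truth mask
#'
#' Procedural renderer: the blade contour is a jittered ellipse with a
#' tapered tip and a smooth low-frequency margin perturbation (kept small
#' so the contour is star-shaped, hence non-self-intersecting); the blade
#' is shaded darker toward the margin, a midrib and secondary veins are
#' drawn, and mild pixel noise is added. Deterministic given the global RNG
#' state ([set.seed()]). If the drawn contour lands outside the declared
#' occupancy range it is rescaled once toward the range midpoint; a spec
#' whose bounds still cannot be met raises an error.
#'
#' @param spec a [LeafSpec-class].
#' @return list with \code{image} (H x W x 3 array in [0, 1]) and
#'   \code{mask} (a [BinaryMask-class], instance-marks-1).
#' @export
generateLeaf <- function(spec = leafSpec()) {
  stopifnot(is(spec, "LeafSpec"))
  S <- spec@size
  cx <- (S + 1) / 2 + stats::runif(1, -0.05, 0.05) * S
  cy <- (S + 1) / 2 + stats::runif(1, -0.05, 0.05) * S
  theta0 <- stats::runif(1, 0, 2 * pi)
  a <- spec@axes[1] * S * stats::runif(1, 0.9, 1.1)
  b <- spec@axes[2] * S * stats::runif(1, 0.9, 1.1)
  amp <- spec@marginAmplitude * stats::runif(3, 0.3, 1)
  ph <- stats::runif(3, 0, 2 * pi)

  radius <- function(psi) {
    r <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    r <- r * (1 - spec@taper * ((1 + cos(psi)) / 2)^2)
    wig <- amp[1] * sin(2 * psi + ph[1]) + amp[2] * sin(3 * psi + ph[2]) +
      amp[3] * sin(4 * psi + ph[3])
    r * (1 + wig)
  }

  ii <- matrix(seq_len(S), S, S)          # row index (y)
  jj <- matrix(seq_len(S), S, S, byrow = TRUE)
  dx <- jj - cx; dy <- ii - cy
  psi <- atan2(dy, dx) - theta0
  dist <- sqrt(dx^2 + dy^2)
  rpsi <- radius(psi)
  grid <- (dist <= rpsi) + 0

  occ <- mean(grid)
  if (occ < spec@occupancy[1] || occ > spec@occupancy[2]) {
    target <- mean(spec@occupancy)
    scale <- sqrt(target / max(occ, 1e-6))
    grid <- (dist <= rpsi * scale) + 0
    rpsi <- rpsi * scale
    occ <- mean(grid)
    if (occ < spec@occupancy[1] || occ > spec@occupancy[2])
      stop("leaf spec cannot meet its occupancy bounds on this raster",
           call. = FALSE)
  }

  img <- array(rep(spec@backgroundColor, each = S * S), c(S, S, 3))
  rel <- pmin(dist / pmax(rpsi, 1e-6), 1)      # 0 centre .. 1 margin
  shade <- 1 - 0.25 * rel^2                    # darker toward the margin
  # veins: midrib along the major axis plus symmetric secondary rays
  axial <- abs(-sin(theta0) * dx + cos(theta0) * dy)   # distance to midrib
  vein <- axial < 0.8
  if (spec@venationDensity > 0L) {
    for (k in seq_len(spec@venationDensity)) {
      angK <- k * pi / (spec@venationDensity + 1) - pi / 2
      dK <- abs(-sin(theta0 + angK) * dx + cos(theta0 + angK) * dy)
      vein <- vein | (dK < 0.5 & rel < 0.8)
    }
  }
  veinFac <- ifelse(vein, 0.85, 1)
  for (ch in 1:3) {
    leafPlane <- spec@leafColor[ch] * shade * veinFac
    plane <- ifelse(grid == 1, leafPlane, img[, , ch])
    img[, , ch] <- plane + stats::rnorm(S * S, sd = 0.015)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = binaryMask(grid, "instance-marks-1"))
}

#' Boundary band of an instance mask
#'
#' The band of leaf pixels within \code{width} pixels of the leaf boundary
#' (mask minus its erosion); the region edge-biased symptoms are confined
#' to. The default width is 15 percent of the leaf's equivalent radius,
#' at least 1 pixel.
#'
#' @param mask a [BinaryMask-class] (instance-marks-1).
#' @param width band width in pixels (default as above).
#' @return 0/1 matrix of band pixels.
#' @export
boundaryBand <- function(mask, width = NULL) {
  .assertConvention(mask, "instance-marks-1")
  g <- maskGrid(mask)
  if (is.null(width))
    width <- max(1L, round(0.15 * sqrt(sum(g) / pi)))
  eroded <- EBImage::erode(g, .diskKernel(width))
  (g > 0 & eroded == 0) + 0
}

#' Overlay stylised disease symptoms on a leaf image
#'
#' Renders the requested symptom style strictly inside the leaf mask:
#' background pixels are returned bit-identically, intensity 0 returns the
#' input unchanged, and the symptom-pixel count grows monotonically with
#' intensity (under a fixed RNG state, lower intensities affect a prefix of
#' the pixels a higher intensity affects). With \code{edgeBias = 1} all
#' changes are confined to the [boundaryBand()].
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mask [BinaryMask-class] with convention \code{instance-marks-1}.
#' @param style a [DiseaseStyle-class].
#' @return diseased image, same shape as \code{image}.
#' @export
applyDisease <- function(image, mask, style) {
  stopifnot(is(mask, "BinaryMask"), is(style, "DiseaseStyle"))
  .assertConvention(mask, "instance-marks-1")
  g <- maskGrid(mask)
  if (!identical(as.integer(dim(image)[1:2]), dim(g) * 1L) &&
      !identical(dim(image)[1:2], dim(g)))
    stop("mask raster does not match the image", call. = FALSE)
  if (style@intensity == 0) return(image)
  S <- nrow(g)
  band <- boundaryBand(mask)
  allowed <- if (style@edgeBias >= 1) band else g
  if (!any(allowed > 0)) allowed <- g

  # per-pixel blend strength in [0,1] toward a symptom colour
  strength <- matrix(0, nrow(g), ncol(g))
  symCol <- c(0.30, 0.18, 0.08)                 # necrotic brown
  ii <- matrix(seq_len(nrow(g)), nrow(g), ncol(g))
  jj <- matrix(seq_len(ncol(g)), nrow(g), ncol(g), byrow = TRUE)

  if (style@style %in% c("dark-spot", "concentric-ring-blight")) {
    # draw the full candidate set first so lower intensities affect a
    # prefix of the higher-intensity lesion set
    cand <- which(allowed > 0)
    bandIdx <- which(band > 0 & allowed > 0)
    centers <- integer(style@maxSpots)
    radii <- stats::runif(style@maxSpots, style@spotRadius[1],
                          style@spotRadius[2]) * S / 64
    useBand <- stats::runif(style@maxSpots) < style@edgeBias &
      length(bandIdx) > 0
    for (s in seq_len(style@maxSpots)) {
      pool <- if (useBand[s]) bandIdx else cand
      centers[s] <- pool[sample.int(length(pool), 1L)]
    }
    nUse <- ceiling(style@intensity * style@maxSpots)
    for (s in seq_len(nUse)) {
      cyx <- arrayInd(centers[s], dim(g))
      d <- sqrt((ii - cyx[1])^2 + (jj - cyx[2])^2)
      if (style@style == "dark-spot") {
        eff <- pmax(1 - d / radii[s], 0)
      } else {
        eff <- ifelse(d <= radii[s] * 1.6,
                      0.5 * (1 + cos(2 * pi * d / pmax(radii[s], 0.5))), 0)
        eff <- eff * pmax(1 - d / (radii[s] * 1.6), 0.15) *
          (d <= radii[s] * 1.6)
      }
      strength <- pmax(strength, eff)
    }
  } else if (style@style == "edge-blight") {
    strength <- band * style@intensity
    symCol <- c(0.35, 0.22, 0.10)
  } else if (style@style == "mosaic-mottle") {
    cell <- max(2L, round(S / 12))
    cr <- ceiling(ii / cell); cc <- ceiling(jj / cell)
    ncell <- max(cr) * max(cc)
    u <- stats::runif(ncell)
    cellVal <- matrix(u[(cc - 1) * max(cr) + cr], nrow(g), ncol(g))
    strength <- (cellVal < style@intensity) * 0.5
    symCol <- c(0.75, 0.78, 0.25)               # chlorotic yellow
  } else if (style@style == "curl-yellowing-tint") {
    strength <- matrix(style@intensity * 0.6, nrow(g), ncol(g))
    symCol <- c(0.80, 0.75, 0.20)
  }

  strength <- strength * allowed
  out <- image
  for (ch in 1:3)
    out[, , ch] <- image[, , ch] * (1 - strength) + symCol[ch] * strength
  pmin(pmax(out, 0), 1)
}

#' Default stylised disease palette for the demo dataset
#'
#' Maps the tomato and grape disease classes of the emulated PlantVillage
#' subset to the five stylised symptom renderers, with per-class counts
#' proportional to that collection's class composition scaled down by 100
#' (tomato 10:8:7:6:5:4:3:2:1 across the nine diseases plus 12 healthy;
#' grape 5:4:3 plus 6 healthy).
#'
#' @param scale multiply all class counts (default 1).
#' @return named list of \code{list(count =, style =)} entries; healthy
#'   classes have \code{style = NULL}.
#' @export
defaultDatasetConfig <- function(scale = 1) {
  st <- function(s, ...) diseaseStyle(s, ...)
  cfg <- list(
    tomato_late_blight = list(count = 10, style = st("dark-spot",
      intensity = 0.8)),
    tomato_early_blight = list(count = 8, style = st(
      "concentric-ring-blight")),
    tomato_septoria_leaf_spot = list(count = 7, style = st("dark-spot",
      maxSpots = 20L, spotRadius = c(1, 2))),
    tomato_target_spot = list(count = 6, style = st(
      "concentric-ring-blight", intensity = 0.6)),
    tomato_mosaic_virus = list(count = 5, style = st("mosaic-mottle")),
    tomato_yellow_leaf_curl = list(count = 4, style = st(
      "curl-yellowing-tint")),
    tomato_spider_mites = list(count = 3, style = st("dark-spot",
      maxSpots = 30L, spotRadius = c(0.8, 1.5))),
    tomato_leaf_mold = list(count = 2, style = st("mosaic-mottle",
      intensity = 0.5)),
    tomato_bacterial_spot = list(count = 1, style = st("dark-spot",
      intensity = 0.5)),
    tomato_healthy = list(count = 12, style = NULL),
    grape_black_rot = list(count = 5, style = st("dark-spot",
      intensity = 0.8)),
    grape_black_measles = list(count = 4, style = st("dark-spot",
      maxSpots = 18L)),
    grape_leaf_blight = list(count = 3, style = st("edge-blight",
      edgeBias = 1)),
    grape_healthy = list(count = 6, style = NULL))
  for (nm in names(cfg)) cfg[[nm]]$count <- as.integer(
    round(cfg[[nm]]$count * scale))
  cfg
}

#' Generate a synthetic leaf dataset on disk
#'
#' Emits image/mask PNG pairs for each class in two layouts at once: a flat
#' layout (\code{images/}, \code{masks/}) for inpainting workflows, and a
#' paired-domain layout (\code{domainX/}, \code{domainX_masks/},
#' \code{domainY/}, \code{domainY_masks/}, filename-matched) for
#' translation workflows, where each diseased render in domain Y is paired
#' with the healthy render of the same leaf in domain X. A JSON manifest
#' recording the seed, per-class counts and file paths is written beside
#' the data; zero-count classes are omitted with a notice.
#'
#' @param config named list of classes, each \code{list(count =, style =)}
#'   (style NULL for healthy classes); see [defaultDatasetConfig()].
#' @param outDir output directory (created if needed).
#' @param spec a [LeafSpec-class] shared by all classes.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return the manifest, invisibly (also written to
#'   \code{outDir/manifest.json}).
#' @export
generateDataset <- function(config = defaultDatasetConfig(), outDir,
                            spec = leafSpec(), seed = 1L) {
  for (d in c("images", "masks", "domainX", "domainX_masks", "domainY",
              "domainY_masks"))
    dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  classes <- list(); files <- list()
  for (nm in names(config)) {
    cls <- config[[nm]]
    if (cls$count < 1L) {
      message(sprintf("class '%s' has count 0; omitted from the manifest",
                      nm))
      next
    }
    imgs <- character(cls$count)
    for (i in seq_len(cls$count)) {
      leaf <- generateLeaf(spec)
      stem <- sprintf("%s_%03d.png", nm, i)
      img <- leaf$image
      if (!is.null(cls$style)) {
        img <- applyDisease(leaf$image, leaf$mask, cls$style)
        png::writePNG(leaf$image, file.path(outDir, "domainX", stem))
        writeMaskPNG(leaf$mask, file.path(outDir, "domainX_masks", stem))
        png::writePNG(img, file.path(outDir, "domainY", stem))
        writeMaskPNG(leaf$mask, file.path(outDir, "domainY_masks", stem))
      }
      png::writePNG(img, file.path(outDir, "images", stem))
      writeMaskPNG(leaf$mask, file.path(outDir, "masks", stem))
      imgs[i] <- file.path("images", stem)
    }
    classes[[nm]] <- cls$count
    files[[nm]] <- imgs
  }
  manifest <- list(seed = as.integer(seed), raster = spec@size,
                   classes = classes, files = files)
  writeManifest(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}

#' Read and write dataset manifests
#'
#' The manifest round-trips losslessly through its JSON file form.
#'
#' @param manifest manifest list as returned by [generateDataset()].
#' @param path JSON file path.
#' @return \code{readManifest} returns the manifest list.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$seed <- as.integer(m$seed)
  m$raster <- as.integer(m$raster)
  m$classes <- lapply(m$classes, as.integer)
  m$files <- lapply(m$files, function(f) as.character(unlist(f)))
  m
}
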