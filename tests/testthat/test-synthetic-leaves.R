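test_that("leaf rendering is seeded-deterministic", {
  spec <- leafSpec()
  set.seed(1); a <- generateLeaf(spec)
  set.seed(1); b <- generateLeaf(spec)
  expect_identical(a$image, b$image)
  expect_identical(maskGrid(a$mask), maskGrid(b$mask))
})

test_that("leaf area stays inside the declared occupancy bounds", {
  spec <- leafSpec()
  set.seed(2)
  occ <- replicate(50, mean(maskGrid(generateLeaf(spec)$mask)))
  expect_true(all(occ >= 0.2 & occ <= 0.8))
})

test_that("leaf pixels are greener than the background", {
  set.seed(3)
  leaf <- generateLeaf(leafSpec())
  sel <- maskGrid(leaf$mask) == 1
  greenLeaf <- mean(leaf$image[, , 2][sel])
  greenBg <- mean(leaf$image[, , 2][!sel])
  # the leaf is darker overall but relatively greener: compare green
  # dominance (G minus mean of R and B)
  domLeaf <- greenLeaf - mean((leaf$image[, , 1][sel] +
                                 leaf$image[, , 3][sel]) / 2)
  domBg <- greenBg - mean((leaf$image[, , 1][!sel] +
                             leaf$image[, , 3][!sel]) / 2)
  expect_gt(domLeaf, domBg)
})

test_that("invalid leaf specs are rejected", {
  expect_error(leafSpec(size = 4), "at least 8")
  expect_error(leafSpec(axes = c(0.9, 0.2)), "<= 0.5")
  expect_error(leafSpec(occupancy = c(0.5, 0.4)), "increasing")
})

test_that("disease overlays touch only leaf pixels and respect intensity", {
  set.seed(4)
  leaf <- generateLeaf(leafSpec())
  bgSel <- array(maskGrid(leaf$mask) == 0, dim(leaf$image))
  for (style in c("concentric-ring-blight", "dark-spot", "edge-blight",
                  "mosaic-mottle", "curl-yellowing-tint")) {
    set.seed(5)
    dis <- applyDisease(leaf$image, leaf$mask, diseaseStyle(style))
    expect_identical(dis[bgSel], leaf$image[bgSel])
    expect_gt(sum(dis != leaf$image), 0)
  }
  # intensity 0 is the identity
  expect_identical(applyDisease(leaf$image, leaf$mask,
                                diseaseStyle("dark-spot", intensity = 0)),
                   leaf$image)
  expect_error(applyDisease(leaf$image, invertMask(leaf$mask),
                            diseaseStyle("dark-spot")), "instance-marks-1")
})

test_that("symptom extent grows monotonically with intensity", {
  set.seed(6)
  leaf <- generateLeaf(leafSpec())
  changed <- function(intensity) {
    set.seed(7)
    dis <- applyDisease(leaf$image, leaf$mask,
                        diseaseStyle("dark-spot", intensity = intensity))
    which(apply(dis != leaf$image, c(1, 2), any))
  }
  c2 <- changed(0.2); c5 <- changed(0.5); c9 <- changed(0.9)
  expect_true(all(c2 %in% c5))
  expect_true(all(c5 %in% c9))
  expect_lt(length(c2), length(c9))
})

test_that("edge-biased symptoms stay inside the boundary band", {
  set.seed(8)
  leaf <- generateLeaf(leafSpec())
  g <- maskGrid(leaf$mask)
  # independent band oracle: erode with the documented disk radius
  w <- max(1L, round(0.15 * sqrt(sum(g) / pi)))
  kern <- outer(-w:w, -w:w, function(i, j) (i^2 + j^2) <= w^2) + 0
  band <- which(g > 0 & EBImage::erode(g, kern) == 0)
  for (style in c("dark-spot", "mosaic-mottle", "curl-yellowing-tint")) {
    set.seed(9)
    dis <- applyDisease(leaf$image, leaf$mask,
                        diseaseStyle(style, edgeBias = 1))
    ch <- which(apply(dis != leaf$image, c(1, 2), any))
    expect_true(all(ch %in% band))
  }
})

test_that("dataset generation writes both layouts and a faithful manifest", {
  out <- file.path(tempdir(), "lds-test")
  unlink(out, recursive = TRUE)
  cfg <- list(
    healthy = list(count = 4L, style = NULL),
    spotty = list(count = 3L, style = diseaseStyle("dark-spot")),
    blight = list(count = 2L, style = diseaseStyle("edge-blight",
                                                   edgeBias = 1)),
    ghost = list(count = 0L, style = NULL))
  expect_message(
    manifest <- generateDataset(cfg, out, spec = leafSpec(size = 24),
                                seed = 11),
    "count 0")
  expect_null(manifest$classes$ghost)
  expect_equal(unlist(manifest$classes), c(healthy = 4, spotty = 3,
                                           blight = 2))
  # files on disk match the manifest census
  for (nm in names(manifest$files)) {
    expect_true(all(file.exists(file.path(out, manifest$files[[nm]]))))
    expect_length(manifest$files[[nm]], manifest$classes[[nm]])
  }
  expect_equal(length(list.files(file.path(out, "images"))), 9)
  # diseased classes populate the paired layout with matched names
  expect_equal(list.files(file.path(out, "domainX")),
               list.files(file.path(out, "domainY")))
  expect_equal(length(list.files(file.path(out, "domainY"))), 5)
  # manifest round-trips through its file form
  m2 <- readManifest(file.path(out, "manifest.json"))
  expect_equal(m2$classes, lapply(manifest$classes, as.integer))
  expect_equal(m2$files, lapply(manifest$files, as.character))
  # reruns under the same seed are byte-identical
  out2 <- file.path(tempdir(), "lds-test2")
  unlink(out2, recursive = TRUE)
  suppressMessages(generateDataset(cfg, out2, spec = leafSpec(size = 24),
                                   seed = 11))
  expect_identical(readLines(file.path(out, "manifest.json")),
                   readLines(file.path(out2, "manifest.json")))
  f <- manifest$files$spotty[1]
  expect_identical(png::readPNG(file.path(out, f)),
                   png::readPNG(file.path(out2, f)))
  unlink(c(out, out2), recursive = TRUE)
})

test_that("default dataset palette mirrors the emulated class ratios", {
  cfg <- defaultDatasetConfig()
  counts <- vapply(cfg, function(x) x$count, numeric(1))
  tomato <- counts[grep("^tomato", names(counts))]
  expect_equal(unname(tomato[c("tomato_late_blight", "tomato_early_blight",
                               "tomato_bacterial_spot", "tomato_healthy")]),
               c(10, 8, 1, 12))
  expect_equal(unname(counts[c("grape_black_rot", "grape_healthy")]),
               c(5, 6))
})
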