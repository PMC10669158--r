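#' Noise schedule for a diffusion chain
#'
#' A \code{NoiseSchedule} holds the per-step noise variances \eqn{\beta_t}
#' of the forward Gaussian corruption chain together with the cumulative
#' signal-retention products \eqn{\bar\alpha_t = \prod_{s \le t} (1 - \beta_s)}
#' for \eqn{t = 1, \dots, T}. Timesteps are 1-based; \eqn{t = 0} denotes the
#' clean image and \eqn{\bar\alpha_0 = 1} by convention.
#'
#' @slot beta numeric vector of length \eqn{T}, each value in (0, 1).
#' @slot alphaBar numeric vector of length \eqn{T}, the running product of
#'   \code{1 - beta}; strictly decreasing and in (0, 1).
#'
#' @seealso [noiseSchedule()] for the validated constructor.
#' @exportClass NoiseSchedule
setClass("NoiseSchedule",
  representation(beta = "numeric", alphaBar = "numeric"))

setValidity("NoiseSchedule", function(object) {
  msg <- character(0)
  b <- object@beta
  ab <- object@alphaBar
  if (length(b) < 1L) msg <- c(msg, "schedule must have at least one step")
  if (length(b) != length(ab))
    msg <- c(msg, "beta and alphaBar must have equal length")
  if (any(!is.finite(b)) || any(b <= 0) || any(b >= 1))
    msg <- c(msg, "all beta values must lie in (0, 1)")
  if (length(b) == length(ab) && length(b) >= 1L) {
    ref <- cumprod(1 - b)
    if (max(abs(ref - ab)) > 1e-12)
      msg <- c(msg, "alphaBar must equal cumprod(1 - beta) to within 1e-12")
    if (any(diff(ab) >= 0))
      msg <- c(msg, "alphaBar must be strictly decreasing")
    if (any(ab <= 0) || any(ab >= 1))
      msg <- c(msg, "alphaBar must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Binary raster mask with an explicit convention tag
#'
#' A \code{BinaryMask} is a height x width \{0,1\} raster plus a tag saying
#' what the 1s mean. Two conventions circulate in mask-guided generation and
#' confusing them is a classic failure (it produces the "ghost leaf" artefact
#' when a whole-leaf instance mask is fed to an inpainter expecting a context
#' mask):
#' \describe{
#'   \item{\code{instance-marks-1}}{1 marks the object instance (a leaf);
#'     the usual segmentation-mask convention.}
#'   \item{\code{known-marks-1}}{1 marks pixels kept as known context during
#'     inpainting; 0 marks pixels to regenerate.}
#' }
#' [invertMask()] flips both the grid and the tag; composition operations
#' check the tag and refuse the wrong one.
#'
#' @slot grid numeric or integer matrix over \{0, 1\}.
#' @slot convention single string, one of \code{"instance-marks-1"},
#'   \code{"known-marks-1"}.
#'
#' @seealso [binaryMask()], [invertMask()], [dilateMask()], [iou()]
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(grid = "matrix", convention = "character"))

.maskConventions <- c("instance-marks-1", "known-marks-1")

setValidity("BinaryMask", function(object) {
  msg <- character(0)
  g <- object@grid
  if (!is.numeric(g)) msg <- c(msg, "grid must be numeric")
  else if (!all(g == 0 | g == 1)) msg <- c(msg, "grid values must be 0 or 1")
  if (length(object@convention) != 1L ||
      !object@convention %in% .maskConventions)
    msg <- c(msg, sprintf("convention must be one of: %s",
                          paste(.maskConventions, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Parametric description of a synthetic leaf
#'
#' Controls the procedural single-leaf renderer: an elliptical blade with a
#' tapered tip, a low-frequency noisy margin, a green base palette with faint
#' venation, composited on a uniform background -- the controlled-conditions,
#' single-leaf-per-frame imaging style of curated leaf-disease collections.
#'
#' @slot size integer raster side length (square images).
#' @slot axes numeric length-2, ellipse semi-axes as fractions of \code{size}.
#' @slot taper numeric in [0, 1), how strongly the blade narrows at the tip.
#' @slot marginAmplitude numeric >= 0, relative amplitude of the smooth
#'   margin perturbation (kept small so the contour stays simple).
#' @slot leafColor numeric length-3 RGB in [0, 1], base blade colour.
#' @slot backgroundColor numeric length-3 RGB in [0, 1].
#' @slot venationDensity integer >= 0, number of secondary veins per side.
#' @slot occupancy numeric length-2, admissible range of leaf-area fraction.
#'
#' @seealso [leafSpec()], [generateLeaf()]
#' @exportClass LeafSpec
setClass("LeafSpec",
  representation(size = "integer", axes = "numeric", taper = "numeric",
                 marginAmplitude = "numeric", leafColor = "numeric",
                 backgroundColor = "numeric", venationDensity = "integer",
                 occupancy = "numeric"))

setValidity("LeafSpec", function(object) {
  msg <- character(0)
  if (object@size < 8L) msg <- c(msg, "size must be at least 8 pixels")
  if (length(object@axes) != 2L || any(object@axes <= 0) ||
      any(object@axes > 0.5))
    msg <- c(msg, "axes must be two positive fractions of size, each <= 0.5")
  if (object@taper < 0 || object@taper >= 1)
    msg <- c(msg, "taper must lie in [0, 1)")
  if (object@marginAmplitude < 0 || object@marginAmplitude > 0.3)
    msg <- c(msg, "marginAmplitude must lie in [0, 0.3]")
  for (nm in c("leafColor", "backgroundColor")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(v < 0) || any(v > 1))
      msg <- c(msg, sprintf("%s must be 3 RGB values in [0, 1]", nm))
  }
  occ <- object@occupancy
  if (length(occ) != 2L || occ[1] >= occ[2] || occ[1] < 0.05 || occ[2] > 0.95)
    msg <- c(msg, "occupancy must be an increasing range inside [0.05, 0.95]")
  if (length(msg)) msg else TRUE
})

.diseaseStyles <- c("concentric-ring-blight", "dark-spot", "edge-blight",
                    "mosaic-mottle", "curl-yellowing-tint")

#' Parametric disease-symptom style
#'
#' Describes a stylised symptom renderer applied on top of a healthy leaf:
#' concentric ring lesions, dark sunken spots, boundary blight, mosaic
#' mottling or a yellowing tint. Symptoms are rendered only on leaf pixels;
#' \code{edgeBias = 1} confines them to a band along the leaf boundary
#' (mimicking diseases that attack leaf edges first).
#'
#' @slot style single string, one of \code{"concentric-ring-blight"},
#'   \code{"dark-spot"}, \code{"edge-blight"}, \code{"mosaic-mottle"},
#'   \code{"curl-yellowing-tint"}.
#' @slot intensity numeric in [0, 1]; 0 leaves the image untouched and the
#'   symptom-pixel count grows monotonically with it.
#' @slot maxSpots integer >= 1, lesion-count ceiling for spotting styles.
#' @slot spotRadius numeric length-2, lesion radius range in pixels.
#' @slot edgeBias numeric in [0, 1], weight pulling lesions to the boundary.
#'
#' @seealso [diseaseStyle()], [applyDisease()]
#' @exportClass DiseaseStyle
setClass("DiseaseStyle",
  representation(style = "character", intensity = "numeric",
                 maxSpots = "integer", spotRadius = "numeric",
                 edgeBias = "numeric"))

setValidity("DiseaseStyle", function(object) {
  msg <- character(0)
  if (length(object@style) != 1L || !object@style %in% .diseaseStyles)
    msg <- c(msg, sprintf("style must be one of: %s",
                          paste(.diseaseStyles, collapse = ", ")))
  if (object@intensity < 0 || object@intensity > 1)
    msg <- c(msg, "intensity must lie in [0, 1]")
  if (object@maxSpots < 1L) msg <- c(msg, "maxSpots must be >= 1")
  if (length(object@spotRadius) != 2L || any(object@spotRadius <= 0) ||
      object@spotRadius[1] > object@spotRadius[2])
    msg <- c(msg, "spotRadius must be an increasing positive range")
  if (object@edgeBias < 0 || object@edgeBias > 1)
    msg <- c(msg, "edgeBias must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Small trainable noise-prediction network
#'
#' A one-hidden-layer perceptron implementing the epsilon-model contract of
#' the reverse diffusion process: given a noised image \eqn{x_t} (flattened,
#' in the [-1, 1] diffusion range) and the timestep \eqn{t}, predict the
#' cumulative standard-normal noise that produced \eqn{x_t} from \eqn{x_0}.
#' The timestep enters as a small vector of smooth embeddings of \eqn{t/T}
#' concatenated to the flattened image. Deliberately tiny so that training
#' and sampling run on one CPU; the full-scale counterpart in the literature
#' is a U-Net with attention, which this class does not attempt to be.
#'
#' @slot W1,b1 first-layer weights (inputDim + 4) x hidden and bias.
#' @slot W2,b2 output-layer weights hidden x inputDim and bias.
#' @slot skip learned per-timestep scalar gate on the input: the prediction
#'   is \code{skip[t] * x + MLP(x, t)}, letting the narrow network carry
#'   the near-identity component of the noise map without spending rank on
#'   it.
#' @slot inputDim integer, flattened image dimension.
#' @slot hidden integer, hidden width.
#' @slot nSteps integer, the schedule length T the model was built for
#'   (used to normalise the timestep embedding).
#'
#' @seealso [epsilonMLP()], [trainEpsilonModel()], [predictNoise()]
#' @exportClass EpsilonMLP
setClass("EpsilonMLP",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 skip = "numeric", inputDim = "integer", hidden = "integer",
                 nSteps = "integer"))

setValidity("EpsilonMLP", function(object) {
  d <- object@inputDim; h <- object@hidden
  msg <- character(0)
  if (!identical(dim(object@W1), c(d + 4L, h)))
    msg <- c(msg, "W1 must be (inputDim + 4) x hidden")
  if (length(object@b1) != h) msg <- c(msg, "b1 length must equal hidden")
  if (!identical(dim(object@W2), c(h, d)))
    msg <- c(msg, "W2 must be hidden x inputDim")
  if (length(object@b2) != d) msg <- c(msg, "b2 length must equal inputDim")
  if (length(object@skip) != object@nSteps)
    msg <- c(msg, "skip length must equal nSteps")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (length(msg)) msg else TRUE
})
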