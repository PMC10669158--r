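#' @title Generics for leafdiffuse classes
#' @name leafdiffuse-generics
#' @keywords internal
NULL

#' Number of diffusion steps of a schedule or model
#' @param x a [NoiseSchedule-class] or [EpsilonMLP-class].
#' @return integer step count T.
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' Per-step noise variances of a schedule
#' @param x a [NoiseSchedule-class].
#' @return numeric vector beta_1..beta_T.
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' Cumulative signal-retention products of a schedule
#' @param x a [NoiseSchedule-class].
#' @param t optional timestep(s) in 0..T; t = 0 returns 1 (clean image).
#' @return numeric vector of alpha-bar values.
#' @export
setGeneric("alphaBars", function(x, t) standardGeneric("alphaBars"))

#' Raster grid of a mask
#' @param x a [BinaryMask-class].
#' @return numeric matrix over \{0, 1\}.
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' Convention tag of a mask
#' @param x a [BinaryMask-class].
#' @return \code{"instance-marks-1"} or \code{"known-marks-1"}.
#' @export
setGeneric("maskConvention", function(x) standardGeneric("maskConvention"))

#' Complement a mask and swap its convention tag
#'
#' Inversion is the bridge between segmentation masks (instance-marks-1)
#' and inpainting context masks (known-marks-1): the grid is complemented
#' and the tag flipped, so double inversion is the identity including the
#' tag.
#'
#' @param x a [BinaryMask-class].
#' @return a [BinaryMask-class] with complemented grid and swapped tag.
#' @export
setGeneric("invertMask", function(x) standardGeneric("invertMask"))

#' Morphological dilation of a mask
#'
#' Dilation with a discrete disk structuring element
#' \eqn{\{(i, j) : i^2 + j^2 \le r^2\}} (radius 1 gives the 5-pixel plus
#' shape). Growing a leaf mask this way leaves a context band along the
#' boundary, the standard fix for inpainters that otherwise receive no
#' usable context from a whole-leaf mask.
#'
#' @param x a [BinaryMask-class].
#' @param radius nonnegative integer radius in pixels; 0 is the identity.
#' @return a [BinaryMask-class] with the same convention tag.
#' @export
setGeneric("dilateMask", function(x, radius) standardGeneric("dilateMask"))

#' Predict the cumulative noise in a diffused image
#'
#' The epsilon-model contract of reverse diffusion: given \eqn{x_t} (in the
#' [-1, 1] diffusion range) and the timestep \eqn{t}, return an estimate of
#' the standard-normal noise epsilon such that
#' \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1 - \bar\alpha_t} \epsilon}.
#' Plain R closures \code{function(x, t)} satisfy the same contract wherever
#' an epsilon model is accepted.
#'
#' @param model an [EpsilonMLP-class] (or any object with a method).
#' @param x numeric array or vector, the diffused state \eqn{x_t}.
#' @param t integer timestep in 1..T.
#' @return array of the same shape as \code{x}.
#' @export
setGeneric("predictNoise", function(model, x, t) standardGeneric("predictNoise"))
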