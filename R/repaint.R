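#' Sample the known region from the forward marginal
#'
#' During mask-conditioned reverse sampling, pixels that are known from the
#' input image are not denoised at all: at each step the known region is
#' drawn afresh from the forward marginal of the untouched image,
#' \eqn{x^{known}_{t-1} = \sqrt{\bar\alpha_{t-1}}\, x_0 +
#' \sqrt{1-\bar\alpha_{t-1}}\, z}, \eqn{z \sim N(0, I)}
#' (with \eqn{\bar\alpha_0 = 1}, so the step to \eqn{t = 0} returns
#' \eqn{x_0} noiselessly).
#'
#' @param x0 numeric array, the ground-truth image in diffusion range.
#' @param t integer timestep in 1..T (the returned state is at t - 1).
#' @param schedule a [NoiseSchedule-class].
#' @return array, the known-region state at t - 1.
#' @export
sampleKnown <- function(x0, t, schedule) {
  t <- .checkStep(t, schedule)
  ab <- alphaBars(schedule, t - 1L)
  z <- stats::rnorm(length(x0))
  if (!is.null(dim(x0))) dim(z) <- dim(x0)
  sqrt(ab) * x0 + sqrt(1 - ab) * z
}

#' One mask-conditioned reverse step
#'
#' Composes the two branches of the conditioned reverse process by the
#' known-region mask: \eqn{x_{t-1} = m \odot x^{known}_{t-1} +
#' (1 - m) \odot x^{unknown}_{t-1}}, where the known branch is the forward
#' marginal of the ground truth ([sampleKnown()]) and the unknown branch is
#' the learned reverse step ([pSample()]). Pixels with \eqn{m = 1} carry no
#' information from the model. The two branches draw independent noise.
#'
#' @param model epsilon model.
#' @param xt numeric array, current state at t (diffusion range).
#' @param t integer timestep in 1..T.
#' @param x0 ground-truth image in diffusion range, same shape as
#'   \code{xt}.
#' @param mask a [BinaryMask-class] with convention \code{known-marks-1};
#'   any other tag is refused.
#' @param schedule a [NoiseSchedule-class].
#' @return array, composed state at t - 1.
#' @export
repaintReverseStep <- function(model, xt, t, x0, mask, schedule) {
  stopifnot(is(mask, "BinaryMask"))
  .assertConvention(mask, "known-marks-1")
  m <- maskGrid(mask)
  if (!identical(dim(xt), dim(x0)))
    stop("'xt' and 'x0' must share a shape", call. = FALSE)
  dm <- dim(xt)
  if (!identical(as.integer(dm[1:2]), as.integer(dim(m))))
    stop("mask raster does not match the image raster", call. = FALSE)
  if (length(dm) == 3L) m <- array(m, dim = dm)  # broadcast over channels
  # skip a branch entirely when the mask is extreme, so that the RNG
  # consumption (hence the trajectory under a fixed seed) matches the
  # corresponding unconditional or pure-forward sampler exactly
  if (all(m == 1)) return(sampleKnown(x0, t, schedule))
  if (all(m == 0)) return(pSample(model, xt, t, schedule))
  known <- sampleKnown(x0, t, schedule)
  unknown <- pSample(model, xt, t, schedule)
  m * known + (1 - m) * unknown
}

#' Re-diffuse a composed sample one step toward noise
#'
#' One application of the forward kernel ([qSampleStep()]) to the composed
#' state, moving it from t - 1 back to t. Repeatedly descending and
#' re-diffusing lets the unknown region absorb information from the known
#' region, harmonising the two (the resampling trick).
#'
#' @param xPrev numeric array, state at t - 1.
#' @param t integer timestep in 1..T.
#' @param schedule a [NoiseSchedule-class].
#' @return array, state at t.
#' @export
rediffuse <- function(xPrev, t, schedule) qSampleStep(xPrev, t, schedule)

#' Inpaint the unknown region of an image with a diffusion model
#'
#' Runs the full mask-conditioned reverse chain from pure noise: at every
#' step the known region is resampled from the input's forward marginal and
#' the unknown region from the learned reverse process, composed by the
#' mask. At each jump boundary the chain additionally re-diffuses
#' \code{jumpLength} steps and re-descends, \code{nResamples} times in
#' total, to harmonise the generated content with its context;
#' \code{jumpLength = 1, nResamples = 1} is exactly the plain conditioned
#' chain. At emission the known region is hard-copied from the input, so
#' known pixels are returned bit-identically.
#'
#' A whole-leaf mask that leaves (almost) no known context invites the
#' "ghost leaf" failure, where the sampler invents a second leaf inside a
#' background-filled outline; a warning is raised when the unknown fraction
#' exceeds \code{ghostLeafThreshold}.
#'
#' @param model epsilon model.
#' @param image numeric array in the [0, 1] I/O range.
#' @param mask [BinaryMask-class], convention \code{known-marks-1}.
#' @param schedule a [NoiseSchedule-class].
#' @param jumpLength integer >= 1, steps to re-diffuse at each jump point
#'   (default 10).
#' @param nResamples integer >= 1, passes per jump point (default 10; 1
#'   disables resampling).
#' @param ghostLeafThreshold warn when the unknown-pixel fraction exceeds
#'   this (default 0.98).
#' @return inpainted image in [0, 1], same shape as \code{image}.
#' @export
inpaint <- function(model, image, mask, schedule, jumpLength = 10L,
                    nResamples = 10L, ghostLeafThreshold = 0.98) {
  stopifnot(is(mask, "BinaryMask"))
  .assertConvention(mask, "known-marks-1")
  if (jumpLength < 1L || nResamples < 1L)
    stop("'jumpLength' and 'nResamples' must be >= 1", call. = FALSE)
  if (any(image < 0) || any(image > 1))
    stop("'image' must be in the [0, 1] I/O range", call. = FALSE)
  m <- maskGrid(mask)
  unknownFrac <- 1 - mean(m)
  if (unknownFrac > ghostLeafThreshold)
    warning(sprintf(paste(
      "unknown region covers %.1f%% of the raster; with so little known",
      "context the sampler may invent a detached 'ghost leaf'"),
      100 * unknownFrac), call. = FALSE)
  x0 <- toDiffusionRange(image)
  T <- nSteps(schedule)
  x <- array(stats::rnorm(length(x0)), dim = dim(x0))

  descend <- function(x, from, to) {
    for (t in seq(from, to)) {
      x <- tryCatch(repaintReverseStep(model, x, t, x0, mask, schedule),
                    error = function(e) stop(sprintf(
                      "conditioned reverse chain failed at t = %d: %s",
                      t, conditionMessage(e)), call. = FALSE))
    }
    x
  }

  t <- T
  while (t >= 1L) {
    lo <- max(t - jumpLength + 1L, 1L)
    x <- descend(x, t, lo)                       # now a state at lo - 1
    if (nResamples > 1L && lo > 1L) {
      for (r in seq_len(nResamples - 1L)) {
        for (tt in seq(lo, t)) x <- rediffuse(x, tt, schedule)
        x <- descend(x, t, lo)
      }
    }
    t <- lo - 1L
  }
  out <- fromDiffusionRange(x)
  mArr <- if (length(dim(out)) == 3L) array(m, dim = dim(out)) else m
  mArr * image + (1 - mArr) * out
}
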