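#' Map images between I/O and diffusion value ranges
#'
#' Images enter and leave the package in [0, 1]; the diffusion chain
#' operates on [-1, 1]. \code{toDiffusionRange} applies \eqn{2x - 1};
#' \code{fromDiffusionRange} inverts it and (by default) clips to [0, 1],
#' so clipping happens only at emission.
#'
#' @param x numeric array.
#' @param clip logical, clip the [0, 1] result (default TRUE).
#' @return array of the same shape.
#' @export
toDiffusionRange <- function(x) 2 * x - 1

#' @rdname toDiffusionRange
#' @export
fromDiffusionRange <- function(x, clip = TRUE) {
  y <- (x + 1) / 2
  if (clip) y <- pmin(pmax(y, 0), 1)
  y
}

# Evaluate an epsilon model (closure or EpsilonMLP) with contract checks.
.callEps <- function(model, x, t) {
  eps <- if (is.function(model)) model(x, t) else predictNoise(model, x, t)
  if (length(eps) != length(x))
    stop(sprintf("epsilon model output length %d does not match input %d",
                 length(eps), length(x)), call. = FALSE)
  if (any(!is.finite(eps)))
    stop(sprintf("epsilon model produced non-finite values at timestep t = %d",
                 t), call. = FALSE)
  if (!is.null(dim(x))) dim(eps) <- dim(x)
  eps
}

#' One forward corruption step of the diffusion chain
#'
#' Draws \eqn{x_t \mid x_{t-1} \sim N(\sqrt{1-\beta_t}\, x_{t-1},
#' \beta_t I)}: the previous state is shrunk by \eqn{\sqrt{1-\beta_t}} and
#' perturbed with fresh Gaussian noise of variance \eqn{\beta_t}. Uses R's
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param xPrev numeric array, state at t - 1 (diffusion range).
#' @param t integer timestep in 1..T.
#' @param schedule a [NoiseSchedule-class].
#' @return array of the same shape, state at t.
#' @seealso [qSample()] for the closed-form multi-step marginal.
#' @export
qSampleStep <- function(xPrev, t, schedule) {
  t <- .checkStep(t, schedule)
  b <- betas(schedule)[t]
  z <- array(stats::rnorm(length(xPrev)), dim = if (is.null(dim(xPrev)))
    length(xPrev) else dim(xPrev))
  out <- sqrt(1 - b) * xPrev + sqrt(b) * z
  if (is.null(dim(xPrev))) as.vector(out) else out
}

#' Closed-form forward marginal: corrupt a clean state in one jump
#'
#' By independence of the per-step noise, iterating the forward chain to
#' step \eqn{t} is equivalent to the single draw
#' \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}
#' with \eqn{\epsilon \sim N(0, I)}. Pass \code{noise} explicitly to reuse
#' a draw (as the training objective does); otherwise fresh noise is drawn
#' from the global RNG.
#'
#' @param x0 numeric array, clean state (diffusion range).
#' @param t integer timestep in 1..T.
#' @param schedule a [NoiseSchedule-class].
#' @param noise optional array of unit-Gaussian noise, same shape as
#'   \code{x0}.
#' @return array of the same shape, state at t.
#' @export
qSample <- function(x0, t, schedule, noise = NULL) {
  t <- .checkStep(t, schedule)
  if (is.null(noise)) {
    noise <- stats::rnorm(length(x0))
    if (!is.null(dim(x0))) dim(noise) <- dim(x0)
  } else if (length(noise) != length(x0)) {
    stop("'noise' must have the same shape as 'x0'", call. = FALSE)
  }
  ab <- alphaBars(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Invert the closed-form marginal given a noise estimate
#'
#' Algebraic inversion of the single-jump corruption: given \eqn{x_t} and a
#' noise prediction \eqn{\hat\epsilon}, returns
#' \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon) /
#' \sqrt{\bar\alpha_t}}. Exact when \eqn{\hat\epsilon} equals the noise
#' actually injected.
#'
#' @param model epsilon model (closure \code{function(x, t)} or
#'   [EpsilonMLP-class]).
#' @param xt numeric array, state at t.
#' @param t integer timestep in 1..T.
#' @param schedule a [NoiseSchedule-class].
#' @return array, the denoised estimate of \eqn{x_0}.
#' @export
predictX0 <- function(model, xt, t, schedule) {
  t <- .checkStep(t, schedule)
  ab <- alphaBars(schedule, t)
  eps <- .callEps(model, xt, t)
  (xt - sqrt(1 - ab) * eps) / sqrt(ab)
}

#' One learned reverse step of the diffusion chain
#'
#' Draws \eqn{x_{t-1} \sim N(\mu_\theta(x_t, t), \Sigma_\theta(x_t, t))}.
#' The mean is computed from the model's noise prediction by the standard
#' posterior-mean formula
#' \eqn{\mu_\theta = (x_t - \beta_t \hat\epsilon / \sqrt{1-\bar\alpha_t}) /
#' \sqrt{1-\beta_t}}, and the variance is the fixed forward-posterior
#' variance \eqn{\tilde\beta_t = \beta_t (1-\bar\alpha_{t-1}) /
#' (1-\bar\alpha_t)} (a learned variance head is not parameterised here;
#' \eqn{\tilde\beta_1 = 0}, so the final step is deterministic). With
#' \code{method = "ddim"} the step is instead the deterministic update
#' \eqn{x_{t-1} = \sqrt{\bar\alpha_{t-1}} \hat x_0 +
#' \sqrt{1-\bar\alpha_{t-1}} \hat\epsilon}.
#'
#' @inheritParams predictX0
#' @param method \code{"ddpm"} (stochastic ancestral step, default) or
#'   \code{"ddim"} (deterministic).
#' @return array, state at t - 1.
#' @export
pSample <- function(model, xt, t, schedule, method = c("ddpm", "ddim")) {
  method <- match.arg(method)
  t <- .checkStep(t, schedule)
  eps <- .callEps(model, xt, t)
  abT <- alphaBars(schedule, t)
  abP <- alphaBars(schedule, t - 1L)
  if (method == "ddim") {
    x0hat <- (xt - sqrt(1 - abT) * eps) / sqrt(abT)
    return(sqrt(abP) * x0hat + sqrt(1 - abP) * eps)
  }
  b <- betas(schedule)[t]
  mu <- (xt - b / sqrt(1 - abT) * eps) / sqrt(1 - b)
  varPost <- b * (1 - abP) / (1 - abT)
  if (t > 1L && varPost > 0) {
    z <- stats::rnorm(length(xt))
    if (!is.null(dim(xt))) dim(z) <- dim(xt)
    mu <- mu + sqrt(varPost) * z
  }
  mu
}

#' Simplified denoising training objective
#'
#' The noise-matching loss \eqn{E_{t, x_0, \epsilon}
#' \|\epsilon - \epsilon_\theta(x_t, t)\|^2} with
#' \eqn{x_t} built by the closed-form marginal from \code{x0} and
#' \code{noise}. The squared error is averaged over dimensions and over the
#' batch, so a model predicting zero on unit-variance noise scores about 1.
#' Zero iff the model reproduces every injected noise exactly.
#'
#' @param model epsilon model.
#' @param x0 clean batch: a list of arrays, or a single array.
#' @param t integer timestep(s), one per batch element (recycled if scalar).
#' @param noise unit-Gaussian batch matching \code{x0}'s shapes.
#' @param schedule a [NoiseSchedule-class].
#' @return nonnegative scalar.
#' @export
simpleLoss <- function(model, x0, t, noise, schedule) {
  if (!is.list(x0)) { x0 <- list(x0); noise <- list(noise) }
  if (length(noise) != length(x0))
    stop("'noise' batch must match 'x0' batch", call. = FALSE)
  t <- rep_len(as.integer(t), length(x0))
  errs <- vapply(seq_along(x0), function(i) {
    xt <- qSample(x0[[i]], t[i], schedule, noise = noise[[i]])
    eps <- .callEps(model, xt, t[i])
    mean((noise[[i]] - eps)^2)
  }, numeric(1))
  mean(errs)
}

#' Generate a sample by running the full reverse chain
#'
#' Starts from unit Gaussian noise \eqn{x_T} and applies [pSample()] for
#' \eqn{t = T, \dots, 1}; the result is clipped to the [-1, 1] diffusion
#' range. Use [fromDiffusionRange()] to obtain a [0, 1] image.
#'
#' @param model epsilon model.
#' @param shape integer vector, the raster dimensions to generate.
#' @param schedule a [NoiseSchedule-class].
#' @param method sampler passed to [pSample()].
#' @return array of dimension \code{shape} in [-1, 1].
#' @export
sampleUnconditional <- function(model, shape, schedule,
                                method = c("ddpm", "ddim")) {
  method <- match.arg(method)
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  for (t in rev(seq_len(nSteps(schedule)))) {
    x <- tryCatch(pSample(model, x, t, schedule, method = method),
                  error = function(e) stop(sprintf(
                    "reverse chain failed at timestep t = %d: %s",
                    t, conditionMessage(e)), call. = FALSE))
  }
  pmin(pmax(x, -1), 1)
}
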