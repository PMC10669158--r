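#' Build a diffusion noise schedule
#'
#' Constructs the variance schedule \eqn{\beta_1, \dots, \beta_T} of the
#' forward corruption chain and its cumulative products
#' \eqn{\bar\alpha_t = \prod_{s \le t}(1 - \beta_s)}. Two shapes are
#' offered: \code{"linear"} interpolates \eqn{\beta_t} evenly from
#' \code{betaMin} to \code{betaMax}; \code{"cosine"} derives \eqn{\beta_t}
#' from the squared-cosine \eqn{\bar\alpha} profile (offset 0.008, betas
#' capped at 0.999), which corrupts more gently at early steps. The
#' full-scale profile of [defaultRunConfig()] uses \code{steps = 4000};
#' small chains (25--100 steps) are entirely adequate for the CPU-scale
#' models this package trains.
#'
#' When the endpoints are left unset they default to the standard
#' 1e-4 -> 0.02 range \emph{rescaled by 1000/T} (capped at 0.999), so the
#' total corruption \eqn{\bar\alpha_T \approx e^{-10}} is preserved for any
#' chain length and \eqn{x_T} is effectively white noise; endpoints passed
#' explicitly are used verbatim.
#'
#' @param steps positive integer, the chain length T.
#' @param kind \code{"linear"} (default) or \code{"cosine"}.
#' @param betaMin,betaMax linear-schedule endpoints, each in (0, 1) with
#'   \code{betaMin <= betaMax}; default as described above. Ignored by the
#'   cosine schedule.
#' @return a [NoiseSchedule-class].
#' @examples
#' sch <- noiseSchedule(4000)
#' nSteps(sch)
#' alphaBars(noiseSchedule(3, betaMin = 0.1, betaMax = 0.3))  # .9 .72 .504
#' @export
noiseSchedule <- function(steps, kind = c("linear", "cosine"),
                          betaMin = NULL, betaMax = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(steps) || length(steps) != 1L || is.na(steps) || steps < 1 ||
      steps != round(steps))
    stop("'steps' must be a positive integer", call. = FALSE)
  steps <- as.integer(steps)
  if (is.null(betaMin)) betaMin <- min(1e-4 * 1000 / steps, 0.999)
  if (is.null(betaMax)) betaMax <- min(0.02 * 1000 / steps, 0.999)
  if (kind == "linear") {
    if (!is.finite(betaMin) || !is.finite(betaMax) ||
        betaMin <= 0 || betaMax >= 1 || betaMin > betaMax)
      stop("beta bounds must satisfy 0 < betaMin <= betaMax < 1",
           call. = FALSE)
    beta <- if (steps == 1L) betaMin else
      seq(betaMin, betaMax, length.out = steps)
  } else {
    # squared-cosine alpha-bar profile; betas recovered from its ratios
    s <- 0.008
    f <- function(u) cos((u / steps + s) / (1 + s) * pi / 2)^2
    ab <- f(seq_len(steps)) / f(0)
    beta <- pmin(1 - ab / c(1, ab[-steps]), 0.999)
  }
  new("NoiseSchedule", beta = beta, alphaBar = cumprod(1 - beta))
}

#' @rdname nSteps
#' @export
setMethod("nSteps", "NoiseSchedule", function(x) length(x@beta))

#' @rdname betas
#' @export
setMethod("betas", "NoiseSchedule", function(x) x@beta)

#' @rdname alphaBars
#' @export
setMethod("alphaBars", "NoiseSchedule", function(x, t) {
  if (missing(t)) return(x@alphaBar)
  if (any(t < 0 | t > length(x@beta)))
    stop("timestep out of range 0..T", call. = FALSE)
  c(1, x@alphaBar)[t + 1L]
})

setMethod("show", "NoiseSchedule", function(object) {
  T <- length(object@beta)
  cat(sprintf("NoiseSchedule with %d steps\n", T))
  cat(sprintf("  beta:      %.3g .. %.3g\n", object@beta[1], object@beta[T]))
  cat(sprintf("  alphaBar:  %.4g .. %.4g\n",
              object@alphaBar[1], object@alphaBar[T]))
})

# internal guard used by every stepper
.checkStep <- function(t, schedule) {
  T <- nSteps(schedule)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t != round(t) ||
      t < 1 || t > T)
    stop(sprintf("timestep t = %s out of range 1..%d", format(t), T),
         call. = FALSE)
  as.integer(t)
}
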