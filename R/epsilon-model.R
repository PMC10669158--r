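#' Construct a small trainable noise-prediction MLP
#'
#' Builds an [EpsilonMLP-class] with seeded Gaussian initialisation
#' (variance 1/fan-in). The flattened image is concatenated with four
#' smooth embeddings of the normalised timestep \eqn{u = t/T}:
#' \eqn{(u, \sin \pi u, \cos \pi u, u^2)}. Parameter count is
#' \code{(inputDim + 4) * hidden + hidden + hidden * inputDim + inputDim};
#' the defaults for a 16 x 16 RGB raster give just under 50k parameters.
#'
#' The prediction is \code{skip[t] * x + MLP(x, t)}: a learned
#' per-timestep scalar gate carries the near-identity component of the
#' noise map (at late timesteps the state is mostly noise, so the identity
#' is the dominant term), and the narrow network models the residual
#' structure.
#'
#' @param inputDim integer, flattened image dimension (e.g. 16*16*3).
#' @param hidden integer hidden width (default 30).
#' @param nSteps integer, schedule length T the model will be used with.
#' @return an untrained [EpsilonMLP-class].
#' @seealso [trainEpsilonModel()], [predictNoise()], [nParams()]
#' @export
epsilonMLP <- function(inputDim, hidden = 30L, nSteps = 50L) {
  inputDim <- as.integer(inputDim); hidden <- as.integer(hidden)
  nSteps <- as.integer(nSteps)
  nin <- inputDim + 4L
  new("EpsilonMLP",
      W1 = matrix(stats::rnorm(nin * hidden, sd = 1 / sqrt(nin)), nin, hidden),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(hidden * inputDim, sd = 1 / sqrt(hidden)),
                  hidden, inputDim),
      b2 = numeric(inputDim),
      skip = rep(1, nSteps),
      inputDim = inputDim, hidden = hidden, nSteps = nSteps)
}

#' Number of trainable parameters
#' @param model an [EpsilonMLP-class].
#' @return integer parameter count.
#' @export
nParams <- function(model) {
  stopifnot(is(model, "EpsilonMLP"))
  length(model@W1) + length(model@b1) + length(model@W2) +
    length(model@b2) + length(model@skip)
}

#' @rdname nSteps
#' @export
setMethod("nSteps", "EpsilonMLP", function(x) x@nSteps)

setMethod("show", "EpsilonMLP", function(object) {
  cat(sprintf("EpsilonMLP: %d -> %d -> %d (%d parameters, T = %d)\n",
              object@inputDim + 4L, object@hidden, object@inputDim,
              nParams(object), object@nSteps))
})

.timeEmbed <- function(t, T) {
  u <- t / T
  cbind(u, sin(pi * u), cos(pi * u), u * u, deparse.level = 0)
}

# batched forward pass: X is n x inputDim, t is length-n; returns n x inputDim
.mlpForward <- function(model, X, t, keepHidden = FALSE) {
  Xin <- cbind(X, .timeEmbed(t, model@nSteps))
  H <- tanh(sweep(Xin %*% model@W1, 2, model@b1, "+"))
  E <- sweep(H %*% model@W2, 2, model@b2, "+") + model@skip[t] * X
  if (keepHidden) list(E = E, H = H, Xin = Xin) else E
}

#' @rdname predictNoise
#' @export
setMethod("predictNoise", "EpsilonMLP", function(model, x, t) {
  if (length(x) != model@inputDim)
    stop(sprintf("input length %d does not match model inputDim %d",
                 length(x), model@inputDim), call. = FALSE)
  e <- .mlpForward(model, matrix(as.vector(x), 1L), as.numeric(t))
  if (!is.null(dim(x))) dim(e) <- dim(x) else e <- as.vector(e)
  e
})

#' Train a noise-prediction MLP on a set of images
#'
#' Minimises the simplified denoising objective by stochastic gradient
#' descent with Adam: at each step a mini-batch of clean images is
#' corrupted to uniformly drawn timesteps via the closed-form forward
#' marginal, and the network's squared error against the injected noise is
#' back-propagated. Images are supplied in the [0, 1] I/O range and mapped
#' to [-1, 1] internally. Uses the global RNG; seed with [set.seed()].
#'
#' @param model an [EpsilonMLP-class] whose \code{inputDim} matches the
#'   flattened image size.
#' @param images list of numeric arrays in [0, 1], all of one shape.
#' @param schedule a [NoiseSchedule-class] with \code{nSteps(model)} steps.
#' @param steps integer, number of Adam updates (default 2000).
#' @param batchSize mini-batch size (default 16).
#' @param lr Adam learning rate (default 2e-3).
#' @return the trained [EpsilonMLP-class]; attribute \code{"lossTrace"}
#'   holds the per-step training loss.
#' @export
trainEpsilonModel <- function(model, images, schedule, steps = 2000L,
                              batchSize = 16L, lr = 2e-3) {
  stopifnot(is(model, "EpsilonMLP"), is.list(images), length(images) >= 1L)
  if (nSteps(schedule) != model@nSteps)
    stop("schedule length does not match the model's nSteps", call. = FALSE)
  d <- model@inputDim
  X0 <- t(vapply(images, function(im) {
    if (length(im) != d)
      stop("image size does not match model inputDim", call. = FALSE)
    toDiffusionRange(as.vector(im))
  }, numeric(d)))
  n <- nrow(X0); T <- model@nSteps
  ab <- alphaBars(schedule)

  W <- list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
            skip = model@skip)
  mA <- lapply(W, function(w) w * 0); vA <- mA
  b1a <- 0.9; b2a <- 0.999; epsA <- 1e-8
  trace <- numeric(steps)

  for (s in seq_len(steps)) {
    idx <- sample.int(n, batchSize, replace = batchSize > n)
    t <- sample.int(T, batchSize, replace = TRUE)
    eps <- matrix(stats::rnorm(batchSize * d), batchSize, d)
    Xt <- sqrt(ab[t]) * X0[idx, , drop = FALSE] + sqrt(1 - ab[t]) * eps

    Xin <- cbind(Xt, .timeEmbed(t, T))
    H <- tanh(sweep(Xin %*% W$W1, 2, W$b1, "+"))
    E <- sweep(H %*% W$W2, 2, W$b2, "+") + W$skip[t] * Xt
    diffE <- E - eps
    trace[s] <- mean(diffE^2)

    dE <- 2 * diffE / length(diffE)
    dH <- (dE %*% t(W$W2)) * (1 - H^2)
    dSkipRow <- rowSums(dE * Xt)
    dSkip <- numeric(T)
    for (bi in seq_along(t)) dSkip[t[bi]] <- dSkip[t[bi]] + dSkipRow[bi]
    g <- list(W1 = crossprod(Xin, dH), b1 = colSums(dH),
              W2 = crossprod(H, dE), b2 = colSums(dE), skip = dSkip)

    for (k in names(W)) {
      mA[[k]] <- b1a * mA[[k]] + (1 - b1a) * g[[k]]
      vA[[k]] <- b2a * vA[[k]] + (1 - b2a) * g[[k]]^2
      mh <- mA[[k]] / (1 - b1a^s); vh <- vA[[k]] / (1 - b2a^s)
      W[[k]] <- W[[k]] - lr * mh / (sqrt(vh) + epsA)
    }
  }
  model@W1 <- W$W1; model@b1 <- W$b1; model@W2 <- W$W2; model@b2 <- W$b2
  model@skip <- W$skip
  attr(model, "lossTrace") <- trace
  model
}
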