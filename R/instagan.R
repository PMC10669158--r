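#' Bundle a paired translation example
#'
#' An instance pair holds a healthy-domain image \code{x} with its list of
#' instance masks \code{a} and a disease-domain image \code{y} with masks
#' \code{b}. All masks share the image raster and use the
#' \code{instance-marks-1} convention.
#'
#' @param x,y numeric arrays (H x W x C or H x W) in [0, 1].
#' @param a,b nonempty lists of [BinaryMask-class] objects
#'   (instance-marks-1).
#' @return a validated list of class \code{"InstancePair"}.
#' @export
instancePair <- function(x, a, y, b) {
  checkMasks <- function(masks, img, nm) {
    if (!is.list(masks) || length(masks) < 1L)
      stop(sprintf("'%s' must be a nonempty list of masks", nm),
           call. = FALSE)
    for (m in masks) {
      stopifnot(is(m, "BinaryMask"))
      .assertConvention(m, "instance-marks-1")
      if (!identical(dim(maskGrid(m)), as.integer(dim(img)[1:2])) &&
          !identical(dim(maskGrid(m)), dim(img)[1:2]))
        stop(sprintf("mask raster does not match image '%s'", nm),
             call. = FALSE)
    }
  }
  checkMasks(a, x, "a"); checkMasks(b, y, "b")
  structure(list(x = x, a = a, y = y, b = b), class = "InstancePair")
}

#' Bundle the feature encoders of the translation networks
#'
#' @param fGX,fGA generator-side image and mask encoders; each a function
#'   returning a fixed-length numeric feature vector.
#' @param fDX,fDA discriminator-side counterparts.
#' @return a list of class \code{"FeatureEncoders"}.
#' @export
featureEncoders <- function(fGX, fGA, fDX = fGX, fDA = fGA) {
  stopifnot(is.function(fGX), is.function(fGA), is.function(fDX),
            is.function(fDA))
  structure(list(fGX = fGX, fGA = fGA, fDX = fDX, fDA = fDA),
            class = "FeatureEncoders")
}

.encodeContext <- function(x, a, fImg, fMask, instance = NULL) {
  if (!is.list(a) || length(a) < 1L)
    stop("instance mask list must be nonempty", call. = FALSE)
  grids <- lapply(a, function(m) if (is(m, "BinaryMask")) maskGrid(m) else m)
  maskSum <- Reduce(`+`, lapply(grids, fMask))
  joint <- c(fImg(x), maskSum)
  if (is.null(instance)) return(joint)
  if (instance < 1L || instance > length(a))
    stop("'instance' index out of range", call. = FALSE)
  c(joint, fMask(grids[[instance]]))
}

#' Permutation-invariant context encodings
#'
#' The generator represents an (image, mask-set) input as the image features
#' concatenated with the \emph{sum} of per-instance mask features -- a
#' permutation-invariant set encoding; the per-instance variant additionally
#' appends the features of the n-th mask so that each instance can be
#' translated individually. \code{encodeDiscriminatorContext} is the
#' discriminator-side analogue.
#'
#' @param x image array.
#' @param a nonempty list of instance masks ([BinaryMask-class] or plain
#'   0/1 matrices).
#' @param encoders a [featureEncoders()] bundle.
#' @param instance optional instance index n; when supplied the
#'   per-instance encoding is returned.
#' @return numeric feature vector.
#' @export
encodeGeneratorContext <- function(x, a, encoders, instance = NULL) {
  .encodeContext(x, a, encoders$fGX, encoders$fGA, instance)
}

#' @rdname encodeGeneratorContext
#' @export
encodeDiscriminatorContext <- function(x, a, encoders) {
  .encodeContext(x, a, encoders$fDX, encoders$fDA, NULL)
}

#' Least-squares adversarial loss
#'
#' The two-sided least-squares GAN objective: the discriminator is pushed
#' toward score 1 on real inputs and 0 on translated ones,
#' \eqn{(D(real) - 1)^2 + D(fake)^2}; the generator side targets 1 on its
#' outputs, \eqn{(D(fake) - 1)^2}. Scores are averaged within each term, so
#' per-domain contributions add when called once per domain.
#'
#' @param dReal numeric scores of the discriminator on real inputs (ignored
#'   for the generator side).
#' @param dFake numeric scores on translated inputs.
#' @param side \code{"discriminator"} (default) or \code{"generator"}.
#' @return nonnegative scalar.
#' @export
lsganLoss <- function(dReal, dFake, side = c("discriminator", "generator")) {
  side <- match.arg(side)
  if (side == "generator") return(mean((dFake - 1)^2))
  mean((dReal - 1)^2) + mean(dFake^2)
}

# generators are function(image, masks) -> list(image =, masks = list of
# plain 0/1 grids or BinaryMask); normalise the mask representation
.gApply <- function(G, image, masks) {
  grids <- lapply(masks, function(m) if (is(m, "BinaryMask")) maskGrid(m)
                  else m)
  out <- G(image, grids)
  if (!is.list(out) || !all(c("image", "masks") %in% names(out)))
    stop("generator must return list(image =, masks =)", call. = FALSE)
  out$masks <- lapply(out$masks, function(m) if (is(m, "BinaryMask"))
    maskGrid(m) else m)
  out
}

.l1PairDist <- function(img1, masks1, img2, masks2) {
  s <- sum(abs(img1 - img2))
  for (i in seq_along(masks1)) s <- s + sum(abs(masks1[[i]] - masks2[[i]]))
  s
}

#' Cycle-consistency loss
#'
#' L1 distance between round-tripped (image, masks) tuples and the
#' originals, in both translation directions; absolute differences are
#' summed over pixels and masks. Zero iff both round trips are exact.
#'
#' @param pair an [instancePair()].
#' @param gXY,gYX generators \code{function(image, masks)} returning
#'   \code{list(image =, masks =)}, mapping X to Y and back.
#' @return nonnegative scalar.
#' @export
cycleLoss <- function(pair, gXY, gYX) {
  fwd <- .gApply(gXY, pair$x, pair$a)
  rtX <- .gApply(gYX, fwd$image, fwd$masks)
  bwd <- .gApply(gYX, pair$y, pair$b)
  rtY <- .gApply(gXY, bwd$image, bwd$masks)
  aG <- lapply(pair$a, maskGrid); bG <- lapply(pair$b, maskGrid)
  .l1PairDist(rtX$image, rtX$masks, pair$x, aG) +
    .l1PairDist(rtY$image, rtY$masks, pair$y, bG)
}

#' Identity-mapping loss
#'
#' L1 penalty on applying each generator to its own target domain:
#' \eqn{\|G_{XY}(y, b) - (y, b)\|_1 + \|G_{YX}(x, a) - (x, a)\|_1}, summed
#' over pixels and masks. Keeps translations from altering inputs that
#' already live in the target domain.
#'
#' @inheritParams cycleLoss
#' @return nonnegative scalar.
#' @export
identityLoss <- function(pair, gXY, gYX) {
  idY <- .gApply(gXY, pair$y, pair$b)
  idX <- .gApply(gYX, pair$x, pair$a)
  aG <- lapply(pair$a, maskGrid); bG <- lapply(pair$b, maskGrid)
  .l1PairDist(idY$image, idY$masks, pair$y, bG) +
    .l1PairDist(idX$image, idX$masks, pair$x, aG)
}

# default context weight: 1 on pixels that are background (0) in every mask
# of both sets, else 0
.defaultContextWeight <- function(masksA, masksB) {
  all0 <- Reduce(`+`, c(masksA, masksB))
  (all0 == 0) + 0
}

#' Context-preserving loss
#'
#' Weighted L1 between originals and translations,
#' \eqn{\|w(a, b') \odot (x - y')\|_1 + \|w(b, a') \odot (y - x')\|_1}.
#' The default weight map is 1 exactly on pixels that are background in
#' every mask of both the source set and the translated set, so only
#' background changes are penalised and translation inside instances is
#' free; pass \code{weightFn(masksSource, masksTranslated)} to plug in
#' another scheme.
#'
#' @param pair an [instancePair()].
#' @param translated list with elements \code{y} (output of
#'   \eqn{G_{XY}(x, a)}) and \code{x} (output of \eqn{G_{YX}(y, b)}), each
#'   \code{list(image =, masks =)}.
#' @param weightFn optional weight-map function.
#' @return nonnegative scalar.
#' @export
contextLoss <- function(pair, translated, weightFn = NULL) {
  if (is.null(weightFn)) weightFn <- .defaultContextWeight
  norm1 <- function(w, img1, img2) {
    d <- abs(img1 - img2)
    if (length(dim(d)) == 3L) w <- array(w, dim = dim(d))
    sum(w * d)
  }
  aG <- lapply(pair$a, maskGrid); bG <- lapply(pair$b, maskGrid)
  toGrid <- function(ms) lapply(ms, function(m) if (is(m, "BinaryMask"))
    maskGrid(m) else m)
  wX <- weightFn(aG, toGrid(translated$y$masks))
  wY <- weightFn(bG, toGrid(translated$x$masks))
  norm1(wX, pair$x, translated$y$image) +
    norm1(wY, pair$y, translated$x$image)
}

#' Loss weights for the combined objective
#'
#' @param lambdaCyc,lambdaIdt,lambdaCtx nonnegative weights of the cycle,
#'   identity and context terms (defaults 10, 10, 10); zero disables a
#'   term.
#' @return a named list of class \code{"LossWeights"}.
#' @export
lossWeights <- function(lambdaCyc = 10, lambdaIdt = 10, lambdaCtx = 10) {
  w <- c(lambdaCyc, lambdaIdt, lambdaCtx)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and nonnegative", call. = FALSE)
  structure(list(lambdaCyc = lambdaCyc, lambdaIdt = lambdaIdt,
                 lambdaCtx = lambdaCtx), class = "LossWeights")
}

#' Combined translation objective
#'
#' \eqn{L = L_{LSGAN} + \lambda_{cyc} L_{cyc} + \lambda_{idt} L_{idt} +
#' \lambda_{ctx} L_{ctx}}.
#'
#' @param parts named list with elements \code{lsgan}, \code{cycle},
#'   \code{identity}, \code{context}.
#' @param weights a [lossWeights()] bundle.
#' @return scalar total; attribute \code{"parts"} carries the per-term
#'   breakdown.
#' @export
totalLoss <- function(parts, weights = lossWeights()) {
  need <- c("lsgan", "cycle", "identity", "context")
  if (!all(need %in% names(parts)))
    stop("'parts' must name lsgan, cycle, identity and context terms",
         call. = FALSE)
  tot <- parts$lsgan + weights$lambdaCyc * parts$cycle +
    weights$lambdaIdt * parts$identity + weights$lambdaCtx * parts$context
  structure(tot, parts = parts[need])
}

# one full loss evaluation on an explicit mask grouping; aUse/bUse are the
# instance subsets entering the content terms, aCum/bCum the cumulative
# translated-mask sets entering the adversarial fake terms
.lossOnGroups <- function(pair, G, D, weights, aUse, bUse,
                          yFake = NULL, xFake = NULL) {
  sub <- function(p, a, b) instancePair(p$x, a, p$y, b)
  pm <- sub(pair, aUse, bUse)
  trY <- .gApply(G$xy, pm$x, pm$a)
  trX <- .gApply(G$yx, pm$y, pm$b)
  if (is.null(yFake)) yFake <- trY
  if (is.null(xFake)) xFake <- trX
  lsgan <-
    lsganLoss(D$y(pair$y, lapply(pair$b, maskGrid)),
              D$y(yFake$image, yFake$masks)) +
    lsganLoss(D$x(pair$x, lapply(pair$a, maskGrid)),
              D$x(xFake$image, xFake$masks))
  parts <- list(
    lsgan = lsgan,
    cycle = cycleLoss(pm, G$xy, G$yx),
    identity = identityLoss(pm, G$xy, G$yx),
    context = contextLoss(pm, list(y = trY, x = trX)))
  totalLoss(parts, weights)
}

#' Full per-batch loss report
#'
#' Evaluates all four loss terms for one instance pair with the supplied
#' generators and discriminators and combines them with [totalLoss()].
#'
#' @param pair an [instancePair()].
#' @param G list with generators \code{xy} and \code{yx}.
#' @param D list with discriminators \code{x} and \code{y}; each a
#'   \code{function(image, masks)} returning numeric score(s).
#' @param weights a [lossWeights()] bundle.
#' @return named list: \code{lsgan}, \code{cycle}, \code{identity},
#'   \code{context}, \code{total}.
#' @export
instaganLossReport <- function(pair, G, D, weights = lossWeights()) {
  tot <- .lossOnGroups(pair, G, D, weights, pair$a, pair$b)
  c(attr(tot, "parts"), list(total = as.numeric(tot)))
}

#' Sequential mini-batch translation loss
#'
#' Handles an arbitrary instance count at fixed memory by translating the
#' instance masks in M sequential groups: for each group m the adversarial
#' term is evaluated on the image translated with group m against the
#' cumulative translated masks of groups 1..m, and the content terms
#' (cycle, identity, context) are evaluated on group m alone; the group
#' losses are summed. With \code{M = 1} this is exactly the combined
#' objective of [instaganLossReport()].
#'
#' @inheritParams instaganLossReport
#' @param M number of sequential groups; must not exceed the instance count
#'   of either mask set.
#' @return scalar loss.
#' @export
sequentialMinibatchLoss <- function(pair, M, G, D, weights = lossWeights()) {
  M <- as.integer(M)
  nA <- length(pair$a); nB <- length(pair$b)
  if (M < 1L || M > min(nA, nB))
    stop(sprintf("M = %d exceeds the instance count (min %d)",
                 M, min(nA, nB)), call. = FALSE)
  groupIdx <- function(n) split(seq_len(n), ceiling(seq_len(n) / (n / M)))
  gA <- groupIdx(nA); gB <- groupIdx(nB)
  total <- 0; bCum <- list(); aCum <- list()
  for (m in seq_len(M)) {
    aUse <- pair$a[gA[[m]]]; bUse <- pair$b[gB[[m]]]
    trY <- .gApply(G$xy, pair$x, lapply(aUse, maskGrid))
    trX <- .gApply(G$yx, pair$y, lapply(bUse, maskGrid))
    bCum <- c(bCum, trY$masks); aCum <- c(aCum, trX$masks)
    total <- total + as.numeric(.lossOnGroups(
      pair, G, D, weights, aUse, bUse,
      yFake = list(image = trY$image, masks = bCum),
      xFake = list(image = trX$image, masks = aCum)))
  }
  total
}

#' Tiny deterministic reference networks
#'
#' Desk-scale stand-ins for the translation networks, used to exercise the
#' loss surface on a CPU: \code{tinyGenerator} applies a seeded per-channel
#' affine perturbation of strength \code{strength} (0 gives the identity
#' map) and passes masks through; \code{tinyDiscriminator} scores an
#' (image, masks) pair by a seeded random projection squashed to (0, 1).
#' The full-scale configuration reported for this model family (batch size
#' 1, 64 first-layer filters, learning rate 2e-4 with decay after 100
#' iterations, instance normalisation, no dropout, flip/resize-crop
#' augmentation, load size 220, fine size 200) is preserved as the
#' documented pipeline configuration rather than as runnable training code.
#'
#' @param seed integer seed fixing the network parameters.
#' @param strength perturbation magnitude for the generator (default 0.1).
#' @return a generator \code{function(image, masks)} or discriminator
#'   \code{function(image, masks)}.
#' @export
tinyGenerator <- function(seed = 1L, strength = 0.1) {
  set.seed(seed)
  state <- list(scale = 1 + strength * stats::runif(3, -1, 1),
                shift = strength * stats::runif(3, -1, 1))
  function(image, masks) {
    out <- image
    if (length(dim(image)) == 3L) {
      for (ch in seq_len(dim(image)[3]))
        out[, , ch] <- pmin(pmax(image[, , ch] * state$scale[ch] +
                                   state$shift[ch], 0), 1)
    } else {
      out <- pmin(pmax(image * state$scale[1] + state$shift[1], 0), 1)
    }
    list(image = out, masks = masks)
  }
}

#' @rdname tinyGenerator
#' @export
tinyDiscriminator <- function(seed = 1L) {
  set.seed(seed)
  w <- stats::rnorm(64)
  function(image, masks) {
    grids <- lapply(masks, function(m) if (is(m, "BinaryMask")) maskGrid(m)
                    else m)
    v <- c(as.vector(image), mean(Reduce(`+`, grids)))
    proj <- sum(v * rep_len(w, length(v))) / sqrt(length(v))
    1 / (1 + exp(-proj))
  }
}
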