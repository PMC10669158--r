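---
title: "Mask-guided generative augmentation for leaf-disease imagery: models, choices, limits"
author: "leafdiffuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-guided generative augmentation for leaf-disease imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafdiffuse)
```

# The problem

Supervised leaf-disease classifiers are starved for images of rare disease
classes: curated collections such as PlantVillage are heavily imbalanced
(a thousand late-blight tomato images against a hundred bacterial-spot
ones). Generative augmentation attacks the imbalance by synthesising
diseased leaves from healthy ones. `leafdiffuse` implements the two
mask-guided routes used for this task, at a scale where every component can
be trained, sampled and verified on one CPU:

1. a **denoising diffusion probabilistic model (DDPM)** whose reverse
   process is conditioned on a binary mask at sampling time (the RePaint
   scheme), so that a masked part of a healthy leaf is regenerated with
   symptoms drawn from a diseased training distribution; and
2. the **instance-aware translation loss family** (InstaGAN), where a pair
   of generators translates (image, instance-mask-set) tuples between a
   healthy and a diseased domain under adversarial, cycle, identity and
   context-preserving penalties.

Around them sit the mask-preparation procedures both routes rely on, the
five evaluation metrics customary for generative imagery, and a procedural
synthetic-leaf generator that replaces the external photographic data with
seeded, ground-truth-complete fixtures.

# Diffusion core

## Forward process and schedule

The forward chain corrupts a clean image $x_0 \in [-1,1]^d$ by
$q(x_t \mid x_{t-1}) = N(\sqrt{1-\beta_t}\,x_{t-1},\, \beta_t I)$ for
$t = 1,\dots,T$. Independence of the per-step noise gives the closed-form
marginal $q(x_t \mid x_0) = N(\sqrt{\bar\alpha_t}\,x_0,\,
(1-\bar\alpha_t) I)$ with $\bar\alpha_t = \prod_{s\le t}(1-\beta_s)$. The
`NoiseSchedule` class stores $\beta$ and $\bar\alpha$ together and its
validity method enforces their consistency to $10^{-12}$; timesteps are
1-based with $t=0$ the clean image and $\bar\alpha_0 = 1$.

The default schedule is linear in $\beta$. The canonical endpoints
$10^{-4} \to 0.02$ are calibrated for $T = 1000$; used verbatim at
$T = 50$ they leave $\bar\alpha_T \approx 0.6$, i.e. a chain that never
reaches noise, and a sampler started from $N(0, I)$ is then badly
mismatched. `noiseSchedule()` therefore rescales the default endpoints by
$1000/T$ (capped at 0.999), preserving the total corruption
$\bar\alpha_T \approx e^{-10}$ at any chain length; endpoints passed
explicitly are honoured verbatim. A squared-cosine $\bar\alpha$ profile
(offset 0.008) is available as `kind = "cosine"`.

## Reverse process

The learned reverse step is
$p_\theta(x_{t-1} \mid x_t) = N(\mu_\theta(x_t,t), \Sigma_\theta(x_t,t))$,
with $\mu_\theta$ computed from a noise prediction $\hat\epsilon$ by the
standard posterior-mean formula. The parameterisation of a learned
$\Sigma_\theta$ is left open in much of the literature; we fix
$\Sigma_\theta = \tilde\beta_t I$, the forward-posterior variance
$\tilde\beta_t = \beta_t (1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$. Since
$\tilde\beta_1 = 0$, the final step is deterministic, which is what makes
the oracle round-trip property exact: a model that returns the very noise
used to corrupt $x_0$ reconstructs it to machine precision. A
deterministic DDIM-style update is exposed via `method = "ddim"` in
`pSample()` / `sampleUnconditional()`; the stochastic ancestral sampler is
the primary route because the mask-conditioned compositing below is
defined against it.

Images cross the API boundary in $[0,1]$ and are mapped to $[-1,1]$
internally; clipping happens once, at emission.

## The noise model

The full-scale architecture for $\epsilon_\theta$ in this model family is
a U-Net with attention (the `"full"` configuration profile records the
customary settings: 4000 steps, 128 channels, attention at 32/16/8,
256-pixel images). Nothing about the conditioning scheme depends on that
architecture, so the package ships `EpsilonMLP`, a one-hidden-layer
perceptron over the flattened image plus four smooth embeddings of $t/T$,
trained by hand-written backpropagation with Adam. One design point
matters: the map $x_t \mapsto \epsilon$ is dominated by a near-identity
component (at late $t$ the state mostly *is* the noise), which a narrow
bottleneck cannot represent. The model therefore predicts
$\hat\epsilon = s_t x_t + \mathrm{MLP}(x_t, t)$ with a learned
per-timestep scalar gate $s_t$; without the gate the training loss stalls
near the trivial value 1 and samples wash out to grey, with it the same
budget reaches losses below 0.1 and samples carry the training palette.
At the default width (30 hidden units on a 16 x 16 RGB raster) the model
has 47,048 parameters.

# Mask-conditioned inpainting

At each reverse step the known region is *not* denoised: it is drawn
afresh from the forward marginal of the untouched input,
$x^{known}_{t-1} \sim N(\sqrt{\bar\alpha_{t-1}}\,x_0,
(1-\bar\alpha_{t-1}) I)$, while the unknown region takes the learned
reverse step, and the two are composed by the known-marks-1 mask $m$:
$x_{t-1} = m \odot x^{known}_{t-1} + (1-m) \odot x^{unknown}_{t-1}$. The
marginal is indexed at $t-1$ (the step the composed state lives at), so
the known branch at the final step returns $x_0$ noiselessly. The two
branches draw independent noise. Directly composed chains harmonise
poorly — the generated region matches its immediate surroundings but not
the global structure — so the sampler re-diffuses the composed state
`jumpLength` steps back toward noise and re-descends, `nResamples` times
per jump point. These two counts are not dictated by the method; the
defaults (10, 10) follow upstream inpainting practice and `(1, 1)`
degenerates exactly to the plain conditioned chain, a property the tests
check trace-by-trace under a shared seed.

Two hard guarantees are engineered rather than hoped for:

* **known-region fidelity** — at emission the known region is hard-copied
  from the input, because applying the stochastic composition at the last
  step would leave residual noise in pixels the caller asked to keep;
* **convention safety** — masks carry an explicit tag
  (`instance-marks-1` vs `known-marks-1`) and every compositing operation
  refuses the wrong tag. Feeding a whole-leaf segmentation mask where a
  context mask is expected is precisely the mistake that produces the
  "ghost leaf" artefact: with (almost) no known context the sampler fills
  the leaf outline with background and invents a second, smaller leaf
  inside it. `inpaint()` additionally warns when the unknown fraction
  exceeds 0.98.

# Mask preparation

`otsuThreshold()` implements exhaustive between-class-variance
maximisation over a histogram, with class means computed from the actual
per-bin value sums (the exact-level form) and the returned threshold
placed strictly between the two classes' observed values.
`leafMaskOtsu()` wraps it with luminance conversion, polarity resolution
(in `"auto"` mode the leaf is the threshold side dominating the central
quarter of the frame — single-leaf-centred imagery makes that reliable),
largest-connected-component retention and hole filling. The cleanup
switches encode the known failure modes of plain thresholding (admitted
shadows, dropped diseased regions); each is independently disablable.
Morphology, labelling and hole filling are delegated to EBImage; the
structuring element is the discrete disk $\{(i,j): i^2+j^2 \le r^2\}$
(radius 1 is the 5-pixel plus), because EBImage's own brush at size 3 is a
full square and dilation tests pin the footprint.

Dilating a leaf mask before inversion leaves a context band along the
boundary — the fix for the ghost-leaf failure. The default radius is 3% of
the raster side: wide enough to carry usable context at 64 pixels, narrow
enough not to freeze the leaf interior. The cost of border context is a
bias — symptoms can never be generated in the preserved band, yet many
diseases attack leaf edges first. The split-mask catalogue addresses this:
simple partial masks (four half-frames, four single-quadrant-context
masks, a centre window and its border-band complement) applied uniformly
at random spread generated symptoms over every leaf region including
edges. The catalogue is a plain named list of template functions and is
user-extensible; the default set is closed under the property that any
two templates' unknown regions jointly cover the raster, and the
half-frame and centre/border pairs are exact complements.
`iou()`/`meanIOU()` score mask agreement, with the empty-union case
defined as 1; an external segmenter's masks can be dropped in as PNG +
sidecar files through `readMaskPNG()`, so mIoU evaluation is independent
of how masks were produced.

# Translation losses

The instance-aware translation objective combines four terms
($L = L_{LSGAN} + \lambda_{cyc} L_{cyc} + \lambda_{idt} L_{idt} +
\lambda_{ctx} L_{ctx}$) over generators that map (image, mask-set)
tuples between domains. Encodings of the mask set enter as a *sum* of
per-mask features — a permutation-invariant set encoding — optionally
concatenated with the features of the instance currently being
translated. Conventions fixed here, where the printed formulas are
ambiguous:

* L1 terms are **sums** of absolute differences over pixels and masks
  (so a uniform +0.1 round-trip shift on an n-element image costs exactly
  0.1n per direction); the closed-form test oracles depend on this.
* The least-squares adversarial loss is the standard two-sided form:
  discriminator targets 1 on real and 0 on translated inputs, the
  generator targets 1 on its outputs.
* The context weight $w(a, b')$ is 1 exactly on pixels that are
  background in every mask of both the source set and the translated set,
  else 0, and is pluggable.
* $\lambda_{cyc} = \lambda_{idt} = \lambda_{ctx} = 10$ by default; the
  weights are not prescribed anywhere authoritative and 10 is the
  customary cycle-loss scale. A zero weight removes its term exactly.

The sequential mini-batch form processes the instance masks in $M$
ordered groups, scoring the adversarial term of group $m$ against the
cumulative translated masks $b'_{1:m}$ and the content terms on group $m$
alone; the source image is held fixed across groups (the single-leaf data
this package targets never exercises $M > 1$ in anger, but the reduction
`M = 1` = combined loss is exact and tested to $10^{-12}$). The shipped
`tinyGenerator`/`tinyDiscriminator` are deliberately small deterministic
closures: the package's contribution here is the loss surface, which is
verified through fixpoints and closed forms, not through GAN training.

# Evaluation metrics

PSNR and the printed global form of SSIM (whole-image moments, stabilisers
$c_1 = (0.01L)^2$, $c_2 = (0.03L)^2$; a non-overlapping-window variant
behind `windowSize`) serve as reconstruction measures. Inception Score is
computed per split (default 10) with the marginal estimated within the
split. FID is the Gaussian moment distance
$\|\mu_r-\mu_f\|^2 + \mathrm{Tr}(\Sigma_r + \Sigma_f -
2(\Sigma_r\Sigma_f)^{1/2})$; the matrix square root is taken by symmetric
eigendecomposition of $\Sigma_r^{1/2}\Sigma_f\Sigma_r^{1/2}$, eigenvalues
in $[-10^{-6}, 0)$ are zeroed and anything more negative is an error
rather than silently clipped. KID is the unbiased squared-MMD estimator
under the kernel $(x \cdot y / d + 1)^3$, averaged over seeded subsets
(defaults: 100 subsets of up to 1000) and reported as mean ± sd; unlike
FID its null distribution is centred on zero, which the tests exploit.

All five run over a pluggable extractor: any callable with a declared
`featureDim`. The default `toyExtractor()` is a fixed seeded random
projection over 4 x 4 average-pooled channel planes — deterministic,
offline, and sufficient to order distributions by similarity, but *not* a
perceptual embedding: absolute FID/KID values computed with it are not
comparable to scores computed over pretrained classifier features, and no
pretrained adapter is bundled (the extractor seam is where one would
plug in). `toyClassifier()` stacks a seeded softmax head on top for
inception-style scores.

# Synthetic leaves

`generateLeaf()` renders a jittered, tapered ellipse with a smooth
low-frequency margin (amplitude capped so the contour stays star-shaped,
hence simple), margin-darkened shading, a midrib plus secondary veins, and
mild pixel noise on a uniform light background — the single-leaf,
controlled-background composition of curated collections. The exact
rasterised contour is returned as the ground-truth mask, which is what
makes the Otsu extractor and the IoU scorer testable against known
answers. Five stylised symptom renderers (`applyDisease()`) cover the
canonical appearance classes: concentric ring lesions, dark spots,
edge blight, mosaic mottling, yellowing tint. Three properties are
guaranteed by construction and tested: background pixels are returned
bit-identically; the changed-pixel set grows monotonically with intensity
under a fixed RNG state (lesion candidates are drawn up front and lower
intensities use a prefix); `edgeBias = 1` confines all changes to the
boundary band (leaf minus its erosion by 15% of the equivalent radius).
`generateDataset()` assembles class-imbalanced datasets in both the flat
and the paired-domain layout, with counts defaulting to the PlantVillage
tomato/grape ratios scaled down by 100, and a JSON manifest that
round-trips losslessly.

What the generator does *not* emulate: photographic texture, specular
lighting, camera noise statistics, intra-class morphological diversity of
real leaves, or photorealistic symptom appearance. Tests passing on this
substrate demonstrate that the samplers, losses and metrics behave as
specified — they say nothing about visual fidelity on real photographs,
which additionally requires full-scale architectures and data.

# Pipeline and problem sizes

`runPipeline()` chains simulate → masks → train → inpaint → evaluate with
per-stage done-markers (resumable; a re-run stage invalidates everything
downstream) and per-stage seeds derived deterministically from the single
run seed, so a finished run is bit-reproducible and resuming cannot change
results. The `"tiny"` profile — 16 x 16 rasters, 8 + 8 images, a 25-step
schedule, 300 training updates, 4 inpainted images — completes in a few
seconds on one CPU; it is sized as a demonstration and integration test,
not as a quality benchmark. The test suite's heavier experiments use
64 training images at 16 x 16 with T = 50 and 2000 updates, chosen as the
smallest setting at which the trained sampler reliably reproduces the
training palette (the acceptance checks ask for the inpainted region's
mean colour within 15% of the training signature; the model lands well
inside). The configuration skeleton rejects unknown keys and records one
setting verbatim without consuming it (`lrKernelSd`, a full-scale
training knob with no defined semantics in this implementation).

# Known limitations

* The bundled noise model is a sanity-scale MLP; it learns colour and
  coarse structure, not texture. Full-scale quality requires an external
  U-Net behind the same `(x, t) -> eps` contract.
* Absolute FID/KID values depend entirely on the extractor; only
  comparisons under a fixed extractor are meaningful.
* The Otsu extractor assumes a single leaf on a roughly uniform
  background; it has no answer to cluttered scenes.
* GAN training loops are out of scope by design: the translation module
  is a loss library with reference networks, not a trainer.
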