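# leafdiffuse

Mask-guided generative augmentation for plant-disease leaf imagery, in R.

Leaf-disease image collections are heavily class-imbalanced: common
diseases come with a thousand photographs, rare ones with a hundred.
`leafdiffuse` implements the two mask-guided generative routes used to
synthesise diseased leaves from healthy ones, sized so that every
component trains, samples and verifies on a single CPU:

* **Diffusion + inpainting.** A denoising diffusion probabilistic model
  with forward chain
  `q(x_t | x_{t-1}) = N(sqrt(1-beta_t) x_{t-1}, beta_t I)`, closed-form
  marginal `q(x_t | x_0) = N(sqrt(abar_t) x_0, (1-abar_t) I)` where
  `abar_t = prod(1-beta_s)`, a learned reverse process driven by a noise
  predictor `eps(x_t, t)`, and the simplified training objective
  `E ||eps - eps_theta(x_t, t)||^2`. Sampling can be conditioned on a
  binary mask RePaint-style: at every reverse step known pixels are drawn
  from the forward marginal of the input, unknown pixels from the learned
  reverse step, composed as
  `x_{t-1} = m * x_known + (1-m) * x_unknown`, with jump-based resampling
  for harmonisation. Known pixels are returned bit-identically.
* **Instance-aware translation losses.** The InstaGAN objective
  `L = L_LSGAN + l_cyc L_cyc + l_idt L_idt + l_ctx L_ctx` over generators
  mapping (image, instance-mask-set) tuples between a healthy and a
  diseased domain, with permutation-invariant set encodings and the
  sequential mini-batch variant for arbitrary instance counts.
* **Mask preparation.** Otsu leaf segmentation (exhaustive between-class
  variance maximisation) with polarity and cleanup switches, disk-kernel
  dilation (the border-context fix for the "ghost leaf" inpainting
  failure), a uniform split-mask catalogue, convention-tagged masks with
  safe inversion, and IoU / mean-IoU scoring.
* **Evaluation metrics.** PSNR, global SSIM, Inception Score, FID (with a
  symmetrised eigendecomposition matrix square root) and unbiased
  subset-averaged KID, all over a pluggable feature extractor; a
  deterministic offline extractor is bundled.
* **Synthetic leaves.** A procedural generator for single-leaf images on
  uniform backgrounds with exact ground-truth masks, five stylised
  symptom renderers and class-imbalanced dataset assembly mirroring the
  PlantVillage tomato/grape ratios — the package's no-download test
  substrate.

## Worked example

Train a small noise model on stylised diseased leaves, inpaint a random
split-masked region of a fresh healthy leaf, and score the results:

```r
library(leafdiffuse)
set.seed(7)

spec   <- leafSpec(size = 16)
leaves <- lapply(1:24, function(i) generateLeaf(spec))
blight <- diseaseStyle("dark-spot", intensity = 0.9, maxSpots = 8,
                       spotRadius = c(6, 10))
train  <- lapply(leaves, function(l) applyDisease(l$image, l$mask, blight))

schedule <- noiseSchedule(50)                      # beta endpoints auto-scale
model <- epsilonMLP(16 * 16 * 3, hidden = 30, nSteps = 50)
model <- trainEpsilonModel(model, train, schedule, steps = 1500)

probe <- generateLeaf(spec)                        # held-out healthy leaf
mask  <- sampleSplitMask(c(16, 16))                # uniform catalogue draw
synth <- inpaint(model, probe$image, mask, schedule,
                 jumpLength = 5, nResamples = 5)

ex       <- toyExtractor(dim = 32)
realF    <- extractFeatures(train, ex)
fakeF    <- extractFeatures(lapply(1:24, function(i) {
  m <- sampleSplitMask(c(16, 16))
  inpaint(model, generateLeaf(spec)$image, m, schedule, 5, 5)
}), ex)
healthyF <- extractFeatures(lapply(leaves, `[[`, "image"), ex)
k <- kid(realF, fakeF, nSubsets = 100, subsetSize = 24)

cat("split mask drawn:", attr(mask, "template"), "\n")
cat(sprintf("FID(diseased, inpainted) = %.3f\n", fid(realF, fakeF)))
cat(sprintf("FID(diseased, healthy)   = %.3f\n", fid(realF, healthyF)))
cat(sprintf("KID(diseased, inpainted) = %.4f (+- %.4f)\n", k$mean, k$sd))
cat(sprintf("PSNR(probe, inpainted)   = %.1f dB\n", psnr(probe$image, synth)))
cat(sprintf("SSIM(probe, inpainted)   = %.3f\n", ssimGlobal(probe$image, synth)))
cat(sprintf("Otsu mask IoU vs truth   = %.3f\n",
            iou(leafMaskOtsu(probe$image), probe$mask)))
```

Output of this script:

```
split mask drawn: border-band
FID(diseased, inpainted) = 0.064
FID(diseased, healthy)   = 0.023
KID(diseased, inpainted) = 0.0033 (+- 0.0000)
PSNR(probe, inpainted)   = 16.5 dB
SSIM(probe, inpainted)   = 0.809
Otsu mask IoU vs truth   = 1.000
```

Reading the numbers: FID/KID computed over the bundled toy extractor are
on an arbitrary scale — only comparisons under the same extractor mean
anything. Here the inpainted set lands near the diseased training
distribution (FID 0.064) but not inside it: at this sanity scale the
30-unit noise model reproduces palette and coarse structure, not texture,
so the healthy originals (FID 0.023) remain closer to the diseased set in
pooled-colour features than the generated images are. PSNR/SSIM compare
the inpainted leaf against its healthy original, so they measure how much
the masked region was changed (16.5 dB / 0.81 — substantially
regenerated), while the known region is guaranteed bit-identical. The
Otsu mask matches the procedural ground truth exactly on this clean
substrate. Swapping in a full-scale U-Net noise model behind the same
`(x, t)` contract is what quality at photographic resolution requires;
see the vignette for the design discussion.

The end-to-end pipeline (simulate → masks → train → inpaint → evaluate)
runs as

```r
runPipeline(defaultRunConfig("tiny"), "runs/demo")
```

and writes a resolved config, per-stage done-markers (resumable),
checkpoints, generated images and a `metric_report.json` with all five
metrics; runs are bit-reproducible given `config$seed`.

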