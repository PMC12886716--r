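---
title: "Virtual multiplexed immunostaining: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual multiplexed immunostaining: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Assessing vascular invasion — tumour cells inside a vessel lumen — needs
three views of the *same* tissue plane: H&E for morphology, ERG
(a nuclear endothelial marker) to outline vessel linings, and PanCK
(a cytoplasmic epithelial marker) to locate tumour cells. Chemically these
stains go on *serial* sections, and a small vessel present on one section
is often gone on the next. Virtual staining sidesteps this: a single
label-free autofluorescence (AF) scan of an unstained section — four
channels acquired through DAPI, FITC, TxRed and Cy5 filter cubes — is
translated computationally into all three brightfield stains on one pixel
grid.

`virtmihc` implements this translation as a conditional generative
adversarial framework with a registration network in the training loop,
together with a tissue-phantom simulator that supplies co-registered
AF/brightfield pairs with known ground truth, so every stage of the
pipeline is testable without any microscope data.

## The model

Three networks cooperate during training:

* **Generator `G`** — an attention U-Net. Input is the 4 AF channels plus
  one conditioning channel, the *digital staining matrix* (DSM): a
  spatially constant plane whose value selects the stain, `-1` for ERG,
  `1` for PanCK, `2` for H&E. The encoder has four levels, each a
  three-convolution residual block (3x3 kernels, leaky ReLU slope 0.1)
  followed by 2x2 max pooling; channels double per level. Decoder levels
  upsample by 2x bilinear resizing, pass the encoder skip through an
  additive attention gate (three 1x1 convolutions and a sigmoid) and apply
  another residual block. A final residual block and a single convolution
  produce the 3-channel RGB output. Spatial dimensions must be divisible
  by 16.
* **Discriminator `D`** — one convolution to the stem width, then five
  residual blocks whose second convolution has stride 2 (halving the
  spatial size, doubling the channels), global average pooling and two
  dense layers giving one raw score; the sigmoid lives inside the
  numerically stable binary cross-entropy. `D` is conditional: the DSM is
  concatenated with the image as a fourth channel.
* **Registration module `R`** — a U-Net-style displacement estimator
  taking the generator output concatenated with the target (6 channels)
  and returning the two components of a per-pixel displacement field `T`.
  Warping `img %o% T` resamples `img` at `x + T(x)` by bilinear
  interpolation with border replication. `R` absorbs residual
  misregistration between network output and chemically stained ground
  truth so that the pixel-wise loss is computed between spatially
  corresponding pixels; it is used only during training.

The losses are

* generator:
  `alpha * L_phi(target, G(x) %o% T) + beta * BCE(D(G(x), dsm), 1) + gamma * TV(G(x))`
* discriminator: `BCE(D(G(x), dsm), 0) + BCE(D(target, dsm), 1)`
* registration: `lambda * L_phi(target, G(x) %o% T) + mu * SMTH(T)`

with `L_phi` the Huber loss (mean over pixels of `d^2 / (2 phi)` below
the threshold `phi`, `|d| - phi / 2` above), `TV` the raw anisotropic
total-variation sum, and `SMTH` the mean squared forward difference of
the field. Defaults: `alpha = 10`, `beta = 10`, `gamma = 1e-4`,
`lambda = 20`, `mu = 10`, `phi = 1`. Note the deliberate scale mismatch:
`TV` is a raw sum while the Huber term is a mean; the small `gamma`
compensates.

Within one scheduled unit the generator is updated four times (the
registration module rides along with each update, optimising its own
parameters on the same batch) and the discriminator once. Gradients are
isolated: in the generator objective the field is a constant and the
warped-Huber term backpropagates through the warp into `G`; in the
registration objective only `R`'s parameters receive gradients; the
adversarial term reaches `G` through a frozen `D`. Batches mix the three
stain datasets with equal probability regardless of their sizes, and
crops are augmented with the eight square symmetries applied identically
to AF, DSM, target and (when present) the misalignment field.

## Presets and tunable parameters

| parameter | `paper` preset | `tiny` preset | notes |
|---|---|---|---|
| generator base width | 64 | 8 | channels at the first level |
| registration depth | 7 | 3 | input divisibility 128 / 8 |
| crop size | 512 px | 64 px | |
| Adam learning rates (G/D/R) | 2e-5 / 2e-6 / 2e-6 | 1e-3 / 1e-4 / 1e-4 | |
| batch size | 4 | 4 | |
| G updates per D update | 4 | 4 | |
| steps | 10,000 (configurable) | 500 | generator updates |
| output activation | sigmoid | linear | see below |

The `paper` preset mirrors the full-scale configuration (a multi-day GPU
run over thousands of 2,000 x 2,000-px tile pairs); the `tiny` preset is
the package's desk-scale study condition: it trains in minutes on one CPU
core and is what the test suite and the acceptance script run.

Two `tiny`-preset choices deserve justification:

* **Linear output head.** With a sigmoid head, brightfield targets that
  contain exactly-white pixels (transmission 1.0) drive the pre-sigmoid
  activations toward infinity; under Adam's fixed-size steps the sigmoid
  saturates within tens of updates, after which all pixel gradients
  vanish and training freezes. A linear head with clipping to `[0, 1]` at
  inference avoids the pathology entirely. The activation is switchable
  (`activation = "sigmoid"`), and the full-scale preset keeps the
  sigmoid, where tiny learning rates make saturation a non-issue.
* **Initialisation discipline.** No normalisation layers appear anywhere
  (the architecture uses only convolutions, residual paths and
  activations), so initialisation carries the burden of scale control:
  the last convolution of every residual block starts at reduced gain
  (blocks begin near their skip path), the generator head starts at small
  gain with its bias at the brightfield mean, the registration head is
  zero-initialised (training starts at the identity field), and the
  discriminator's final dense layer starts near zero so that the
  adversarial gradient — weighted `beta = 10` — does not drown the
  pixel-fidelity term during the short desk-scale run.

## The phantom simulator

`generate_phantom()` builds a latent tissue geometry: a circular core on
background, stromal interior, epithelial blobs (unions of discs closed
with the evaluation pipeline's structuring element, so the stored mask is
a fixed point of the analysis-time morphology), vessels as annuli whose
lumen boundary is studded with small endothelial nuclei, and elliptical
nuclei (axis lengths 4-10 px). Nucleus instances keep a 6-px clearance so
connected components never merge under 8-connectivity or the default
closing. Default structure counts are sized for 64-px tiles.

From one phantom, `render_af()` produces the 4-channel AF image as a
linear compartment mixture (nuclei dominate DAPI, stroma FITC, epithelial
cytoplasm TxRed, vessel lumina Cy5) plus a smooth Gaussian-filtered
texture (amplitude 0.03, scale 8 px) and per-pixel Gaussian noise
(sd 0.01) — relative contrast is what matters for learning, so no attempt
is made to model real fluorophore spectra. `render_stain()` renders the
brightfield targets through Beer-Lambert transmission
`rgb = 10^(-sum_k c_k v_k)` using the classical hematoxylin/eosin/DAB
optical-density vectors: H&E puts hematoxylin on nuclei and eosin on
stroma/cytoplasm; ERG puts DAB only on endothelial nuclei; PanCK puts DAB
only on the epithelial mask. Base-10 transmission matches the
optical-density convention of colour deconvolution, so
`color_deconvolve()` recovers the generating concentration maps exactly
(to float precision) and the recovered DAB masks equal the ground-truth
masks bit-for-bit in the noise-free case.

`make_misaligned_pair()` emulates staining-induced distortion by warping
the target along a Gaussian-smoothed random vector field; the amplitude
is capped at 10% of the image side so the warp stays invertible.

What the phantoms do *not* emulate: real AF spectral overlap and
photobleaching, chromatic aberration, stain batch variability, nuclear
chromatin texture, out-of-focus blur, and tissue-level pathology
(follicles, colloid, carcinoma architecture). Passing tests therefore
demonstrate that the machinery — conditioning, losses, registration,
quantification — behaves correctly, not that the model reaches clinical
image quality on real tissue.

## Evaluation suite

* `psnr()` uses `10 log10(max(reference)^2 / MSE)` with the maximum taken
  over the histochemical reference, not a fixed dynamic range; identical
  images report `Inf`.
* `ssim()` is the standard windowed index on Rec. 601 luminance
  (11-px Gaussian window, sigma 1.5, `K = (0.01, 0.03)`, `L = 1`),
  averaged over valid window positions.
* `perceptual_distance()` is a layer-weighted mean squared distance of
  channel-unit-normalised feature maps from a pluggable extractor. The
  default identity extractor reduces it to a normalised MSE; where a
  pretrained feature network is available it can be plugged in, and with
  no extractor the metric is reported absent, never substituted.
* `color_deconvolve()` inverts the optical-density mixture
  (`OD = -log10(rgb)`, concentrations `OD %*% solve(V)`), returning raw
  (possibly negative) concentrations; clamping happens only in
  `dab_mask()`, which applies Otsu's threshold followed by dilation then
  erosion with a disc of radius 2 (order as specified; element
  configurable). A constant map yields an empty mask with a warning.
* `erg_nuclei_stats()` counts connected components under 8-connectivity
  (configurable to 4); the labelling is implemented in compiled code
  because the available image library labels 4-connected components only.
* `d_iou()` mean-pools both masks over non-overlapping 8x8 blocks
  (zero-padding to a multiple of 8), re-binarises at `> 0.01` and
  computes `sum(A * B) / sum(min(A + B, 1))`; two empty masks compare
  as 1.
* `paired_t()` wraps the paired two-tailed t test with sentinels for the
  degenerate cases (identical lists: statistic 0, p 1; constant nonzero
  difference: signed infinity, p 0).

## Numerical choices

* Convolutions pad by border replication, so a spatially constant input
  stays constant through the whole network — this is also what makes
  tiled inference seamless on constant regions.
* The registration objective's smoothness term is evaluated on the
  displacement expressed in normalized image coordinates (pixels divided
  by half the shorter side) — the units a spatial-transformer sampling
  grid uses. On pixel-unit fields the same penalty would be inflated by
  the squared half-side, and with `mu = 10` the objective would prefer
  the zero field over recovering any genuine smooth misalignment,
  defeating the module's purpose. The warp itself keeps pixel units;
  only the penalty rescales (`registration_loss(normalize_field =
  FALSE)` restores the raw reading).
* The warp clamps out-of-bounds sample positions to the border; at
  clamped positions the derivative with respect to the field is zero.
* Tiled inference (`stain_field()`) feather-blends overlapping tiles with
  raised-cosine weights normalised to sum to one at every pixel; zero
  overlap reproduces per-tile outputs bit-exactly, and outputs are
  clipped to `[0, 1]`.
* Images are stored as 16-bit TIFF; writers snap to the k/65535 grid and
  return the snapped array, so write/read round-trips are exact on the
  stored representation. The manifest is the single source of truth for
  channel order and DSM codes.
* All randomness derives from one master seed through named substreams
  (phantom, sampler, augmentation, initialisation, noise, misalignment),
  so consuming randomness in one component never shifts another, and the
  training batch plan is a pure function of the seed — which is what
  makes checkpoint resumption reproduce the uninterrupted loss trajectory
  bitwise.
* Huber is normalised per element (per-channel means averaged across
  channels); TV and SMTH use interior forward differences only, the
  literal reading of their definitions.

## Desk-scale problem sizes

The test suite and `scripts/acceptance.R` run the `tiny` preset on 64-px
phantom tiles: 12 training tiles x 3 stains, 6 held-out tiles, 500
generator updates; the registration-recovery experiment uses 4 pairs
misaligned by 4-px smooth fields and 300 updates; nuclei quantification
uses 20 phantoms of 96 px with two vessels each. These sizes are the
package's chosen study conditions for a single CPU core.

## Known limitations

* The hand-rolled network core is CPU-only and double-precision;
  full-scale (512-px, base-width-64) training is expressed in the
  `paper` preset but is not practical without accelerator hardware.
* The DSM encoding places PanCK's code (1) between ERG's (-1) and H&E's
  (2); at very short training budgets the PanCK output is the last to
  separate from its neighbours, which is visible in the training
  diagnostics as a later assignment transition.
* `evaluate_pairs()` assumes co-registered pairs; it skips (and reports)
  pairs with mismatched dimensions but does not register them.
* Spatially varying DSMs (micro-structured multiplexing) are accepted by
  the warp/conditioning machinery but are untested and unsupported.
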