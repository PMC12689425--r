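---
title: "Sparse-sampling restoration of cone photoreceptor mosaics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-sampling restoration of cone photoreceptor mosaics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsecone)
```

## The problem

Adaptive optics optical coherence tomography (AOOCT) resolves individual cone
photoreceptors in the living retina, but only when the beam samples the tissue
densely enough: the cones near 1 mm eccentricity are a few micrometres apart,
so each line of the raster needs hundreds of A-scans. Dense sampling costs
acquisition time, worsens eye-motion artifacts and multiplies data volume.
Sparse sampling — acquiring, say, every fourth A-scan — recovers speed and
storage at the price of laterally pixelated images in which cones become
rectangular blocks.

`sparsecone` provides the complete desk-scale machinery for studying this
trade-off: a synthetic generator of cone-mosaic images and layered
outer-retina volumes with *known* ground truth; the lateral degradation
operator and its patch/split bookkeeping; a trainable restorer (a
residual-in-residual windowed-attention transformer generator, optionally
adversarial) plus interpolation baselines; and the validation statistics —
radial power-spectrum cone spacing and contrast, an edge-directionality
pixelation score, PSNR, a paired one-tailed t-test, and a paraxial schematic
eye for pixel-to-micrometre conversion.

## The synthetic mosaic generator

Real human AOOCT data are not redistributable, so the generator is a
first-class module, not a fixture. It emulates the features of the cone
mosaic that the package's statistics measure:

* **Quasi-hexagonal geometry.** Cone centres sit on a hexagonal lattice with
  nearest-neighbour distance `spacing_px`, each displaced by independent
  uniform jitter of up to `position_jitter_frac * spacing_px` per axis
  (default 0.15, enough to blur the lattice's discrete Bragg spots into the
  quasi-crystalline ring seen in real mosaics while keeping the ring sharp).
  A square-lattice option exists because its spectral peak sits exactly at
  `1/spacing`, which makes a clean oracle for the spectral code.
* **Cone profiles.** Each cone is an isotropic Gaussian blob with
  `sigma = cone_radius_frac * spacing` (default 0.25: blobs just short of
  touching, as in en-face cone images) and log-free amplitude jitter
  (`amplitude_cv`, default 0.1). Cones whose centres fall within three blob
  sigmas outside the frame are still rendered so border density is not
  depleted.
* **Noise.** Additive Gaussian noise (default sigma 0.05 on a [0, 1] scale)
  after rendering, plus an optional unit-mean Rayleigh speckle gain for OCT
  realism. No published noise model exists for this instrument class at this
  scale, so these are deliberately generic choices; the calibration target is
  only that the spacing is recoverable spectrally, which the test suite
  checks across spacings 6–16 px.
* **Volumes.** A volume assigns every cone an axial column whose profile is a
  sum of Gaussian bands (IS/OS-like and COST-like by default, 0-based centres
  at configurable depths); a band may be expressed by a random subset of
  cones, emulating sparse sub-mosaics such as S-cones. Repeat volumes share
  geometry and differ only in seeded noise — they are *pre-aligned*, because
  eye-motion simulation and registration are out of scope.

What passing tests on these images do **not** show: robustness to real
speckle statistics, axial curvature of the retina, eye-motion residuals,
intra-frame density gradients, or pathology. The generator holds spacing
constant within a frame and varies it across frames only.

## Degradation, patches and splits

Sparse acquisition skips A-scans, so the default degradation is **decimation**
(keep columns 1, 1+k, 1+2k, ... — phase 0), not block averaging; averaging is
retained as an option for binned-acquisition studies. The phase is fixed and
documented so the round-trip identities (`degrade` then `pixelate_upsample`
restores kept columns exactly; decimation composes multiplicatively) are
bit-exact. Widths not divisible by the factor are an error unless an explicit
crop flag is set, in which case the right edge is cropped with a warning.

Training data are random dense crops (default 40 x 400, the size used for
B-scan regions of interest at factor 4) paired with their degraded
counterparts; every pair carries a subject id, and the evaluation split is
leave-one-subject-out. Test-time crop geometry is a configuration value, not
a constant, because evaluation crops legitimately differ from training crops.

## The restorer

The generator maps H x W to H x 4W (the factor is configurable, lateral
only, because the degradation is lateral only):

1. shallow 3 x 3 convolution into `embed_dim` channels;
2. `n_rrt_groups` residual groups, each a chain of `n_blocks_per_group`
   pre-norm transformer blocks — windowed multi-head self-attention then a
   GELU MLP, each branch scaled by `residual_scale` (default 0.2) before the
   residual add;
3. each group closes with a zero-initialised projection added back to the
   group input, and the whole chain closes with a zero-initialised projection
   added back to the shallow features (residual-in-residual connectivity);
4. a per-token linear head emits `factor` lateral sub-pixels (a 1D pixel
   shuffle), and with `global_skip` the nearest-neighbour-upsampled input is
   added to the result.

Because every branch-closing projection starts at zero, a freshly built
generator **is** the nearest-neighbour upsampler, exactly. This gives a sharp
identity-at-initialisation contract, and it means the network only ever
learns the high-frequency residual on top of the low-frequency content
carried by the long skip.

Attention windows tile the feature map with truncated windows at the edges
rather than zero-padding to a window multiple: every token then belongs to
exactly one window, no masking is needed, and outputs are shape-exact for any
input size. (Zero-padding plus masking is the other standard choice; the
tiling variant was preferred as it removes an entire class of mask-handling
errors at identical contract.)

The discriminator is a small strided convolutional stack producing a logit
per 4 x 4 input patch. The generator loss is
`lambda_pix * L1 + lambda_adv * adversarial`, with the relativistic-average
formulation (applied per image pair, so per-image logit means stand in for
batch means) or the standard non-saturating loss. `lambda_adv = 0` — the
default in every bundled study — degrades to pure regression pretraining,
which is the stable, deterministic regime appropriate for CPU-scale runs;
the adversarial path is exercised by tests for stability, not for quality
claims.

All forward and backward passes are implemented natively in dense matrix
algebra (the package has no deep-learning framework dependency). The
backward implementation is pinned by finite-difference gradient checks in the
test suite — parameter-wise for the generator, and a directional derivative
across all parameters for the discriminator (agreement to ~1e-6 away from
LeakyReLU kinks). Optimisation is Adam (beta 0.9/0.999, lr 1e-3 by default).
Training aborts with a diagnostic on a non-finite loss rather than silently
diverging. Output images are clipped to [0, 1] at inference; the training
loss sees unclipped outputs so gradients are not zeroed at the rails.

**Toy scale.** The reference study (`toy_restoration_study()`) uses embed 32,
2 groups x 2 blocks, 4 heads, window 8, 200 pairs of 24 x 96 dense patches
from a 4-subject synthetic cohort, 600 steps at batch 2 — a few minutes on
one CPU. Held-out evaluation is against the nearest-neighbour baseline. The
claim tested is ordering (restorer above replication baseline), never
human-data image quality: reproducing the published quality of a fully
trained model on clinical AOOCT data is explicitly out of scope.

## Quantification

**Radial PSD.** Images are mean-subtracted, Hann-windowed (frame-edge leakage
otherwise dominates the low-frequency bins; the tests that need exact Fourier
pairs switch the window off), FFT-transformed, and the squared magnitude is
averaged over annuli of constant radial frequency in cycles/pixel over
(0, 0.5], DC excluded, 128 annuli by default (matching the natural FFT
resolution of a 256-px frame). Annular means are normalised by the total
non-DC power in the binned region, and the unnormalised sums are kept so the
binning can be Parseval-checked against a direct FFT. Constant images yield
a flagged all-zero spectrum rather than an error.

**Cone peak.** The background under the ring is a running median of the log
spectrum computed *outside* the search band and interpolated across it; the
peak is the maximum positive excess of the normalised power over this
background within the band (default 0.05–0.35 cycles/px), with parabolic
sub-bin refinement. No positive excess returns a flagged no-peak result.
Peak height — the cellular-contrast surrogate — is that excess, in
normalised-power units; its absolute scale is a package convention (the
normalisation in the source work is unspecified), so only *orderings* of
peak heights are meaningful, and that is all the tests assert. A hexagonal
mosaic's ring sits at the lattice *row* frequency, so `hex_correction`
(default on) multiplies `1/f` by `2/sqrt(3)` to convert row spacing to
centre-to-centre spacing.

**Edge directionality.** Sobel gradients (central differences optional), edge
pixels above the 90th magnitude percentile, full-circle angles binned over
[0, 360) in 36 bins, normalised to unit mass. The angle convention is fixed
so that purely lateral gradients — the block boundaries of column-replicated
images — land at 90/270 degrees. The pixelation score is the variance of the
normalised bin heights around their mean 1/n: 0 for uniform (smooth round
cells), (n-1)/n^2 when one bin takes all mass. The alternative reading
(circular variance of the angles themselves) was rejected because it moves in
the *opposite* direction under pixelation: concentrating angles at two fixed
directions lowers angular dispersion while raising bin-height variance, and
only the latter matches "pixelated images score higher".

**Paired t-test.** `t = mean(d) / (sd(d)/sqrt(n))`, one-tailed p from the t
distribution on n-1 degrees of freedom; zero-variance differences are an
error (undefined t), and the suite cross-checks against both `stats::t.test`
and direct numeric integration of the t density.

## The schematic eye

Pixel spacings convert to retinal micrometres through a three-surface
paraxial eye: a single corneal surface and two lens surfaces, personalised by
the three quantities measured per subject in practice (axial length, corneal
radius, anterior chamber depth) with the remaining constants defaulting to
the Gullstrand–Emsley simplified eye (lens radii +10/-6 mm, thickness 3.6 mm,
lens index 1.416, aqueous/vitreous 4/3). The elements act on (height, angle)
rays, so each element's determinant equals the refractive-index ratio across
it — asserted in tests as a conservation check. The second nodal point is
located by solving for the ray that exits at its entry angle, and

```
um_per_degree = (axial_length - nodal_point) * pi/180 * 1000
```

i.e. the posterior nodal distance times one degree in radians. The paraxial
(small-angle) regime is assumed, so the scale is constant across the ~1.5
degree fields involved; `um_per_pixel = um_per_degree * fov_deg / n_pixels`.
A degenerate single-surface eye has its nodal point at the centre of
curvature, giving the closed form `(L - R) * pi/180 * 1000` used as an exact
test anchor, and the full system is verified against an independent
surface-by-surface ray-trace oracle to 1e-9.

## Determinism and problem sizes

Every stochastic stage draws its seed from a single global seed via
`derive_seed(seed, stage_name)` (a 32-bit multiplicative hash), so re-running
a persisted configuration reproduces every artifact bit-for-bit, and adding a
stage does not shift another stage's stream. The bundled study sizes — 256-px
frames for spectral sweeps, 64 x 128 frames and 24 x 96 patches for the toy
restorer, 600 training steps — were chosen so that the full test suite and
the acceptance script each complete comfortably on a single CPU while leaving
the measured effects (spacing recovery within 5%, pixelation-score ordering,
restorer-above-baseline PSNR) far from their thresholds.

## Known limitations

* The restorer is a contract-faithful, desk-scale member of the
  residual-in-residual transformer-GAN family, not a replica of any published
  network's internals, capacity or training recipe; quality numbers obtained
  on synthetic data say nothing quantitative about clinical AOOCT data.
* Perceptual metrics that require externally pretrained feature extractors
  (DISTS, LPIPS, FID) are excluded by design; `quantify_images()` is the
  extension point for plugging them in where pretrained weights are
  available.
* No eye motion, scanner desinusoiding, wavefront-aberration residuals or
  foveal density gradients are simulated; no cone detection/counting is
  performed (spacing is estimated spectrally, not by segmentation).
* Speckle is available only as an i.i.d. multiplicative gain; correlated
  speckle is not modelled.
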