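# sparsecone

Simulation, sparse-sampling restoration and quantification of cone
photoreceptor mosaics for adaptive optics OCT (AOOCT) imaging studies.

## The problem

Cellular-resolution retinal imaging needs dense lateral pixel sampling: at
~1 mm from the fovea, cone photoreceptors are a few micrometres apart, so
each raster line needs hundreds of A-scans. Dense sampling costs acquisition
time, worsens eye-motion artifacts and generates terabytes of data. Sparsely
sampling the retina — keeping only every k-th A-scan — recovers speed and
storage, but renders the cones as laterally pixelated blocks. This package
provides the desk-scale machinery to study whether learned restoration can
close that gap, for researchers in ophthalmic imaging and computational
microscopy:

* **simulate** — synthetic en-face cone mosaics (Gaussian blobs on jittered
  hexagonal lattices at known spacing) and layered outer-retina volumes
  (IS/OS- and COST-like bands, optional sparse sub-mosaics, seeded repeat
  frames), standing in for human data that cannot be redistributed;
* **sampling** — factor-k lateral decimation (`degrade`), pixelated
  rendering (`pixelate_upsample`), seeded dense/sparse patch pairs and
  leave-one-subject-out splits;
* **restore** — a residual-in-residual windowed-attention transformer
  generator with an optional patch discriminator (GAN training), implemented
  natively in R with hand-derived gradients and trainable at toy scale on one
  CPU, plus nearest/linear/cubic interpolation baselines and frame averaging;
* **quantify** — PSNR, circumferentially averaged power spectral density
  with cone-peak detection (spacing and contrast), edge-direction histograms
  (pixelation score), and a one-tailed paired t-test;
* **eyemodel** — a three-surface paraxial schematic eye personalised by
  measured biometry, converting pixels to retinal micrometres.

## The statistics at the core

For an image `I`, the spectral spacing estimate is the radial position of the
off-DC peak of the circumferentially averaged power spectrum

```
P(f) = mean over annulus |f'| in bin(f) of |FFT(hann * (I - mean I))|^2 ,
```

normalised by total non-DC power. A quasi-hexagonal mosaic of spacing `s`
produces a ring (Yellott's ring) at its lattice row frequency, so
`s = (2/sqrt(3)) / f_peak`; the height of the peak above a running-median
background measures cellular contrast. Pixelation is scored as the variance
of the normalised edge-direction histogram (gradient directions
`atan2`-mapped to [0, 360), edges above the 90th magnitude percentile):
uniform directions (round cells) score 0, column-replication edges
concentrate mass at 90/270 degrees and score high. Image-space distances
convert to the retina through the posterior nodal distance of a paraxial
three-surface eye: `um/deg = (L - N) * pi/180 * 1000`.

## Worked example

```r
library(sparsecone)

spec  <- mosaic_spec(height_px = 256, width_px = 256, spacing_px = 10, seed = 1)
dense <- generate_mosaic(spec)

estimate_cone_spacing(dense)
#> <spectrum_peak> f = 0.1175 cyc/px, height = 0.001298 a.u., spacing = 9.83 px (hex-corrected)

sparse <- degrade(dense, factor = 4)   # keep every 4th column: 25% of the data
sparse
#> <image_plane> 256 x 64 px, range [0, 1]

nn <- pixelate_upsample(sparse, 4)     # pixelated rendering at dense size
psnr(dense, nn)
#> [1] 16.82 (dB)
edge_direction_histogram(dense)$bin_variance   # 5.31e-06  : smooth round cells
edge_direction_histogram(nn)$bin_variance      # 7.02e-04  : pixelated

scale <- retinal_scale(eye_biometry(axial_length_mm = 24.1, corneal_radius_mm = 7.7,
                                    anterior_chamber_depth_mm = 3.5),
                       fov_deg = 1.5, n_pixels = 512)
scale
#> <retinal_scale> 293.78 um/deg (nodal point 7.268 mm, PND 16.832 mm)
#>   0.8607 um/px over 1.5 deg / 512 px
spacing_px_to_um(9.83, 1.5, 512, scale)
#> [1] 8.46 (um)
```

The spacing estimate recovers the generated ground truth within 2%, the
pixelation score of the sparsely sampled rendering is two orders of magnitude
above the dense original, and the micron conversion lands in the anatomically
expected mid-peripheral range.

Training the restorer end to end (a few minutes on one CPU):

```r
study <- toy_restoration_study(seed = 1, steps = 600)
c(nearest = study$mean_psnr_nearest, enhanced = study$mean_psnr_enhanced)
#>  nearest enhanced
#>    17.14    23.28   (dB, held-out subject)
```

`run_pipeline(pipeline_config(seed = 7), "out/")` chains every stage —
simulate, degrade, pairs, leave-one-subject-out split, train, enhance,
quantify, micron scaling — and writes TIFFs, metrics CSVs, a model
checkpoint and a hashed JSON manifest. The same stages are scriptable from a
shell via `inst/cli/sparsecone.R`.

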