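#' Specification of a synthetic cone-photoreceptor mosaic
#'
#' Parameters of a synthetic en-face image of the cone mosaic: bright Gaussian
#' blobs on a jittered quasi-hexagonal lattice over a dim background, with
#' additive Gaussian (optionally multiplicative speckle-like) noise. The
#' defaults emulate a mid-peripheral AOOCT cone mosaic at a scale where the
#' spacing is comfortably resolved by a 256 px frame.
#'
#' @param height_px,width_px positive integers, image size in pixels.
#' @param spacing_px positive real, target nearest-neighbour cone distance in
#'   pixels (constant within a frame).
#' @param position_jitter_frac jitter magnitude as a fraction of spacing, in
#'   `[0, 0.5)`; each lattice node is displaced by independent uniform jitter
#'   of this magnitude per axis.
#' @param cone_radius_frac Gaussian blob sigma as a fraction of spacing,
#'   in `(0, 1)`.
#' @param amplitude_mean,amplitude_cv per-cone peak brightness mean and
#'   coefficient of variation.
#' @param background_level constant background in `[0, 1)`.
#' @param noise_sigma standard deviation of additive Gaussian noise applied
#'   after rendering (before clipping); `>= 0`.
#' @param noise_model `"gaussian"` (additive only) or `"speckle"` (additionally
#'   multiplies the rendered signal by unit-mean Rayleigh-distributed gain,
#'   emulating OCT speckle).
#' @param lattice `"hex"` (quasi-hexagonal, the photoreceptor-mosaic default)
#'   or `"square"` (exact square lattice, useful as a spectral oracle).
#' @param seed integer; the same spec and seed give a bit-identical image.
#' @return A `mosaic_spec` object (validated list).
#' @export
mosaic_spec <- function(height_px = 256L, width_px = 256L, spacing_px = 10,
                        position_jitter_frac = 0.15, cone_radius_frac = 0.25,
                        amplitude_mean = 0.7, amplitude_cv = 0.1,
                        background_level = 0.1, noise_sigma = 0.05,
                        noise_model = c("gaussian", "speckle"),
                        lattice = c("hex", "square"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  lattice <- match.arg(lattice)
  if (height_px < 1 || width_px < 1) stop("image dimensions must be positive", call. = FALSE)
  if (spacing_px <= 0) stop("`spacing_px` must be positive", call. = FALSE)
  if (position_jitter_frac < 0 || position_jitter_frac >= 0.5) {
    stop("`position_jitter_frac` must lie in [0, 0.5)", call. = FALSE)
  }
  if (cone_radius_frac <= 0 || cone_radius_frac >= 1) {
    stop("`cone_radius_frac` must lie in (0, 1)", call. = FALSE)
  }
  if (background_level < 0 || background_level >= 1) {
    stop("`background_level` must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(list(height_px = as.integer(height_px), width_px = as.integer(width_px),
                 spacing_px = spacing_px, position_jitter_frac = position_jitter_frac,
                 cone_radius_frac = cone_radius_frac, amplitude_mean = amplitude_mean,
                 amplitude_cv = amplitude_cv, background_level = background_level,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 lattice = lattice, seed = as.integer(seed)),
            class = "mosaic_spec")
}

# Jittered lattice of cone centres (x = column, y = row coordinates, 1-based
# pixel units) plus per-cone amplitudes. Centres up to `margin` px outside the
# frame are kept so that blob mass near the border is not depleted.
mosaic_centers <- function(spec) {
  s <- spec$spacing_px
  sigma <- spec$cone_radius_frac * s
  margin <- 3 * sigma
  if (spec$lattice == "hex") {
    row_step <- s * sqrt(3) / 2
    rows <- seq(1 - margin, spec$height_px + margin, by = row_step)
    pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      xs <- seq(1 - margin + off, spec$width_px + margin, by = s)
      cbind(x = xs, y = rows[i])
    }))
  } else {
    xs <- seq(1 - margin, spec$width_px + margin, by = s)
    ys <- seq(1 - margin, spec$height_px + margin, by = s)
    pts <- as.matrix(expand.grid(x = xs, y = ys))
  }
  n <- nrow(pts)
  jit <- spec$position_jitter_frac * s
  with_seed(derive_seed(spec$seed, "mosaic_geometry"), {
    if (jit > 0) {
      pts[, "x"] <- pts[, "x"] + stats::runif(n, -jit, jit)
      pts[, "y"] <- pts[, "y"] + stats::runif(n, -jit, jit)
    }
    amp <- spec$amplitude_mean *
      pmax(0, 1 + spec$amplitude_cv * stats::rnorm(n))
  })
  data.frame(x = pts[, "x"], y = pts[, "y"], amplitude = amp)
}

# Render Gaussian blobs at the given centres onto an H x W canvas.
render_blobs <- function(centers, height_px, width_px, sigma) {
  img <- matrix(0, height_px, width_px)
  half <- ceiling(3.5 * sigma)
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x[i]; cy <- centers$y[i]; a <- centers$amplitude[i]
    if (a <= 0) next
    r0 <- max(1L, floor(cy - half)); r1 <- min(height_px, ceiling(cy + half))
    c0 <- max(1L, floor(cx - half)); c1 <- min(width_px, ceiling(cx + half))
    if (r0 > r1 || c0 > c1) next
    gy <- exp(-((r0:r1 - cy)^2) / (2 * sigma^2))
    gx <- exp(-((c0:c1 - cx)^2) / (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + a * outer(gy, gx)
  }
  img
}

#' Generate a synthetic en-face cone mosaic
#'
#' Renders the jittered-lattice mosaic described by `spec` as an image in
#' `[0, 1]`. The hexagonal lattice produces the quasi-crystalline ring
#' (Yellott's ring analogue) in the power spectrum at the lattice row
#' frequency, so the ground-truth spacing is recoverable spectrally.
#'
#' @param spec a [mosaic_spec()].
#' @return An [image_plane()]; the jittered cone centres used are attached as
#'   attribute `"centers"` (a data.frame of x, y, amplitude).
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  centers <- mosaic_centers(spec)
  sigma <- spec$cone_radius_frac * spec$spacing_px
  img <- render_blobs(centers, spec$height_px, spec$width_px, sigma)
  with_seed(derive_seed(spec$seed, "mosaic_noise"), {
    if (spec$noise_model == "speckle") {
      # unit-mean Rayleigh gain: mode sigma_r with mean sigma_r * sqrt(pi/2)
      sigma_r <- sqrt(2 / pi)
      gain <- sigma_r * sqrt(-2 * log(stats::runif(length(img))))
      img <- img * matrix(gain, nrow(img), ncol(img))
    }
    img <- img + spec$background_level
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sigma),
                          nrow(img), ncol(img))
    }
  })
  out <- image_plane(clip01(img))
  attr(out, "centers") <- centers
  out
}

#' Specification of a layered synthetic AOOCT outer-retina volume
#'
#' Describes a volume in which every cone is an axial column whose depth
#' profile is a sum of Gaussian bands (at minimum an IS/OS-like and a
#' COST-like band). A band may be expressed by only a fraction of cones,
#' emulating sparse subsets such as S-cones.
#'
#' @param mosaic a [mosaic_spec()] defining the lateral cone geometry.
#' @param depth_px positive integer, number of depth samples.
#' @param layer_centers_px numeric vector of band centre depths, 0-based, each
#'   in `[0, depth_px)`.
#' @param layer_sigma_px axial Gaussian sigma per band (recycled).
#' @param layer_cone_fraction fraction of cones expressed in each band
#'   (recycled), in `(0, 1]`.
#' @param layer_gain relative band brightness (recycled).
#' @param n_repeats number of pre-aligned repeat volumes sharing geometry and
#'   differing only in noise realisation.
#' @return A `volume_spec` object.
#' @export
volume_spec <- function(mosaic, depth_px = 64L,
                        layer_centers_px = c(20, 44),
                        layer_sigma_px = 2, layer_cone_fraction = 1,
                        layer_gain = 1, n_repeats = 1L) {
  stopifnot(inherits(mosaic, "mosaic_spec"))
  if (depth_px < 1) stop("`depth_px` must be positive", call. = FALSE)
  if (length(layer_centers_px) == 0) stop("at least one layer is required", call. = FALSE)
  if (any(layer_centers_px < 0 | layer_centers_px >= depth_px)) {
    stop("`layer_centers_px` must lie in [0, depth_px)", call. = FALSE)
  }
  nb <- length(layer_centers_px)
  layer_sigma_px <- rep_len(layer_sigma_px, nb)
  layer_cone_fraction <- rep_len(layer_cone_fraction, nb)
  layer_gain <- rep_len(layer_gain, nb)
  if (any(layer_cone_fraction <= 0 | layer_cone_fraction > 1)) {
    stop("`layer_cone_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (n_repeats < 1) stop("`n_repeats` must be >= 1", call. = FALSE)
  structure(list(mosaic = mosaic, depth_px = as.integer(depth_px),
                 layer_centers_px = layer_centers_px,
                 layer_sigma_px = layer_sigma_px,
                 layer_cone_fraction = layer_cone_fraction,
                 layer_gain = layer_gain, n_repeats = as.integer(n_repeats)),
            class = "volume_spec")
}

#' Generate pre-aligned repeat volumes of a layered cone mosaic
#'
#' All repeats share the cone geometry and band layout (seeded from the mosaic
#' seed) and differ only in their noise realisation, which is seeded
#' deterministically from the spec seed and the repeat index. No eye motion is
#' simulated: repeats are returned already aligned.
#'
#' @param spec a [volume_spec()].
#' @return A list of [volume_stack()] objects of length `n_repeats`. The
#'   noiseless volume is attached to the list as attribute `"noiseless"`.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  ms <- spec$mosaic
  centers <- mosaic_centers(ms)
  sigma <- ms$cone_radius_frac * ms$spacing_px
  n <- nrow(centers)
  depth <- spec$depth_px
  zgrid <- seq_len(depth) - 1   # 0-based depth coordinates
  vol <- array(0, dim = c(depth, ms$height_px, ms$width_px))
  for (b in seq_along(spec$layer_centers_px)) {
    keep <- with_seed(derive_seed(ms$seed, paste0("band_subset_", b)), {
      stats::runif(n) < spec$layer_cone_fraction[b]
    })
    band_img <- render_blobs(centers[keep, , drop = FALSE],
                             ms$height_px, ms$width_px, sigma)
    ax <- spec$layer_gain[b] *
      exp(-((zgrid - spec$layer_centers_px[b])^2) / (2 * spec$layer_sigma_px[b]^2))
    nz <- which(ax > 1e-8)
    for (z in nz) vol[z, , ] <- vol[z, , ] + ax[z] * band_img
  }
  vol <- vol + ms$background_level
  noiseless <- volume_stack(clip01(vol))
  reps <- lapply(seq_len(spec$n_repeats), function(r) {
    v <- vol
    with_seed(derive_seed(ms$seed, paste0("volume_noise_", r)), {
      if (ms$noise_model == "speckle") {
        sigma_r <- sqrt(2 / pi)
        gain <- sigma_r * sqrt(-2 * log(stats::runif(length(v))))
        v <- (v - ms$background_level) * array(gain, dim(v)) + ms$background_level
      }
      if (ms$noise_sigma > 0) {
        v <- v + array(stats::rnorm(length(v), sd = ms$noise_sigma), dim(v))
      }
    })
    volume_stack(clip01(v))
  })
  attr(reps, "noiseless") <- noiseless
  reps
}

#' Project a depth band of a volume to an en-face image
#'
#' Projects over the half-open 0-based depth interval `[depth_lo, depth_hi)`.
#' Mean projection is linear in the voxel values; max projection is provided
#' for visualisation.
#'
#' @param volume a [volume_stack()].
#' @param depth_lo,depth_hi 0-based band limits, `0 <= depth_lo < depth_hi <= depth`.
#' @param mode `"mean"` or `"max"`.
#' @return An [image_plane()] of size slow x fast.
#' @export
extract_enface <- function(volume, depth_lo, depth_hi, mode = c("mean", "max")) {
  stopifnot(inherits(volume, "volume_stack"))
  mode <- match.arg(mode)
  d <- dim(volume)[1]
  if (depth_lo < 0 || depth_hi > d || depth_lo >= depth_hi) {
    stop("require 0 <= depth_lo < depth_hi <= depth", call. = FALSE)
  }
  idx <- (depth_lo + 1):depth_hi   # half-open [lo, hi) in 0-based depths
  slab <- unclass(volume)[idx, , , drop = FALSE]
  img <- if (mode == "mean") colMeans(slab, dims = 1) else apply(slab, c(2, 3), max)
  image_plane(img, pixel_pitch_deg = attr(volume, "pixel_pitch_deg"))
}
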