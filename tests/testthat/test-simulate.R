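test_that("noiseless jitter-free mosaic puts local maxima on lattice nodes", {
  spec <- mosaic_spec(height_px = 128, width_px = 128, spacing_px = 10,
                      position_jitter_frac = 0, amplitude_cv = 0,
                      noise_sigma = 0, seed = 1)
  img <- generate_mosaic(spec)
  centers <- attr(img, "centers")
  m <- unclass(img)
  # every interior local maximum above background must sit within 0.5 px of a node
  for (r in 3:(nrow(m) - 2)) {
    for (cc in 3:(ncol(m) - 2)) {
      v <- m[r, cc]
      if (v <= spec$background_level + 0.3) next
      if (v == max(m[(r - 1):(r + 1), (cc - 1):(cc + 1)])) {
        d <- sqrt((centers$x - cc)^2 + (centers$y - r)^2)
        expect_lt(min(d), 0.75)
      }
    }
  }
  expect_gt(nrow(centers), 0)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("mosaic generation is deterministic and seed-sensitive", {
  spec <- mosaic_spec(spacing_px = 9, seed = 42, height_px = 64, width_px = 64)
  a <- generate_mosaic(spec)
  b <- generate_mosaic(spec)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  spec2 <- mosaic_spec(spacing_px = 9, seed = 43, height_px = 64, width_px = 64)
  expect_false(identical(unclass(a)[, ], unclass(generate_mosaic(spec2))[, ]))
})

test_that("mosaic spec rejects invalid parameters", {
  expect_error(mosaic_spec(spacing_px = 0), "positive")
  expect_error(mosaic_spec(height_px = 0), "positive")
  expect_error(mosaic_spec(position_jitter_frac = 0.5), "0.5")
  expect_error(mosaic_spec(background_level = 1), "\\[0, 1\\)")
})

test_that("PSD pipeline recovers generated spacing within 5% on a jittered mosaic", {
  img <- tiny_mosaic(spacing = 10, seed = 7, h = 256, w = 256,
                     position_jitter_frac = 0.15)
  pk <- estimate_cone_spacing(img)
  expect_false(pk$no_peak)
  expect_lt(abs(pk$spacing_px - 10) / 10, 0.05)
})

test_that("volume bands sit at their stated depths and repeats average noise down", {
  ms <- mosaic_spec(height_px = 48, width_px = 48, spacing_px = 8,
                    noise_sigma = 0.08, seed = 3)
  vs <- volume_spec(ms, depth_px = 40, layer_centers_px = 12,
                    layer_sigma_px = 1.2, n_repeats = 3)
  reps <- generate_volume(vs)
  expect_length(reps, 3)
  noiseless <- attr(reps, "noiseless")
  # depth profile of the mean A-scan peaks at the band centre (0-based)
  prof <- apply(unclass(noiseless), 1, mean)
  expect_equal(which.max(prof) - 1L, 12L)
  # averaging repeats reduces residual vs noiseless below any single repeat
  avg <- average_frames(reps)
  res_avg <- sqrt(mean((unclass(avg) - unclass(noiseless))^2))
  res_single <- vapply(reps, function(v) {
    sqrt(mean((unclass(v) - unclass(noiseless))^2))
  }, numeric(1))
  expect_lt(res_avg, min(res_single))
})

test_that("volume generation rejects invalid layer layouts", {
  ms <- mosaic_spec(height_px = 32, width_px = 32, seed = 1)
  expect_error(volume_spec(ms, layer_centers_px = numeric(0)), "at least one")
  expect_error(volume_spec(ms, depth_px = 16, layer_centers_px = 16), "\\[0, depth_px\\)")
})

test_that("en-face band projection recovers the band mosaic and its spacing", {
  ms <- mosaic_spec(height_px = 128, width_px = 128, spacing_px = 10,
                    noise_sigma = 0, seed = 11)
  vs <- volume_spec(ms, depth_px = 48, layer_centers_px = c(14, 34),
                    layer_sigma_px = 2, n_repeats = 1)
  vol <- generate_volume(vs)[[1]]
  enf <- extract_enface(vol, 10, 19)
  # same geometry seed renders the same mosaic; projection matches up to the
  # axial gain profile and clipping
  direct <- generate_mosaic(ms)
  expect_gt(stats::cor(as.vector(unclass(enf)), as.vector(unclass(direct))), 0.9)
  pk <- estimate_cone_spacing(enf)
  expect_lt(abs(pk$spacing_px - 10) / 10, 0.05)
})

test_that("extract_enface obeys mean/max contracts and projection linearity", {
  const <- volume_stack(array(0.37, dim = c(8, 6, 5)))
  expect_equal(max(abs(unclass(extract_enface(const, 0, 8)) - 0.37)), 0)
  # one bright plane dominates a max projection
  v <- array(0, dim = c(8, 6, 5)); v[4, , ] <- 0.9
  expect_equal(unclass(extract_enface(volume_stack(v), 0, 8, mode = "max"))[, ],
               matrix(0.9, 6, 5))
  # mean projection is linear in the voxels
  a <- array(runif(8 * 6 * 5), dim = c(8, 6, 5))
  b <- array(runif(8 * 6 * 5), dim = c(8, 6, 5))
  pa <- unclass(extract_enface(volume_stack(a), 2, 7))
  pb <- unclass(extract_enface(volume_stack(b), 2, 7))
  pab <- unclass(extract_enface(volume_stack(a + b), 2, 7))
  expect_equal(pab, pa + pb, tolerance = 1e-12)
  expect_error(extract_enface(const, 3, 3), "depth_lo < depth_hi")
  expect_error(extract_enface(const, -1, 3), "depth_lo")
})

test_that("speckle noise model and square lattice are available and deterministic", {
  sp <- mosaic_spec(height_px = 64, width_px = 64, spacing_px = 8,
                    noise_model = "speckle", lattice = "square", seed = 5)
  a <- generate_mosaic(sp)
  expect_identical(unclass(a)[, ], unclass(generate_mosaic(sp))[, ])
  expect_true(all(a >= 0 & a <= 1))
})
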