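test_that("psnr matches closed forms and behaves under noise", {
  z <- matrix(0, 8, 8)
  expect_equal(psnr(z, matrix(1, 8, 8), max_value = 1), 0)
  # MSE = max^2 / 100  ->  20 dB
  expect_equal(psnr(z, matrix(0.1, 8, 8), max_value = 1), 20)
  expect_identical(psnr(z, z), Inf)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(psnr(a, b), psnr(b, a))                      # symmetric
  set.seed(4)
  p1 <- psnr(a, a + matrix(rnorm(64, sd = 0.01), 8, 8))
  p2 <- psnr(a, a + matrix(rnorm(64, sd = 0.05), 8, 8))
  expect_gt(p1, p2)                                         # noise decreases psnr
  expect_error(psnr(a, matrix(0, 4, 4)), "shape")
})

test_that("radial PSD localises a pure cosine and flags constant images", {
  x <- outer(rep(1, 64), cos(2 * pi * (0:63) / 8))          # period 8 px laterally
  spec <- radial_psd(0.5 + 0.3 * x, n_bins = 32, window = "none")
  band <- which(spec$frequencies > 0.11 & spec$frequencies < 0.14)
  energy <- spec$raw_power * spec$counts
  expect_gt(sum(energy[band]) / sum(energy), 0.9)
  const <- radial_psd(matrix(0.5, 32, 32))
  expect_true(const$degenerate)
  expect_equal(sum(const$power), 0)
})

test_that("radial PSD satisfies Parseval consistency against a direct FFT", {
  img <- tiny_mosaic(spacing = 9, seed = 13, h = 96, w = 96)
  spec <- radial_psd(img, n_bins = 48)
  # independent total: Hann-windowed FFT power over 0 < r <= 0.5
  m <- unclass(img)[, ]
  m0 <- m - mean(m)
  hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  P <- Mod(stats::fft(m0 * outer(hann(96), hann(96))))^2
  fr <- (0:95); fr <- ifelse(fr <= 48, fr, fr - 96) / 96
  r <- sqrt(outer(fr^2, fr^2, "+"))
  total <- sum(P[r > 0 & r <= 0.5])
  expect_equal(sum(spec$raw_power * spec$counts) / total, 1, tolerance = 1e-6)
  expect_equal(spec$total_power / total, 1, tolerance = 1e-6)
})

test_that("cell peak detection matches constructed spectra and hex correction", {
  # synthetic spectrum: flat background with a triangular bump at f = 0.1
  n <- 64
  freqs <- seq(0, 0.5, length.out = n + 1)
  centers <- (freqs[-1] + freqs[-(n + 1)]) / 2
  pw <- rep(0.01, n)
  i0 <- which.min(abs(centers - 0.1))
  pw[(i0 - 2):(i0 + 2)] <- pw[(i0 - 2):(i0 + 2)] + c(0.2, 0.6, 1, 0.6, 0.2) * 0.05
  spec <- structure(list(frequencies = centers, power = pw, raw_power = pw,
                         counts = rep(100L, n), total_power = sum(pw * 100),
                         normalization = "total_nonDC_power", degenerate = FALSE),
                    class = "radial_spectrum")
  pk <- find_cell_peak(spec, search_band = c(0.05, 0.2), hex_correction = FALSE)
  expect_false(pk$no_peak)
  expect_equal(pk$peak_frequency, centers[i0], tolerance = 1e-3)
  expect_equal(pk$spacing_px, 1 / pk$peak_frequency)
  pk_hex <- find_cell_peak(spec, search_band = c(0.05, 0.2), hex_correction = TRUE)
  expect_equal(pk_hex$spacing_px, pk$spacing_px * 2 / sqrt(3))
  # no positive excess -> flagged
  flat <- spec; flat$power <- rep(0.01, n); flat$raw_power <- flat$power
  expect_true(find_cell_peak(flat, search_band = c(0.05, 0.2))$no_peak)
})

test_that("square-lattice mosaic peak sits at 1/spacing without hex correction", {
  img <- generate_mosaic(mosaic_spec(height_px = 256, width_px = 256,
                                     spacing_px = 8, position_jitter_frac = 0,
                                     noise_sigma = 0, lattice = "square", seed = 1))
  pk <- estimate_cone_spacing(img, hex_correction = FALSE)
  expect_equal(pk$spacing_px, 8, tolerance = 0.05)
})

test_that("spacing estimates survive rotation and recover across the spacing range", {
  img <- tiny_mosaic(spacing = 11, seed = 21, h = 192, w = 192)
  pk1 <- estimate_cone_spacing(img)
  pk2 <- estimate_cone_spacing(t(unclass(img)[, ]))
  expect_lt(abs(pk1$spacing_px - pk2$spacing_px) / pk1$spacing_px, 0.02)
  for (s in c(6, 12, 16)) {
    pk <- estimate_cone_spacing(tiny_mosaic(spacing = s, seed = 31, h = 256, w = 256),
                                search_band = c(0.04, 0.35))
    expect_lt(abs(pk$spacing_px - s) / s, 0.05)
  }
})

test_that("peak height decreases monotonically with added noise", {
  base <- tiny_mosaic(spacing = 10, seed = 17, h = 192, w = 192, noise_sigma = 0)
  m <- unclass(base)[, ]
  set.seed(5)
  heights <- vapply(c(0, 0.05, 0.12), function(s) {
    noisy <- m + matrix(rnorm(length(m), sd = s), nrow(m))
    noisy[noisy < 0] <- 0; noisy[noisy > 1] <- 1
    estimate_cone_spacing(noisy)$peak_height
  }, numeric(1))
  expect_true(all(diff(heights) < 0))
})

test_that("edge histogram: single-direction field loads one bin with maximal variance", {
  ramp <- outer(seq(0, 1, length.out = 32), rep(1, 32))     # varies along rows only
  h <- edge_direction_histogram(ramp, n_bins = 36)
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_equal(max(h$mass), 1)
  expect_equal(h$bin_variance, (36 - 1) / 36^2, tolerance = 1e-12)
  const <- edge_direction_histogram(matrix(0.5, 32, 32))
  expect_true(const$empty)
})

test_that("edge histogram is near-uniform for isotropic filtered noise", {
  set.seed(3)
  n <- 128
  wn <- matrix(rnorm(n * n), n, n)
  # isotropic Gaussian low-pass in the Fourier domain
  fr <- (0:(n - 1)); fr <- ifelse(fr <= n / 2, fr, fr - n) / n
  r2 <- outer(fr^2, fr^2, "+")
  sm <- Re(stats::fft(stats::fft(wn) * exp(-r2 / (2 * 0.05^2)), inverse = TRUE)) / n^2
  h <- edge_direction_histogram(sm, n_bins = 36)
  expect_lt(max(h$mass), 2 / 36)
  expect_lt(h$bin_variance, 1e-4)
})

test_that("lateral pixel replication concentrates edges at 90 and 270 degrees", {
  img <- tiny_mosaic(spacing = 10, seed = 23)
  nn <- pixelate_upsample(degrade(img, 4), 4)
  hd <- edge_direction_histogram(img)
  hn <- edge_direction_histogram(nn)
  expect_gt(mass_at(hn, c(90, 270)), 2 * (2 / length(hn$mass)))
  expect_gt(hn$bin_variance, hd$bin_variance)
  # smooth interpolation also scores lower than replication
  hc <- edge_direction_histogram(baseline_upsample(degrade(img, 4), 4, "cubic"))
  expect_gt(hn$bin_variance, hc$bin_variance)
})

test_that("one-tailed paired t-test matches its formula and handles degenerate input", {
  expect_error(paired_ttest_one_tailed(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  r <- paired_ttest_one_tailed(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 0.5)
  expect_equal(r$degrees_of_freedom, 3)
  before <- c(10, 11, 12, 13); after <- before + c(1, 2, 3, 4)
  r2 <- paired_ttest_one_tailed(before, after, "greater")
  # agreement with stats::t.test as an independent route
  tt <- stats::t.test(after, before, paired = TRUE, alternative = "greater")
  expect_equal(r2$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(r2$mean_difference, 2.5)
  r3 <- paired_ttest_one_tailed(after, before, "less")
  expect_equal(r3$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("quantify_images returns one labelled row per image with micron scaling", {
  img <- tiny_mosaic(spacing = 10, seed = 29)
  nn <- pixelate_upsample(degrade(img, 4), 4)
  sc <- retinal_scale(eye_biometry(), fov_deg = 1.5, n_pixels = 512)
  df <- quantify_images(list(img, img), list(img, nn), labels = c("dense", "nearest"),
                        fov_deg = 1.5, n_pixels = 512, scale = sc)
  expect_equal(nrow(df), 2)
  expect_identical(df$psnr_db[1], Inf)
  expect_true(all(c("spacing_px", "peak_height", "edge_bin_variance", "spacing_um")
                  %in% names(df)))
  expect_equal(df$spacing_um[1], df$spacing_px[1] * (1.5 / 512) * sc$um_per_degree)
})
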