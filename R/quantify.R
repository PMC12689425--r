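#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` with MSE the mean squared pixel difference;
#' identical images return `Inf`.
#'
#' @param reference,test same-shaped images (matrices or [image_plane()]s).
#' @param max_value positive dynamic range (1 for images in `[0, 1]`).
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, test, max_value = 1) {
  r <- as.matrix(reference); t2 <- as.matrix(test)
  if (!identical(dim(r), dim(t2))) stop("images must share a shape", call. = FALSE)
  if (max_value <= 0) stop("`max_value` must be > 0", call. = FALSE)
  mse <- mean((r - t2)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Circumferentially averaged power spectral density
#'
#' Hann-windowed 2D FFT, squared magnitude, mean over annuli of constant
#' radial frequency in cycles/pixel over `(0, 0.5]` (DC excluded). The annular
#' means are normalised by the total non-DC power inside the binned region, so
#' peak heights are comparable across images; the unnormalised annular power,
#' per-annulus pixel counts and the normalising total are kept for Parseval
#' checks.
#'
#' @param image an [image_plane()] or matrix, at least 16 x 16.
#' @param n_bins number of annuli, `>= 8`.
#' @param window `"hann"` or `"none"`.
#' @param aspect ratio of row-axis to column-axis pixel pitch; the row
#'   frequency grid is scaled by it, handling anisotropic sampling (default 1).
#' @return A `radial_spectrum`: list with `frequencies` (bin centres),
#'   `power` (normalised annular means), `raw_power`, `counts`, `total_power`,
#'   `normalization` and `degenerate` flag.
#' @export
radial_psd <- function(image, n_bins = 128L, window = c("hann", "none"),
                       aspect = 1) {
  window <- match.arg(window)
  m <- as.matrix(image)
  H <- nrow(m); W <- ncol(m)
  if (H < 16L || W < 16L) stop("image must be at least 16 x 16", call. = FALSE)
  if (n_bins < 8L) stop("`n_bins` must be >= 8", call. = FALSE)
  edges <- seq(0, 0.5, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  if (max(m) == min(m)) {
    return(structure(list(frequencies = centers, power = numeric(n_bins),
                          raw_power = numeric(n_bins), counts = integer(n_bins),
                          total_power = 0, normalization = "total_nonDC_power",
                          degenerate = TRUE),
                     class = "radial_spectrum"))
  }
  m0 <- m - mean(m)
  if (window == "hann") {
    hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    m0 <- m0 * outer(hann(H), hann(W))
  }
  P <- Mod(stats::fft(m0))^2
  fr <- function(n) {
    k <- seq_len(n) - 1L
    ifelse(k <= n %/% 2, k, k - n) / n
  }
  fy <- fr(H) * aspect
  fx <- fr(W)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  keep <- r > 0 & r <= 0.5
  total <- sum(P[keep])
  bin <- findInterval(r[keep], edges, rightmost.closed = TRUE)
  raw <- numeric(n_bins); counts <- integer(n_bins)
  agg_sum <- tapply(P[keep], bin, sum)
  agg_n <- tapply(P[keep], bin, length)
  ii <- as.integer(names(agg_sum))
  raw[ii] <- as.numeric(agg_sum) / as.numeric(agg_n)
  counts[ii] <- as.integer(agg_n)
  structure(list(frequencies = centers,
                 power = if (total > 0) raw / total else raw,
                 raw_power = raw, counts = counts, total_power = total,
                 normalization = "total_nonDC_power", degenerate = FALSE),
            class = "radial_spectrum")
}

#' @export
print.radial_spectrum <- function(x, ...) {
  cat(sprintf("<radial_spectrum> %d annuli over (0, 0.5] cycles/px%s\n",
              length(x$frequencies),
              if (x$degenerate) " (degenerate: constant image)" else ""))
  invisible(x)
}

#' Detect the cone fundamental-frequency peak of a radial spectrum
#'
#' The cone mosaic produces a ring (Yellott's ring) in the 2D spectrum whose
#' radial position is the cell fundamental frequency and whose height above
#' background measures cellular contrast. Background is estimated by a running
#' median of the log spectrum outside the search band, interpolated across it;
#' the peak is the maximum excess of the normalised power over that background
#' within the band, with parabolic sub-bin refinement of its frequency. For a
#' hexagonal mosaic the ring sits at the lattice row frequency, so
#' `hex_correction` multiplies the naive `1 / frequency` spacing by
#' `2 / sqrt(3)` to convert row spacing to centre-to-centre distance.
#'
#' @param spectrum a [radial_psd()] result.
#' @param search_band numeric `(f_lo, f_hi)` inside `(0, 0.5]`.
#' @param hex_correction logical, see above.
#' @param median_k odd integer width of the running-median background filter.
#' @return A `spectrum_peak`: `peak_frequency` (cycles/px), `peak_height`
#'   (normalised power excess), `spacing_px`, `search_band`, `hex_correction`
#'   and a `no_peak` flag (fields are `NA` when flagged).
#' @export
find_cell_peak <- function(spectrum, search_band = c(0.05, 0.35),
                           hex_correction = TRUE, median_k = 11L) {
  stopifnot(inherits(spectrum, "radial_spectrum"))
  lo <- search_band[1]; hi <- search_band[2]
  if (lo <= 0 || hi > 0.5 || lo >= hi) {
    stop("`search_band` must lie within (0, 0.5]", call. = FALSE)
  }
  f <- spectrum$frequencies
  pw <- spectrum$power
  no_peak <- function() {
    structure(list(peak_frequency = NA_real_, peak_height = NA_real_,
                   spacing_px = NA_real_, search_band = c(lo, hi),
                   hex_correction = hex_correction, no_peak = TRUE),
              class = "spectrum_peak")
  }
  in_band <- f >= lo & f <= hi
  if (spectrum$degenerate || !any(in_band)) return(no_peak())
  eps <- 1e-12
  ls <- log(pw + eps)
  out_idx <- which(!in_band & spectrum$counts > 0)
  if (length(out_idx) >= 3L) {
    k <- min(as.integer(median_k), length(out_idx))
    if (k %% 2L == 0L) k <- k - 1L
    sm <- stats::runmed(ls[out_idx], max(k, 1L))
    bg_log <- stats::approx(f[out_idx], sm, xout = f, rule = 2)$y
  } else {
    bg_log <- rep(stats::median(ls), length(f))
  }
  excess <- pw - exp(bg_log)
  band_idx <- which(in_band)
  i_max <- band_idx[which.max(excess[band_idx])]
  if (!is.finite(excess[i_max]) || excess[i_max] <= 0) return(no_peak())
  # parabolic sub-bin refinement of the peak frequency
  fpk <- f[i_max]
  if (i_max > 1L && i_max < length(f)) {
    y1 <- excess[i_max - 1L]; y2 <- excess[i_max]; y3 <- excess[i_max + 1L]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      delta <- max(-1, min(1, delta))
      fpk <- f[i_max] + delta * (f[2] - f[1])
    }
  }
  spacing <- 1 / fpk * (if (hex_correction) 2 / sqrt(3) else 1)
  structure(list(peak_frequency = fpk, peak_height = excess[i_max],
                 spacing_px = spacing, search_band = c(lo, hi),
                 hex_correction = hex_correction, no_peak = FALSE),
            class = "spectrum_peak")
}

#' @export
print.spectrum_peak <- function(x, ...) {
  if (x$no_peak) {
    cat("<spectrum_peak> no peak found in band\n")
  } else {
    cat(sprintf("<spectrum_peak> f = %.4f cyc/px, height = %.4g a.u., spacing = %.2f px%s\n",
                x$peak_frequency, x$peak_height, x$spacing_px,
                if (x$hex_correction) " (hex-corrected)" else ""))
  }
  invisible(x)
}

#' Estimate cone spacing of an en-face image
#'
#' Convenience chain of [radial_psd()] and [find_cell_peak()].
#'
#' @inheritParams radial_psd
#' @inheritParams find_cell_peak
#' @return A `spectrum_peak`.
#' @export
estimate_cone_spacing <- function(image, n_bins = 128L,
                                  search_band = c(0.05, 0.35),
                                  hex_correction = TRUE, window = "hann",
                                  aspect = 1) {
  find_cell_peak(radial_psd(image, n_bins = n_bins, window = window,
                            aspect = aspect),
                 search_band = search_band, hex_correction = hex_correction)
}

sobel_gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- 2:(H - 1L); ci <- 2:(W - 1L)
  # Gx: horizontal (column-direction) derivative; Gy: vertical (row-direction)
  Gx <- (m[ri - 1L, ci + 1L] + 2 * m[ri, ci + 1L] + m[ri + 1L, ci + 1L]) -
        (m[ri - 1L, ci - 1L] + 2 * m[ri, ci - 1L] + m[ri + 1L, ci - 1L])
  Gy <- (m[ri + 1L, ci - 1L] + 2 * m[ri + 1L, ci] + m[ri + 1L, ci + 1L]) -
        (m[ri - 1L, ci - 1L] + 2 * m[ri - 1L, ci] + m[ri - 1L, ci + 1L])
  list(Gx = Gx, Gy = Gy)
}

central_diff_gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- 2:(H - 1L); ci <- 2:(W - 1L)
  list(Gx = (m[ri, ci + 1L] - m[ri, ci - 1L]) / 2,
       Gy = (m[ri + 1L, ci] - m[ri - 1L, ci]) / 2)
}

#' Edge-direction histogram (pixelation score)
#'
#' Computes per-pixel intensity gradients, keeps the pixels whose gradient
#' magnitude exceeds the given percentile (the "edges"), maps each edge's
#' full-circle direction to `[0, 360)` degrees and histograms it, normalised
#' to unit mass. The axis convention is fixed so that the block boundaries of
#' laterally pixel-replicated images load the 90 / 270 degree bins. The
#' variance of the normalised bin heights around their mean `1/n_bins` is the
#' pixelation score: 0 for a uniform distribution (smooth round cells),
#' maximal `(n_bins - 1) / n_bins^2` when all mass falls in one bin.
#'
#' @param image an [image_plane()] or matrix.
#' @param gradient_op `"sobel"` (default) or `"central_difference"`.
#' @param threshold_percentile magnitude percentile in `(0, 100)` above which
#'   a pixel counts as an edge (default 90).
#' @param n_bins number of angular bins, `>= 8` (default 36).
#' @return An `edge_direction_histogram`: `bin_edges` (degrees), `mass`
#'   (normalised heights), `magnitude_threshold`, `bin_variance`,
#'   `n_edge_pixels` and an `empty` flag (constant image).
#' @export
edge_direction_histogram <- function(image,
                                     gradient_op = c("sobel", "central_difference"),
                                     threshold_percentile = 90, n_bins = 36L) {
  gradient_op <- match.arg(gradient_op)
  if (n_bins < 8L) stop("`n_bins` must be >= 8", call. = FALSE)
  if (threshold_percentile <= 0 || threshold_percentile >= 100) {
    stop("`threshold_percentile` must lie in (0, 100)", call. = FALSE)
  }
  m <- as.matrix(image)
  if (nrow(m) < 3L || ncol(m) < 3L) stop("image too small for gradients", call. = FALSE)
  g <- if (gradient_op == "sobel") sobel_gradients(m) else central_diff_gradients(m)
  mag <- sqrt(g$Gx^2 + g$Gy^2)
  edges_deg <- seq(0, 360, length.out = n_bins + 1L)
  if (max(mag) == 0) {
    return(structure(list(bin_edges = edges_deg, mass = numeric(n_bins),
                          magnitude_threshold = 0, bin_variance = NA_real_,
                          n_edge_pixels = 0L, empty = TRUE),
                     class = "edge_direction_histogram"))
  }
  thr <- stats::quantile(mag, threshold_percentile / 100, names = FALSE)
  sel <- mag > thr
  if (!any(sel)) sel <- mag >= thr   # ties at a flat top percentile
  # convention: atan2(Gx, Gy) puts purely lateral gradients at 90 / 270 deg
  ang <- (atan2(g$Gx[sel], g$Gy[sel]) * 180 / pi) %% 360
  bin <- pmin(findInterval(ang, edges_deg, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mass <- counts / sum(counts)
  structure(list(bin_edges = edges_deg, mass = mass,
                 magnitude_threshold = thr,
                 bin_variance = mean((mass - 1 / n_bins)^2),
                 n_edge_pixels = sum(counts), empty = FALSE),
            class = "edge_direction_histogram")
}

#' @export
print.edge_direction_histogram <- function(x, ...) {
  if (x$empty) {
    cat("<edge_direction_histogram> empty (constant image)\n")
  } else {
    cat(sprintf("<edge_direction_histogram> %d bins, %d edge px, bin variance %.3g\n",
                length(x$mass), x$n_edge_pixels, x$bin_variance))
  }
  invisible(x)
}

#' One-tailed paired Student's t-test
#'
#' Tests for improvement in paired per-image metrics. With differences
#' `d = after - before`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees
#' of freedom; `direction = "greater"` takes the one-tailed p for
#' `mean(d) > 0` (metric increased), `"less"` for `mean(d) < 0`.
#'
#' @param before,after equal-length numeric vectors, `n >= 2`.
#' @param direction `"greater"` (default) or `"less"`.
#' @return A `paired_test_result`: `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `mean_difference`, `direction`.
#' @export
paired_ttest_one_tailed <- function(before, after,
                                    direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(before) != length(after)) stop("unequal lengths", call. = FALSE)
  n <- length(before)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: t statistic undefined", call. = FALSE)
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  p <- if (direction == "greater") {
    stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df)
  }
  structure(list(t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p, mean_difference = mean(d), direction = direction),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> t = %.4g (df %d), one-tailed p = %.4g (%s), mean diff = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$direction,
              x$mean_difference))
  invisible(x)
}

#' Per-image quality metrics table
#'
#' Computes the package's scalar metrics for a set of test images against
#' their references: PSNR, cone peak frequency / spacing / contrast, and
#' edge-direction bin variance. Returns one row per image.
#'
#' @param references,tests equal-length lists of same-shaped images.
#' @param labels optional row labels.
#' @param search_band,hex_correction passed to [find_cell_peak()].
#' @param fov_deg,n_pixels,scale optional: when all are given, spacing is also
#'   reported in micrometres via [spacing_px_to_um()].
#' @return A data.frame with columns `label`, `psnr_db`, `peak_frequency`,
#'   `spacing_px`, `peak_height`, `edge_bin_variance` (and `spacing_um` when a
#'   scale is supplied).
#' @export
quantify_images <- function(references, tests, labels = NULL,
                            search_band = c(0.05, 0.35), hex_correction = TRUE,
                            fov_deg = NULL, n_pixels = NULL, scale = NULL) {
  stopifnot(length(references) == length(tests))
  if (is.null(labels)) labels <- sprintf("image_%02d", seq_along(tests))
  rows <- lapply(seq_along(tests), function(i) {
    pk <- estimate_cone_spacing(tests[[i]], search_band = search_band,
                                hex_correction = hex_correction)
    eh <- edge_direction_histogram(tests[[i]])
    out <- data.frame(label = labels[i],
                      psnr_db = psnr(references[[i]], tests[[i]]),
                      peak_frequency = pk$peak_frequency,
                      spacing_px = pk$spacing_px,
                      peak_height = pk$peak_height,
                      edge_bin_variance = eh$bin_variance)
    if (!is.null(fov_deg) && !is.null(n_pixels) && !is.null(scale)) {
      out$spacing_um <- spacing_px_to_um(pk$spacing_px, fov_deg, n_pixels, scale)
    }
    out
  })
  do.call(rbind, rows)
}
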