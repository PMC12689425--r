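#' Interpolation baselines for lateral up-sampling
#'
#' 1D interpolation along the lateral (column) axis only, used as comparator
#' restorations. Alignment convention: sparse sample `j` (1-based) sits at
#' dense column `(j - 1) * factor + 1`, matching phase-0 decimation, and
#' queries beyond the last sample are held constant. `"nearest"` is bit-exact
#' with [pixelate_upsample()].
#'
#' @param sparse an [image_plane()] or matrix.
#' @param factor integer up-sampling factor, `>= 1`.
#' @param method `"nearest"`, `"linear"` or `"cubic"` (natural spline).
#' @return An [image_plane()] with width `width * factor`.
#' @export
baseline_upsample <- function(sparse, factor = 4L,
                              method = c("nearest", "linear", "cubic")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  m <- as.matrix(sparse)
  if (method == "nearest" || factor == 1L) {
    return(pixelate_upsample(m, factor))
  }
  W <- ncol(m)
  xs <- (seq_len(W) - 1L) * factor + 1L
  xq <- seq_len(W * factor)
  out <- matrix(0, nrow(m), W * factor)
  for (r in seq_len(nrow(m))) {
    out[r, ] <- if (method == "linear") {
      stats::approx(xs, m[r, ], xout = xq, rule = 2)$y
    } else {
      fn <- stats::splinefun(xs, m[r, ], method = "natural")
      y <- fn(xq)
      y[xq > xs[W]] <- m[r, W]   # constant extension past the last sample
      y
    }
  }
  as_image_plane(out, sparse)
}

#' Voxelwise mean of pre-aligned repeat volumes
#'
#' Averaging independent-noise repeats reduces the noise standard deviation by
#' about `1/sqrt(k)`; inputs must already be aligned (no registration is
#' performed).
#'
#' @param volumes non-empty list of [volume_stack()] objects of identical shape.
#' @return A [volume_stack()].
#' @export
average_frames <- function(volumes) {
  if (length(volumes) == 0L) stop("empty volume list", call. = FALSE)
  stopifnot(all(vapply(volumes, inherits, logical(1), "volume_stack")))
  d <- dim(volumes[[1]])
  for (v in volumes) {
    if (!identical(dim(v), d)) stop("volumes must share a common shape", call. = FALSE)
  }
  acc <- array(0, dim = d)
  for (v in volumes) acc <- acc + unclass(v)
  volume_stack(acc / length(volumes),
               pixel_pitch_deg = attr(volumes[[1]], "pixel_pitch_deg"))
}
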