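#' Grayscale en-face image or B-scan
#'
#' Lightweight carrier for a 2D pixel grid in `[0, 1]` with optional angular
#' pixel pitch metadata. Rows are the first (axial or slow) axis, columns the
#' second (lateral/fast) axis; all crops and bands use 0-free, 1-based R
#' indexing with half-open conventions documented per function.
#'
#' @param pixels numeric matrix, finite values.
#' @param pixel_pitch_deg optional numeric length-2 vector, degrees of visual
#'   angle per pixel along (row, column) axes.
#' @return An `image_plane` object (a matrix with class and pitch attributes).
#' @export
image_plane <- function(pixels, pixel_pitch_deg = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("`pixels` must be finite", call. = FALSE)
  if (!is.null(pixel_pitch_deg)) {
    pixel_pitch_deg <- rep_len(as.numeric(pixel_pitch_deg), 2L)
    if (any(pixel_pitch_deg < 0)) stop("pixel pitch must be >= 0", call. = FALSE)
  }
  structure(pixels,
            pixel_pitch_deg = pixel_pitch_deg,
            class = c("image_plane", "matrix", "array"))
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  pp <- attr(x, "pixel_pitch_deg")
  if (!is.null(pp)) cat(sprintf("  pixel pitch: %.5g x %.5g deg/px\n", pp[1], pp[2]))
  invisible(x)
}

#' @export
as.matrix.image_plane <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

as_image_plane <- function(x, template = NULL) {
  if (inherits(x, "image_plane")) return(x)
  image_plane(as.matrix(x),
              pixel_pitch_deg = if (!is.null(template)) attr(template, "pixel_pitch_deg"))
}

#' 3D image volume (depth x slow-lateral x fast-lateral)
#'
#' Axis order is fixed everywhere in the package as
#' (depth, slow-lateral, fast-lateral); a B-scan is the
#' (depth, fast-lateral) slice at a fixed slow position.
#'
#' @param voxels numeric 3D array, finite values.
#' @param pixel_pitch_deg optional numeric length-2 vector, degrees per pixel
#'   along the (slow, fast) lateral axes.
#' @return A `volume_stack` object.
#' @export
volume_stack <- function(voxels, pixel_pitch_deg = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(voxels))) stop("`voxels` must be finite", call. = FALSE)
  if (!is.null(pixel_pitch_deg)) {
    pixel_pitch_deg <- rep_len(as.numeric(pixel_pitch_deg), 2L)
  }
  structure(voxels,
            pixel_pitch_deg = pixel_pitch_deg,
            class = c("volume_stack", "array"))
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_stack> depth %d x slow %d x fast %d, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Extract one B-scan from a volume
#'
#' @param volume a [volume_stack()].
#' @param slow 1-based index along the slow lateral axis.
#' @return An [image_plane()] with rows = depth, columns = fast lateral axis.
#' @export
bscan <- function(volume, slow) {
  stopifnot(inherits(volume, "volume_stack"))
  d <- dim(volume)
  if (slow < 1L || slow > d[2]) stop("slow index out of range", call. = FALSE)
  m <- volume[, slow, , drop = TRUE]
  dim(m) <- c(d[1], d[3])
  pp <- attr(volume, "pixel_pitch_deg")
  image_plane(m, pixel_pitch_deg = if (!is.null(pp)) c(NA_real_, pp[2]))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
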