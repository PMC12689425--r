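#' Laterally down-sample a densely sampled image
#'
#' Emulates sparse acquisition: a factor-`factor` reduction of the lateral
#' (column) sampling density, so a 40 x 400 B-scan region of interest becomes
#' 40 x 100 at the default factor 4. `"decimate"` keeps the columns at 1-based
#' indices 1, 1 + k, 1 + 2k, ... (phase 0 in 0-based terms), which models
#' skipped A-scans; `"block_average"` averages each consecutive block of k
#' columns, which models binned acquisition.
#'
#' @param dense an [image_plane()] or numeric matrix.
#' @param factor integer down-sampling factor, `>= 1`.
#' @param mode `"decimate"` (default) or `"block_average"`.
#' @param allow_crop if `TRUE`, a width not divisible by `factor` is cropped
#'   from the right edge with a warning; otherwise it is an error.
#' @return An [image_plane()] with width `width / factor`; rows untouched.
#' @export
degrade <- function(dense, factor = 4L, mode = c("decimate", "block_average"),
                    allow_crop = FALSE) {
  mode <- match.arg(mode)
  m <- as.matrix(dense)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  w <- ncol(m)
  if (w %% factor != 0L) {
    if (!allow_crop) {
      stop(sprintf("width %d not divisible by factor %d (set allow_crop = TRUE to crop)",
                   w, factor), call. = FALSE)
    }
    w2 <- (w %/% factor) * factor
    warning(sprintf("cropping width %d -> %d from the right edge", w, w2), call. = FALSE)
    m <- m[, seq_len(w2), drop = FALSE]
    w <- w2
  }
  if (factor == 1L) return(as_image_plane(m, dense))
  out <- if (mode == "decimate") {
    m[, seq(1L, w, by = factor), drop = FALSE]
  } else {
    # averaging operator: w x (w/k) block-indicator matrix / k
    grp <- rep(seq_len(w %/% factor), each = factor)
    A <- matrix(0, w, w %/% factor)
    A[cbind(seq_len(w), grp)] <- 1 / factor
    m %*% A
  }
  as_image_plane(out, dense)
}

#' Replicate sparse columns to the dense grid (pixelated rendering)
#'
#' Nearest-neighbour replication of each column `factor` times along the
#' lateral axis; renders a sparsely sampled image at dense-grid size with the
#' characteristic pixelated appearance.
#'
#' @param sparse an [image_plane()] or numeric matrix.
#' @param factor integer replication factor, `>= 1`.
#' @return An [image_plane()] with width `width * factor`.
#' @export
pixelate_upsample <- function(sparse, factor = 4L) {
  m <- as.matrix(sparse)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(as_image_plane(m, sparse))
  as_image_plane(m[, rep(seq_len(ncol(m)), each = factor), drop = FALSE], sparse)
}

#' Build a dense/sparse patch-pair training set
#'
#' Randomly crops `n_per_image` dense patches of `dense_shape` from each input
#' image (seeded, reproducible), pairs each with its lateral degradation, and
#' carries per-image metadata for leave-one-subject-out splitting. By
#' construction `degrade(dense) == sparse` exactly for every pair.
#'
#' @param images list of [image_plane()] / matrices.
#' @param subject_id character/integer vector, one per image.
#' @param location_mm optional numeric vector, one per image (retinal
#'   eccentricity bookkeeping; defaults to `NA`).
#' @param dense_shape integer length-2 `(rows, cols)` of the dense patch
#'   (default `c(40, 400)`).
#' @param factor,mode degradation parameters passed to [degrade()].
#' @param n_per_image number of crops per image.
#' @param seed integer seed for the crop coordinates.
#' @return A `patch_pair_set`: list with elements `dense` (list), `sparse`
#'   (list) and `meta` (data.frame with subject_id, location_mm, image, row0,
#'   col0 of each 1-based crop origin).
#' @export
make_patch_pairs <- function(images, subject_id, location_mm = NULL,
                             dense_shape = c(40L, 400L), factor = 4L,
                             mode = "decimate", n_per_image = 1L, seed = 1L) {
  stopifnot(length(images) >= 1L, length(subject_id) == length(images))
  if (is.null(location_mm)) location_mm <- rep(NA_real_, length(images))
  dense_shape <- as.integer(dense_shape)
  if (dense_shape[2] %% factor != 0L) {
    stop("dense patch width must be divisible by `factor`", call. = FALSE)
  }
  dense <- list(); sparse <- list(); meta <- NULL
  with_seed(derive_seed(seed, "patch_crops"), {
    for (i in seq_along(images)) {
      m <- as.matrix(images[[i]])
      if (nrow(m) < dense_shape[1] || ncol(m) < dense_shape[2]) {
        stop(sprintf("image %d (%d x %d) smaller than dense patch %d x %d",
                     i, nrow(m), ncol(m), dense_shape[1], dense_shape[2]),
             call. = FALSE)
      }
      for (k in seq_len(n_per_image)) {
        r0 <- sample.int(nrow(m) - dense_shape[1] + 1L, 1L)
        c0 <- sample.int(ncol(m) - dense_shape[2] + 1L, 1L)
        d <- m[r0:(r0 + dense_shape[1] - 1L), c0:(c0 + dense_shape[2] - 1L), drop = FALSE]
        dense[[length(dense) + 1L]] <- image_plane(d)
        sparse[[length(sparse) + 1L]] <- degrade(d, factor = factor, mode = mode)
        meta <- rbind(meta, data.frame(subject_id = subject_id[i],
                                       location_mm = location_mm[i],
                                       image = i, row0 = r0, col0 = c0))
      }
    }
  })
  structure(list(dense = dense, sparse = sparse, meta = meta,
                 factor = as.integer(factor), mode = mode),
            class = "patch_pair_set")
}

#' @export
print.patch_pair_set <- function(x, ...) {
  d1 <- dim(x$dense[[1]]); s1 <- dim(x$sparse[[1]])
  cat(sprintf("<patch_pair_set> %d pairs, dense %d x %d / sparse %d x %d, factor %d (%s)\n",
              length(x$dense), d1[1], d1[2], s1[1], s1[2], x$factor, x$mode))
  cat(sprintf("  subjects: %s\n", paste(unique(x$meta$subject_id), collapse = ", ")))
  invisible(x)
}

subset_pairs <- function(pairs, idx) {
  structure(list(dense = pairs$dense[idx], sparse = pairs$sparse[idx],
                 meta = pairs$meta[idx, , drop = FALSE],
                 factor = pairs$factor, mode = pairs$mode),
            class = "patch_pair_set")
}

#' Leave-one-subject-out split of a patch-pair set
#'
#' Places every pair from the held-out subject in the test set and all other
#' pairs in the training set; the two are disjoint and exhaustive.
#'
#' @param pairs a [make_patch_pairs()] result.
#' @param held_out_subject a subject id present in `pairs$meta$subject_id`.
#' @return A list with elements `train` and `test`, both `patch_pair_set`s.
#' @export
split_leave_one_subject_out <- function(pairs, held_out_subject) {
  stopifnot(inherits(pairs, "patch_pair_set"))
  subj <- pairs$meta$subject_id
  if (!held_out_subject %in% subj) {
    stop(sprintf("subject '%s' not present", held_out_subject), call. = FALSE)
  }
  test_idx <- which(subj == held_out_subject)
  train_idx <- which(subj != held_out_subject)
  if (length(train_idx) == 0L) {
    stop("holding out the only subject leaves an empty training set", call. = FALSE)
  }
  list(train = subset_pairs(pairs, train_idx),
       test = subset_pairs(pairs, test_idx))
}
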