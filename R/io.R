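#' Read and write grayscale images
#'
#' Images live in `[0, 1]` in memory and are written as 16-bit grayscale TIFF
#' (the package's lossless interchange format; values are scaled by 65535, so
#' a quantised grid round-trips bit-identically) or 8-bit PNG. Multi-channel
#' files are read as the channel mean.
#'
#' @param image an [image_plane()] or matrix in `[0, 1]`.
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @return `write_image` returns `path` invisibly; `read_image` returns an
#'   [image_plane()].
#' @export
write_image <- function(image, path) {
  m <- as.matrix(image)
  if (min(m) < 0 || max(m) > 1) stop("image values must lie in [0, 1]", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- tryCatch({
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else if (ext == "png") png::readPNG(path)
    else stop("unsupported image format: ", ext)
  }, error = function(e) {
    stop("failed to read '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  image_plane(m)
}

#' Read and write volumes as multi-page TIFF
#'
#' One TIFF page per depth slice (a slow x fast matrix), preserving page
#' order, 16-bit grayscale.
#'
#' @param volume a [volume_stack()] with values in `[0, 1]`.
#' @param path file path (`.tif`/`.tiff`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume_stack()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_stack"))
  v <- unclass(volume)
  if (min(v) < 0 || max(v) > 1) stop("volume values must lie in [0, 1]", call. = FALSE)
  d <- dim(v)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- v[z, , , drop = TRUE]
    dim(m) <- d[2:3]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE), error = function(e) {
    stop("failed to read '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  v <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]]
  volume_stack(v)
}

#' Serialize and restore configuration objects as YAML
#'
#' Stores the fields of the package's spec/config objects (e.g.
#' [mosaic_spec()], [generator_config()]) together with their class, so a
#' persisted config rebuilds the identical object.
#'
#' @param config a spec/config object (a classed list of scalar fields).
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the object.
#' @export
write_config <- function(config, path) {
  fields <- unclass(config)
  if ("mosaic" %in% names(fields) && inherits(fields$mosaic, "mosaic_spec")) {
    fields$mosaic <- unclass(fields$mosaic)
  }
  yaml::write_yaml(c(list(.class = class(config)[1]), fields), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  builder <- switch(cls,
    mosaic_spec = mosaic_spec,
    volume_spec = function(...) { a <- list(...); a$mosaic <- do.call(mosaic_spec, a$mosaic); do.call(volume_spec, a) },
    generator_config = generator_config,
    train_config = train_config,
    eye_biometry = eye_biometry,
    pipeline_config = pipeline_config,
    stop("unknown config class: ", cls, call. = FALSE))
  do.call(builder, x)
}
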