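# Patch discriminator: a small strided convolutional stack mapping a
# dense-sized image to a map of real/fake logits (PatchGAN-style). Receptive
# stride is 4 (two stride-2 stages), so an H x W input yields a
# ceil(H/4) x ceil(W/4) logit map.

disc_channels <- c(8L, 16L, 32L)

#' Build the patch discriminator
#'
#' Convolutional stack: 3x3 conv (stride 1) -> LeakyReLU -> 3x3 conv
#' (stride 2) -> LeakyReLU -> 3x3 conv (stride 2) -> LeakyReLU -> 1x1 conv to
#' a single-channel logit map. Fully convolutional, so any input of at least
#' 4 x 4 pixels is accepted; the logit map has one logit per 4 x 4 input
#' region (receptive stride 4).
#'
#' @param seed integer seed for parameter initialisation.
#' @return A `patch_discriminator` object; score images with `predict()`.
#' @export
build_discriminator <- function(seed = 1L) {
  ch <- disc_channels
  p <- list()
  with_seed(derive_seed(seed, "discriminator_init"), {
    p[["c1.W"]] <- nn_rand(9L * 1L, ch[1])
    p[["c1.b"]] <- numeric(ch[1])
    p[["c2.W"]] <- nn_rand(9L * ch[1], ch[2])
    p[["c2.b"]] <- numeric(ch[2])
    p[["c3.W"]] <- nn_rand(9L * ch[2], ch[3])
    p[["c3.b"]] <- numeric(ch[3])
    p[["c4.W"]] <- nn_rand(ch[3], 1L)
    p[["c4.b"]] <- numeric(1L)
  })
  structure(list(params = p, stride = 4L), class = "patch_discriminator")
}

#' @export
print.patch_discriminator <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<patch_discriminator> receptive stride %d, %d parameters\n",
              x$stride, np))
  invisible(x)
}

disc_forward <- function(params, m, want_cache = FALSE) {
  H <- nrow(m); W <- ncol(m)
  if (H < 4L || W < 4L) stop("discriminator input must be at least 4 x 4", call. = FALSE)
  ci1 <- conv_index(H, W, 3L, stride = 1L)
  x0 <- matrix(as.vector(m), H * W, 1L)
  f1 <- conv_forward(x0, params[["c1.W"]], params[["c1.b"]], ci1)
  a1 <- lrelu_forward(f1$out)
  ci2 <- conv_index(H, W, 3L, stride = 2L)
  f2 <- conv_forward(a1$out, params[["c2.W"]], params[["c2.b"]], ci2)
  a2 <- lrelu_forward(f2$out)
  ci3 <- conv_index(ci2$Ho, ci2$Wo, 3L, stride = 2L)
  f3 <- conv_forward(a2$out, params[["c3.W"]], params[["c3.b"]], ci3)
  a3 <- lrelu_forward(f3$out)
  logits <- add_cols(a3$out %*% params[["c4.W"]], params[["c4.b"]])
  cache <- if (want_cache) {
    list(f1 = f1$cache, a1 = a1$cache, f2 = f2$cache, a2 = a2$cache,
         f3 = f3$cache, a3 = a3$cache, a3_out = a3$out,
         H = H, W = W, Ho = ci3$Ho, Wo = ci3$Wo)
  }
  list(logits = as.vector(logits), shape = c(ci3$Ho, ci3$Wo), cache = cache)
}

# Backward pass; returns parameter gradients and the gradient w.r.t. the
# input image (needed to push adversarial gradients into the generator).
disc_backward <- function(params, cache, dlogits) {
  gr <- list()
  dl <- matrix(dlogits, ncol = 1L)
  gr[["c4.W"]] <- crossprod(cache$a3_out, dl)
  gr[["c4.b"]] <- sum(dl)
  da3 <- tcrossprod(dl, params[["c4.W"]])
  df3 <- lrelu_backward(da3, cache$a3)
  b3 <- conv_backward(df3, cache$f3, params[["c3.W"]])
  gr[["c3.W"]] <- b3$dW; gr[["c3.b"]] <- b3$db
  df2 <- lrelu_backward(b3$dX, cache$a2)
  b2 <- conv_backward(df2, cache$f2, params[["c2.W"]])
  gr[["c2.W"]] <- b2$dW; gr[["c2.b"]] <- b2$db
  df1 <- lrelu_backward(b2$dX, cache$a1)
  b1 <- conv_backward(df1, cache$f1, params[["c1.W"]])
  gr[["c1.W"]] <- b1$dW; gr[["c1.b"]] <- b1$db
  list(grads = gr, dinput = matrix(b1$dX, cache$H, cache$W))
}

#' @export
predict.patch_discriminator <- function(object, newdata, ...) {
  fw <- disc_forward(object$params, as.matrix(newdata))
  matrix(fw$logits, fw$shape[1], fw$shape[2])
}
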