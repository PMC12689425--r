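#' Configuration of the residual-in-residual transformer generator
#'
#' The generator maps an H x W sparsely sampled image to an
#' H x (W * upsample_factor) restored image. Structure: a shallow 3x3
#' convolutional feature extraction, then `n_rrt_groups` residual groups, each
#' a chain of `n_blocks_per_group` windowed multi-head self-attention
#' transformer blocks whose branch output is scaled by `residual_scale` before
#' being added back; each group carries its own residual connection through a
#' zero-initialisable projection, the whole group chain carries an outer
#' residual back to the shallow features, and a lateral pixel-rearrangement
#' head produces the up-sampled output. With `global_skip` the
#' nearest-neighbour up-sampled input is added to the output, so the network
#' body only has to learn the high-frequency residual.
#'
#' @param upsample_factor integer lateral up-sampling factor (default 4).
#' @param embed_dim embedding width; must be divisible by `n_heads`.
#' @param n_rrt_groups number of outer residual groups.
#' @param n_blocks_per_group transformer blocks per group.
#' @param n_heads attention heads.
#' @param attn_window spatial window size for windowed self-attention; windows
#'   tile the feature map, with truncated windows at the edges, so any input
#'   size is accepted exactly.
#' @param mlp_ratio width multiplier of the feed-forward sub-block.
#' @param residual_scale scaling of inner residual branches, in `(0, 1]`.
#' @param global_skip logical; add the nearest-neighbour up-sampled input to
#'   the output (long skip carrying low-frequency content).
#' @return A `generator_config` object.
#' @export
generator_config <- function(upsample_factor = 4L, embed_dim = 32L,
                             n_rrt_groups = 2L, n_blocks_per_group = 2L,
                             n_heads = 4L, attn_window = 8L, mlp_ratio = 2,
                             residual_scale = 0.2, global_skip = TRUE) {
  if (embed_dim %% n_heads != 0L) {
    stop("`embed_dim` must be divisible by `n_heads`", call. = FALSE)
  }
  if (residual_scale <= 0 || residual_scale > 1) {
    stop("`residual_scale` must lie in (0, 1]", call. = FALSE)
  }
  if (upsample_factor < 1L) stop("`upsample_factor` must be >= 1", call. = FALSE)
  structure(list(upsample_factor = as.integer(upsample_factor),
                 embed_dim = as.integer(embed_dim),
                 n_rrt_groups = as.integer(n_rrt_groups),
                 n_blocks_per_group = as.integer(n_blocks_per_group),
                 n_heads = as.integer(n_heads),
                 attn_window = as.integer(attn_window),
                 mlp_ratio = mlp_ratio,
                 residual_scale = residual_scale,
                 global_skip = isTRUE(global_skip)),
            class = "generator_config")
}

# Parameter set for a generator config. Branch-closing projections (per-group
# projection, body projection, head) are zero-initialised, so a freshly built
# generator with `global_skip` is exactly the nearest-neighbour up-sampler;
# gradients reach the head first and the body from step two onward.
init_generator_params <- function(cfg, seed = 1L) {
  C <- cfg$embed_dim
  hC <- round(C * cfg$mlp_ratio)
  p <- list()
  with_seed(derive_seed(seed, "generator_init"), {
    p[["shallow.W"]] <- nn_rand(9L, C)
    p[["shallow.b"]] <- numeric(C)
    for (g in seq_len(cfg$n_rrt_groups)) {
      for (b in seq_len(cfg$n_blocks_per_group)) {
        pre <- sprintf("g%d.b%d", g, b)
        p[[paste0(pre, ".ln1.g")]] <- rep(1, C)
        p[[paste0(pre, ".ln1.b")]] <- numeric(C)
        p[[paste0(pre, ".attn.Wqkv")]] <- nn_rand(C, 3L * C)
        p[[paste0(pre, ".attn.bqkv")]] <- numeric(3L * C)
        p[[paste0(pre, ".attn.Wo")]] <- nn_rand(C, C)
        p[[paste0(pre, ".attn.bo")]] <- numeric(C)
        p[[paste0(pre, ".ln2.g")]] <- rep(1, C)
        p[[paste0(pre, ".ln2.b")]] <- numeric(C)
        p[[paste0(pre, ".mlp.W1")]] <- nn_rand(C, hC)
        p[[paste0(pre, ".mlp.b1")]] <- numeric(hC)
        p[[paste0(pre, ".mlp.W2")]] <- nn_rand(hC, C)
        p[[paste0(pre, ".mlp.b2")]] <- numeric(C)
      }
      p[[sprintf("g%d.proj.W", g)]] <- matrix(0, C, C)
      p[[sprintf("g%d.proj.b", g)]] <- numeric(C)
    }
    p[["body.W"]] <- matrix(0, C, C)
    p[["body.b"]] <- numeric(C)
    p[["head.W"]] <- matrix(0, C, cfg$upsample_factor)
    p[["head.b"]] <- numeric(cfg$upsample_factor)
  })
  p
}

#' Build the residual-in-residual transformer generator
#'
#' Constructs a generator with freshly initialised parameters. At
#' initialisation the branch-closing projections are zero, so with
#' `global_skip` the forward map is exactly nearest-neighbour lateral
#' up-sampling; training then learns the high-frequency residual.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for the parameter initialisation.
#' @return An `rrt_generator` object; apply it to images with [enhance()] or
#'   `predict()`.
#' @export
build_generator <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  structure(list(config = config, params = init_generator_params(config, seed)),
            class = "rrt_generator")
}

#' @export
print.rrt_generator <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<rrt_generator> x%d lateral, embed %d, %d group(s) x %d block(s), ",
                     "%d heads, window %d, %s global skip; %d parameters\n"),
              cfg$upsample_factor, cfg$embed_dim, cfg$n_rrt_groups,
              cfg$n_blocks_per_group, cfg$n_heads, cfg$attn_window,
              if (cfg$global_skip) "with" else "no", np))
  invisible(x)
}

# lateral pixel rearrangement: token matrix P (N x f) -> H x (W*f) image
lateral_shuffle <- function(P, H, W, f) {
  out <- matrix(0, H, W * f)
  for (k in seq_len(f)) out[, (seq_len(W) - 1L) * f + k] <- matrix(P[, k], H, W)
  out
}

lateral_shuffle_backward <- function(dimg, H, W, f) {
  dP <- matrix(0, H * W, f)
  for (k in seq_len(f)) dP[, k] <- as.vector(dimg[, (seq_len(W) - 1L) * f + k])
  dP
}

generator_forward <- function(params, m, cfg, want_cache = FALSE) {
  H <- nrow(m); W <- ncol(m); N <- H * W
  f <- cfg$upsample_factor
  rs <- cfg$residual_scale
  ci3 <- conv_index(H, W, 3L)
  wins <- win_index(H, W, cfg$attn_window)
  x0 <- matrix(as.vector(m), N, 1L)
  sh <- conv_forward(x0, params[["shallow.W"]], params[["shallow.b"]], ci3)
  F0 <- sh$out
  x <- F0
  caches <- list(shallow = if (want_cache) sh$cache, groups = list())
  for (g in seq_len(cfg$n_rrt_groups)) {
    x_in <- x
    blocks <- list()
    for (b in seq_len(cfg$n_blocks_per_group)) {
      pre <- sprintf("g%d.b%d", g, b)
      bl <- list()
      l1 <- layernorm_forward(x, params[[paste0(pre, ".ln1.g")]],
                              params[[paste0(pre, ".ln1.b")]])
      at <- attn_forward(l1$out, params[[paste0(pre, ".attn.Wqkv")]],
                         params[[paste0(pre, ".attn.bqkv")]],
                         params[[paste0(pre, ".attn.Wo")]],
                         params[[paste0(pre, ".attn.bo")]], wins, cfg$n_heads)
      x <- x + rs * at$out
      l2 <- layernorm_forward(x, params[[paste0(pre, ".ln2.g")]],
                              params[[paste0(pre, ".ln2.b")]])
      h1 <- l2$out %*% params[[paste0(pre, ".mlp.W1")]]
      h1 <- add_cols(h1, params[[paste0(pre, ".mlp.b1")]])
      ge <- gelu_forward(h1)
      h2 <- ge$out %*% params[[paste0(pre, ".mlp.W2")]]
      h2 <- add_cols(h2, params[[paste0(pre, ".mlp.b2")]])
      x <- x + rs * h2
      if (want_cache) {
        bl$ln1 <- l1$cache; bl$attn <- at$cache; bl$ln2 <- l2$cache
        bl$ln2_out <- l2$out; bl$gelu_in <- ge$cache; bl$gelu_out <- ge$out
        blocks[[b]] <- bl
      }
    }
    gp <- add_cols(x %*% params[[sprintf("g%d.proj.W", g)]],
                   params[[sprintf("g%d.proj.b", g)]])
    if (want_cache) {
      caches$groups[[g]] <- list(blocks = blocks, x_in = x_in, chain_out = x)
    }
    x <- x_in + rs * gp
  }
  body <- add_cols(x %*% params[["body.W"]], params[["body.b"]])
  deep <- F0 + body
  P <- add_cols(deep %*% params[["head.W"]], params[["head.b"]])
  out <- lateral_shuffle(P, H, W, f)
  if (cfg$global_skip) out <- out + m[, rep(seq_len(W), each = f), drop = FALSE]
  if (want_cache) {
    caches$F0 <- F0; caches$x0 <- x0; caches$chain_final <- x
    caches$deep <- deep; caches$H <- H; caches$W <- W
  }
  list(out = out, cache = caches)
}

generator_backward <- function(params, cache, dout, cfg) {
  H <- cache$H; W <- cache$W
  f <- cfg$upsample_factor
  rs <- cfg$residual_scale
  gr <- list()
  dP <- lateral_shuffle_backward(dout, H, W, f)
  gr[["head.W"]] <- crossprod(cache$deep, dP)
  gr[["head.b"]] <- colSums(dP)
  ddeep <- tcrossprod(dP, params[["head.W"]])
  dF0 <- ddeep
  dbody <- ddeep
  gr[["body.W"]] <- crossprod(cache$chain_final, dbody)
  gr[["body.b"]] <- colSums(dbody)
  dx <- tcrossprod(dbody, params[["body.W"]])
  for (g in rev(seq_len(cfg$n_rrt_groups))) {
    gc <- cache$groups[[g]]
    # x_out = x_in + rs * (chain_out %*% Wg + bg)
    dgp <- rs * dx
    gr[[sprintf("g%d.proj.W", g)]] <- crossprod(gc$chain_out, dgp)
    gr[[sprintf("g%d.proj.b", g)]] <- colSums(dgp)
    dchain <- tcrossprod(dgp, params[[sprintf("g%d.proj.W", g)]])
    dx_in_direct <- dx
    dx <- dchain
    for (b in rev(seq_len(cfg$n_blocks_per_group))) {
      pre <- sprintf("g%d.b%d", g, b)
      bl <- gc$blocks[[b]]
      # x2 = x1 + rs * mlp(ln2(x1))
      dh2 <- rs * dx
      gr[[paste0(pre, ".mlp.W2")]] <- crossprod(bl$gelu_out, dh2)
      gr[[paste0(pre, ".mlp.b2")]] <- colSums(dh2)
      dge <- tcrossprod(dh2, params[[paste0(pre, ".mlp.W2")]])
      dh1 <- gelu_backward(dge, bl$gelu_in)
      gr[[paste0(pre, ".mlp.W1")]] <- crossprod(bl$ln2_out, dh1)
      gr[[paste0(pre, ".mlp.b1")]] <- colSums(dh1)
      dl2o <- tcrossprod(dh1, params[[paste0(pre, ".mlp.W1")]])
      l2b <- layernorm_backward(dl2o, bl$ln2)
      gr[[paste0(pre, ".ln2.g")]] <- l2b$dg
      gr[[paste0(pre, ".ln2.b")]] <- l2b$db
      dx <- dx + l2b$dX
      # x1 = x0 + rs * attn(ln1(x0))
      dat <- rs * dx
      ab <- attn_backward(dat, bl$attn,
                          params[[paste0(pre, ".attn.Wqkv")]],
                          params[[paste0(pre, ".attn.Wo")]])
      gr[[paste0(pre, ".attn.Wqkv")]] <- ab$dWqkv
      gr[[paste0(pre, ".attn.bqkv")]] <- ab$dbqkv
      gr[[paste0(pre, ".attn.Wo")]] <- ab$dWo
      gr[[paste0(pre, ".attn.bo")]] <- ab$dbo
      l1b <- layernorm_backward(ab$dX, bl$ln1)
      gr[[paste0(pre, ".ln1.g")]] <- l1b$dg
      gr[[paste0(pre, ".ln1.b")]] <- l1b$db
      dx <- dx + l1b$dX
    }
    dx <- dx + dx_in_direct
  }
  dF0 <- dF0 + dx
  cb <- conv_backward(dF0, cache$shallow, params[["shallow.W"]])
  gr[["shallow.W"]] <- cb$dW
  gr[["shallow.b"]] <- cb$db
  gr
}

#' @export
predict.rrt_generator <- function(object, newdata, ...) {
  m <- as.matrix(newdata)
  out <- generator_forward(object$params, m, object$config)$out
  as_image_plane(clip01(out), newdata)
}
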