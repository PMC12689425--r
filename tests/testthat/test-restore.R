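gf <- sparsecone:::generator_forward
gb <- sparsecone:::generator_backward

test_that("freshly built generator is exactly the nearest-neighbour upsampler", {
  cfg <- generator_config(upsample_factor = 4, embed_dim = 8, n_rrt_groups = 2,
                          n_blocks_per_group = 1, n_heads = 2, attn_window = 4)
  gen <- build_generator(cfg, seed = 3)
  m <- matrix(runif(10 * 25), 10, 25)   # width not divisible by the window
  out <- gf(gen$params, m, cfg)$out
  expect_identical(out, m[, rep(1:25, each = 4)])
  # evaluation is deterministic
  expect_identical(out, gf(gen$params, m, cfg)$out)
  # shape law: lateral width times factor, rows preserved
  expect_equal(dim(predict(gen, m)), c(10L, 100L))
})

test_that("generator config invariants are enforced", {
  expect_error(generator_config(embed_dim = 10, n_heads = 4), "divisible")
  expect_error(generator_config(residual_scale = 0), "\\(0, 1\\]")
  expect_error(generator_config(upsample_factor = 0), ">= 1")
})

test_that("generator backward matches finite differences", {
  cfg <- generator_config(upsample_factor = 2, embed_dim = 8, n_rrt_groups = 1,
                          n_blocks_per_group = 1, n_heads = 2, attn_window = 3)
  p <- build_generator(cfg, seed = 5)$params
  set.seed(9)
  for (k in names(p)) p[[k]] <- p[[k]] + rnorm(length(p[[k]]), sd = 0.05)
  m <- matrix(runif(7 * 10), 7, 10)
  target <- matrix(runif(7 * 20), 7, 20)
  fw <- gf(p, m, cfg, want_cache = TRUE)
  gr <- gb(p, fw$cache, 2 * (fw$out - target) / length(target), cfg)
  lossfn <- function(pp) mean((gf(pp, m, cfg)$out - target)^2)
  eps <- 1e-5
  set.seed(2)
  for (k in names(p)) {
    for (j in sample(length(p[[k]]), min(2, length(p[[k]])))) {
      pp <- p
      pp[[k]][j] <- pp[[k]][j] + eps; f1 <- lossfn(pp)
      pp[[k]][j] <- pp[[k]][j] - 2 * eps; f0 <- lossfn(pp)
      num <- (f1 - f0) / (2 * eps)
      expect_lt(abs(num - gr[[k]][j]) / max(1e-6, abs(num) + abs(gr[[k]][j])), 1e-3)
    }
  }
})

test_that("discriminator scores are finite, deterministic and patch-shaped", {
  d <- build_discriminator(seed = 2)
  img <- matrix(runif(40 * 400), 40, 400)
  s1 <- predict(d, img)
  expect_true(all(is.finite(s1)))
  expect_identical(s1, predict(d, img))
  # logit map dims = input dims / receptive stride (stride 4 here)
  expect_equal(dim(s1), c(10L, 100L))
  expect_equal(dim(predict(d, matrix(0.5, 24, 64))), c(6L, 16L))
})

test_that("discriminator backward matches a directional finite difference", {
  ns <- asNamespace("sparsecone")
  dp <- build_discriminator(seed = 3)$params
  set.seed(7)
  img <- matrix(runif(9 * 13), 9, 13)
  sp <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
  lossfn <- function(pp) mean(sp(ns$disc_forward(pp, img)$logits))
  fw <- ns$disc_forward(dp, img, want_cache = TRUE)
  dl <- stats::plogis(fw$logits) / length(fw$logits)
  bk <- ns$disc_backward(dp, fw$cache, dl)
  set.seed(11)
  dir <- lapply(dp, function(x) { d <- x; d[] <- rnorm(length(x)); d })
  ana <- sum(mapply(function(g, d) sum(as.numeric(g) * as.numeric(d)),
                    bk$grads, dir[names(bk$grads)]))
  eps <- 1e-6
  shift <- function(s) mapply(function(p, d) p + s * d, dp, dir, SIMPLIFY = FALSE)
  num <- (lossfn(shift(eps)) - lossfn(shift(-eps))) / (2 * eps)
  expect_lt(abs(ana - num) / abs(ana), 1e-6)
})

test_that("pure-regression training descends on a single pair and is reproducible", {
  img <- tiny_mosaic(spacing = 9, seed = 2, h = 48, w = 96)
  pairs <- make_patch_pairs(list(img), "s1", dense_shape = c(24, 64),
                            factor = 4, n_per_image = 1, seed = 3)
  gcfg <- generator_config(embed_dim = 16, n_rrt_groups = 1,
                           n_blocks_per_group = 1, n_heads = 2, attn_window = 4)
  m1 <- train_restorer(pairs, gcfg, train_config(steps = 200, batch_size = 1, seed = 4))
  expect_lt(m1$history$loss_pix[200], m1$history$loss_pix[1])
  m2 <- train_restorer(pairs, gcfg, train_config(steps = 1, batch_size = 1, seed = 4))
  expect_equal(m2$history$loss_pix[1], m1$history$loss_pix[1])
  # the overfit model beats column replication on its own pair
  expect_gt(psnr(pairs$dense[[1]], enhance(m1, pairs$sparse[[1]])),
            psnr(pairs$dense[[1]], pixelate_upsample(pairs$sparse[[1]], 4)))
  expect_error(train_restorer(pairs, generator_config(upsample_factor = 2,
                                                      embed_dim = 16, n_heads = 2),
                              train_config(steps = 1)), "match")
})

test_that("adversarial training records finite generator and discriminator losses", {
  img <- tiny_mosaic(spacing = 9, seed = 6, h = 32, w = 64)
  pairs <- make_patch_pairs(list(img), "s1", dense_shape = c(16, 32),
                            factor = 4, n_per_image = 2, seed = 3)
  gcfg <- generator_config(embed_dim = 8, n_rrt_groups = 1,
                           n_blocks_per_group = 1, n_heads = 2, attn_window = 4)
  for (form in c("relativistic", "standard")) {
    m <- train_restorer(pairs, gcfg,
                        train_config(steps = 8, batch_size = 1, lambda_adv = 0.01,
                                     adversarial = form, seed = 5))
    expect_true(all(is.finite(m$history$loss_adv)))
    expect_true(all(is.finite(m$history$loss_d)))
  }
})

test_that("volume enhancement is per-B-scan and multiplies the fast axis", {
  ms <- mosaic_spec(height_px = 12, width_px = 16, spacing_px = 6, seed = 2)
  vol <- generate_volume(volume_spec(ms, depth_px = 10, layer_centers_px = 5))[[1]]
  cfg <- generator_config(upsample_factor = 4, embed_dim = 8, n_rrt_groups = 1,
                          n_blocks_per_group = 1, n_heads = 2, attn_window = 4)
  gen <- build_generator(cfg, seed = 1)
  out <- enhance(gen, vol)
  expect_equal(dim(out), c(10L, 12L, 16L * 4L))
  # slice-by-slice equals enhancing each extracted B-scan separately
  for (s in c(1L, 7L)) {
    expect_equal(unclass(out)[, s, ], unclass(enhance(gen, bscan(vol, s)))[, ],
                 tolerance = 1e-12)
  }
})

test_that("model serialization round-trips with bit-identical forwards", {
  img <- tiny_mosaic(spacing = 8, seed = 3, h = 32, w = 64)
  pairs <- make_patch_pairs(list(img), "s1", dense_shape = c(16, 32),
                            factor = 4, n_per_image = 1, seed = 2)
  gcfg <- generator_config(embed_dim = 8, n_rrt_groups = 1,
                           n_blocks_per_group = 1, n_heads = 2, attn_window = 4)
  m <- train_restorer(pairs, gcfg, train_config(steps = 5, batch_size = 1, seed = 1))
  path <- tempfile(fileext = ".rds")
  save_restoration_model(m, path)
  m2 <- load_restoration_model(path)
  x <- matrix(runif(16 * 32), 16, 32)
  expect_identical(unclass(enhance(m, x))[, ], unclass(enhance(m2, x))[, ])
  unlink(path)
})

test_that("baseline upsamplers honour their alignment conventions", {
  expect_identical(as.matrix(baseline_upsample(matrix(c(1, 5), 1, 2), 4, "nearest")),
                   as.matrix(pixelate_upsample(matrix(c(1, 5), 1, 2), 4)))
  # linear on [0, 4] at factor 4: ramp then constant extension
  lin <- as.vector(baseline_upsample(matrix(c(0, 4), 1, 2), 4, "linear"))
  expect_equal(lin, c(0, 1, 2, 3, 4, 4, 4, 4))
  for (meth in c("nearest", "linear", "cubic")) {
    cst <- baseline_upsample(matrix(0.3, 5, 6), 4, meth)
    expect_equal(max(abs(as.matrix(cst) - 0.3)), 0)
  }
  expect_error(baseline_upsample(matrix(0, 2, 2), 0), ">= 1")
})

test_that("frame averaging reduces noise like one over sqrt(k)", {
  ms <- mosaic_spec(height_px = 40, width_px = 40, spacing_px = 8,
                    noise_sigma = 0.1, seed = 8)
  reps <- generate_volume(volume_spec(ms, depth_px = 24, layer_centers_px = 12,
                                      n_repeats = 4))
  truth <- unclass(attr(reps, "noiseless"))
  expect_identical(unclass(average_frames(reps[1]))[, , ], unclass(reps[[1]])[, , ])
  same <- average_frames(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_equal(unclass(same)[, , ], unclass(reps[[1]])[, , ], tolerance = 1e-15)
  res1 <- stats::sd(unclass(reps[[1]]) - truth)
  res4 <- stats::sd(unclass(average_frames(reps)) - truth)
  expect_lt(res4, 0.65 * res1)   # theory: 1/sqrt(4) = 0.5, plus clipping losses
  expect_error(average_frames(list()), "empty")
})
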