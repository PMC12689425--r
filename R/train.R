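#' Training configuration for the restorer
#'
#' @param steps number of optimisation steps.
#' @param batch_size images per step.
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param lambda_pix weight of the mean-absolute pixel loss; must be `> 0`.
#' @param lambda_adv weight of the adversarial loss; `0` (default) degrades to
#'   pure regression pretraining and skips the discriminator entirely.
#' @param adversarial `"relativistic"` (relativistic average formulation,
#'   applied per image pair) or `"standard"` (non-saturating GAN loss).
#' @param seed integer; fixes batch order, initialisation and hence the whole
#'   loss trajectory.
#' @return A `train_config` object.
#' @export
train_config <- function(steps = 500L, batch_size = 2L, lr_generator = 1e-3,
                         lr_discriminator = 1e-3, lambda_pix = 1,
                         lambda_adv = 0,
                         adversarial = c("relativistic", "standard"),
                         seed = 1L) {
  adversarial <- match.arg(adversarial)
  if (lambda_pix <= 0) stop("`lambda_pix` must be > 0", call. = FALSE)
  if (lambda_adv < 0) stop("`lambda_adv` must be >= 0", call. = FALSE)
  if (steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 lr_generator = lr_generator, lr_discriminator = lr_discriminator,
                 lambda_pix = lambda_pix, lambda_adv = lambda_adv,
                 adversarial = adversarial, seed = as.integer(seed)),
            class = "train_config")
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Relativistic-average / standard GAN gradients on logit vectors.
# Returns per-logit gradients for the discriminator step (w.r.t. both real and
# fake logits) and for the generator step (w.r.t. fake logits; real detached).
gan_grads <- function(r, f, formulation) {
  n_r <- length(r); n_f <- length(f)
  if (formulation == "standard") {
    list(loss_d = mean(softplus(-r)) + mean(softplus(f)),
         dr = (sigmoid(r) - 1) / n_r,
         df_d = sigmoid(f) / n_f,
         loss_g = mean(softplus(-f)),
         df_g = (sigmoid(f) - 1) / n_f)
  } else {
    a <- r - mean(f)
    b <- f - mean(r)
    list(loss_d = mean(softplus(-a)) + mean(softplus(b)),
         dr = -sigmoid(-a) / n_r - mean(sigmoid(b)) / n_r,
         df_d = sigmoid(b) / n_f + mean(sigmoid(-a)) / n_f,
         loss_g = mean(softplus(a)) + mean(softplus(-b)),
         df_g = -sigmoid(-b) / n_f - mean(sigmoid(a)) / n_f)
  }
}

#' Train the restoration model on dense/sparse patch pairs
#'
#' Alternates discriminator and generator Adam updates (the discriminator is
#' only instantiated when `lambda_adv > 0`). The generator loss is
#' `lambda_pix * mean-absolute pixel error + lambda_adv * adversarial term`;
#' both components are recorded per step in the training history. A fixed seed
#' reproduces the whole loss trajectory.
#'
#' @param pairs a [make_patch_pairs()] result (or any `patch_pair_set`).
#' @param gcfg a [generator_config()]; its `upsample_factor` must equal the
#'   pair set's degradation factor.
#' @param tcfg a [train_config()].
#' @return A `restoration_model`: generator, optional discriminator, config
#'   snapshots and a per-step history data.frame.
#' @export
train_restorer <- function(pairs, gcfg, tcfg = train_config()) {
  stopifnot(inherits(pairs, "patch_pair_set"), inherits(gcfg, "generator_config"),
            inherits(tcfg, "train_config"))
  n_pairs <- length(pairs$dense)
  if (n_pairs == 0L) stop("empty training set", call. = FALSE)
  if (gcfg$upsample_factor != pairs$factor) {
    stop("generator `upsample_factor` must match the pair set's degradation factor",
         call. = FALSE)
  }
  gp <- init_generator_params(gcfg, seed = tcfg$seed)
  gstate <- adam_init(gp)
  use_adv <- tcfg$lambda_adv > 0
  dp <- NULL; dstate <- NULL
  if (use_adv) {
    dp <- build_discriminator(seed = tcfg$seed)$params
    dstate <- adam_init(dp)
  }
  hist <- data.frame(step = integer(0), loss_pix = numeric(0),
                     loss_adv = numeric(0), loss_d = numeric(0))
  with_seed(derive_seed(tcfg$seed, "train"), {
    for (step in seq_len(tcfg$steps)) {
      idx <- sample.int(n_pairs, tcfg$batch_size, replace = n_pairs < tcfg$batch_size)
      ggrads <- NULL; dgrads <- NULL
      loss_pix <- 0; loss_adv <- 0; loss_d <- 0
      for (i in idx) {
        dense <- as.matrix(pairs$dense[[i]])
        sparse <- as.matrix(pairs$sparse[[i]])
        fw <- generator_forward(gp, sparse, gcfg, want_cache = TRUE)
        fake <- fw$out
        resid <- fake - dense
        loss_pix <- loss_pix + mean(abs(resid))
        dout <- tcfg$lambda_pix * sign(resid) / length(resid)
        if (use_adv) {
          fr <- disc_forward(dp, dense, want_cache = TRUE)
          ff <- disc_forward(dp, fake, want_cache = TRUE)
          gg <- gan_grads(fr$logits, ff$logits, tcfg$adversarial)
          loss_d <- loss_d + gg$loss_d
          loss_adv <- loss_adv + gg$loss_g
          br <- disc_backward(dp, fr$cache, gg$dr)
          bf <- disc_backward(dp, ff$cache, gg$df_d)
          dgrads <- grad_add(dgrads, grad_add(br$grads, bf$grads))
          badv <- disc_backward(dp, ff$cache, gg$df_g)
          dout <- dout + tcfg$lambda_adv * badv$dinput
        }
        ggrads <- grad_add(ggrads, generator_backward(gp, fw$cache, dout, gcfg))
      }
      nb <- length(idx)
      loss_pix <- loss_pix / nb; loss_adv <- loss_adv / nb; loss_d <- loss_d / nb
      if (!is.finite(loss_pix) || !is.finite(loss_adv) || !is.finite(loss_d)) {
        stop(sprintf("non-finite loss at step %d (pix %.4g, adv %.4g, d %.4g); aborting",
                     step, loss_pix, loss_adv, loss_d), call. = FALSE)
      }
      up <- adam_step(gp, grad_scale(ggrads, 1 / nb), gstate, lr = tcfg$lr_generator)
      gp <- up$params; gstate <- up$state
      if (use_adv) {
        ud <- adam_step(dp, grad_scale(dgrads, 1 / nb), dstate,
                        lr = tcfg$lr_discriminator)
        dp <- ud$params; dstate <- ud$state
      }
      hist[nrow(hist) + 1L, ] <- list(step, loss_pix,
                                      if (use_adv) loss_adv else NA_real_,
                                      if (use_adv) loss_d else NA_real_)
    }
  })
  structure(list(generator = structure(list(config = gcfg, params = gp),
                                       class = "rrt_generator"),
                 discriminator = if (use_adv) {
                   structure(list(params = dp, stride = 4L),
                             class = "patch_discriminator")
                 },
                 train_config = tcfg, history = hist),
            class = "restoration_model")
}

#' @export
print.restoration_model <- function(x, ...) {
  cat("<restoration_model>\n  ")
  print(x$generator)
  h <- x$history
  if (nrow(h)) {
    cat(sprintf("  trained %d steps; pixel loss %.5g -> %.5g\n",
                nrow(h), h$loss_pix[1], h$loss_pix[nrow(h)]))
  }
  invisible(x)
}

#' Apply a trained restorer to an image or volume
#'
#' For a volume, each B-scan (depth x fast-lateral slice at a fixed
#' slow-lateral position) is enhanced independently and the results are
#' restacked, so volume enhancement is exactly per-B-scan enhancement. The
#' lateral (fast) width is multiplied by the generator's `upsample_factor`;
#' output values are clipped to `[0, 1]`.
#'
#' @param model a `restoration_model` or `rrt_generator`.
#' @param input an [image_plane()] / matrix, or a [volume_stack()].
#' @return The restored object of the same kind as the input.
#' @export
enhance <- function(model, input) {
  gen <- if (inherits(model, "restoration_model")) model$generator else model
  stopifnot(inherits(gen, "rrt_generator"))
  f <- gen$config$upsample_factor
  if (inherits(input, "volume_stack")) {
    d <- dim(input)
    out <- array(0, dim = c(d[1], d[2], d[3] * f))
    for (s in seq_len(d[2])) {
      m <- unclass(input)[, s, , drop = TRUE]
      dim(m) <- c(d[1], d[3])
      out[, s, ] <- clip01(generator_forward(gen$params, m, gen$config)$out)
    }
    pp <- attr(input, "pixel_pitch_deg")
    volume_stack(out, pixel_pitch_deg = if (!is.null(pp)) c(pp[1], pp[2] / f))
  } else {
    m <- as.matrix(input)
    out <- clip01(generator_forward(gen$params, m, gen$config)$out)
    pp <- attr(input, "pixel_pitch_deg")
    image_plane(out, pixel_pitch_deg = if (!is.null(pp)) c(pp[1], pp[2] / f))
  }
}

#' Save / load a restoration model
#'
#' The on-disk representation contains the parameters, config snapshot and
#' training history; a loaded model reproduces forward outputs bit-identically.
#'
#' @param model a `restoration_model`.
#' @param path file path.
#' @return `save_restoration_model` returns `path` invisibly;
#'   `load_restoration_model` returns the model.
#' @export
save_restoration_model <- function(model, path) {
  stopifnot(inherits(model, "restoration_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_restoration_model
#' @export
load_restoration_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "restoration_model")) {
    stop("file does not contain a restoration_model", call. = FALSE)
  }
  model
}
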