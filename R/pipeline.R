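#' Configuration of the end-to-end toy pipeline
#'
#' One object drives simulate -> degrade -> pairs -> train -> enhance ->
#' quantify -> scale. All randomness flows from `seed` through per-stage
#' derived seeds ([derive_seed()]), so a persisted config re-executes to
#' identical outputs. Defaults are sized to run end to end in well under a
#' minute on one CPU while still training a real (tiny) restorer.
#'
#' @param seed global seed.
#' @param n_subjects,images_per_subject synthetic cohort size.
#' @param mosaic_height,mosaic_width simulated en-face frame size in pixels.
#' @param spacing_range cone-spacing range (px); each image draws uniformly.
#' @param factor lateral down-sampling factor.
#' @param dense_shape dense training-patch shape `(rows, cols)`.
#' @param n_crops_per_image training crops per image.
#' @param held_out_subject subject id held out for testing (leave one subject
#'   out); defaults to the last subject.
#' @param generator list of [generator_config()] arguments.
#' @param train list of [train_config()] arguments.
#' @param search_band spectral search band for the cone peak.
#' @param fov_deg,n_pixels_across_fov acquisition geometry used for the
#'   pixel-to-micrometre conversion (defaults: 1.5 degrees, 512 A-scans).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 7L, n_subjects = 3L, images_per_subject = 2L,
                            mosaic_height = 64L, mosaic_width = 128L,
                            spacing_range = c(8, 12), factor = 4L,
                            dense_shape = c(24L, 64L), n_crops_per_image = 6L,
                            held_out_subject = NULL,
                            generator = list(embed_dim = 16L, n_rrt_groups = 1L,
                                             n_blocks_per_group = 1L,
                                             n_heads = 2L, attn_window = 4L),
                            train = list(steps = 120L, batch_size = 2L),
                            search_band = c(0.05, 0.35),
                            fov_deg = 1.5, n_pixels_across_fov = 512L) {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 images_per_subject = as.integer(images_per_subject),
                 mosaic_height = as.integer(mosaic_height),
                 mosaic_width = as.integer(mosaic_width),
                 spacing_range = spacing_range, factor = as.integer(factor),
                 dense_shape = as.integer(dense_shape),
                 n_crops_per_image = as.integer(n_crops_per_image),
                 held_out_subject = held_out_subject,
                 generator = generator, train = train,
                 search_band = search_band, fov_deg = fov_deg,
                 n_pixels_across_fov = as.integer(n_pixels_across_fov)),
            class = "pipeline_config")
}

#' Run the end-to-end sparse-sampling restoration pipeline
#'
#' Simulates a cohort of cone-mosaic images with known spacing, builds
#' dense/sparse patch pairs, trains the toy restorer on all but one subject,
#' enhances the held-out subject's sparse patches, quantifies the restoration
#' (PSNR against ground truth for the nearest-neighbour baseline and the
#' restorer, cone spacing, edge-direction pixelation score) and converts
#' spacing to micrometres through the schematic eye. Artifacts (TIFF images,
#' metrics CSV, model checkpoint and a JSON manifest with MD5 hashes and
#' stage timings) are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `metrics` (per-patch data.frame), `summary`
#'   (named scalars, including the paired one-tailed t-test of enhanced vs
#'   baseline PSNR) and `manifest` (artifact paths, hashes, timings).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  # -- simulate ---------------------------------------------------------------
  sims <- stage("simulate", {
    images <- list(); subject <- character(0); spacing <- numeric(0)
    for (s in seq_len(config$n_subjects)) {
      for (i in seq_len(config$images_per_subject)) {
        sd_i <- derive_seed(config$seed, sprintf("mosaic_s%d_i%d", s, i))
        sp <- with_seed(sd_i, stats::runif(1, config$spacing_range[1],
                                           config$spacing_range[2]))
        spec <- mosaic_spec(height_px = config$mosaic_height,
                            width_px = config$mosaic_width,
                            spacing_px = sp, seed = sd_i)
        images[[length(images) + 1L]] <- generate_mosaic(spec)
        subject <- c(subject, sprintf("s%d", s))
        spacing <- c(spacing, sp)
      }
    }
    list(images = images, subject = subject, spacing = spacing)
  })

  # -- pairs + split ----------------------------------------------------------
  pairs <- stage("pairs", {
    make_patch_pairs(sims$images, subject_id = sims$subject,
                     dense_shape = config$dense_shape, factor = config$factor,
                     n_per_image = config$n_crops_per_image,
                     seed = derive_seed(config$seed, "pairs"))
  })
  held <- config$held_out_subject
  if (is.null(held)) held <- sprintf("s%d", config$n_subjects)
  split <- stage("split", split_leave_one_subject_out(pairs, held))

  # -- train ------------------------------------------------------------------
  gcfg <- do.call(generator_config,
                  c(list(upsample_factor = config$factor), config$generator))
  tcfg <- do.call(train_config,
                  c(config$train, list(seed = derive_seed(config$seed, "train"))))
  model <- stage("train", train_restorer(split$train, gcfg, tcfg))

  # -- enhance + quantify -----------------------------------------------------
  test <- split$test
  metrics <- stage("quantify", {
    rows <- lapply(seq_along(test$dense), function(i) {
      dense <- test$dense[[i]]
      nn <- pixelate_upsample(test$sparse[[i]], config$factor)
      enh <- enhance(model, test$sparse[[i]])
      data.frame(patch = i, subject = test$meta$subject_id[i],
                 psnr_nearest = psnr(dense, nn),
                 psnr_enhanced = psnr(dense, enh),
                 edge_var_nearest = edge_direction_histogram(nn)$bin_variance,
                 edge_var_enhanced = edge_direction_histogram(enh)$bin_variance,
                 edge_var_dense = edge_direction_histogram(dense)$bin_variance)
    })
    do.call(rbind, rows)
  })

  # held-out full frames: spacing recovery through the restorer
  frames <- stage("frames", {
    idx <- which(sims$subject == held)
    rows <- lapply(idx, function(i) {
      dense <- sims$images[[i]]
      sparse <- degrade(dense, factor = config$factor)
      enh <- enhance(model, sparse)
      pk <- estimate_cone_spacing(enh, search_band = config$search_band)
      data.frame(image = i, true_spacing_px = sims$spacing[i],
                 est_spacing_px = pk$spacing_px, peak_height = pk$peak_height)
    })
    do.call(rbind, rows)
  })

  scale <- stage("scale", retinal_scale(eye_biometry(), fov_deg = config$fov_deg,
                                        n_pixels = config$n_pixels_across_fov))
  frames$est_spacing_um <- spacing_px_to_um(frames$est_spacing_px,
                                            config$fov_deg,
                                            config$n_pixels_across_fov, scale)

  tt <- paired_ttest_one_tailed(metrics$psnr_nearest, metrics$psnr_enhanced,
                                direction = "greater")
  summary <- list(mean_psnr_nearest = mean(metrics$psnr_nearest),
                  mean_psnr_enhanced = mean(metrics$psnr_enhanced),
                  psnr_ttest_t = tt$t_statistic, psnr_ttest_p = tt$p_value,
                  um_per_degree = scale$um_per_degree,
                  held_out_subject = held)

  # -- persist artifacts ------------------------------------------------------
  paths <- stage("write", {
    p <- list(metrics = file.path(out_dir, "metrics.csv"),
              frames = file.path(out_dir, "frames.csv"),
              model = file.path(out_dir, "model.rds"),
              config = file.path(out_dir, "config.yaml"),
              example_dense = file.path(out_dir, "example_dense.tif"),
              example_enhanced = file.path(out_dir, "example_enhanced.tif"))
    utils::write.csv(metrics, p$metrics, row.names = FALSE)
    utils::write.csv(frames, p$frames, row.names = FALSE)
    save_restoration_model(model, p$model)
    write_config(config, p$config)
    i1 <- which(sims$subject == held)[1]
    write_image(sims$images[[i1]], p$example_dense)
    write_image(enhance(model, degrade(sims$images[[i1]], factor = config$factor)),
                p$example_enhanced)
    p
  })
  manifest <- list(artifacts = lapply(paths, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  }), timings_s = as.list(timings), summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, frames = frames, summary = summary,
                 manifest = manifest, out_dir = out_dir))
}
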