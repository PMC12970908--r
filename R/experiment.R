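# End-to-end experiments on synthetic data: dataset preparation, the
# two-phase training run, evaluation of the exported recognition model, and
# the ablation suite toggling attention, the VAE phase, and the
# reconstruction-generation components.

#' Prepare train/validation/test splits from a synthetic dataset
#'
#' Splits 6:2:2 per class, partitions the training pool into labeled and
#' unlabeled fractions, and stacks images into arrays. The VAE phase pool is
#' the full training pool (labeled + unlabeled + any extra unlabeled images);
#' the supervised phase sees only the labeled part.
#'
#' @param ds a `synth_dataset` from [synth_generate()]
#' @param split_seed seed for the split and the labeled partition
#' @param labeled_fraction fraction of the training pool carrying labels
#' @return list with `train_x`/`train_y` (labeled), `pool_x` (all training
#'   images plus unlabeled extras), `val_x`/`val_y`, `test_x`/`test_y`,
#'   `classes`
#' @export
prepare_splits <- function(ds, split_seed = 1L, labeled_fraction = 1) {
  manifest <- tibble::tibble(index = seq_along(ds$images),
                             class = ds$classes[ds$labels])
  manifest <- split_dataset(manifest, c(0.6, 0.2, 0.2), seed = split_seed,
                            per_class = TRUE)
  tr <- manifest[manifest$subset == "train", ]
  tr <- label_partition(tr, labeled_fraction, seed = split_seed)
  va <- manifest[manifest$subset == "validation", ]
  te <- manifest[manifest$subset == "test", ]
  pool_idx <- tr$index
  lab <- tr[tr$labeled, ]
  pool <- c(ds$images[pool_idx], ds$unlabeled)
  list(
    train_x = stack_images(ds$images[lab$index]),
    train_y = ds$labels[lab$index],
    pool_x = stack_images(pool),
    val_x = stack_images(ds$images[va$index]),
    val_y = ds$labels[va$index],
    test_x = stack_images(ds$images[te$index]),
    test_y = ds$labels[te$index],
    classes = ds$classes
  )
}

# One training configuration: optional VAE phase, then the supervised phase
# (plain classifier when use_rgn = FALSE), evaluation of the exported
# recognition model on the test split.
train_eval <- function(splits, cfg, use_attention = TRUE, use_vae = TRUE,
                       use_rgn = TRUE, seed = 1L) {
  side <- dim(splits$train_x)[2]
  n_cls <- length(splits$classes)
  # reduced configurations scale the encoder widths and the decoder seed
  # with the working resolution; the 128-pixel configuration is full size
  enc_cfg <- if (side == 32L) {
    tiny_encoder_config(num_classes = n_cls, use_attention = use_attention)
  } else if (side < 32L) {
    encoder_config(input_side = side, stem_width = 4L, num_stages = 2L,
                   groups = 2L, se_reduction = 2L, num_classes = n_cls,
                   use_attention = use_attention)
  } else {
    encoder_config(input_side = side, num_classes = n_cls,
                   use_attention = use_attention)
  }
  model <- init_rgn_model(enc_cfg, classes = splits$classes,
                          N = cfg$N, k = cfg$k, seed = seed,
                          dec_seed_channels = if (side <= 32L)
                            2L * enc_cfg$latent_dim else NULL)
  vae_log <- NULL
  if (use_vae) {
    ph1 <- train_vae_phase(model, splits$pool_x, cfg)
    vae_log <- ph1$log
  }
  w <- cfg$loss_weights
  cfg2 <- cfg
  # the supervised phase optimizes classification + adversarial + alignment;
  # the ELBO terms belong to the VAE phase
  cfg2$loss_weights <- list(
    cls = w$cls,
    adv = if (use_rgn) w$adv else 0,
    align = if (use_rgn) w$align else 0,
    recon = 0,
    kl = 0
  )
  ph2 <- train_rgn_phase(model, splits$train_x, splits$train_y, cfg2,
                         val_images = splits$val_x, val_labels = splits$val_y)
  inf <- export_inference(model, ph2$best_values)
  ev <- evaluate_model(inf, splits$test_x, splits$test_y)
  list(model = model, inference = inf, vae_log = vae_log, rgn_log = ph2$log,
       best_accuracy = ph2$best_accuracy,
       test_accuracy = ev$accuracy, macro_f1 = ev$macro$macro_f1,
       confusion = ev$confusion)
}

#' Run the scaled-down synthetic end-to-end experiment
#'
#' Generates a synthetic leaf dataset, runs the VAE phase and the
#' reconstruction-generation phase, exports the recognition model, and
#' evaluates it on the held-out test split. The default problem size (4
#' classes x 100 images at side 32, 10 epochs per phase) keeps a full run in
#' the minutes range on one CPU while preserving every component of the
#' method.
#'
#' @param n_per_class images per class
#' @param side image side (32 selects the reduced encoder configuration)
#' @param epochs epochs per phase
#' @param seed master seed covering data generation, splitting,
#'   initialization and training
#' @param labeled_fraction labeled fraction of the training pool
#' @param n_unlabeled extra unlabeled pool images
#' @param use_attention,use_vae,use_rgn component toggles (see
#'   [ablation_suite()])
#' @param batch_size minibatch size
#' @return list with the trained `model`, exported `inference` model,
#'   training logs, `test_accuracy`, `macro_f1`, `confusion`, and the
#'   first/final-epoch mean reconstruction losses (`recon_first`,
#'   `recon_final`)
#' @export
run_synthetic_experiment <- function(n_per_class = 100L, side = 32L,
                                     epochs = 10L, seed = 1L,
                                     labeled_fraction = 1,
                                     n_unlabeled = 0L,
                                     use_attention = TRUE, use_vae = TRUE,
                                     use_rgn = TRUE, batch_size = 32L) {
  ds <- synth_generate(n_per_class, seed = seed, side = side,
                       n_unlabeled = n_unlabeled)
  splits <- prepare_splits(ds, split_seed = seed,
                           labeled_fraction = labeled_fraction)
  cfg <- train_config(batch_size = batch_size, epochs = epochs, seed = seed)
  res <- train_eval(splits, cfg, use_attention = use_attention,
                    use_vae = use_vae, use_rgn = use_rgn, seed = seed)
  if (!is.null(res$vae_log)) {
    vl <- res$vae_log
    res$recon_first <- mean(vl$recon[vl$epoch == min(vl$epoch)])
    res$recon_final <- mean(vl$recon[vl$epoch == max(vl$epoch)])
  }
  res
}

#' Ablation suite
#'
#' Runs the five configurations of the component ablation on one dataset:
#' `i` (no attention, plain classifier), `i+a` (attention), `i+a+V`
#' (attention + VAE phase), `i+a+d+r` (attention + discriminator +
#' reconstruction-generation), and `i+a+V+d+r` (the full method). All runs
#' share the data, splits and seed; components toggle via the attention
#' flag, skipping the VAE phase, and zeroing the adversarial/alignment loss
#' weights.
#'
#' @param ds a `synth_dataset`
#' @param cfg a [train_config()]
#' @param seed seed shared by all configurations
#' @param labeled_fraction labeled fraction of the training pool
#' @return tibble with `config`, `accuracy`, `macro_f1`
#' @export
ablation_suite <- function(ds, cfg = train_config(), seed = 1L,
                           labeled_fraction = 1) {
  splits <- prepare_splits(ds, split_seed = seed,
                           labeled_fraction = labeled_fraction)
  grid <- list(
    list(name = "i", a = FALSE, v = FALSE, r = FALSE),
    list(name = "i+a", a = TRUE, v = FALSE, r = FALSE),
    list(name = "i+a+V", a = TRUE, v = TRUE, r = FALSE),
    list(name = "i+a+d+r", a = TRUE, v = FALSE, r = TRUE),
    list(name = "i+a+V+d+r", a = TRUE, v = TRUE, r = TRUE)
  )
  rows <- lapply(grid, function(g) {
    res <- train_eval(splits, cfg, use_attention = g$a, use_vae = g$v,
                      use_rgn = g$r, seed = seed)
    tibble::tibble(config = g$name, accuracy = res$test_accuracy,
                   macro_f1 = res$macro_f1)
  })
  do.call(rbind, rows)
}
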