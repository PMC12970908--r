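# The three-phase training scheme: (1) VAE training on the full labeled +
# unlabeled pool, (2) supervised training with the reconstruction-generation
# scheme (region confusion, generator, discriminator, region alignment) on
# the labeled pool, (3) extraction of the recognition-only inference model.

#' Training configuration
#'
#' Defaults follow the reference experimental setup: minibatch 32, momentum
#' optimizer with learning rate 0.001 (momentum coefficient 0.9, constant
#' schedule), 10 epochs per phase, validation every 4096 training images
#' with retention of the best checkpoint, region confusion grid N = 8 with
#' locality k = 2. Loss weights default to 1 for every component; ablations
#' set individual weights to 0.
#'
#' @param batch_size minibatch size
#' @param learning_rate constant learning rate
#' @param momentum momentum coefficient
#' @param epochs epochs per training phase
#' @param validate_every_images run validation each time this many training
#'   images have been consumed (must be a multiple of `batch_size`); the
#'   checkpoint with the highest validation accuracy is retained (ties keep
#'   the earlier one), and validation always also runs at the end of a phase
#' @param loss_weights named list with `cls`, `recon`, `kl`, `adv`, `align`
#' @param N,k region confusion grid size and locality parameter
#' @param destroy_fraction fraction of each batch given a destroyed twin
#'   (the twin's original feeds the discriminator as real, its restored
#'   version as fake, keeping the two classes balanced)
#' @param cls_on_destroyed also apply the classification loss to destroyed
#'   images
#' @param classify_generated also apply the classification loss to restored
#'   images
#' @param seed integer seed covering batch order, latent sampling and region
#'   permutations
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         momentum = 0.9, epochs = 10L,
                         validate_every_images = 4096L,
                         loss_weights = list(cls = 1, recon = 1, kl = 1,
                                             adv = 1, align = 1),
                         N = 8L, k = 2L, destroy_fraction = 0.5,
                         cls_on_destroyed = FALSE, classify_generated = FALSE,
                         seed = 1L) {
  stopifnot(batch_size >= 1L, validate_every_images %% batch_size == 0L,
            all(unlist(loss_weights) >= 0))
  w <- list(cls = 1, recon = 1, kl = 1, adv = 1, align = 1)
  w[names(loss_weights)] <- loss_weights
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 validate_every_images = as.integer(validate_every_images),
                 loss_weights = w, N = as.integer(N), k = as.integer(k),
                 destroy_fraction = destroy_fraction,
                 cls_on_destroyed = isTRUE(cls_on_destroyed),
                 classify_generated = isTRUE(classify_generated),
                 seed = as.integer(seed)),
            class = "train_config")
}

as_image_array <- function(images) {
  if (is.list(images)) stack_images(images) else images
}

log_row <- function(phase, epoch, step, images_seen, ...) {
  tibble::tibble(phase = phase, epoch = epoch, step = step,
                 images_seen = images_seen, ...)
}

# z = mu + exp(log_var / 2) * eps as graph nodes
sample_latent_node <- function(mu, lv) {
  eps <- matrix(stats::rnorm(length(mu$value)), nrow(mu$value), ncol(mu$value))
  ag_add(mu, ag_mul(ag_exp(ag_scale(lv, 0.5)), ag_const(eps)))
}

#' VAE training phase
#'
#' Trains encoder + decoder on the pooled labeled and unlabeled images
#' (labels are ignored): per batch, encode, sample the latent by the
#' reparameterization trick, decode, and minimize mean-squared
#' reconstruction error plus the KL divergence from the standard normal
#' prior, with a momentum update. The model is updated in place and
#' returned.
#'
#' @param model an `rgn_model`
#' @param images `(N,H,W,C)` array or list of `(H,W,C)` arrays: the full
#'   pool, labeled and unlabeled together
#' @param cfg a [train_config()]
#' @return list with `model` and `log` (a tibble of per-step losses)
#' @export
train_vae_phase <- function(model, images, cfg = train_config()) {
  x_all <- as_image_array(images)
  n <- dim(x_all)[1]
  if (n == 0L) stop("empty training pool", call. = FALSE)
  set.seed(cfg$seed)
  params <- collect_params(list(model$enc, model$de))
  w <- cfg$loss_weights
  logs <- list()
  step <- 0L; seen <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    pos <- 1L
    while (pos <= n) {
      idx <- ord[pos:min(pos + cfg$batch_size - 1L, n)]
      pos <- pos + cfg$batch_size
      if (length(idx) < 2L) next # batch statistics need at least two images
      xb <- x_all[idx, , , , drop = FALSE]
      r <- with_training(with_tape({
        out <- encoder_forward(ag_const(xb), model$enc, model$cfg)
        z <- sample_latent_node(out$mu, out$log_var)
        xhat <- decoder_forward(z, model$de, model$dec_cfg, model$cfg$groups)
        recon <- ag_mse(xhat, ag_const(xb))
        kl <- ag_kl(out$mu, out$log_var)
        total <- ag_add(ag_scale(recon, w$recon), ag_scale(kl, w$kl))
        list(recon = recon, kl = kl, total = total)
      }))
      zero_grads(params)
      ag_backward(r$value$total, r$tape)
      sgd_momentum_step(params, cfg$learning_rate, cfg$momentum)
      step <- step + 1L; seen <- seen + length(idx)
      logs[[step]] <- log_row("vae", epoch, step, seen,
                              recon = r$value$recon$value,
                              kl = r$value$kl$value,
                              total = r$value$total$value)
    }
  }
  list(model = model, log = do.call(rbind, logs))
}

# destroyed twins for a sub-batch: images, flattened alignment targets
make_destroyed_batch <- function(xb, idx_d, N, k) {
  side <- dim(xb)[2]
  xd <- array(0, c(length(idx_d), dim(xb)[2], dim(xb)[3], dim(xb)[4]))
  tg <- matrix(0, length(idx_d), 2L * N^2)
  for (j in seq_along(idx_d)) {
    pm <- make_permutation(N, k)
    xd[j, , , ] <- destroy(xb[idx_d[j], , , ], pm)
    tg[j, ] <- flatten_targets(alignment_targets(pm))
  }
  list(images = xd, targets = tg)
}

#' Supervised reconstruction-generation training phase
#'
#' Per batch: a fraction of the images receive a destroyed twin via the
#' region confusion mechanism; the classification loss is computed on the
#' originals (sampled latent), the generator restores the destroyed twins,
#' the discriminator scores the twin originals as real and the restorations
#' as fake (adversarial cross-entropy, non-saturating generator loss), and
#' the alignment head predicts each shuffled region's original coordinates
#' (mean absolute error). One discriminator-head update follows each model
#' update. Every `validate_every_images` consumed images (and at the end of
#' the phase) the validation set is evaluated and the best checkpoint
#' retained.
#'
#' @param model an `rgn_model` (typically after [train_vae_phase()]; a fresh
#'   model gives the no-VAE ablation)
#' @param images labeled training images, `(N,H,W,C)` array or list
#' @param labels integer labels in `1..C`
#' @param cfg a [train_config()]
#' @param val_images,val_labels validation data for checkpoint retention
#'   (optional; without it the final parameters are retained)
#' @return list with `model` (final parameters, in place), `log`,
#'   `best_values` (retained checkpoint parameter values), `best_accuracy`
#' @export
train_rgn_phase <- function(model, images, labels, cfg = train_config(),
                            val_images = NULL, val_labels = NULL) {
  x_all <- as_image_array(images)
  n <- dim(x_all)[1]
  if (n == 0L) stop("empty labeled set", call. = FALSE)
  stopifnot(length(labels) == n)
  set.seed(cfg$seed + 1L)
  w <- cfg$loss_weights
  use_rgn <- (w$adv > 0 || w$align > 0) && cfg$destroy_fraction > 0
  use_vae_loss <- w$recon > 0 || w$kl > 0
  model_params <- collect_params(list(model$enc, model$cls, model$de,
                                      model$gdec, model$align))
  disc_params <- collect_params(model$disc)
  all_params <- c(model_params, disc_params)
  logs <- list()
  best <- list(acc = -Inf, values = NULL)
  validate <- function(epoch, step, seen) {
    if (is.null(val_images)) return(invisible(NULL))
    ev <- evaluate_model(model, val_images, val_labels)
    if (ev$accuracy > best$acc) {
      best <<- list(acc = ev$accuracy, values = param_values(unclass(model)))
    }
    logs[[length(logs) + 1L]] <<- log_row("rgn-val", epoch, step, seen,
                                          cls = NA_real_, adv_d = NA_real_,
                                          adv_g = NA_real_, align = NA_real_,
                                          recon = NA_real_, kl = NA_real_,
                                          val_accuracy = ev$accuracy)
    invisible(NULL)
  }
  step <- 0L; seen <- 0L; next_val <- cfg$validate_every_images
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    pos <- 1L
    while (pos <= n) {
      idx <- ord[pos:min(pos + cfg$batch_size - 1L, n)]
      pos <- pos + cfg$batch_size
      if (length(idx) < 2L) next
      xb <- x_all[idx, , , , drop = FALSE]
      yb <- labels[idx]
      b <- length(idx)
      n_d <- if (use_rgn) max(1L, round(cfg$destroy_fraction * b)) else 0L
      db <- if (n_d > 0L) make_destroyed_batch(xb, seq_len(n_d), cfg$N, cfg$k)
      r <- with_training(with_tape({
        out <- encoder_forward(ag_const(xb), model$enc, model$cfg)
        z <- sample_latent_node(out$mu, out$log_var)
        cls_loss <- ag_softmax_ce(classifier_forward(z, model$cls), yb)
        total <- ag_scale(cls_loss, w$cls)
        comps <- list(cls = cls_loss$value, adv_d = NA_real_,
                      adv_g = NA_real_, align = NA_real_,
                      recon = NA_real_, kl = NA_real_)
        d_loss <- NULL
        if (use_vae_loss) {
          xhat <- decoder_forward(z, model$de, model$dec_cfg, model$cfg$groups)
          recon <- ag_mse(xhat, ag_const(xb))
          kl <- ag_kl(out$mu, out$log_var)
          total <- ag_add(total, ag_add(ag_scale(recon, w$recon),
                                        ag_scale(kl, w$kl)))
          comps$recon <- recon$value; comps$kl <- kl$value
        }
        if (n_d > 0L) {
          out_d <- encoder_forward(ag_const(db$images), model$enc, model$cfg)
          if (w$align > 0) {
            ap <- ag_sigmoid(ag_add_rowvec(
              ag_matmul(scale_fc_forward(out_d$feat, model$align$sfc),
                        ag_use(model$align$fc$w)),
              ag_use(model$align$fc$b)))
            align <- ag_mae(ap, ag_const(db$targets))
            total <- ag_add(total, ag_scale(align, w$align))
            comps$align <- align$value
          }
          if (cfg$cls_on_destroyed) {
            zd <- sample_latent_node(out_d$mu, out_d$log_var)
            cls_d <- ag_softmax_ce(classifier_forward(zd, model$cls),
                                   yb[seq_len(n_d)])
            total <- ag_add(total, ag_scale(cls_d, w$cls))
          }
          if (w$adv > 0) {
            gen <- decoder_forward(out_d$mu, model$gdec, model$dec_cfg,
                                   model$cfg$groups)
            # generator update: evaluate the discriminator path with frozen
            # parameters so the gradient pushes G (and the encoder as its
            # front end) to fool D, without perturbing the judge itself
            out_g <- with_frozen(encoder_forward(gen, model$enc, model$cfg))
            g_sc <- with_frozen(disc_head_forward(out_g$feat, model$disc))
            g_loss <- ag_softmax_ce(g_sc, rep(2L, n_d))
            # discriminator update: live head on detached shared features
            real_sc <- disc_head_forward(ag_detach(ag_slice_rows(
              out$feat, seq_len(n_d))), model$disc)
            fake_sc <- disc_head_forward(ag_detach(out_g$feat), model$disc)
            d_loss <- ag_scale(ag_add(ag_softmax_ce(real_sc, rep(2L, n_d)),
                                      ag_softmax_ce(fake_sc, rep(1L, n_d))),
                               0.5)
            total <- ag_add(total, ag_scale(g_loss, w$adv))
            comps$adv_g <- g_loss$value; comps$adv_d <- d_loss$value
            if (cfg$classify_generated) {
              zg <- sample_latent_node(out_g$mu, out_g$log_var)
              cls_g <- ag_softmax_ce(classifier_forward(zg, model$cls),
                                     yb[seq_len(n_d)])
              total <- ag_add(total, ag_scale(cls_g, w$cls))
            }
          }
        }
        list(total = total, d_loss = d_loss, comps = comps)
      }))
      zero_grads(all_params)
      ag_backward(r$value$total, r$tape)
      sgd_momentum_step(model_params, cfg$learning_rate, cfg$momentum)
      if (!is.null(r$value$d_loss)) {
        zero_grads(all_params)
        ag_backward(r$value$d_loss, r$tape)
        sgd_momentum_step(disc_params, cfg$learning_rate, cfg$momentum)
      }
      step <- step + 1L; seen <- seen + b
      logs[[length(logs) + 1L]] <-
        do.call(log_row, c(list("rgn", epoch, step, seen), r$value$comps,
                           list(val_accuracy = NA_real_)))
      if (seen >= next_val) {
        validate(epoch, step, seen)
        next_val <- next_val + cfg$validate_every_images
      }
    }
  }
  validate(cfg$epochs, step, seen)
  if (is.null(best$values)) best <- list(acc = NA_real_,
                                         values = param_values(unclass(model)))
  list(model = model, log = do.call(rbind, logs),
       best_values = best$values, best_accuracy = best$acc)
}

clone_params <- function(x) {
  if (inherits(x, "ag_param")) return(new_param(x$value, x$trainable))
  if (is.list(x)) {
    out <- lapply(x, clone_params)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

#' Export the recognition-only inference model
#'
#' Strips the decoder, generator, discriminator and alignment networks,
#' keeping the encoder (with attention) and the classifier. Parameters are
#' deep-copied, so later training of the full model does not affect the
#' export; predictions of the exported model are bit-identical to the full
#' model's inference branch.
#'
#' @param model a trained `rgn_model`
#' @param values optional parameter values to restore first (e.g.
#'   `best_values` from [train_rgn_phase()], the retained checkpoint)
#' @return an `rgn_inference` model
#' @export
export_inference <- function(model, values = NULL) {
  if (!is.null(values)) set_param_values(unclass(model), values)
  out <- list(cfg = model$cfg,
              enc = clone_params(model$enc),
              cls = clone_params(model$cls),
              classes = model$classes)
  class(out) <- "rgn_inference"
  out
}

#' Save / load a model archive
#'
#' The archive holds a JSON metadata header (model type, encoder
#' configuration, class names, region-confusion settings) and the full
#' parameter values, including batch-normalization running statistics.
#'
#' @param model an `rgn_model` or `rgn_inference` model
#' @param path file path
#' @return `path` invisibly; `load_model()` returns the rebuilt model
#' @export
save_model <- function(model, path) {
  meta <- list(type = class(model)[1],
               cfg = unclass(model$cfg),
               classes = model$classes,
               rcm = model$rcm)
  saveRDS(list(meta = jsonlite::toJSON(meta, auto_unbox = TRUE),
               values = param_values(unclass(model))), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ar <- readRDS(path)
  meta <- jsonlite::fromJSON(ar$meta)
  cfg <- do.call(encoder_config, meta$cfg[setdiff(names(meta$cfg), "latent_dim")])
  if (meta$type == "rgn_model") {
    model <- init_rgn_model(cfg, classes = meta$classes,
                            N = meta$rcm$N, k = meta$rcm$k)
  } else {
    model <- structure(list(cfg = cfg,
                            enc = encoder_init(cfg),
                            cls = list(sfc = scale_fc_init(cfg$latent_dim),
                                       fc = linear_init(cfg$latent_dim,
                                                        cfg$num_classes)),
                            classes = meta$classes),
                       class = "rgn_inference")
  }
  set_param_values(unclass(model), ar$values)
  model
}
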