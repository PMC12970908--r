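# Training-time satellite networks: the VAE decoder (reconstruction), the
# generation head restoring destroyed images, the real/fake discriminator
# head on shared encoder features, and their losses. None of these
# participate at inference.

#' Decoder configuration
#'
#' The decoder maps a latent vector to an image: a fully-connected layer to
#' `fc_width` (4096 at full size) reshaped to a `2 x 2 x seed_channels` seed
#' map, then `num_upsample_stages` upsample modules (nearest-neighbour x2
#' followed by a 3x3 convolution that transforms the channel count), a scale
#' block at the final resolution, and a final 3x3 convolution to the output
#' channels with sigmoid squashing to `[0, 1]`. Channel widths halve per
#' stage, with the final width repeated so the last convolution reduces 32
#' channels to 3 at full size (2x2x1024 -> ... -> 128x128x32 -> 128x128x3).
#'
#' @param latent_dim latent width (256 at full size)
#' @param output_side output image side; `2 * 2^num_upsample_stages`
#' @param output_channels output channels (3 for RGB)
#' @param seed_channels channels of the 2x2 seed map; the default,
#'   `4 * latent_dim`, gives the full-size 256 -> 4096 -> 2x2x1024 mapping.
#'   Reduced test configurations may use a narrower seed.
#' @return a `decoder_config` list
#' @export
decoder_config <- function(latent_dim = 256L, output_side = 128L,
                           output_channels = 3L,
                           seed_channels = 4L * latent_dim) {
  if (output_side < 4L || bitwAnd(output_side, output_side - 1L) != 0L) {
    stop("output_side must be a power of two >= 4", call. = FALSE)
  }
  stages <- as.integer(round(log2(output_side / 2L)))
  seed_channels <- as.integer(seed_channels)
  widths <- vapply(seq_len(stages), function(s) {
    max(seed_channels %/% 2L^s, seed_channels %/% 2L^(stages - 1L))
  }, numeric(1))
  widths <- as.integer(widths)
  structure(list(
    latent_dim = as.integer(latent_dim),
    fc_width = 4L * seed_channels,
    seed_side = 2L,
    seed_channels = seed_channels,
    stage_widths = widths,
    num_upsample_stages = stages,
    output_side = as.integer(output_side),
    output_channels = as.integer(output_channels)
  ), class = "decoder_config")
}

decoder_init <- function(cfg, groups = 4L) {
  c_in <- cfg$seed_channels
  stages <- lapply(cfg$stage_widths, function(w) {
    st <- list(conv = conv_init(3L, c_in, w, bias = FALSE), bn = bn_init(w))
    c_in <<- w
    st
  })
  list(
    fc = linear_init(cfg$latent_dim, cfg$fc_width),
    stages = stages,
    scale = scale_init(c_in, groups),
    out = conv_init(3L, c_in, cfg$output_channels)
  )
}

decoder_forward <- function(z, p, cfg, groups = 4L) {
  n <- nrow(z$value)
  h <- ag_relu(ag_add_rowvec(ag_matmul(z, ag_use(p$fc$w)), ag_use(p$fc$b)))
  h <- ag_reshape(h, c(n, cfg$seed_side, cfg$seed_side, cfg$seed_channels))
  for (st in p$stages) {
    h <- ag_upsample2(h)
    h <- ag_conv2d(h, ag_use(st$conv$w), k = 3L)
    h <- ag_relu(ag_batchnorm(h, st$bn))
  }
  h <- scale_forward(h, p$scale, groups)
  h <- ag_conv2d(h, ag_use(p$out$w), k = 3L, bias = ag_use(p$out$b))
  ag_sigmoid(h)
}

#' Decode latent vectors to images
#'
#' @param z latent vector (length `latent_dim`) or `N x latent_dim` matrix
#' @param model an `rgn_model` (uses the VAE decoder `De`)
#' @return `(N, side, side, channels)` array with values in `[0, 1]`
#' @export
decode <- function(z, model) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$dec_cfg$latent_dim) {
    stop("latent length ", ncol(z), " does not match latent_dim ",
         model$dec_cfg$latent_dim, call. = FALSE)
  }
  decoder_forward(ag_const(z), model$de, model$dec_cfg, model$cfg$groups)$value
}

# KL(q(z|x) || N(0, I)) summed per sample, averaged over the batch; closed
# form for a diagonal Gaussian parameterized by mean and log-variance.
ag_kl <- function(mu, lv) {
  n <- nrow(mu$value)
  e <- exp(lv$value)
  val <- -0.5 * sum(1 + lv$value - mu$value^2 - e) / n
  ag_node(val, list(mu, lv), function(nd) {
    ag_acc(mu, nd$grad * mu$value / n)
    ag_acc(lv, nd$grad * (-0.5) * (1 - e) / n)
  })
}

#' VAE loss (reconstruction + KL divergence)
#'
#' `recon` is the mean squared error between the image and its
#' reconstruction; `kl` is the closed-form divergence of the latent Gaussian
#' from the standard normal prior, summed over latent dimensions and averaged
#' over the batch: `-0.5 * sum(1 + log_var - mu^2 - exp(log_var))`. The total
#' is `recon + beta * kl`.
#'
#' @param x,x_hat image arrays of identical shape
#' @param lg a [latent_gaussian()]
#' @param beta KL weight (default 1)
#' @return list with `recon`, `kl`, `total`
#' @export
vae_loss <- function(x, x_hat, lg, beta = 1) {
  if (!identical(dim_of(x), dim_of(x_hat))) {
    stop("image and reconstruction shapes differ", call. = FALSE)
  }
  stopifnot(inherits(lg, "latent_gaussian"))
  recon <- mean((x - x_hat)^2)
  kl <- -0.5 * sum(1 + lg$log_var - lg$mu^2 - exp(lg$log_var)) / nrow(lg$mu)
  list(recon = recon, kl = kl, total = recon + beta * kl)
}

# generator: shared encoder on the destroyed image, latent mean, independent
# decoder-shaped head
generator_forward <- function(x, model) {
  out <- encoder_forward(x, model$enc, model$cfg)
  decoder_forward(out$mu, model$gdec, model$dec_cfg, model$cfg$groups)
}

#' Restore a destroyed image with the generation network
#'
#' The generation network shares the recognition encoder: the destroyed image
#' is encoded, and a decoder-shaped head with its own weights produces the
#' restored image. Gradients flow back into the shared encoder during
#' training.
#'
#' @param destroyed `(H,W,C)` or `(N,H,W,C)` array in `[0, 1]`
#' @param model an `rgn_model`
#' @return restored image array of the input's shape, values in `[0, 1]`
#' @export
generate_restored <- function(destroyed, model) {
  xb <- check_image_batch(destroyed, model$cfg)
  generator_forward(ag_const(xb), model)$value
}

disc_head_forward <- function(feat, disc) {
  h <- scale_fc_forward(feat, disc$sfc)
  ag_add_rowvec(ag_matmul(h, ag_use(disc$fc$w)), ag_use(disc$fc$b))
}

#' Score images as real or generated
#'
#' The discriminator consumes the shared encoder's pooled hidden features and
#' applies a residual fully-connected block followed by a linear layer of
#' size 2, scoring each image as (fake, real).
#'
#' @param image `(H,W,C)` or `(N,H,W,C)` array in `[0, 1]`
#' @param model an `rgn_model`
#' @return `N x 2` matrix of scores (logits)
#' @export
discriminate <- function(image, model) {
  xb <- check_image_batch(image, model$cfg)
  out <- encoder_forward(ag_const(xb), model$enc, model$cfg)
  disc_head_forward(out$feat, model$disc)$value
}

ce_against <- function(scores, class_idx) {
  p <- softmax_rows(scores)
  -mean(log(pmax(p[, class_idx], 1e-12)))
}

#' Adversarial losses
#'
#' Two-class cross-entropy objective: the discriminator should score original
#' images as real (class 2) and generated images as fake (class 1), so
#' `d_loss` is the average of the two cross-entropies and tends to 0 under
#' perfect separation. The generator loss is the non-saturating form: the
#' cross-entropy of the fake scores against the *real* label, tending to 0 as
#' the generator fools the discriminator. With all probabilities at 0.5 each
#' per-sample cross-entropy equals `log(2)`.
#'
#' @param scores list with `real_scores` and `fake_scores`, each an `N x 2`
#'   matrix of discriminator logits
#' @return list with `d_loss` and `g_loss`
#' @export
adversarial_losses <- function(scores) {
  r <- scores$real_scores
  f <- scores$fake_scores
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  stopifnot(ncol(r) == 2L, ncol(f) == 2L)
  list(
    d_loss = 0.5 * (ce_against(r, 2L) + ce_against(f, 1L)),
    g_loss = ce_against(f, 2L)
  )
}
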