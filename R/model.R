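# The recognition model: encoder with squeeze-and-excitation attention,
# variational latent head (mean + log-variance), and classifier. Satellite
# networks used only during training (decoder, generator head, discriminator,
# region-alignment head) attach to the shared encoder without modifying it,
# so the deployed recognition model is unchanged by their presence.

#' Encoder configuration
#'
#' Describes the encoder topology: a 3x3 convolution stem producing
#' `stem_width` channels, then `num_stages` stages of scale block -> SE
#' attention -> downsample (each stage halves the side and doubles the
#' channels), a final scale block with attention, global average pooling,
#' a residual fully-connected block, and two parallel projections producing
#' the latent mean and log-variance. The latent width equals the final stage
#' width, `stem_width * 2^num_stages`.
#'
#' The default is the full-size configuration (128x128x3 input, widths
#' 16-256, 256-d latent); `tiny_encoder_config()` gives a reduced version
#' (32x32 input, widths 8-64, 64-d latent) used for fast experiments.
#'
#' @param input_side input image side in pixels (square images)
#' @param input_channels image channels (3 for RGB)
#' @param stem_width channels after the stem convolution
#' @param num_stages number of scale/attention/downsample stages
#' @param groups grouped-convolution groups inside blocks
#' @param se_reduction squeeze-and-excitation bottleneck ratio
#' @param num_classes number of output classes
#' @param use_attention if `FALSE` the SE blocks are omitted entirely
#'   (the ablation "i" configuration)
#' @return an `encoder_config` list
#' @export
encoder_config <- function(input_side = 128L, input_channels = 3L,
                           stem_width = 16L, num_stages = 4L, groups = 4L,
                           se_reduction = 16L, num_classes = 38L,
                           use_attention = TRUE) {
  latent_dim <- stem_width * 2L^num_stages
  if (input_side %% 2L^num_stages != 0L || input_side / 2L^num_stages < 1L) {
    stop("input_side must be divisible by 2^num_stages", call. = FALSE)
  }
  structure(list(
    input_side = as.integer(input_side),
    input_channels = as.integer(input_channels),
    stem_width = as.integer(stem_width),
    num_stages = as.integer(num_stages),
    groups = as.integer(groups),
    se_reduction = as.integer(se_reduction),
    num_classes = as.integer(num_classes),
    latent_dim = as.integer(latent_dim),
    use_attention = isTRUE(use_attention)
  ), class = "encoder_config")
}

#' @rdname encoder_config
#' @param num_classes number of output classes
#' @export
tiny_encoder_config <- function(num_classes = 4L, use_attention = TRUE) {
  encoder_config(input_side = 32L, stem_width = 8L, num_stages = 3L,
                 se_reduction = 4L, num_classes = num_classes,
                 use_attention = use_attention)
}

stage_width <- function(cfg, s) cfg$stem_width * 2L^(s - 1L)

encoder_init <- function(cfg) {
  stages <- lapply(seq_len(cfg$num_stages), function(s) {
    w <- stage_width(cfg, s)
    st <- list(scale = scale_init(w, cfg$groups),
               down = downsample_init(w, cfg$groups))
    if (cfg$use_attention) st$se <- se_init(w, cfg$se_reduction)
    st
  })
  top <- list(scale = scale_init(cfg$latent_dim, cfg$groups),
              bn = bn_init(cfg$latent_dim))
  if (cfg$use_attention) top$se <- se_init(cfg$latent_dim, cfg$se_reduction)
  list(
    stem = conv_init(3L, cfg$input_channels, cfg$stem_width, bias = FALSE),
    stages = stages,
    top = top,
    sfc = scale_fc_init(cfg$latent_dim),
    fc_mu = linear_init(cfg$latent_dim, cfg$latent_dim),
    # zero-initialized: the latent starts at unit variance (log_var = 0), so
    # early sampling noise is controlled and the KL term is 0 at the mean
    fc_lv = linear_init(cfg$latent_dim, cfg$latent_dim, zero = TRUE)
  )
}

dims_label <- function(d) paste(d[-1], collapse = " x ")

trace_add <- function(trace, layer, d_in, d_out) {
  if (is.null(trace)) return(invisible(NULL))
  trace$rows[[length(trace$rows) + 1L]] <-
    list(layer = layer, input = dims_label(d_in), output = dims_label(d_out))
  invisible(NULL)
}

# Node-level encoder forward. Returns mu, log_var and the shared pooled
# feature vector (after scale_fc) used by the classifier, discriminator and
# alignment head. `trace`, if an environment with $rows, records the
# layer-by-layer input/output shapes.
encoder_forward <- function(x, enc, cfg, trace = NULL) {
  d0 <- dim(x$value)
  h <- ag_conv2d(x, ag_use(enc$stem$w), k = 3L)
  trace_add(trace, sprintf("conv(3 x 3, %d)", cfg$stem_width), d0, dim(h$value))
  for (s in seq_len(cfg$num_stages)) {
    st <- enc$stages[[s]]
    din <- dim(h$value)
    h <- scale_forward(h, st$scale, cfg$groups)
    trace_add(trace, paste0("scale-", s), din, dim(h$value))
    if (cfg$use_attention) {
      h <- se_forward(h, st$se)
      trace_add(trace, paste0("SENet-", s), din, dim(h$value))
    }
    h <- downsample_forward(h, st$down, cfg$groups)
    trace_add(trace, paste0("downsample-", s), din, dim(h$value))
  }
  din <- dim(h$value)
  h <- scale_forward(h, enc$top$scale, cfg$groups)
  trace_add(trace, "scale", din, dim(h$value))
  if (cfg$use_attention) {
    h <- se_forward(h, enc$top$se)
    trace_add(trace, paste0("SENet-", cfg$num_stages + 1L), din, dim(h$value))
  }
  h <- ag_relu(ag_batchnorm(h, enc$top$bn))
  din <- dim(h$value)
  pooled <- ag_global_mean_hw(h)
  trace_add(trace, "reduce_mean", din, dim(pooled$value))
  feat <- scale_fc_forward(pooled, enc$sfc)
  trace_add(trace, "scale_fc", dim(pooled$value), dim(feat$value))
  mu <- ag_add_rowvec(ag_matmul(feat, ag_use(enc$fc_mu$w)), ag_use(enc$fc_mu$b))
  lv <- ag_add_rowvec(ag_matmul(feat, ag_use(enc$fc_lv$w)), ag_use(enc$fc_lv$b))
  trace_add(trace, "FC", dim(feat$value), dim(mu$value))
  list(mu = mu, log_var = lv, feat = feat)
}

classifier_forward <- function(z, cls) {
  h <- scale_fc_forward(z, cls$sfc)
  ag_add_rowvec(ag_matmul(h, ag_use(cls$fc$w)), ag_use(cls$fc$b))
}

#' Initialize a full reconstruction-generation model
#'
#' Builds the recognition model (encoder + classifier) together with its
#' training-time satellites: the VAE decoder, the generation head that
#' restores destroyed images, the real/fake discriminator head, and the
#' region-alignment head. All satellites consume the shared encoder's
#' features; removing them (see [export_inference()]) leaves the recognition
#' model's parameters untouched.
#'
#' @param cfg an [encoder_config()]
#' @param classes character vector of class names (defaults to `class_1..C`)
#' @param N region-confusion grid size
#' @param k region-confusion locality parameter
#' @param seed optional integer seed for weight initialization
#' @param dec_seed_channels decoder seed-map channels (default
#'   `4 * latent_dim`, the full-size mapping; see [decoder_config()])
#' @return an object of class `rgn_model`
#' @export
init_rgn_model <- function(cfg, classes = NULL, N = 8L, k = 2L, seed = NULL,
                           dec_seed_channels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(classes)) classes <- paste0("class_", seq_len(cfg$num_classes))
  stopifnot(length(classes) == cfg$num_classes)
  if (is.null(dec_seed_channels)) dec_seed_channels <- 4L * cfg$latent_dim
  dec_cfg <- decoder_config(latent_dim = cfg$latent_dim,
                            output_side = cfg$input_side,
                            output_channels = cfg$input_channels,
                            seed_channels = dec_seed_channels)
  model <- list(
    cfg = cfg,
    dec_cfg = dec_cfg,
    enc = encoder_init(cfg),
    cls = list(sfc = scale_fc_init(cfg$latent_dim),
               fc = linear_init(cfg$latent_dim, cfg$num_classes)),
    de = decoder_init(dec_cfg, groups = cfg$groups),
    gdec = decoder_init(dec_cfg, groups = cfg$groups),
    disc = list(sfc = scale_fc_init(cfg$latent_dim),
                fc = linear_init(cfg$latent_dim, 2L)),
    align = list(sfc = scale_fc_init(cfg$latent_dim),
                 fc = linear_init(cfg$latent_dim, 2L * N^2)),
    rcm = list(N = as.integer(N), k = as.integer(k)),
    classes = classes
  )
  class(model) <- "rgn_model"
  model
}

recognition_params <- function(model) {
  list(enc = model$enc, cls = model$cls)
}

check_image_batch <- function(images, cfg) {
  d <- dim(images)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("images must be a (H,W,C) or (N,H,W,C) array", call. = FALSE)
  }
  if (length(d) == 3L) {
    dim(images) <- c(1L, d)
    d <- dim(images)
  }
  if (d[2] != cfg$input_side || d[3] != cfg$input_side || d[4] != cfg$input_channels) {
    stop(sprintf("expected %d x %d x %d images, got %d x %d x %d",
                 cfg$input_side, cfg$input_side, cfg$input_channels,
                 d[2], d[3], d[4]), call. = FALSE)
  }
  images
}

#' Encode images to latent Gaussians
#'
#' Runs the encoder on a batch of images and returns, per image, the mean and
#' log-variance of the latent Gaussian (both of length `latent_dim`). The
#' forward pass is deterministic; sampling happens in [reparameterize()].
#'
#' @param images `(H,W,C)` or `(N,H,W,C)` array with values in `[0, 1]`
#' @param model an `rgn_model` or exported `rgn_inference` model
#' @param trace if `TRUE`, attach a layer-by-layer shape trace (a tibble) as
#'   attribute `"trace"` of the result
#' @return a `latent_gaussian` list with matrices `mu` and `log_var`
#'   (`N x latent_dim`)
#' @export
encode <- function(images, model, trace = FALSE) {
  cfg <- model$cfg
  images <- check_image_batch(images, cfg)
  tr <- if (trace) {
    e <- new.env(parent = emptyenv()); e$rows <- list(); e
  } else NULL
  out <- encoder_forward(ag_const(images), model$enc, cfg, trace = tr)
  lg <- latent_gaussian(out$mu$value, out$log_var$value)
  if (trace) {
    attr(lg, "trace") <- tibble::as_tibble(do.call(
      rbind, lapply(tr$rows, function(r) as.data.frame(r, stringsAsFactors = FALSE))))
  }
  lg
}

#' @rdname encode
#' @param mu,log_var `N x latent_dim` matrices (vectors are treated as N = 1)
#' @export
latent_gaussian <- function(mu, log_var) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (is.null(dim(log_var))) log_var <- matrix(log_var, nrow = 1L)
  stopifnot(all(dim(mu) == dim(log_var)), all(is.finite(mu)), all(is.finite(log_var)))
  structure(list(mu = mu, log_var = log_var), class = "latent_gaussian")
}

#' Reparameterized latent sampling
#'
#' In training mode draws `z = mu + exp(log_var / 2) * eps` with standard
#' normal `eps` (the reparameterization trick, using R's current RNG stream);
#' in inference mode returns `mu` exactly, so repeated predictions are
#' bit-identical.
#'
#' @param lg a [latent_gaussian()]
#' @param mode `"train"` (sample) or `"inference"` (return the mean)
#' @return an `N x latent_dim` matrix of latent vectors
#' @export
reparameterize <- function(lg, mode = c("train", "inference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lg, "latent_gaussian"))
  if (mode == "inference") return(lg$mu)
  eps <- matrix(stats::rnorm(length(lg$mu)), nrow(lg$mu), ncol(lg$mu))
  lg$mu + exp(lg$log_var / 2) * eps
}

#' Classify latent vectors
#'
#' Maps latent vectors through the classifier head (residual fully-connected
#' block, linear layer, softmax) to class probabilities.
#'
#' @param z latent vector (length `latent_dim`) or `N x latent_dim` matrix
#' @param model an `rgn_model` or `rgn_inference` model
#' @return a `class_prediction` list: `probs` (`N x C` matrix, rows summing
#'   to 1), `label` (integer argmax), `class` (class names)
#' @export
classify <- function(z, model) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$cfg$latent_dim) {
    stop("latent length ", ncol(z), " does not match latent_dim ",
         model$cfg$latent_dim, call. = FALSE)
  }
  logits <- classifier_forward(ag_const(z), model$cls)$value
  probs <- softmax_rows(logits)
  colnames(probs) <- model$classes
  label <- max.col(probs, ties.method = "first")
  structure(list(probs = probs, label = label, class = model$classes[label]),
            class = "class_prediction")
}

#' Predict disease classes for images
#'
#' Inference path of the recognition model: encode, substitute the latent
#' mean for the sampled latent (no randomness), classify. Identical inputs
#' always give identical outputs.
#'
#' @param object an `rgn_model` or `rgn_inference` model
#' @param images `(H,W,C)` or `(N,H,W,C)` array in `[0, 1]`
#' @param ... unused
#' @return a tibble with one row per image: `label` (integer), `class`,
#'   `prob` (maximum class probability)
#' @export
predict.rgn_model <- function(object, images, ...) {
  lg <- encode(images, object)
  z <- reparameterize(lg, mode = "inference")
  pred <- classify(z, object)
  tibble::tibble(
    index = seq_along(pred$label),
    label = pred$label,
    class = pred$class,
    prob = pred$probs[cbind(seq_along(pred$label), pred$label)]
  )
}

#' @rdname predict.rgn_model
#' @export
predict.rgn_inference <- predict.rgn_model

#' @export
print.rgn_model <- function(x, ...) {
  cat("<rgn_model>\n")
  cat(sprintf("  input: %d x %d x %d, latent %d, classes %d\n",
              x$cfg$input_side, x$cfg$input_side, x$cfg$input_channels,
              x$cfg$latent_dim, x$cfg$num_classes))
  cat(sprintf("  recognition parameters: %d (total with satellites: %d)\n",
              n_parameters(recognition_params(x)), n_parameters(unclass(x))))
  invisible(x)
}
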