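# Reusable encoder/decoder building blocks: grouped convolution with channel
# shuffle, squeeze-and-excitation attention, residual "scale" blocks (feature
# map and fully-connected variants) and the halve-size/double-channel
# downsample block. Each block has an `*_init()` constructor returning its
# parameters and a node-level `*_forward()` used inside the networks; the
# exported block functions take plain arrays so the blocks can be exercised
# and tested in isolation.

as_batched <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array", call. = FALSE)
  if (length(d) == 3L) {
    dim(x) <- c(1L, d)
    attr(x, "was_unbatched") <- TRUE
  } else if (length(d) != 4L) {
    stop("input must be a (H,W,C) or (N,H,W,C) array", call. = FALSE)
  }
  x
}

unbatch_like <- function(y, x) {
  if (isTRUE(attr(x, "was_unbatched"))) {
    d <- dim(y)
    dim(y) <- d[-1]
  }
  y
}

# group-transpose permutation: out channel j takes in channel perm[j]
shuffle_perm <- function(channels, groups) {
  if (channels %% groups != 0L) {
    stop("channel count (", channels, ") not divisible by groups (", groups, ")",
         call. = FALSE)
  }
  as.vector(t(matrix(seq_len(channels), nrow = channels %/% groups)))
}

#' Channel shuffle
#'
#' Deterministic channel rearrangement used after grouped convolution so that
#' information mixes across groups: channels are reshaped to
#' `groups x (C/groups)`, transposed, and flattened. With `groups = 1` this is
#' the identity; for any valid `groups` it is a bijection on channels and
#' leaves spatial values untouched.
#'
#' @param x a `(H,W,C)` or `(N,H,W,C)` numeric array
#' @param groups number of convolution groups
#' @return an array of identical shape with channels permuted
#' @examples
#' x <- array(seq_len(2 * 2 * 4), c(2, 2, 4))
#' y <- channel_shuffle(x, groups = 2)
#' @export
channel_shuffle <- function(x, groups) {
  xb <- as_batched(x)
  perm <- shuffle_perm(dim(xb)[4], groups)
  y <- xb[, , , perm, drop = FALSE]
  unbatch_like(y, xb)
}

# ---- squeeze-and-excitation ------------------------------------------------

se_init <- function(channels, se_reduction = 16L) {
  if (channels < se_reduction) {
    stop("se_attention requires channels >= se_reduction", call. = FALSE)
  }
  hidden <- max(1L, channels %/% se_reduction)
  list(fc1 = linear_init(channels, hidden), fc2 = linear_init(hidden, channels))
}

se_forward <- function(x, p) {
  s <- ag_global_mean_hw(x)
  h <- ag_relu(ag_add_rowvec(ag_matmul(s, ag_use(p$fc1$w)), ag_use(p$fc1$b)))
  g <- ag_sigmoid(ag_add_rowvec(ag_matmul(h, ag_use(p$fc2$w)), ag_use(p$fc2$b)))
  ag_scale_channels(x, g)
}

#' Squeeze-and-excitation channel attention
#'
#' Per-channel gating computed from globally average-pooled features through a
#' bottleneck (width `C / se_reduction`), expansion, and sigmoid. The output
#' has the input's shape, each channel scaled by a gate in (0, 1); with all
#' gate-producing weights at zero the gate is sigmoid(0) = 0.5 everywhere.
#'
#' @param x a `(H,W,C)` or `(N,H,W,C)` array
#' @param params parameters from `se_init()`; created fresh (random) if `NULL`
#' @param se_reduction bottleneck ratio used when `params` is `NULL`
#' @return gated array with the same shape as `x`
#' @export
se_attention <- function(x, params = NULL, se_reduction = 16L) {
  xb <- as_batched(x)
  C <- dim(xb)[4]
  if (is.null(params)) params <- se_init(C, se_reduction)
  y <- se_forward(ag_const(xb), params)$value
  unbatch_like(y, xb)
}

# ---- residual scale block ---------------------------------------------------

scale_init <- function(channels, groups = 4L) {
  if (channels %% groups != 0L) {
    stop("channels (", channels, ") not divisible by groups (", groups, ")",
         call. = FALSE)
  }
  list(
    bn1 = bn_init(channels),
    gconv = conv_init(3L, channels %/% groups, channels, bias = FALSE),
    bn2 = bn_init(channels),
    # final 1x1 projection zero-initialized: blocks start as exact identities
    proj = conv_init(1L, channels, channels, zero = TRUE)
  )
}

scale_forward <- function(x, p, groups) {
  C <- dim(x$value)[4]
  h <- ag_relu(ag_batchnorm(x, p$bn1))
  h <- ag_conv2d(h, ag_use(p$gconv$w), k = 3L, groups = groups)
  h <- ag_permute_channels(h, shuffle_perm(C, groups))
  h <- ag_relu(ag_batchnorm(h, p$bn2))
  h <- ag_conv2d(h, ag_use(p$proj$w), k = 1L, bias = ag_use(p$proj$b))
  ag_add(x, h)
}

#' Residual scale block
#'
#' The feature-extraction block of the encoder: a shape-preserving residual
#' unit whose branch is pre-activation batch norm -> ReLU -> grouped 3x3
#' convolution -> channel shuffle -> batch norm -> ReLU -> 1x1 projection. The
#' projection is zero-initialized, so a freshly built block is the identity.
#'
#' @param x a `(H,W,C)` or `(N,H,W,C)` array
#' @param params parameters from `scale_init()`; fresh if `NULL`
#' @param groups grouped-convolution groups (channels must be divisible)
#' @return array with the same shape as `x`
#' @export
scale_block <- function(x, params = NULL, groups = 4L) {
  xb <- as_batched(x)
  if (is.null(params)) params <- scale_init(dim(xb)[4], groups)
  y <- scale_forward(ag_const(xb), params, groups)$value
  unbatch_like(y, xb)
}

# ---- downsample block -------------------------------------------------------

downsample_init <- function(c_in, groups = 4L) {
  if (c_in %% groups != 0L) {
    stop("channels (", c_in, ") not divisible by groups (", groups, ")",
         call. = FALSE)
  }
  list(
    bn = bn_init(c_in),
    gconv = conv_init(3L, c_in %/% groups, 2L * c_in, bias = FALSE),
    short = conv_init(1L, c_in, 2L * c_in)
  )
}

downsample_forward <- function(x, p, groups) {
  pool <- ag_avgpool2(x)
  h <- ag_relu(ag_batchnorm(pool, p$bn))
  h <- ag_conv2d(h, ag_use(p$gconv$w), k = 3L, groups = groups)
  h <- ag_permute_channels(h, shuffle_perm(dim(h$value)[4], groups))
  s <- ag_conv2d(pool, ag_use(p$short$w), k = 1L, bias = ag_use(p$short$b))
  ag_add(h, s)
}

#' Downsample block
#'
#' Halves the spatial side with 2x2 average pooling (stride 2) and doubles the
#' channel count with a grouped 3x3 convolution (plus a 1x1 shortcut), the
#' stage transition used throughout the encoder (e.g. 128x128x16 -> 64x64x32).
#'
#' @param x a `(H,W,C)` or `(N,H,W,C)` array with even spatial side
#' @param params parameters from `downsample_init()`; fresh if `NULL`
#' @param groups grouped-convolution groups
#' @return array with half the side and twice the channels
#' @export
downsample_block <- function(x, params = NULL, groups = 4L) {
  xb <- as_batched(x)
  d <- dim(xb)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stop("downsample_block requires an even spatial side", call. = FALSE)
  }
  if (is.null(params)) params <- downsample_init(d[4], groups)
  y <- downsample_forward(ag_const(xb), params, groups)$value
  unbatch_like(y, xb)
}

# ---- residual fully-connected block -----------------------------------------

scale_fc_init <- function(width) {
  list(
    fc1 = linear_init(width, width),
    fc2 = linear_init(width, width, zero = TRUE)
  )
}

scale_fc_forward <- function(x, p) {
  h <- ag_relu(ag_add_rowvec(ag_matmul(x, ag_use(p$fc1$w)), ag_use(p$fc1$b)))
  h <- ag_add_rowvec(ag_matmul(h, ag_use(p$fc2$w)), ag_use(p$fc2$b))
  ag_add(x, h)
}

#' Residual fully-connected (scale_fc) block
#'
#' Length-preserving residual unit on vectors, used to aggregate global
#' information after pooling and at the head of the classifier and
#' discriminator: `out = v + W2 relu(W1 v + b1) + b2`, with `W2`, `b2`
#' zero-initialized.
#'
#' @param v a numeric vector or a `(N, width)` matrix of row vectors
#' @param params parameters from `scale_fc_init()`; fresh if `NULL`
#' @return object with the same shape as `v`
#' @export
scale_fc <- function(v, params = NULL) {
  vec <- is.null(dim(v))
  m <- if (vec) matrix(v, nrow = 1L) else v
  if (is.null(params)) params <- scale_fc_init(ncol(m))
  if (ncol(m) != nrow(params$fc1$w$value)) {
    stop("input length ", ncol(m), " does not match configured width ",
         nrow(params$fc1$w$value), call. = FALSE)
  }
  y <- scale_fc_forward(ag_const(m), params)$value
  if (vec) as.vector(y) else y
}
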