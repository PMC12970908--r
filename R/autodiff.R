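# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# Every operation creates a node holding its value, its parent nodes and a
# backward closure; nodes created while a tape is active are recorded so a
# single reverse sweep propagates gradients from a scalar loss to every
# trainable parameter. Feature maps are stored channels-last (N, H, W, C) so
# that `dim(x) <- c(N*H*W, C)` gives a zero-copy matrix view with channels as
# columns, and convolutions reduce to im2col + BLAS matrix products.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$training <- FALSE
.ag$freeze <- FALSE

ag_training <- function() .ag$training

# Freeze mode: operations behave normally and gradients still flow through
# them to their *inputs*, but parameters entered while frozen collect no
# gradient (and batch-norm running statistics are left untouched). Used to
# evaluate the discriminator path during the generator update without
# perturbing the shared encoder.
with_frozen <- function(expr) {
  old <- .ag$freeze
  .ag$freeze <- TRUE
  on.exit(.ag$freeze <- old)
  expr
}

#' Run an expression in training mode
#'
#' Training mode switches batch normalization to batch statistics (updating
#' running estimates) and enables reparameterized sampling. Everything else in
#' the package runs in inference mode, which is fully deterministic.
#'
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_training <- function(expr) {
  old <- .ag$training
  .ag$training <- TRUE
  on.exit(.ag$training <- old)
  expr
}

# Record `expr`'s nodes on a fresh tape; returns list(value, tape).
with_tape <- function(expr) {
  old <- .ag$tape
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  .ag$tape <- tape
  on.exit(.ag$tape <- old)
  val <- expr
  list(value = val, tape = tape)
}

ag_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  tp <- .ag$tape
  if (!is.null(tp) && !is.null(backward)) {
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$n]] <- n
  }
  n
}

ag_const <- function(value) ag_node(value)

is_ag_node <- function(x) is.environment(x) && !is.null(x$value) && is.null(x$trainable)

# Accumulate gradient g into node or parameter p.
ag_acc <- function(p, g) {
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

#' Create a trainable parameter
#'
#' @param value initial numeric array
#' @param trainable if `FALSE` the optimizer skips it (used for batch-norm
#'   running statistics, which the forward pass updates itself)
#' @return a parameter environment with fields `value`, `grad`, `v`, `trainable`
#' @keywords internal
new_param <- function(value, trainable = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$v <- NULL # momentum buffer
  p$trainable <- trainable
  class(p) <- "ag_param"
  p
}

# Enter a parameter into the current graph: gradients reaching the returned
# node accumulate into the parameter itself (unless frozen).
ag_use <- function(p) {
  if (.ag$freeze) return(ag_node(p$value))
  ag_node(p$value, list(), function(n) ag_acc(p, n$grad))
}

# detach a node: same value, no gradient path
ag_detach <- function(a) ag_node(a$value)

# Reverse sweep from scalar loss over the given tape.
ag_backward <- function(loss, tape) {
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad)) n$backward(n)
  }
  invisible(NULL)
}

# ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(n) {
    ag_acc(a, n$grad)
    ag_acc(b, n$grad)
  })
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(n) {
    ag_acc(a, n$grad)
    ag_acc(b, -n$grad)
  })
}

ag_mul <- function(a, b) {
  ag_node(a$value * b$value, list(a, b), function(n) {
    ag_acc(a, n$grad * b$value)
    ag_acc(b, n$grad * a$value)
  })
}

# multiply by a plain scalar constant
ag_scale <- function(a, k) {
  ag_node(a$value * k, list(a), function(n) ag_acc(a, n$grad * k))
}

ag_relu <- function(a) {
  m <- a$value > 0
  ag_node(a$value * m, list(a), function(n) ag_acc(a, n$grad * m))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(n) ag_acc(a, n$grad * s * (1 - s)))
}

ag_exp <- function(a) {
  e <- exp(a$value)
  ag_node(e, list(a), function(n) ag_acc(a, n$grad * e))
}

# ---- reductions ------------------------------------------------------------

ag_sum_all <- function(a) {
  ag_node(sum(a$value), list(a), function(n) {
    g <- array(n$grad, dim = dim_of(a$value))
    ag_acc(a, g)
  })
}

ag_mean_all <- function(a) ag_scale(ag_sum_all(a), 1 / length(a$value))

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- dense algebra ---------------------------------------------------------

# a: (n x d), w: (d x m)
ag_matmul <- function(a, w) {
  ag_node(a$value %*% w$value, list(a, w), function(n) {
    ag_acc(a, n$grad %*% t(w$value))
    ag_acc(w, crossprod(a$value, n$grad))
  })
}

# column-broadcast helpers: apply a length-C vector to every row of an
# (M x C) matrix without sweep()'s aperm overhead
col_add <- function(m, v) m + rep(v, each = nrow(m))
col_sub <- function(m, v) m - rep(v, each = nrow(m))
col_mul <- function(m, v) m * rep(v, each = nrow(m))
col_div <- function(m, v) m / rep(v, each = nrow(m))

# does gradient flowing into this node do any work?
ag_needs_grad <- function(n) !is.null(n$backward)

# a: (n x m) + row vector b (length m)
ag_add_rowvec <- function(a, b) {
  ag_node(col_add(a$value, b$value), list(a, b), function(n) {
    ag_acc(a, n$grad)
    ag_acc(b, colSums(n$grad))
  })
}

ag_reshape <- function(a, dims) {
  v <- a$value
  old <- dim_of(v)
  dim(v) <- dims
  ag_node(v, list(a), function(n) {
    g <- n$grad
    dim(g) <- old
    ag_acc(a, g)
  })
}

# select rows of a matrix node
ag_slice_rows <- function(a, idx) {
  d <- dim(a$value)
  ag_node(a$value[idx, , drop = FALSE], list(a), function(n) {
    g <- matrix(0, d[1], d[2])
    g[idx, ] <- n$grad
    ag_acc(a, g)
  })
}

# ---- feature-map operations (N, H, W, C) -----------------------------------

# Matrix view of a channels-last array: (N*H*W) x C, zero copy.
nhwc_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

# Same-padded stride-1 (grouped) convolution via C++ im2col + BLAS. The
# weight parameter is a (Cin_per_group * k^2) x Cout matrix, output channels
# partitioned by group; bias optional (length Cout). The im2col buffer lives
# in a persistent C++ workspace and is recomputed in the backward pass, so
# the tape retains nothing beyond the activations themselves.
ag_conv2d <- function(x, w, k = 3L, groups = 1L, bias = NULL) {
  d <- dim(x$value)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (C %% groups != 0L) stop("channel count not divisible by groups", call. = FALSE)
  if (nrow(w$value) != (C %/% groups) * k * k) {
    stop("weight shape mismatch", call. = FALSE)
  }
  if (ncol(w$value) %% groups != 0L) {
    stop("output channels not divisible by groups", call. = FALSE)
  }
  out <- cpp_conv_fwd(x$value, w$value, N, H, W, C, k, groups)
  if (!is.null(bias)) {
    Cout <- ncol(w$value)
    dim(out) <- c(N * H * W, Cout)
    out <- col_add(out, bias$value)
    dim(out) <- c(N, H, W, Cout)
  }
  parents <- if (is.null(bias)) list(x, w) else list(x, w, bias)
  x_needs <- ag_needs_grad(x)
  ag_node(out, parents, function(n) {
    bw <- cpp_conv_bwd(x$value, w$value, n$grad, N, H, W, C, k, groups,
                       x_needs)
    ag_acc(w, bw$gw)
    if (x_needs) ag_acc(x, bw$gx)
    if (!is.null(bias)) {
      gmat <- n$grad
      dim(gmat) <- c(N * H * W, ncol(w$value))
      ag_acc(bias, colSums(gmat))
    }
  })
}

# 2x2 average pooling, stride 2.
ag_avgpool2 <- function(x) {
  d <- dim(x$value)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (H %% 2L != 0L || W %% 2L != 0L) stop("spatial side must be even", call. = FALSE)
  io <- seq(1L, H, by = 2L); ie <- io + 1L
  jo <- seq(1L, W, by = 2L); je <- jo + 1L
  v <- (x$value[, io, jo, , drop = FALSE] + x$value[, ie, jo, , drop = FALSE] +
        x$value[, io, je, , drop = FALSE] + x$value[, ie, je, , drop = FALSE]) / 4
  ag_node(v, list(x), function(n) {
    g <- array(0, d)
    q <- n$grad / 4
    g[, io, jo, ] <- q; g[, ie, jo, ] <- g[, ie, jo, ] + q
    g[, io, je, ] <- g[, io, je, ] + q; g[, ie, je, ] <- g[, ie, je, ] + q
    ag_acc(x, g)
  })
}

# nearest-neighbour x2 upsampling
ag_upsample2 <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[2]), each = 2L)
  rj <- rep(seq_len(d[3]), each = 2L)
  v <- x$value[, ri, rj, , drop = FALSE]
  ag_node(v, list(x), function(n) {
    g <- n$grad
    io <- seq(1L, 2L * d[2], by = 2L); jo <- seq(1L, 2L * d[3], by = 2L)
    gx <- g[, io, jo, , drop = FALSE] + g[, io + 1L, jo, , drop = FALSE] +
      g[, io, jo + 1L, , drop = FALSE] + g[, io + 1L, jo + 1L, , drop = FALSE]
    ag_acc(x, gx)
  })
}

# global average over H and W: (N,H,W,C) -> (N,C)
ag_global_mean_hw <- function(x) {
  d <- dim(x$value)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  v <- cpp_mean_hw(x$value, N, H, W, C)
  ag_node(v, list(x), function(n) {
    ag_acc(x, cpp_broadcast_hw(n$grad, N, H, W, C, 1 / (H * W)))
  })
}

# per-channel gating: x (N,H,W,C) scaled by g (N,C)
ag_scale_channels <- function(x, gate) {
  d <- dim(x$value)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  y <- cpp_scale_channels_fwd(x$value, gate$value, N, H, W, C)
  ag_node(y, list(x, gate), function(n) {
    bw <- cpp_scale_channels_bwd(x$value, gate$value, n$grad, N, H, W, C)
    ag_acc(x, bw$gx)
    ag_acc(gate, bw$dgate)
  })
}

# fixed channel permutation: works for (N,C) and (N,H,W,C)
ag_permute_channels <- function(x, perm) {
  d <- dim(x$value)
  inv <- order(perm)
  if (length(d) == 2L) {
    v <- x$value[, perm, drop = FALSE]
    ag_node(v, list(x), function(n) ag_acc(x, n$grad[, inv, drop = FALSE]))
  } else {
    v <- x$value[, , , perm, drop = FALSE]
    ag_node(v, list(x), function(n) ag_acc(x, n$grad[, , , inv, drop = FALSE]))
  }
}

# ---- batch normalization ---------------------------------------------------

bn_init <- function(channels) {
  list(
    gamma = new_param(rep(1, channels)),
    beta = new_param(rep(0, channels)),
    run_mean = new_param(rep(0, channels), trainable = FALSE),
    run_var = new_param(rep(1, channels), trainable = FALSE)
  )
}

# Batch normalization over all-but-last dimension, with running statistics
# carried across training phases. `momentum` is the running-average retention.
ag_batchnorm <- function(x, bn, eps = 1e-5, momentum = 0.9) {
  d <- dim_of(x$value)
  C <- d[length(d)]
  M <- as.integer(prod(d) / C)
  training <- ag_training()
  frozen <- .ag$freeze
  gamma <- bn$gamma; beta <- bn$beta
  fw <- cpp_bn_fwd(x$value, M, C, bn$run_mean$value, bn$run_var$value,
                   gamma$value, beta$value, training, eps)
  if (training && !frozen) {
    bn$run_mean$value <- momentum * bn$run_mean$value + (1 - momentum) * fw$mean
    bn$run_var$value <- momentum * bn$run_var$value + (1 - momentum) * fw$var
  }
  y <- fw$y
  xhat <- fw$xhat
  sd_ <- fw$sd
  dim(y) <- d
  ag_node(y, list(x, gamma, beta), function(n) {
    bw <- cpp_bn_bwd(n$grad, xhat, M, C, gamma$value, sd_, training)
    if (!frozen) {
      ag_acc(gamma, bw$dgamma)
      ag_acc(beta, bw$dbeta)
    }
    gx <- bw$gx
    dim(gx) <- d
    ag_acc(x, gx)
  })
}

# ---- losses ----------------------------------------------------------------

# softmax + cross-entropy against integer labels (1-based); mean over batch
ag_softmax_ce <- function(logits, labels) {
  z <- logits$value
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  p <- e / rowSums(e)
  N <- nrow(p)
  idx <- cbind(seq_len(N), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  n <- ag_node(loss, list(logits), function(n) {
    g <- p
    g[idx] <- g[idx] - 1
    ag_acc(logits, n$grad * g / N)
  })
  attr(n, "probs") <- p
  n
}

softmax_rows <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  e / rowSums(e)
}

ag_mse <- function(a, b) {
  d <- a$value - b$value
  n_el <- length(d)
  ag_node(mean(d * d), list(a, b), function(n) {
    g <- n$grad * 2 * d / n_el
    ag_acc(a, g)
    ag_acc(b, -g)
  })
}

ag_mae <- function(a, b) {
  d <- a$value - b$value
  n_el <- length(d)
  ag_node(mean(abs(d)), list(a, b), function(n) {
    g <- n$grad * sign(d) / n_el
    ag_acc(a, g)
    ag_acc(b, -g)
  })
}

# ---- parameters: collection, optimizer, (de)serialization -------------------

#' @keywords internal
collect_params <- function(x) {
  if (inherits(x, "ag_param")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

n_parameters <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# classical momentum SGD: v <- mu*v - lr*g ; theta <- theta + v
sgd_momentum_step <- function(params, lr, momentum) {
  for (p in params) {
    if (!p$trainable || is.null(p$grad)) next
    if (is.null(p$v)) p$v <- p$grad * 0
    p$v <- momentum * p$v - lr * p$grad
    p$value <- p$value + p$v
  }
  invisible(NULL)
}

# snapshot / restore all parameter values (including running statistics)
param_values <- function(x) lapply(collect_params(x), function(p) p$value)

set_param_values <- function(x, values) {
  ps <- collect_params(x)
  stopifnot(length(ps) == length(values))
  for (i in seq_along(ps)) ps[[i]]$value <- values[[i]]
  invisible(x)
}

# ---- initializers ----------------------------------------------------------

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

linear_init <- function(d_in, d_out, zero = FALSE) {
  w <- if (zero) matrix(0, d_in, d_out) else he_init(d_in, d_out)
  list(w = new_param(w), b = new_param(rep(0, d_out)))
}

conv_init <- function(k, c_in_g, c_out, zero = FALSE, bias = TRUE) {
  nr <- c_in_g * k * k
  w <- if (zero) matrix(0, nr, c_out) else he_init(nr, c_out)
  out <- list(w = new_param(w))
  if (bias) out$b <- new_param(rep(0, c_out))
  out
}
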