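test_that("channel shuffle applies the group-transpose permutation", {
  x <- array(0, c(1, 1, 4))
  x[1, 1, ] <- 0:3
  expect_identical(channel_shuffle(x, groups = 1L), x)
  y <- channel_shuffle(x, groups = 2L)
  expect_equal(as.vector(y[1, 1, ]), c(0, 2, 1, 3))
  expect_error(channel_shuffle(x, groups = 3L), "divisible")
})

test_that("channel shuffle is a bijection on channels and leaves spatial
           content untouched", {
  set.seed(1)
  x <- array(rnorm(2 * 4 * 4 * 8), c(2, 4, 4, 8))
  for (g in c(2L, 4L, 8L)) {
    y <- channel_shuffle(x, g)
    expect_identical(dim(y), dim(x))
    # multiset of channel slices preserved
    sl_x <- apply(x, 4, function(m) paste(signif(m, 12), collapse = ","))
    sl_y <- apply(y, 4, function(m) paste(signif(m, 12), collapse = ","))
    expect_setequal(sl_y, sl_x)
    # inverse permutation recovers the input bit-exactly
    perm <- leafrgn:::shuffle_perm(8L, g)
    expect_identical(y[, , , order(perm), drop = FALSE], x)
  }
})

test_that("SE attention preserves shape and gates each channel in (0, 1)", {
  set.seed(2)
  x <- array(rnorm(2 * 8 * 8 * 16), c(2, 8, 8, 16))
  p <- leafrgn:::se_init(16L, 4L)
  y <- se_attention(x, p)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x))) # gates strictly below 1
  expect_true(all((y >= 0) == (x >= 0) | y == 0)) # sign preserved
  expect_error(se_attention(x[, , , 1:2, drop = FALSE], se_reduction = 16L),
               "channels")
})

test_that("SE attention with zero weights scales by sigmoid(0) = 0.5, and a
           two-channel toy matches the hand-computed squeeze-excite", {
  p <- leafrgn:::se_init(4L, 2L)
  for (q in leafrgn:::collect_params(p)) q$value[] <- 0
  x <- array(rnorm(1 * 2 * 2 * 4), c(1, 2, 2, 4))
  expect_equal(se_attention(x, p), 0.5 * x, tolerance = 1e-12)

  # 2-channel toy with known weights, spatially constant input
  p2 <- leafrgn:::se_init(2L, 2L)
  p2$fc1$w$value <- matrix(c(1, -1), 2, 1)  # squeeze: s1 - s2
  p2$fc1$b$value <- 0.5
  p2$fc2$w$value <- matrix(c(2, -1), 1, 2)
  p2$fc2$b$value <- c(0, 0.25)
  x2 <- array(0, c(1, 3, 3, 2))
  x2[, , , 1] <- 2; x2[, , , 2] <- -1
  h <- max(0, 2 - (-1) + 0.5)               # relu bottleneck = 3.5
  gate <- 1 / (1 + exp(-c(2 * h, -h + 0.25)))
  y2 <- se_attention(x2, p2)
  expect_equal(as.vector(y2[1, 1, 1, ]), c(2, -1) * gate, tolerance = 1e-12)
})

test_that("scale block is residual: zero branch weights give the identity", {
  set.seed(3)
  x <- array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  p <- leafrgn:::scale_init(8L, 4L)
  y <- scale_block(x, p, groups = 4L)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # freshly built blocks are exact identities (zero-init projection)
  expect_equal(y, x, tolerance = 1e-12)
  # and remain identities when every branch weight is forced to zero
  for (q in leafrgn:::collect_params(p)) if (q$trainable) q$value[] <- 0
  p$bn1$gamma$value[] <- 1; p$bn2$gamma$value[] <- 1
  expect_equal(scale_block(x, p, groups = 4L), x, tolerance = 1e-12)
  expect_error(scale_block(x, groups = 3L), "divisible")
})

test_that("downsample halves the side and doubles the channels", {
  set.seed(4)
  x <- array(rnorm(1 * 16 * 16 * 8), c(1, 16, 16, 8))
  y <- downsample_block(x)
  expect_identical(dim(y), c(1L, 8L, 8L, 16L))
  y2 <- downsample_block(y)
  expect_identical(dim(y2), c(1L, 4L, 4L, 32L)) # quarter side, 4x channels
  odd <- array(rnorm(1 * 5 * 5 * 8), c(1, 5, 5, 8))
  expect_error(downsample_block(odd), "even")
})

test_that("scale_fc preserves length, is deterministic, and zero branch
           weights give the identity", {
  set.seed(5)
  v <- rnorm(256)
  p <- leafrgn:::scale_fc_init(256L)
  y1 <- scale_fc(v, p)
  y2 <- scale_fc(v, p)
  expect_length(y1, 256L)
  expect_identical(y1, y2)
  for (q in leafrgn:::collect_params(p)) q$value[] <- 0
  expect_equal(scale_fc(v, p), v, tolerance = 1e-12)
  expect_error(scale_fc(rnorm(100), p), "does not match")
})

test_that("blocks preserve batch size", {
  x <- random_images(5, side = 8L, channels = 8L)
  expect_equal(dim(scale_block(x, groups = 4L))[1], 5L)
  expect_equal(dim(downsample_block(x))[1], 5L)
  expect_equal(dim(se_attention(x, se_reduction = 4L))[1], 5L)
})
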