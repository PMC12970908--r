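# Region confusion mechanism: constrained shuffles, content conservation,
# exact inversion, and alignment supervision.

test_that("permutation displacements never exceed 2k", {
  for (seed in 1:200) {
    pm <- make_permutation(8L, 2L, seed = seed)
    for (j in 1:8) {
      expect_true(all(abs(pm$row_perms[j, ] - 1:8) <= 4))
      expect_true(all(abs(pm$col_perms[, j] - 1:8) <= 4))
    }
  }
  expect_error(make_permutation(8L, 0L), "k must")
  expect_error(make_permutation(8L, 8L), "k must")
})

test_that("at N = 2, k = 1 the reachable row permutations are exactly
           identity and swap", {
  seen <- character(0)
  for (seed in 1:400) {
    pm <- make_permutation(2L, 1L, seed = seed)
    seen <- union(seen, c(paste(pm$row_perms[1, ], collapse = ""),
                          paste(pm$row_perms[2, ], collapse = "")))
  }
  expect_setequal(seen, c("12", "21"))
})

region_blocks <- function(img, N) {
  s <- dim(img)[1] %/% N
  out <- character(0)
  for (j in seq_len(N)) for (i in seq_len(N)) {
    out <- c(out, paste(signif(img[(j - 1) * s + seq_len(s),
                                   (i - 1) * s + seq_len(s), ], 12),
                        collapse = ","))
  }
  out
}

test_that("destroy conserves region content and restores exactly", {
  set.seed(5)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(destroy(img, identity_permutation(8L)), img)
  for (seed in c(3, 17, 99)) {
    pm <- make_permutation(8L, 2L, seed = seed)
    sh <- destroy(img, pm)
    expect_setequal(region_blocks(sh, 8L), region_blocks(img, 8L))
    expect_equal(sort(as.vector(sh)), sort(as.vector(img))) # pixel histogram
    expect_identical(restore_layout(sh, pm), img)
  }
  expect_error(destroy(array(0, c(30, 30, 3)), make_permutation(8L, 2L)),
               "divisible")
})

test_that("with k = N-1 shuffles reach far displacements; the identity is
           its own fixed point", {
  disp <- 0
  for (seed in 1:50) {
    pm <- make_permutation(8L, 7L, seed = seed)
    disp <- max(disp, max(abs(pm$row_perms - matrix(1:8, 8, 8, byrow = TRUE))))
  }
  expect_gte(disp, 5) # near-unrestricted shuffling
})

test_that("alignment targets name each slot's original region", {
  # identity: every slot points at itself
  tg <- alignment_targets(identity_permutation(8L))
  own <- (matrix(1:8, 8, 8) - 1) / 7
  expect_equal(tg[, , 1], own)
  expect_equal(tg[, , 2], t(own))

  # a single adjacent swap in row 1 (columns 1 and 2) swaps exactly those
  # two targets
  pm <- identity_permutation(8L)
  pm$row_perms[1, 1:2] <- c(2L, 1L)
  tg2 <- alignment_targets(pm)
  expect_equal(tg2[1, 1, 2], 1 / 7)
  expect_equal(tg2[1, 2, 2], 0)
  expect_equal(tg2[1, 1, 1], 0) # rows unchanged
  same <- tg2
  same[1, 1:2, ] <- tg[1, 1:2, ]
  expect_equal(same, tg)
})

test_that("alignment targets agree with an exact block-matching oracle", {
  set.seed(8)
  N <- 4L
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  s <- 4L
  for (seed in c(2, 21)) {
    pm <- make_permutation(N, 2L, seed = seed)
    sh <- destroy(img, pm)
    tg <- alignment_targets(pm)
    for (j in seq_len(N)) for (i in seq_len(N)) {
      blk <- sh[(j - 1) * s + seq_len(s), (i - 1) * s + seq_len(s), ]
      # search the original image for this block
      found <- NULL
      for (jj in seq_len(N)) for (ii in seq_len(N)) {
        cand <- img[(jj - 1) * s + seq_len(s), (ii - 1) * s + seq_len(s), ]
        if (identical(cand, blk)) found <- c(jj, ii)
      }
      expect_equal((found - 1) / (N - 1), as.vector(tg[j, i, ]))
    }
  }
})

test_that("the two target conventions are inverses of each other", {
  pm <- make_permutation(6L, 2L, seed = 12)
  a <- alignment_targets(pm, "original")
  b <- alignment_targets(pm, "new")
  N <- 6L
  for (j in seq_len(N)) for (i in seq_len(N)) {
    oj <- round(a[j, i, 1] * (N - 1)) + 1L
    oi <- round(a[j, i, 2] * (N - 1)) + 1L
    expect_equal(round(b[oj, oi, ] * (N - 1)) + 1L, c(j, i),
                 ignore_attr = TRUE)
  }
})

test_that("alignment loss is the mean absolute coordinate error", {
  tg <- alignment_targets(identity_permutation(8L))
  expect_identical(alignment_loss(tg, tg), 0)
  off <- tg
  off[3, 5, 1] <- off[3, 5, 1] + 0.25
  expect_equal(alignment_loss(off, tg), 0.25 / (2 * 64))
  expect_equal(alignment_loss(tg, off), alignment_loss(off, tg))
  expect_error(alignment_loss(tg[, , 1], tg), "shapes")
})
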