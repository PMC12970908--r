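test_that("split sizes follow round-half-up", {
  expect_identical(split_counts(54303),
                   c(train = 32581L, validation = 10861L, test = 10861L))
  expect_identical(split_counts(10),
                   c(train = 6L, validation = 2L, test = 2L))
  expect_identical(split_counts(558, c(0.7, 0.3)), c(train = 391L, test = 167L))
  expect_identical(split_counts(463, c(0.7, 0.3)), c(train = 324L, test = 139L))
  expect_error(split_counts(10, c(0.5, 0.4)), "sum to 1")
})

test_that("labeled-fraction partition reproduces the benchmark cells,
           including the half-up tie at 50%", {
  expect_identical(label_counts(32581, 0.1), c(labeled = 3258L, unlabeled = 29323L))
  expect_identical(label_counts(32581, 0.3), c(labeled = 9774L, unlabeled = 22807L))
  expect_identical(label_counts(32581, 0.5), c(labeled = 16291L, unlabeled = 16290L))
  expect_identical(label_counts(32581, 0.7), c(labeled = 22807L, unlabeled = 9774L))
  expect_identical(label_counts(32581, 0.9), c(labeled = 29323L, unlabeled = 3258L))
  expect_identical(label_counts(10, 1), c(labeled = 10L, unlabeled = 0L))
  expect_error(label_counts(10, 0), "fraction")
})

test_that("split_dataset partitions disjointly, exhaustively, and stably
           under a fixed seed", {
  recs <- tibble::tibble(id = 1:100,
                         class = rep(c("a", "b", "c", "d"), each = 25))
  s1 <- split_dataset(recs, seed = 42)
  s2 <- split_dataset(recs, seed = 42)
  expect_identical(s1, s2)
  expect_setequal(s1$id, recs$id)
  expect_identical(as.vector(table(s1$subset)[c("train", "validation", "test")]),
                   c(60L, 20L, 20L))
  # per-class rounding: each class splits 15/5/5
  for (cl in unique(recs$class)) {
    expect_identical(sum(s1$subset == "train" & s1$class == cl), 15L)
  }
  s3 <- split_dataset(recs, seed = 43)
  expect_false(identical(s1$subset, s3$subset))
  # global convention
  s4 <- split_dataset(recs, seed = 1, per_class = FALSE)
  expect_identical(sum(s4$subset == "validation"), 20L)
  expect_error(split_dataset(recs[0, ]), "no records")
})

test_that("label_partition marks a deterministic labeled subset", {
  recs <- tibble::tibble(id = 1:101)
  p1 <- label_partition(recs, 0.3, seed = 5)
  expect_identical(sum(p1$labeled), 30L) # round_half_up(30.3)
  expect_identical(label_partition(recs, 0.3, seed = 5)$labeled, p1$labeled)
  expect_true(all(label_partition(recs, 1, seed = 1)$labeled))
})

test_that("augmentation triples the set in original/mirror/rotation order
           and mirroring is an involution", {
  set.seed(6)
  imgs <- lapply(1:4, function(i) array(runif(6 * 6 * 3), c(6, 6, 3)))
  out <- augment_mirror_rotate(imgs)
  expect_length(out, 12L)
  expect_identical(out[[1]], imgs[[1]])
  expect_identical(out[[4]], imgs[[2]])
  expect_identical(leafrgn:::mirror_image(out[[2]]), imgs[[1]])
  rot <- out[[3]]
  expect_identical(rot[6, 6, ], imgs[[1]][1, 1, ])
  expect_length(augment_mirror_rotate(list()), 0L)
})

test_that("preprocess resizes to a normalized square and passes conforming
           input through unchanged", {
  set.seed(7)
  big <- array(runif(40 * 60 * 3), c(40, 60, 3))
  out <- preprocess(big, side = 16L)
  expect_identical(dim(out), c(16L, 16L, 3L))
  expect_true(min(out) >= 0 && max(out) <= 1)
  conforming <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(preprocess(conforming, side = 16L), conforming)
  gray <- matrix(runif(25), 5, 5)
  expect_identical(dim(preprocess(gray, side = 8L)), c(8L, 8L, 3L))
  bad <- tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(preprocess(bad, side = 16L), "failed to read image")
})

test_that("a written class-per-folder tree reads back with classes and an
           unlabeled pool", {
  ds <- synth_generate(2, seed = 3, side = 16L, n_unlabeled = 3L)
  dir <- file.path(tempdir(), "synthtree")
  unlink(dir, recursive = TRUE)
  synth_write_dir(ds, dir)
  man <- read_image_dir(dir)
  expect_identical(nrow(man), 8L + 3L)
  expect_setequal(stats::na.omit(unique(man$class)), ds$classes)
  expect_identical(sum(!man$labeled), 3L)
  arr <- load_images(man[man$labeled, ][1:2, ], side = 16L)
  expect_identical(dim(arr), c(2L, 16L, 16L, 3L))
  # PNG quantizes to 8 bits; content survives within that precision
  first <- man$path[man$labeled & man$class == ds$classes[1]][1]
  expect_lt(max(abs(preprocess(first, side = 16L) - ds$images[[1]])),
            1 / 255)
})

test_that("the synthetic generator is deterministic and produces the
           declared layout", {
  a <- synth_generate(3, seed = 11, side = 16L, n_unlabeled = 2L)
  b <- synth_generate(3, seed = 11, side = 16L, n_unlabeled = 2L)
  expect_identical(a, b)
  expect_length(a$images, 12L)
  expect_identical(a$labels, rep(1:4, each = 3L))
  expect_length(a$unlabeled, 2L)
  expect_length(synth_generate(0, seed = 1, side = 16L)$images, 0L)
  expect_error(synth_generate(2, class_specs = list(x = list())), "at least 2")
  bad <- synth_class_specs()
  bad$healthy$lesion_count <- c(3L, 1L)
  expect_error(synth_generate(2, class_specs = bad, side = 16L), "invalid")
})

test_that("a lesion-pixel-fraction threshold separates healthy from diseased
           with >90% accuracy on 200 images", {
  ds <- synth_generate(50, seed = 19, side = 32L)
  specs <- synth_class_specs()
  frac <- vapply(seq_along(ds$images), function(i) {
    max(vapply(2:4, function(j) {
      lesion_fraction(ds$images[[i]], specs[[j]]$lesion_color)
    }, numeric(1)))
  }, numeric(1))
  diseased <- ds$labels != 1L
  accs <- vapply(sort(unique(frac)), function(th) {
    mean((frac >= th) == diseased)
  }, numeric(1))
  expect_gt(max(accs), 0.9)
})
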