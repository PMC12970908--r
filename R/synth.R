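# Synthetic leaf-lesion image generator. Stands in for field datasets when
# exercising the pipeline end to end: each image is a textured soil
# background with a green leaf ellipse and class-specific lesion disks.
# The classes differ in lesion count, size and hue, so they are visually
# separable by local lesion statistics -- the property the fine-grained
# training scheme is meant to exploit -- while leaf shape, pose and
# lighting vary within every class.

#' Default synthetic class specifications
#'
#' Four classes emulating common foliar conditions: `healthy` (no lesions),
#' `brown_spot` (small dark-brown necrotic disks), `yellow_blight` (larger
#' chlorotic yellow patches) and `powdery_mildew` (many small pale spots).
#' Lesion radii are fractions of the image side so the same specs work at
#' any resolution.
#'
#' @return a named list of class specs with fields `lesion_count` (min/max),
#'   `lesion_radius` (min/max, relative to side), `lesion_color` (RGB)
#' @export
synth_class_specs <- function() {
  list(
    healthy = list(lesion_count = c(0L, 0L), lesion_radius = c(0, 0),
                   lesion_color = c(0, 0, 0)),
    brown_spot = list(lesion_count = c(3L, 7L), lesion_radius = c(0.025, 0.05),
                      lesion_color = c(0.18, 0.07, 0.05)),
    yellow_blight = list(lesion_count = c(2L, 5L), lesion_radius = c(0.05, 0.09),
                         lesion_color = c(0.85, 0.74, 0.18)),
    powdery_mildew = list(lesion_count = c(6L, 12L), lesion_radius = c(0.018, 0.035),
                          lesion_color = c(0.9, 0.9, 0.86))
  )
}

check_spec <- function(spec, name) {
  ok <- is.list(spec) &&
    length(spec$lesion_count) == 2L && spec$lesion_count[1] <= spec$lesion_count[2] &&
    spec$lesion_count[1] >= 0 &&
    length(spec$lesion_radius) == 2L && spec$lesion_radius[1] <= spec$lesion_radius[2] &&
    spec$lesion_radius[1] >= 0 &&
    length(spec$lesion_color) == 3L
  if (!ok) stop("invalid class spec '", name, "'", call. = FALSE)
  invisible(NULL)
}

synth_one_image <- function(spec, side) {
  # soil background: brown base with speckle
  img <- array(0, c(side, side, 3L))
  soil <- c(0.36, 0.24, 0.13) * stats::runif(1, 0.9, 1.15)
  speck <- matrix(stats::rnorm(side * side, sd = 0.02), side, side)
  for (c3 in 1:3) img[, , c3] <- pmin(pmax(soil[c3] + speck, 0), 1)

  # leaf ellipse with random pose
  cx <- side / 2 + stats::runif(1, -0.06, 0.06) * side
  cy <- side / 2 + stats::runif(1, -0.06, 0.06) * side
  a <- stats::runif(1, 0.30, 0.42) * side
  b <- stats::runif(1, 0.22, 0.36) * side
  th <- stats::runif(1, 0, pi)
  xs <- matrix(seq_len(side), side, side)           # row coordinate
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  leaf <- (u / a)^2 + (v / b)^2 <= 1
  green <- c(0.13, 0.44, 0.15) * stats::runif(1, 0.85, 1.15)
  shade <- 1 - 0.25 * ((u / a)^2 + (v / b)^2) # brighter centre, darker rim
  noise <- matrix(stats::rnorm(side * side, sd = 0.03), side, side)
  for (c3 in 1:3) {
    ch <- img[, , c3]
    ch[leaf] <- pmin(pmax(green[c3] * shade[leaf] + noise[leaf], 0), 1)
    img[, , c3] <- ch
  }

  # class-specific lesion disks, kept on the leaf
  n_les <- if (spec$lesion_count[2] > 0) {
    sample(spec$lesion_count[1]:spec$lesion_count[2], 1L)
  } else 0L
  if (n_les > 0L) {
    for (l in seq_len(n_les)) {
      # draw the centre inside the ellipse (polar in ellipse coordinates)
      rr <- sqrt(stats::runif(1, 0, 0.8))
      ph <- stats::runif(1, 0, 2 * pi)
      lu <- rr * a * cos(ph); lv <- rr * b * sin(ph)
      lx <- cx + lu * cos(th) - lv * sin(th)
      ly <- cy + lu * sin(th) + lv * cos(th)
      rad <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2]) * side
      disk <- ((xs - lx)^2 + (ys - ly)^2 <= rad^2) & leaf
      if (!any(disk)) next
      col <- pmin(pmax(spec$lesion_color * stats::runif(1, 0.9, 1.1), 0), 1)
      for (c3 in 1:3) {
        ch <- img[, , c3]
        ch[disk] <- pmin(pmax(col[c3] + stats::rnorm(sum(disk), sd = 0.02), 0), 1)
        img[, , c3] <- ch
      }
    }
  }
  img
}

#' Generate a synthetic leaf-lesion dataset
#'
#' Fully deterministic under `seed`: the same call yields bit-identical
#' images. Labeled images come `n_per_class` per class in spec order; an
#' optional unlabeled pool draws classes at random and carries no label.
#'
#' @param n_per_class labeled images per class
#' @param class_specs named list of specs, see [synth_class_specs()]
#' @param seed integer seed
#' @param side image side in pixels
#' @param n_unlabeled size of the unlabeled pool
#' @return a `synth_dataset`: `images` (list of arrays), `labels` (integer),
#'   `classes` (names), `unlabeled` (list of arrays)
#' @export
synth_generate <- function(n_per_class, class_specs = synth_class_specs(),
                           seed = 1L, side = 128L, n_unlabeled = 0L) {
  if (length(class_specs) < 2L) stop("need at least 2 class specs", call. = FALSE)
  for (nm in names(class_specs)) check_spec(class_specs[[nm]], nm)
  set.seed(seed)
  n_cls <- length(class_specs)
  images <- vector("list", n_per_class * n_cls)
  labels <- integer(n_per_class * n_cls)
  pos <- 0L
  for (ci in seq_len(n_cls)) {
    for (i in seq_len(n_per_class)) {
      pos <- pos + 1L
      images[[pos]] <- synth_one_image(class_specs[[ci]], side)
      labels[pos] <- ci
    }
  }
  unlabeled <- vector("list", n_unlabeled)
  if (n_unlabeled > 0L) {
    draw <- sample.int(n_cls, n_unlabeled, replace = TRUE)
    for (i in seq_len(n_unlabeled)) {
      unlabeled[[i]] <- synth_one_image(class_specs[[draw[i]]], side)
    }
  }
  structure(list(images = images, labels = labels,
                 classes = names(class_specs), unlabeled = unlabeled),
            class = "synth_dataset")
}

#' Fraction of pixels near a reference color
#'
#' The simple pixel statistic that makes the synthetic classes separable: the
#' share of pixels whose RGB distance to `color` is below `tol`. Used to
#' validate that the fixture is learnable by construction.
#'
#' @param image `(H,W,C)` array
#' @param color length-3 RGB reference
#' @param tol Euclidean RGB distance threshold
#' @return scalar in `[0, 1]`
#' @export
lesion_fraction <- function(image, color, tol = 0.12) {
  d2 <- (image[, , 1] - color[1])^2 + (image[, , 2] - color[2])^2 +
    (image[, , 3] - color[3])^2
  mean(d2 < tol^2)
}

#' Write a synthetic dataset as a class-per-folder directory
#'
#' @param ds a `synth_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
synth_write_dir <- function(ds, dir) {
  for (ci in seq_along(ds$classes)) {
    d <- file.path(dir, ds$classes[ci])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    idx <- which(ds$labels == ci)
    for (j in seq_along(idx)) {
      png::writePNG(ds$images[[idx[j]]], file.path(d, sprintf("img_%04d.png", j)))
    }
  }
  if (length(ds$unlabeled) > 0L) {
    d <- file.path(dir, "_unlabeled")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(ds$unlabeled)) {
      png::writePNG(ds$unlabeled[[j]], file.path(d, sprintf("img_%04d.png", j)))
    }
  }
  invisible(dir)
}
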