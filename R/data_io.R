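# Dataset handling: deterministic train/validation/test splits with the
# round-half-up convention, labeled/unlabeled partitioning of the training
# pool, mirror + 180-degree-rotation augmentation, and 128x128x3
# preprocessing of class-per-folder image directories.

#' Round half up
#'
#' The rounding convention used for every split size: `floor(x + 0.5)`.
#' (Fixed by the benchmark split of a 32,581-image pool at 50%, which gives
#' 16,291 labeled / 16,290 unlabeled.)
#'
#' @param x numeric
#' @return integer vector
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Deterministic split sizes
#'
#' For a three-way ratio (train/validation/test), validation and test sizes
#' are `round_half_up(ratio * n)` and train takes the remainder; for a
#' two-way ratio the first part is rounded and the second takes the
#' remainder. 54,303 records at 6:2:2 give 32,581 / 10,861 / 10,861;
#' 558 records at 7:3 give 391 / 167.
#'
#' @param n number of records
#' @param ratios numeric vector of length 2 or 3 summing to 1
#' @return named integer vector of part sizes
#' @export
split_counts <- function(n, ratios = c(0.6, 0.2, 0.2)) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  n <- as.integer(n)
  if (length(ratios) == 3L) {
    val <- round_half_up(ratios[2] * n)
    test <- round_half_up(ratios[3] * n)
    c(train = n - val - test, validation = val, test = test)
  } else if (length(ratios) == 2L) {
    a <- round_half_up(ratios[1] * n)
    c(train = a, test = n - a)
  } else {
    stop("ratios must have length 2 or 3", call. = FALSE)
  }
}

assign_subsets <- function(n, ratios, seed_offset = 0L) {
  sizes <- split_counts(n, ratios)
  idx <- sample.int(n)
  subset <- character(n)
  pos <- 0L
  for (nm in names(sizes)) {
    take <- idx[pos + seq_len(sizes[[nm]])]
    subset[take] <- nm
    pos <- pos + sizes[[nm]]
  }
  subset
}

#' Split a dataset into train/validation/test
#'
#' Randomly but reproducibly partitions records. With `per_class = TRUE`
#' (the default) the rounding convention applies within each class so class
#' balance is preserved; with `per_class = FALSE` it applies globally,
#' which reproduces whole-collection benchmark totals exactly.
#'
#' @param records a data frame with one row per sample; must contain a
#'   `class` column when `per_class = TRUE`
#' @param ratios split ratios (length 3 for train/validation/test, length 2
#'   for train/test), summing to 1
#' @param seed integer seed making the split deterministic
#' @param per_class apply the split within each class
#' @return the records as a tibble with an added `subset` column
#' @export
split_dataset <- function(records, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                          per_class = TRUE) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) stop("no records to split", call. = FALSE)
  set.seed(seed)
  if (per_class) {
    if (is.null(records$class)) {
      stop("per-class splitting requires a `class` column", call. = FALSE)
    }
    records$subset <- NA_character_
    for (cl in unique(records$class)) {
      rows <- which(records$class == cl)
      records$subset[rows] <- assign_subsets(length(rows), ratios)
    }
  } else {
    records$subset <- assign_subsets(nrow(records), ratios)
  }
  records
}

#' Labeled-fraction counts and partition
#'
#' `label_counts()` gives the labeled/unlabeled sizes for a pool of `n`
#' records under round-half-up (e.g. 32,581 at 10% -> 3,258 labeled /
#' 29,323 unlabeled; at 50% -> 16,291 / 16,290). `label_partition()` applies
#' the partition to the training rows of a manifest, adding a logical
#' `labeled` column.
#'
#' @param n pool size
#' @param fraction labeled fraction in (0, 1]
#' @return named integer vector `c(labeled, unlabeled)`
#' @export
label_counts <- function(n, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- as.integer(n)
  lab <- round_half_up(fraction * n)
  c(labeled = lab, unlabeled = n - lab)
}

#' @rdname label_counts
#' @param train_pool data frame of training records
#' @param seed integer seed
#' @export
label_partition <- function(train_pool, fraction, seed = 1L) {
  train_pool <- tibble::as_tibble(train_pool)
  n <- nrow(train_pool)
  sizes <- label_counts(n, fraction)
  set.seed(seed)
  lab_idx <- sample.int(n)[seq_len(sizes[["labeled"]])]
  train_pool$labeled <- FALSE
  train_pool$labeled[lab_idx] <- TRUE
  train_pool
}

mirror_image <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
rotate180_image <- function(x) {
  x[rev(seq_len(dim(x)[1])), rev(seq_len(dim(x)[2])), , drop = FALSE]
}

#' Mirror and rotation augmentation
#'
#' Expands an image set threefold: for each input, the original, its
#' horizontal mirror, and its 180-degree rotation, in that order (so labels
#' expand as `rep(labels, each = 3)`). 186 disease images expand to 558.
#'
#' @param images a list of `(H,W,C)` arrays (a single array is treated as a
#'   list of one)
#' @return a list of `3 * length(images)` arrays
#' @export
augment_mirror_rotate <- function(images) {
  if (is.array(images)) images <- list(images)
  out <- vector("list", 3L * length(images))
  for (i in seq_along(images)) {
    x <- images[[i]]
    out[[3L * i - 2L]] <- x
    out[[3L * i - 1L]] <- mirror_image(x)
    out[[3L * i]] <- rotate180_image(x)
  }
  out
}

#' Preprocess an image to a normalized square array
#'
#' Reads (if given a path) and bilinearly resizes an RGB image to
#' `side x side x 3` with values in `[0, 1]`. Grayscale images are expanded
#' to three channels and an alpha channel is dropped. An input that is
#' already a conforming `side x side x 3` array in `[0, 1]` is returned
#' unchanged.
#'
#' @param image a file path or a numeric `(H,W)` / `(H,W,C)` array in
#'   `[0, 1]`
#' @param side target side in pixels (128 by default)
#' @return a `(side, side, 3)` array in `[0, 1]`
#' @export
preprocess <- function(image, side = 128L) {
  if (is.character(image)) {
    img <- tryCatch(EBImage::readImage(image), error = function(e) {
      stop("failed to read image '", image, "': ", conditionMessage(e),
           call. = FALSE)
    })
    a <- as.array(img)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    image <- aperm(a, c(2L, 1L, 3L)) # EBImage stores (x, y, c)
  }
  d <- dim(image)
  if (length(d) == 2L) image <- array(rep(image, 3L), c(d, 3L))
  d <- dim(image)
  if (d[3] > 3L) image <- image[, , 1:3, drop = FALSE]
  if (d[1] == side && d[2] == side && dim(image)[3] == 3L) {
    return(pmin(pmax(image, 0), 1))
  }
  img <- EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
  img <- EBImage::resize(img, w = side, h = side) # bilinear
  out <- aperm(as.array(img), c(2L, 1L, 3L))
  pmin(pmax(out, 0), 1)
}

#' Read a class-per-folder image directory
#'
#' Expects `root/<class_name>/*.png|jpg|jpeg`; a folder named `_unlabeled`
#' becomes the unlabeled pool (`class = NA`, `labeled = FALSE`). Images are
#' not loaded; use [load_images()] on the returned manifest.
#'
#' @param root directory path
#' @return a tibble with `path`, `class`, `labeled`
#' @export
read_image_dir <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0L) stop("no class folders under ", root, call. = FALSE)
  rows <- lapply(dirs, function(d) {
    files <- list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) return(NULL)
    cl <- basename(d)
    tibble::tibble(path = files,
                   class = if (cl == "_unlabeled") NA_character_ else cl,
                   labeled = cl != "_unlabeled")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no images found under ", root, call. = FALSE)
  out
}

#' @rdname read_image_dir
#' @param paths character vector of image paths (or a manifest tibble with a
#'   `path` column)
#' @param side target image side
#' @return `(N, side, side, 3)` array
#' @export
load_images <- function(paths, side = 128L) {
  if (is.data.frame(paths)) paths <- paths$path
  arr <- array(0, c(length(paths), side, side, 3L))
  for (i in seq_along(paths)) arr[i, , , ] <- preprocess(paths[[i]], side)
  arr
}

# stack a list of (H,W,C) arrays into (N,H,W,C)
stack_images <- function(images) {
  d <- dim(images[[1]])
  arr <- array(0, c(length(images), d))
  for (i in seq_along(images)) arr[i, , , ] <- images[[i]]
  arr
}
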