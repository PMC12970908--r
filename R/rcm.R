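# Region confusion mechanism: partition an image into an N x N grid of
# regions and shuffle them under a locality constraint. Each row's columns
# are permuted by sorting a ramp perturbed with uniform noise on [-k, k];
# after all rows, each column's rows are permuted the same way. Sorting a
# +-k-perturbed ramp moves no element more than 2k positions, so regions
# are regrouped only within an adjustable neighbourhood.

#' Draw a constrained region permutation
#'
#' For each row `j`, draws `q[j, i] = i + r_i` with `r_i` uniform on
#' `[-k, k]` and takes the sorting permutation `sigma_j = order(q_j)`;
#' column-wise permutations `tau_i` are drawn analogously and are applied
#' after all row permutations. Ties (measure-zero for the continuous draw)
#' break by original index. Every displacement satisfies
#' `|sigma_j(i) - i| <= 2k` and `|tau_i(j) - j| <= 2k`.
#'
#' @param N grid size (the image is split into `N x N` regions)
#' @param k locality parameter, `1 <= k < N`
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used)
#' @return a `region_permutation`: matrices `row_perms` (`row_perms[j, i]` is
#'   the source column of slot `i` in row `j`) and `col_perms`
#'   (`col_perms[j, i]` is the source row of slot `(j, i)` after row
#'   shuffling), plus `N` and `k`
#' @export
make_permutation <- function(N, k, seed = NULL) {
  N <- as.integer(N); k <- as.integer(k)
  if (is.na(k) || k < 1L || k >= N) {
    stop("k must satisfy 1 <= k < N", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rp <- t(vapply(seq_len(N), function(j) {
    order(seq_len(N) + stats::runif(N, -k, k))
  }, integer(N)))
  cp <- vapply(seq_len(N), function(i) {
    order(seq_len(N) + stats::runif(N, -k, k))
  }, integer(N)) # cp[j, i] = tau_i(j)
  structure(list(N = N, k = k, row_perms = rp, col_perms = cp),
            class = "region_permutation")
}

#' @rdname make_permutation
#' @export
identity_permutation <- function(N) {
  N <- as.integer(N)
  structure(list(
    N = N, k = 1L,
    row_perms = matrix(seq_len(N), N, N, byrow = TRUE), # sigma_j(i) = i
    col_perms = matrix(seq_len(N), N, N)                # tau_i(j) = j
  ), class = "region_permutation")
}

# Per-slot source region in the original image: slot (j, i) of the shuffled
# grid holds original region (col_perms[j, i], row_perms[col_perms[j, i], i]).
perm_source <- function(perm) {
  N <- perm$N
  src_row <- perm$col_perms
  src_col <- matrix(0L, N, N)
  for (i in seq_len(N)) src_col[, i] <- perm$row_perms[cbind(src_row[, i], i)]
  list(row = src_row, col = src_col)
}

region_side <- function(image, N) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L) {
    stop("image must be a (H,W,C) array", call. = FALSE)
  }
  if (d[1] != d[2] || d[1] %% N != 0L) {
    stop("image side must be square and divisible by N", call. = FALSE)
  }
  d[1] %/% N
}

#' Destroy an image's global structure
#'
#' Rearranges the `N x N` region grid by the stored permutation: row
#' permutations first (columns within each row), then column permutations
#' (rows within each column). The multiset of region pixel blocks is
#' preserved, and [restore_layout()] with the same permutation is an exact
#' inverse. The identity permutation returns the input bit-exactly.
#'
#' @param image a `(H,W,C)` array with side divisible by `perm$N`
#' @param perm a `region_permutation`
#' @return the shuffled image, same shape
#' @export
destroy <- function(image, perm) {
  s <- region_side(image, perm$N)
  src <- perm_source(perm)
  out <- image
  for (j in seq_len(perm$N)) {
    for (i in seq_len(perm$N)) {
      out[(j - 1L) * s + seq_len(s), (i - 1L) * s + seq_len(s), ] <-
        image[(src$row[j, i] - 1L) * s + seq_len(s),
              (src$col[j, i] - 1L) * s + seq_len(s), ]
    }
  }
  out
}

#' @rdname destroy
#' @param shuffled an image produced by [destroy()] with the same `perm`
#' @export
restore_layout <- function(shuffled, perm) {
  s <- region_side(shuffled, perm$N)
  src <- perm_source(perm)
  out <- shuffled
  for (j in seq_len(perm$N)) {
    for (i in seq_len(perm$N)) {
      out[(src$row[j, i] - 1L) * s + seq_len(s),
          (src$col[j, i] - 1L) * s + seq_len(s), ] <-
        shuffled[(j - 1L) * s + seq_len(s), (i - 1L) * s + seq_len(s), ]
    }
  }
  out
}

#' Region-alignment supervision targets
#'
#' For each slot of the shuffled grid, the normalized `(row, col)` grid
#' coordinates of that region in the original image (the default
#' convention), or with `convention = "new"` the inverse mapping: where the
#' region originally at each slot ended up. Coordinates are `(index - 1) /
#' (N - 1)`, so the identity permutation yields each slot's own coordinates.
#'
#' @param perm a `region_permutation`
#' @param convention `"original"` (default) or `"new"`
#' @return an `(N, N, 2)` array; `[j, i, ]` is `(row, col)` in `[0, 1]`
#' @export
alignment_targets <- function(perm, convention = c("original", "new")) {
  convention <- match.arg(convention)
  N <- perm$N
  src <- perm_source(perm)
  if (convention == "new") {
    dst_row <- matrix(0L, N, N); dst_col <- matrix(0L, N, N)
    for (j in seq_len(N)) for (i in seq_len(N)) {
      dst_row[src$row[j, i], src$col[j, i]] <- j
      dst_col[src$row[j, i], src$col[j, i]] <- i
    }
    src <- list(row = dst_row, col = dst_col)
  }
  out <- array(0, c(N, N, 2L))
  out[, , 1L] <- (src$row - 1) / (N - 1)
  out[, , 2L] <- (src$col - 1) / (N - 1)
  out
}

#' Region-alignment loss
#'
#' Mean absolute error over the `2 * N^2` predicted region coordinates; zero
#' if and only if the prediction matches the targets, and symmetric in its
#' arguments.
#'
#' @param predicted_coords,targets arrays of identical shape (normally
#'   `(N, N, 2)`)
#' @return non-negative scalar
#' @export
alignment_loss <- function(predicted_coords, targets) {
  if (!identical(dim_of(predicted_coords), dim_of(targets))) {
    stop("prediction and target shapes differ", call. = FALSE)
  }
  mean(abs(predicted_coords - targets))
}

# flatten alignment targets to the head's output layout (row-coords then
# col-coords, slot index column-major over the N x N grid)
flatten_targets <- function(tg) as.vector(tg)
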