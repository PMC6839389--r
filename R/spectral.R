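# Orthonormal 2-D discrete cosine transform, block partitioning and
# per-block frequency statistics.
#
# The transform of an M x N matrix A is
#   B[p,q] = a_p a_q sum_m sum_n A[m,n] cos(pi (2m+1) p / 2M) cos(pi (2n+1) q / 2N)
# with a_0 = 1/sqrt(M) and a_p = sqrt(2/M) otherwise (type-II DCT with
# orthonormal scaling), i.e. B = C_M A C_N' for the orthonormal DCT matrix
# C. Implemented as two dense matrix products; the basis matrices are cached
# per dimension, so repeated transforms of same-size blocks cost one BLAS
# call each.

.dct_cache <- new.env(parent = emptyenv())

# orthonormal type-II DCT basis matrix: row p, column m (0-based)
.dct_basis <- function(n) {
  key <- as.character(n)
  cached <- .dct_cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- 0:(n - 1L)
  p <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(p, 2 * m + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  .dct_cache[[key]] <- C
  C
}

.as_pixel_matrix <- function(a) {
  if (inherits(a, "bmode_image")) a <- a$pixels
  if (!is.matrix(a) || !is.numeric(a)) {
    sono_stop("sonodct_input_error", "input must be a numeric matrix or bmode_image")
  }
  a
}

#' Construct a spectrum matrix
#'
#' @param coeffs Matrix of DCT coefficients, same shape as the source image.
#' @param dc_removed Logical; `TRUE` if the DC coefficient has been zeroed.
#' @return An object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(coeffs, dc_removed = FALSE) {
  if (!is.matrix(coeffs) || !is.numeric(coeffs)) {
    sono_stop("sonodct_input_error", "`coeffs` must be a numeric matrix")
  }
  if (dc_removed && coeffs[1, 1] != 0) {
    sono_stop("sonodct_input_error", "dc_removed spectrum must have coeffs[1,1] == 0")
  }
  structure(list(coeffs = coeffs, dc_removed = isTRUE(dc_removed)),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d x %d, DC %s\n",
              nrow(x$coeffs), ncol(x$coeffs),
              if (x$dc_removed) "removed" else "present"))
  invisible(x)
}

#' Orthonormal 2-D discrete cosine transform
#'
#' Computes the type-II DCT with orthonormal scaling, so the transform is an
#' isometry: the Frobenius norm of the coefficients equals that of the input
#' (Parseval), and [idct2()] inverts it exactly.
#'
#' @param a Numeric matrix or [bmode_image()].
#' @return A [spectrum_matrix()] of the same shape; `coeffs[1, 1]` is the DC
#'   term (scaled image mean).
#' @export
#' @examples
#' s <- dct2(matrix(1, 2, 2))
#' s$coeffs  # constant image: only the DC term is nonzero
dct2 <- function(a) {
  a <- .as_pixel_matrix(a)
  if (any(!is.finite(a))) {
    sono_stop("sonodct_numeric_error", "input contains non-finite values")
  }
  B <- .dct_basis(nrow(a)) %*% a %*% t(.dct_basis(ncol(a)))
  spectrum_matrix(B, dc_removed = FALSE)
}

#' Inverse orthonormal 2-D DCT
#'
#' @param s A [spectrum_matrix()] or coefficient matrix.
#' @return Numeric matrix reconstructing the source image.
#' @export
idct2 <- function(s) {
  B <- if (inherits(s, "spectrum_matrix")) s$coeffs else s
  if (!is.matrix(B) || !is.numeric(B)) {
    sono_stop("sonodct_input_error", "input must be a spectrum_matrix or numeric matrix")
  }
  t(.dct_basis(nrow(B))) %*% B %*% .dct_basis(ncol(B))
}

#' Remove the DC coefficient from a spectrum
#'
#' Zeroes the (0,0) coefficient so only alternating (non-constant) spectral
#' content remains; all other coefficients are untouched. Idempotent.
#'
#' @param s A [spectrum_matrix()].
#' @return A [spectrum_matrix()] with `dc_removed = TRUE`.
#' @export
remove_dc <- function(s) {
  stopifnot(inherits(s, "spectrum_matrix"))
  coeffs <- s$coeffs
  coeffs[1, 1] <- 0
  spectrum_matrix(coeffs, dc_removed = TRUE)
}

#' Partition an image into non-overlapping square blocks
#'
#' The image is tiled from the origin with `block_size x block_size` tiles;
#' trailing rows/columns that do not fill a complete block are cropped (no
#' padding, which would inject artificial spectral content). The minimum
#' block size is 4 pixels; 32 (default elsewhere) and 16 are the sizes that
#' balance frequency locality against spatial resolution for 1024 x 384
#' sonograms.
#'
#' @param b A [bmode_image()] or numeric matrix.
#' @param block_size Side length of the square blocks in pixels (>= 4).
#' @return An object of class `block_grid`: `blocks` (row-major list of
#'   tiles), `block_size`, `grid_rows`, `grid_cols`, `crop_origin`.
#' @export
partition_blocks <- function(b, block_size) {
  px <- .as_pixel_matrix(b)
  block_size <- as.integer(block_size)
  if (block_size < 4L) {
    sono_stop("sonodct_config_error",
              sprintf("block_size must be >= 4 pixels (got %d)", block_size))
  }
  if (nrow(px) < block_size || ncol(px) < block_size) {
    sono_stop("sonodct_input_error",
              sprintf("image (%d x %d) is smaller than one %d x %d block",
                      nrow(px), ncol(px), block_size, block_size))
  }
  grid_rows <- nrow(px) %/% block_size
  grid_cols <- ncol(px) %/% block_size
  blocks <- vector("list", grid_rows * grid_cols)
  k <- 1L
  for (i in seq_len(grid_rows)) {
    r0 <- (i - 1L) * block_size
    for (j in seq_len(grid_cols)) {
      c0 <- (j - 1L) * block_size
      blocks[[k]] <- px[(r0 + 1L):(r0 + block_size), (c0 + 1L):(c0 + block_size), drop = FALSE]
      k <- k + 1L
    }
  }
  structure(
    list(blocks = blocks, block_size = block_size,
         grid_rows = grid_rows, grid_cols = grid_cols,
         crop_origin = c(0L, 0L)),
    class = "block_grid"
  )
}

#' Reassemble a block grid into the cropped image
#'
#' Inverse of [partition_blocks()] on the retained region.
#'
#' @param grid A `block_grid`.
#' @return Numeric matrix of shape
#'   `(grid_rows * block_size) x (grid_cols * block_size)`.
#' @export
reassemble_blocks <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  bs <- grid$block_size
  out <- matrix(0, grid$grid_rows * bs, grid$grid_cols * bs)
  k <- 1L
  for (i in seq_len(grid$grid_rows)) {
    r0 <- (i - 1L) * bs
    for (j in seq_len(grid$grid_cols)) {
      c0 <- (j - 1L) * bs
      out[(r0 + 1L):(r0 + bs), (c0 + 1L):(c0 + bs)] <- grid$blocks[[k]]
      k <- k + 1L
    }
  }
  out
}

#' Mean absolute DCT coefficient of a block, DC excluded
#'
#' The per-block "mean frequency" statistic used for segmentation: the
#' arithmetic mean of the absolute DCT coefficients over all coefficients
#' except the DC term. Only the transform amplitude matters, and the DC
#' (constant) component carries no textural information, so it is excluded;
#' the statistic is therefore invariant to adding a constant to the tile.
#' Healthy speckled tissue has broadband content and a high statistic;
#' smooth hypoechoic lesions concentrate energy at low frequencies and score
#' low.
#'
#' @param tile Square numeric matrix, side >= 4.
#' @return Nonnegative scalar.
#' @export
block_mean_frequency <- function(tile) {
  tile <- .as_pixel_matrix(tile)
  if (nrow(tile) != ncol(tile) || nrow(tile) < 4L) {
    sono_stop("sonodct_input_error", "tile must be square with side >= 4")
  }
  B <- dct2(tile)$coeffs
  (sum(abs(B)) - abs(B[1, 1])) / (length(B) - 1L)
}
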