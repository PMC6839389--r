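# Whole-image spectral features: singular values of the log-absolute DCT.

#' Construct a feature vector
#'
#' @param values Nonnegative singular values in non-increasing order.
#' @param source_shape Integer vector `c(M, N)` of the source image shape.
#' @return An object of class `feature_vector` with fields `values`,
#'   `length`, `source_shape`.
#' @export
feature_vector <- function(values, source_shape) {
  values <- as.numeric(values)
  if (any(values < 0) || is.unsorted(rev(values))) {
    sono_stop("sonodct_input_error",
              "feature values must be nonnegative and sorted non-increasing")
  }
  source_shape <- as.integer(source_shape)
  if (length(values) != min(source_shape)) {
    sono_stop("sonodct_dimension_error",
              sprintf("economy SVD of a %d x %d image must yield %d values, got %d",
                      source_shape[1], source_shape[2], min(source_shape), length(values)))
  }
  structure(list(values = values, length = length(values),
                 source_shape = source_shape),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> length %d from %d x %d image; sigma_1 = %.4g\n",
              x$length, x$source_shape[1], x$source_shape[2], x$values[1]))
  invisible(x)
}

#' Extract whole-image spectral features
#'
#' Computes `S = svd(log(max(abs(dct2(b)), eps)))`: the 2-D DCT of the whole
#' B-mode image, element-wise absolute value floored at `eps`, natural log,
#' then the economy-size singular values in descending order. All
#' `min(height, width)` values are kept — the discriminating information for
#' sonograms lies in the low-energy tail, so nothing is truncated. For the
#' standard 1024 x 384 sonogram geometry the feature vector has length 384.
#'
#' The floor `eps` bounds the logarithm on exact-zero coefficients (flat
#' regions produce them); at the default `1e-12` the floor contributes about
#' -27.6 without distorting informative coefficients.
#'
#' @param b A [bmode_image()] or numeric matrix.
#' @param eps Positive floor applied to absolute coefficients before the log.
#' @return A [feature_vector()].
#' @export
extract_features <- function(b, eps = 1e-12) {
  px <- .as_pixel_matrix(b)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    sono_stop("sonodct_config_error", "`eps` must be a single positive number")
  }
  if (any(!is.finite(px))) {
    sono_stop("sonodct_numeric_error", "image contains non-finite pixels")
  }
  G <- log(pmax(abs(dct2(px)$coeffs), eps))
  s <- svd(G, nu = 0, nv = 0)$d
  s <- sort(s, decreasing = TRUE)  # contract, not an assumption about svd()
  feature_vector(s, dim(px))
}

#' Per-index location/scale statistics of a feature matrix
#'
#' Computes column means and standard deviations of a training-set feature
#' matrix for use with [normalize_features()]. Each scale is floored at
#' `scale_floor` times the largest column standard deviation: the trailing
#' singular values of sonogram log-spectra are nearly constant across
#' images, and dividing by their (tiny, noise-dominated) spread would
#' amplify pure noise to the same magnitude as the informative leading
#' features. The relative floor keeps flat indices numerically small while
#' leaving informative indices ordinarily z-scored. If every column is
#' constant, all scales fall back to 1.
#'
#' @param x Numeric matrix, one feature vector per row.
#' @param scale_floor Minimum scale as a fraction of the largest column
#'   standard deviation (default 0.05); set 0 for plain per-index z-scoring.
#' @return List with numeric vectors `location` and `scale`.
#' @export
feature_stats <- function(x, scale_floor = 0.05) {
  x <- as.matrix(x)
  location <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale)] <- 0
  floor_val <- scale_floor * max(scale)
  scale <- pmax(scale, floor_val)
  scale[scale == 0] <- 1
  list(location = location, scale = scale)
}

.fv_values <- function(f) {
  if (inherits(f, "feature_vector")) f$values else as.numeric(f)
}

#' Normalize feature vectors with training-set statistics
#'
#' Applies `(value - location) / scale` per index. The statistics must come
#' from the training set (see [feature_stats()]) and are persisted with any
#' trained model so prediction uses the same mapping.
#'
#' @param f A [feature_vector()], numeric vector, or matrix (rows = samples).
#' @param stats List with `location` and `scale` vectors (`scale > 0`).
#' @return Same container type as `f`, normalized.
#' @export
normalize_features <- function(f, stats) {
  .check_stats <- function(d) {
    if (length(stats$location) != d || length(stats$scale) != d) {
      sono_stop("sonodct_dimension_error",
                sprintf("stats length (%d) does not match feature length (%d)",
                        length(stats$location), d))
    }
    if (any(stats$scale <= 0)) {
      sono_stop("sonodct_config_error", "all scale entries must be > 0")
    }
  }
  if (is.matrix(f)) {
    .check_stats(ncol(f))
    return(sweep(sweep(f, 2L, stats$location, "-"), 2L, stats$scale, "/"))
  }
  v <- .fv_values(f)
  .check_stats(length(v))
  (v - stats$location) / stats$scale
}

#' Invert [normalize_features()]
#'
#' @param f Normalized numeric vector or matrix.
#' @param stats The statistics used to normalize.
#' @return De-normalized values, same container type.
#' @export
denormalize_features <- function(f, stats) {
  if (is.matrix(f)) {
    return(sweep(sweep(f, 2L, stats$scale, "*"), 2L, stats$location, "+"))
  }
  as.numeric(f) * stats$scale + stats$location
}

#' Write feature vectors to CSV
#'
#' One image per row, columns `s1..sK` plus an optional `label` column.
#'
#' @param x Matrix of feature vectors (rows = samples) or a single
#'   [feature_vector()].
#' @param path Output CSV path.
#' @param labels Optional character vector of per-row labels.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(x, path, labels = NULL) {
  if (inherits(x, "feature_vector")) x <- matrix(x$values, nrow = 1L)
  x <- as.matrix(x)
  df <- as.data.frame(x)
  names(df) <- paste0("s", seq_len(ncol(x)))
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
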