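# Block-wise semantic segmentation: per-block mean DCT magnitude thresholded
# by Otsu's adaptive method. High mean frequency = healthy speckled tissue;
# low = suspicious (hypoechoic, spectrally concentrated) tissue.

#' Otsu's adaptive threshold for a set of scalars
#'
#' Builds an equal-width histogram over `[min, max]` with `n_bins` bins and
#' returns the interior bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` (equivalently minimizing the combined
#' within-class spread). Values `<= threshold` fall in the lower class.
#' Ties are broken toward the lowest threshold.
#'
#' @param values Numeric vector (length >= 2, finite).
#' @param n_bins Number of histogram bins (>= 2, default 256). Classical Otsu
#'   assumes integer gray levels; for continuous statistics the equal-width
#'   histogram plays that role.
#' @return The threshold as a single numeric (a bin-edge value), with
#'   attributes `between_var` (maximized between-class variance) and
#'   `effectiveness` (between-class variance as a fraction of the total
#'   variance of the binned values; 0..1, higher = more bimodal).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    sono_stop("sonodct_input_error", "need at least 2 values to threshold")
  }
  if (any(!is.finite(values))) {
    sono_stop("sonodct_numeric_error", "values contain non-finite entries")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) {
    sono_stop("sonodct_config_error", "n_bins must be >= 2")
  }
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) {
    sono_stop("sonodct_degenerate_error",
              "all values identical: no threshold separates two classes")
  }
  width <- (hi - lo) / n_bins
  # bin index 1..n_bins; the max value closes the last bin
  bin <- pmin(floor((values - lo) / width) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  p <- counts / length(values)
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  # cumulative weight and mean for every cut after bin k (k = 1..n_bins-1)
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * centers)[-n_bins]
  mu_total <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mu_total * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  k_best <- which.max(between)   # which.max returns the first (lowest) maximum
  total_var <- sum(p * (centers - mu_total)^2)
  structure(
    lo + k_best * width,
    between_var = between[k_best],
    effectiveness = if (total_var > 0) between[k_best] / total_var else 0
  )
}

#' Construct a block map
#'
#' @param labels Character matrix over `{"healthy", "suspicious"}`.
#' @param block_stats Numeric matrix of per-block mean-frequency statistics,
#'   same shape as `labels`.
#' @param threshold Decision threshold: blocks with statistic strictly above
#'   it are healthy (`-Inf` when the image was declared lesion-free).
#' @param block_size Block side in pixels.
#' @param crop_origin Integer `(row, col)` offset of the retained region.
#' @param otsu Otsu diagnostics from [otsu_threshold()] or `NULL`.
#' @param no_lesion_reason `NULL`, `"degenerate"`, or `"low_contrast"`.
#' @return An object of class `block_map`.
#' @export
block_map <- function(labels, block_stats, threshold, block_size,
                      crop_origin = c(0L, 0L), otsu = NULL,
                      no_lesion_reason = NULL) {
  stopifnot(is.matrix(labels), is.matrix(block_stats),
            all(dim(labels) == dim(block_stats)))
  if (!all(labels %in% c("healthy", "suspicious"))) {
    sono_stop("sonodct_input_error", "labels must be 'healthy' or 'suspicious'")
  }
  if (!all((labels == "healthy") == (block_stats > threshold))) {
    sono_stop("sonodct_input_error",
              "label invariant violated: healthy <=> statistic > threshold")
  }
  structure(list(labels = labels, block_stats = block_stats,
                 threshold = threshold, block_size = as.integer(block_size),
                 crop_origin = as.integer(crop_origin), otsu = otsu,
                 no_lesion_reason = no_lesion_reason),
            class = "block_map")
}

#' @export
print.block_map <- function(x, ...) {
  n_susp <- sum(x$labels == "suspicious")
  cat(sprintf("<block_map> %d x %d blocks of %d px, threshold %s, %d suspicious (%.1f%%)%s\n",
              nrow(x$labels), ncol(x$labels), x$block_size,
              if (is.finite(x$threshold)) sprintf("%.4g", x$threshold) else "none",
              n_susp, 100 * n_susp / length(x$labels),
              if (is.null(x$no_lesion_reason)) "" else
                sprintf(" [declared lesion-free: %s]", x$no_lesion_reason)))
  invisible(x)
}

#' Segment a sonogram into healthy and suspicious blocks
#'
#' The image is tiled into `block_size` squares, each block's mean absolute
#' DCT coefficient (DC excluded, [block_mean_frequency()]) is computed, and
#' Otsu's method derives one threshold per image from the distribution of
#' block statistics. Blocks whose mean frequency exceeds the threshold are
#' healthy; the rest are suspicious.
#'
#' Otsu's method always produces a split, even for an image with no lesion,
#' so a hypoechogenicity gate is applied after thresholding: the candidate
#' suspicious class must be markedly darker in the frequency domain, i.e.
#' its mean statistic must fall below `(1 - min_contrast)` times the healthy
#' class mean. If the relative contrast between the two candidate classes is
#' below `min_contrast`, the split is judged spurious and the whole image is
#' labeled healthy (`no_lesion_reason = "low_contrast"`). The gate is
#' scale-invariant, so segmentation commutes with rescaling the image.
#'
#' A constant (degenerate) image yields an all-healthy map with a warning.
#'
#' @param b A [bmode_image()] or numeric matrix, at least one block in each
#'   dimension.
#' @param block_size Block side in pixels (default 32; 16 also works well for
#'   1024 x 384 sonograms).
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @param min_contrast Minimum relative contrast
#'   `(mean_healthy - mean_suspicious) / mean_healthy` required to accept the
#'   Otsu split; in `[0, 1)`, default 0.5.
#' @return A [block_map()].
#' @export
segment <- function(b, block_size = 32L, n_bins = 256L, min_contrast = 0.5) {
  grid <- partition_blocks(b, block_size)
  stats <- matrix(
    vapply(grid$blocks, block_mean_frequency, numeric(1)),
    nrow = grid$grid_rows, ncol = grid$grid_cols, byrow = TRUE
  )
  all_healthy <- function(reason, otsu = NULL) {
    warning(sprintf("image declared lesion-free (%s); all blocks labeled healthy",
                    reason), call. = FALSE)
    block_map(matrix("healthy", nrow(stats), ncol(stats)), stats,
              threshold = -Inf, block_size = grid$block_size,
              crop_origin = grid$crop_origin, otsu = otsu,
              no_lesion_reason = reason)
  }
  ot <- tryCatch(otsu_threshold(as.vector(stats), n_bins = n_bins),
                 sonodct_degenerate_error = function(e) NULL)
  if (is.null(ot)) return(all_healthy("degenerate"))
  thr <- as.numeric(ot)
  susp <- stats <= thr
  mu_s <- mean(stats[susp])
  mu_h <- mean(stats[!susp])
  contrast <- (mu_h - mu_s) / mu_h
  if (!is.finite(contrast) || contrast < min_contrast) {
    return(all_healthy("low_contrast", otsu = ot))
  }
  labels <- matrix(ifelse(susp, "suspicious", "healthy"), nrow(stats), ncol(stats))
  block_map(labels, stats, threshold = thr,
            block_size = grid$block_size, crop_origin = grid$crop_origin,
            otsu = ot)
}

#' Render a block map as an RGB raster
#'
#' Produces the block-level classification image at the resolution of the
#' cropped source: healthy blocks bright, suspicious blocks dark. With
#' `blend > 0` the tone is mixed with the min-max-normalized B-mode image so
#' the underlying anatomy shows through.
#'
#' @param m A [block_map()].
#' @param b The [bmode_image()] (or matrix) the map was derived from.
#' @param blend Fraction of image intensity mixed into the tones, in `[0, 1]`
#'   (default 0: pure two-tone rendering).
#' @param healthy_tone,suspicious_tone Gray levels in `[0, 1]`.
#' @param draw_grid Draw 1-px block boundaries.
#' @return `height x width x 3` RGB array over the cropped region.
#' @export
render_blockmap <- function(m, b, blend = 0, healthy_tone = 0.9,
                            suspicious_tone = 0.15, draw_grid = FALSE) {
  stopifnot(inherits(m, "block_map"))
  px <- .as_pixel_matrix(b)
  bs <- m$block_size
  h <- nrow(m$labels) * bs
  w <- ncol(m$labels) * bs
  if (nrow(px) < h || ncol(px) < w) {
    sono_stop("sonodct_dimension_error",
              "block map does not fit inside the supplied image")
  }
  tone <- matrix(0, h, w)
  for (i in seq_len(nrow(m$labels))) {
    for (j in seq_len(ncol(m$labels))) {
      v <- if (m$labels[i, j] == "healthy") healthy_tone else suspicious_tone
      tone[((i - 1) * bs + 1):(i * bs), ((j - 1) * bs + 1):(j * bs)] <- v
    }
  }
  if (blend > 0) {
    crop <- px[seq_len(h), seq_len(w)]
    rng <- range(crop)
    norm <- if (rng[1] == rng[2]) matrix(0.5, h, w) else (crop - rng[1]) / (rng[2] - rng[1])
    tone <- (1 - blend) * tone + blend * norm
  }
  if (draw_grid) {
    tone[seq(bs, h, by = bs), ] <- 0
    tone[, seq(bs, w, by = bs)] <- 0
  }
  out <- array(0, dim = c(h, w, 3L))
  out[, , 1] <- tone; out[, , 2] <- tone; out[, , 3] <- tone
  out
}

#' Structured per-block report for a block map
#'
#' @param m A [block_map()].
#' @param pixel_spacing_cm Optional `(row, col)` pixel spacing in cm, for
#'   lesion area in cm^2.
#' @return A list: `threshold`, `block_size`, `n_blocks`,
#'   `suspicious_fraction`, `lesion_area_px`, `lesion_area_cm2` (or `NA`),
#'   `no_lesion_reason`, and a `blocks` data frame with grid position, pixel
#'   bounding box in the original image frame (1-based, inclusive),
#'   statistic, and label.
#' @export
blockmap_report <- function(m, pixel_spacing_cm = NULL) {
  stopifnot(inherits(m, "block_map"))
  bs <- m$block_size
  gr <- nrow(m$labels)
  gc <- ncol(m$labels)
  ij <- expand.grid(col = seq_len(gc), row = seq_len(gr))[, c("row", "col")]
  blocks <- data.frame(
    row = ij$row, col = ij$col,
    row0 = m$crop_origin[1] + (ij$row - 1L) * bs + 1L,
    row1 = m$crop_origin[1] + ij$row * bs,
    col0 = m$crop_origin[2] + (ij$col - 1L) * bs + 1L,
    col1 = m$crop_origin[2] + ij$col * bs,
    stat = m$block_stats[cbind(ij$row, ij$col)],
    label = m$labels[cbind(ij$row, ij$col)],
    stringsAsFactors = FALSE
  )
  n_susp <- sum(m$labels == "suspicious")
  area_px <- n_susp * bs^2
  area_cm2 <- if (!is.null(pixel_spacing_cm)) {
    area_px * pixel_spacing_cm[1] * pixel_spacing_cm[2]
  } else {
    NA_real_
  }
  list(
    threshold = m$threshold,
    block_size = bs,
    n_blocks = gr * gc,
    suspicious_fraction = n_susp / (gr * gc),
    lesion_area_px = area_px,
    lesion_area_cm2 = area_cm2,
    no_lesion_reason = m$no_lesion_reason,
    blocks = blocks
  )
}

#' Write a block-map report to JSON (and optionally CSV)
#'
#' @param report Output of [blockmap_report()].
#' @param json_path JSON output path (per-block table included).
#' @param csv_path Optional CSV path for the per-block table alone.
#' @return `json_path`, invisibly.
#' @export
write_blockmap_report <- function(report, json_path, csv_path = NULL) {
  obj <- report
  obj$threshold <- if (is.finite(report$threshold)) report$threshold else NULL
  jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  if (!is.null(csv_path)) utils::write.csv(report$blocks, csv_path, row.names = FALSE)
  invisible(json_path)
}
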