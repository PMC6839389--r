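# Synthetic 50 MHz-style skin sonogram phantoms with ground-truth masks.
#
# The generator emulates the echo statistics the diagnostic method exploits,
# not the acoustic physics: healthy skin layers are bright (hyperechoic) and
# near-homogeneous under multiplicative speckle, while lesions are dark
# (hypoechoic) with smooth low-spatial-frequency internal heterogeneity, so
# their DCT energy concentrates at low frequencies relative to the broadband
# speckle around them.

#' Describe a lesion for a phantom
#'
#' @param shape `"rect"` or `"ellipse"`.
#' @param center `(row, col)` centre in pixels.
#' @param size `(height, width)` in pixels; each >= 4.
#' @param drop Echogenicity drop factor in (0, 1): lesion mean intensity is
#'   `drop` times the surrounding layer mean (strictly hypoechoic).
#' @param heterogeneity Relative amplitude of the smooth intra-lesion
#'   texture (standard deviation as a fraction of the lesion mean).
#' @param smooth_sigma Gaussian smoothing sigma (pixels) of the intra-lesion
#'   texture; keep it at or above half the analysis block size so the lesion
#'   spectrum stays low-frequency (default 16).
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(shape = c("rect", "ellipse"), center, size,
                        drop = 0.35, heterogeneity = 0.2, smooth_sigma = 16) {
  shape <- match.arg(shape)
  size <- as.numeric(size)
  if (any(size < 4)) {
    sono_stop("sonodct_spec_error", "lesion must be at least 4 px in each dimension")
  }
  if (!is.numeric(drop) || drop <= 0 || drop >= 1) {
    sono_stop("sonodct_spec_error", "drop factor must lie strictly in (0, 1)")
  }
  structure(list(shape = shape, center = as.numeric(center), size = size,
                 drop = drop, heterogeneity = heterogeneity,
                 smooth_sigma = smooth_sigma),
            class = "lesion_spec")
}

#' Describe a synthetic sonogram phantom
#'
#' Defaults mirror the standard high-frequency skin sonogram geometry:
#' 1024 (depth) x 384 (lateral) pixels with three tissue layers
#' (epidermis/dermis/hypodermis) of decreasing echogenicity and fully
#' developed multiplicative speckle.
#'
#' @param height,width Image shape in pixels.
#' @param layer_boundaries Depth fractions where the layer changes
#'   (epidermis|dermis, dermis|hypodermis).
#' @param layer_echogenicity Mean intensity per layer (bright healthy skin).
#' @param speckle_shape Gamma shape parameter of the unit-mean multiplicative
#'   speckle; smaller = noisier (default 6, coefficient of variation ~0.41).
#' @param lesions List of [lesion_spec()] objects (possibly empty). Lesions
#'   must lie fully inside the image and must not overlap.
#' @param label Class tag (`"benign"`, `"malignant"`, or `"healthy"`) carried
#'   into classification experiments.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 1024L, width = 384L,
                         layer_boundaries = c(0.10, 0.45),
                         layer_echogenicity = c(190, 165, 140),
                         speckle_shape = 6,
                         lesions = list(),
                         label = "healthy",
                         seed = 1L) {
  if (height < 1L || width < 1L) {
    sono_stop("sonodct_spec_error", "phantom must have positive height and width")
  }
  if (length(layer_echogenicity) != length(layer_boundaries) + 1L) {
    sono_stop("sonodct_spec_error",
              "need one more echogenicity value than layer boundaries")
  }
  for (les in lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    r <- les$center[1] + c(-1, 1) * les$size[1] / 2
    cc <- les$center[2] + c(-1, 1) * les$size[2] / 2
    if (r[1] < 1 || r[2] > height || cc[1] < 1 || cc[2] > width) {
      sono_stop("sonodct_spec_error", "lesion extends outside the image")
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 layer_boundaries = layer_boundaries,
                 layer_echogenicity = layer_echogenicity,
                 speckle_shape = speckle_shape, lesions = lesions,
                 label = label, seed = as.integer(seed)),
            class = "phantom_spec")
}

# binary mask of one lesion on the full image grid
.lesion_mask <- function(les, height, width) {
  r0 <- les$center[1]; c0 <- les$center[2]
  hh <- les$size[1] / 2; hw <- les$size[2] / 2
  rows <- seq_len(height); cols <- seq_len(width)
  if (les$shape == "rect") {
    outer(abs(rows - r0) <= hh, abs(cols - c0) <= hw, "&")
  } else {
    outer(((rows - r0) / hh)^2, ((cols - c0) / hw)^2, "+") <= 1
  }
}

# "same"-size 1-D convolution of each column of A with symmetric kernel g
# (odd length), zero-padded at the boundaries
.conv_cols <- function(A, g) {
  half <- (length(g) - 1L) %/% 2L
  n <- nrow(A)
  P <- rbind(matrix(0, half, ncol(A)), A, matrix(0, half, ncol(A)))
  out <- matrix(0, n, ncol(A))
  for (k in seq_along(g)) {
    out <- out + g[k] * P[(k - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Gaussian-smoothed unit-variance noise field of the given shape; the
# Gaussian is separable, so smoothing is two 1-D passes. Boundary
# attenuation from zero padding is divided out before restandardizing.
.smooth_field <- function(h, w, sigma) {
  sigma <- min(sigma, max(2, min(h, w) / 4))
  half <- min(max(1L, ceiling(2 * sigma)), (min(h, w) - 1L) %/% 2L)
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g <- g / sum(g)
  smooth2 <- function(M) t(.conv_cols(t(.conv_cols(M, g)), g))
  sm <- smooth2(matrix(stats::rnorm(h * w), h, w))
  sm <- sm / smooth2(matrix(1, h, w))
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic sonogram phantom
#'
#' Healthy tissue is per-layer mean intensity times unit-mean gamma speckle;
#' each lesion region is the layer intensity times its drop factor, modulated
#' by a smooth (Gaussian-filtered) heterogeneity field. RF samples are the
#' B-mode intensities halved with random signs, so `rf_to_bmode()` with
#' offset 0 reproduces the constructed B-mode bit-exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_sample` list: `rf` ([rf_image()]), `bmode`
#'   ([bmode_image()]), `mask` (binary matrix, 1 = lesion), `label`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  # overlap check (pairwise, via summed masks)
  masks <- lapply(spec$lesions, .lesion_mask, height = h, width = w)
  mask <- matrix(0L, h, w)
  for (m in masks) mask <- mask + m
  if (any(mask > 1L)) {
    sono_stop("sonodct_spec_error", "lesions overlap")
  }
  mask <- matrix(as.integer(mask > 0L), h, w)

  with_seed(spec$seed, {
    cuts <- c(0, spec$layer_boundaries, 1)
    layer_of_row <- findInterval((seq_len(h) - 0.5) / h, cuts,
                                 rightmost.closed = TRUE)
    base <- matrix(spec$layer_echogenicity[layer_of_row], h, w)
    speckle <- matrix(stats::rgamma(h * w, shape = spec$speckle_shape,
                                    rate = spec$speckle_shape), h, w)
    bmode <- base * speckle
    for (i in seq_along(spec$lesions)) {
      les <- spec$lesions[[i]]
      m <- masks[[i]]
      # smooth texture generated over the lesion bounding box only
      rr <- range(which(rowSums(m) > 0))
      cc <- range(which(colSums(m) > 0))
      fld <- .smooth_field(rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L,
                           les$smooth_sigma)
      full <- matrix(0, h, w)
      full[rr[1]:rr[2], cc[1]:cc[2]] <- fld
      lesion_int <- base * les$drop * pmax(1 + les$heterogeneity * full, 0.05)
      bmode[m == 1L] <- lesion_int[m == 1L]
    }
    bmode <- pmax(bmode, 0)
    signs <- matrix(sample(c(-1, 1), h * w, replace = TRUE), h, w)
    rf <- rf_image(signs * bmode / 2, offset = 0L, transducer_freq = 50)
    structure(list(rf = rf, bmode = rf_to_bmode(rf), mask = mask,
                   label = spec$label, spec = spec),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d, label '%s', %d lesion(s), %.1f%% lesion pixels\n",
              x$bmode$height, x$bmode$width, x$label,
              length(x$spec$lesions), 100 * mean(x$mask)))
  invisible(x)
}

#' Block-level ground truth induced by a pixel mask
#'
#' A block is a lesion block when at least half of its pixels are lesion
#' (majority rule). Trailing partial blocks are cropped, matching
#' [partition_blocks()].
#'
#' @param mask Binary pixel matrix (1 = lesion).
#' @param block_size Block side in pixels.
#' @return Logical `grid_rows x grid_cols` matrix, `TRUE` = lesion block.
#' @export
block_mask <- function(mask, block_size) {
  grid <- partition_blocks(mask, block_size)
  frac <- vapply(grid$blocks, mean, numeric(1))
  matrix(frac >= 0.5, nrow = grid$grid_rows, ncol = grid$grid_cols, byrow = TRUE)
}

#' Phantom with one rectangular lesion aligned to the analysis grid
#'
#' Convenience constructor for segmentation validation: places a single
#' rectangular hypoechoic lesion whose edges coincide with block boundaries,
#' so the induced block-level ground truth is unambiguous. The lesion's
#' block-footprint (rows x cols) is drawn uniformly so the total block count
#' falls within `n_blocks_range`, positioned uniformly at a block-aligned
#' offset below the epidermis.
#'
#' @param seed Integer seed (drives geometry and texture).
#' @param n_blocks_range Inclusive range for the number of lesion blocks.
#' @param block_size Analysis block size in pixels.
#' @param height,width Image shape.
#' @param drop,heterogeneity,smooth_sigma Lesion parameters, see
#'   [lesion_spec()].
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A `phantom_sample` (see [generate_phantom()]).
#' @export
phantom_with_block_lesion <- function(seed, n_blocks_range = c(6L, 20L),
                                      block_size = 32L,
                                      height = 1024L, width = 384L,
                                      drop = 0.35, heterogeneity = 0.2,
                                      smooth_sigma = 16, ...) {
  grid_rows <- height %/% block_size
  grid_cols <- width %/% block_size
  geom <- with_seed(seed, {
    # enumerate feasible (rows x cols) footprints, pick one uniformly
    combos <- expand.grid(r = 1:min(6L, grid_rows), c = 1:min(6L, grid_cols))
    combos <- combos[combos$r * combos$c >= n_blocks_range[1] &
                     combos$r * combos$c <= n_blocks_range[2], ]
    pick <- combos[sample(nrow(combos), 1L), ]
    # keep the lesion out of the top (epidermis) block row
    r_off <- sample(1L:(grid_rows - pick$r - 1L), 1L)
    c_off <- sample(0L:(grid_cols - pick$c), 1L)
    list(r = pick$r, c = pick$c, r_off = r_off, c_off = c_off)
  })
  size <- c(geom$r, geom$c) * block_size
  center <- c(geom$r_off * block_size + size[1] / 2 + 0.5,
              geom$c_off * block_size + size[2] / 2 + 0.5)
  les <- lesion_spec("rect", center = center, size = size - 1L, drop = drop,
                     heterogeneity = heterogeneity, smooth_sigma = smooth_sigma)
  generate_phantom(phantom_spec(height = height, width = width,
                                lesions = list(les), label = "malignant",
                                seed = seed, ...))
}

# default class templates: benign lesions are smaller, with a milder
# echogenicity drop and more homogeneous interior; malignant lesions are
# larger, darker and more heterogeneous
.default_templates <- function() {
  list(
    benign = list(shape = "ellipse", size_range = c(40, 72),
                  drop_range = c(0.65, 0.80), het_range = c(0.01, 0.05),
                  smooth_sigma = 16),
    malignant = list(shape = "rect", size_range = c(144, 224),
                     drop_range = c(0.15, 0.25), het_range = c(0.30, 0.40),
                     smooth_sigma = 16)
  )
}

#' Generate a labeled phantom dataset with extracted features
#'
#' Draws `n_per_class` benign and `n_per_class` malignant phantoms. Per-class
#' templates control the lesion geometry distributions; per-sample lesion
#' size, position, drop factor and heterogeneity are sampled within the
#' template ranges, and the layer structure is jittered slightly between
#' samples so no single constant separates the classes trivially. Per-sample
#' seeds are derived reproducibly from `seed`.
#'
#' @param n_per_class Samples per class (>= 1).
#' @param seed Master integer seed.
#' @param height,width Image shape.
#' @param templates Named list with `benign` and `malignant` template lists
#'   (fields `shape`, `size_range`, `drop_range`, `het_range`,
#'   `smooth_sigma`); defaults as above.
#' @param eps Log floor for [extract_features()].
#' @param keep_samples Keep the phantom images in the result (set `FALSE` to
#'   save memory when only features are needed).
#' @return List with `samples` (phantom list or `NULL`), `dataset`
#'   ([labeled_dataset()] of feature vectors), and `manifest` (data frame:
#'   id, label, seed, lesion geometry).
#' @export
generate_dataset <- function(n_per_class, seed = 1L,
                             height = 1024L, width = 384L,
                             templates = .default_templates(),
                             eps = 1e-12, keep_samples = TRUE) {
  if (n_per_class < 1L) {
    sono_stop("sonodct_spec_error", "n_per_class must be >= 1")
  }
  n <- 2L * n_per_class
  draw <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n),
         params = replicate(n, stats::runif(8), simplify = FALSE))
  })
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  samples <- vector("list", n)
  feats <- matrix(0, n, min(height, width))
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- templates[[labels[i]]]
    u <- draw$params[[i]]
    size <- c(tpl$size_range[1] + u[1] * diff(tpl$size_range),
              tpl$size_range[1] + u[2] * diff(tpl$size_range))
    drop <- tpl$drop_range[1] + u[3] * diff(tpl$drop_range)
    het <- tpl$het_range[1] + u[4] * diff(tpl$het_range)
    # position anywhere below the epidermis with a margin
    top <- 0.12 * height
    center <- c(top + size[1] / 2 + u[5] * (height - top - size[1] - 2) + 1,
                size[2] / 2 + u[6] * (width - size[2] - 2) + 1)
    les <- lesion_spec(tpl$shape, center = center, size = size, drop = drop,
                       heterogeneity = het, smooth_sigma = tpl$smooth_sigma)
    spec <- phantom_spec(
      height = height, width = width,
      layer_echogenicity = c(190, 165, 140) * (0.98 + 0.04 * u[7]),
      layer_boundaries = c(0.10, 0.45) + (u[8] - 0.5) * 0.04,
      lesions = list(les), label = labels[i], seed = draw$seeds[i]
    )
    ph <- generate_phantom(spec)
    feats[i, ] <- extract_features(ph$bmode, eps = eps)$values
    manifest[[i]] <- data.frame(
      id = sprintf("%s_%03d", labels[i], i), label = labels[i],
      seed = draw$seeds[i], shape = tpl$shape,
      lesion_h = size[1], lesion_w = size[2],
      center_row = center[1], center_col = center[2],
      drop = drop, heterogeneity = het, stringsAsFactors = FALSE
    )
    if (keep_samples) samples[[i]] <- ph
  }
  list(
    samples = if (keep_samples) samples else NULL,
    dataset = labeled_dataset(feats, labels,
                              class_names = c("benign", "malignant")),
    manifest = do.call(rbind, manifest)
  )
}

#' Write a phantom set to a directory
#'
#' For each sample: RF flat binary plus YAML sidecar, 16-bit B-mode TIFF
#' (raw intensities exceed the 8-bit range), binary mask PNG, and one
#' manifest CSV listing paths, labels, seeds and lesion geometry.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_class Samples per class.
#' @param seed Master seed.
#' @param ... Passed to [generate_dataset()].
#' @return Path to the manifest CSV, invisibly.
#' @export
write_phantom_set <- function(out_dir, n_per_class, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_dataset(n_per_class, seed = seed, keep_samples = TRUE, ...)
  man <- gen$manifest
  man$rf_path <- file.path(out_dir, paste0(man$id, ".rf"))
  man$bmode_path <- file.path(out_dir, paste0(man$id, "_bmode.tif"))
  man$mask_path <- file.path(out_dir, paste0(man$id, "_mask.png"))
  for (i in seq_len(nrow(man))) {
    s <- gen$samples[[i]]
    write_rf(s$rf, man$rf_path[i])
    save_bmode(s$bmode, man$bmode_path[i], bits = 16)
    png::writePNG(s$mask + 0, man$mask_path[i])  # writePNG needs doubles
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
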