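# RF and B-mode image containers and file I/O.
#
# Conventions: matrices are indexed [row, col] with rows = depth along the
# ultrasound beam and columns = lateral transducer travel. Shapes are always
# reported as (height = depth, width = lateral).

#' Construct an RF image
#'
#' An RF (radio-frequency) image holds the raw signed echo samples recorded
#' by the scanner before any display processing, together with the
#' acquisition metadata needed for B-mode conversion.
#'
#' @param samples Numeric matrix of signed scan values (rows = depth,
#'   columns = lateral position).
#' @param offset Integer device offset subtracted during B-mode conversion;
#'   scanners add it so recorded values can be stored unsigned. Default 0.
#' @param transducer_freq Transducer centre frequency in MHz, or `NULL` if
#'   unknown. Must be positive when given (50 for the high-frequency skin
#'   probes this package targets).
#' @return An object of class `rf_image` with fields `samples`, `height`,
#'   `width`, `offset`, `transducer_freq`.
#' @export
#' @examples
#' rf <- rf_image(matrix(c(-5, 3, 0, 2), 2, 2), offset = 0)
#' rf_to_bmode(rf)$pixels
rf_image <- function(samples, offset = 0L, transducer_freq = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    sono_stop("sonodct_input_error", "`samples` must be a numeric matrix")
  }
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    sono_stop("sonodct_input_error", "RF image must have height >= 1 and width >= 1")
  }
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset)) {
    sono_stop("sonodct_metadata_error", "`offset` must be a single finite number")
  }
  if (!is.null(transducer_freq)) {
    if (!is.numeric(transducer_freq) || length(transducer_freq) != 1L ||
        !is.finite(transducer_freq) || transducer_freq <= 0) {
      sono_stop("sonodct_metadata_error", "`transducer_freq` must be > 0 (MHz)")
    }
  }
  structure(
    list(
      samples = samples,
      height = nrow(samples),
      width = ncol(samples),
      offset = as.numeric(offset),
      transducer_freq = transducer_freq
    ),
    class = "rf_image"
  )
}

#' @export
print.rf_image <- function(x, ...) {
  cat(sprintf(
    "<rf_image> %d x %d (depth x lateral), offset = %g%s\n",
    x$height, x$width, x$offset,
    if (is.null(x$transducer_freq)) "" else sprintf(", %g MHz", x$transducer_freq)
  ))
  invisible(x)
}

#' Construct a B-mode image
#'
#' @param pixels Numeric intensity matrix (rows = depth). Negative values are
#'   permitted: B-mode conversion with a positive device offset can produce
#'   them and they are preserved for exact downstream spectral analysis;
#'   clipping happens only at render time.
#' @param source_meta Optional list of acquisition metadata (e.g. `offset`,
#'   `transducer_freq`, `pixel_spacing_cm`) carried along from the RF source.
#' @return An object of class `bmode_image` with fields `pixels`, `height`,
#'   `width`, `source_meta`.
#' @export
bmode_image <- function(pixels, source_meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    sono_stop("sonodct_input_error", "`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    sono_stop("sonodct_input_error", "B-mode image must have height >= 1 and width >= 1")
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      source_meta = source_meta
    ),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf(
    "<bmode_image> %d x %d (depth x lateral), intensity range [%g, %g]\n",
    x$height, x$width, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Convert an RF image to B-mode
#'
#' Applies the rectification rule `imgB = 2 * abs(imgRF) - offset` pixel by
#' pixel. No envelope detection, beamforming or gain compensation is
#' performed; the conversion is exactly this algebraic rule. Negative output
#' pixels (possible when `offset > 0`) are preserved.
#'
#' @param rf An [rf_image()].
#' @return A [bmode_image()] of the same shape.
#' @export
rf_to_bmode <- function(rf) {
  stopifnot(inherits(rf, "rf_image"))
  bmode_image(
    2 * abs(rf$samples) - rf$offset,
    source_meta = list(offset = rf$offset, transducer_freq = rf$transducer_freq)
  )
}

# supported raw sample types: readBin/writeBin parameters per dtype name
.rf_dtypes <- list(
  int8    = list(what = "integer", size = 1L, signed = TRUE),
  uint8   = list(what = "integer", size = 1L, signed = FALSE),
  int16   = list(what = "integer", size = 2L, signed = TRUE),
  uint16  = list(what = "integer", size = 2L, signed = FALSE),
  int32   = list(what = "integer", size = 4L, signed = TRUE),
  float32 = list(what = "numeric", size = 4L, signed = TRUE),
  float64 = list(what = "numeric", size = 8L, signed = TRUE)
)

.read_sidecar <- function(meta) {
  if (is.character(meta) && length(meta) == 1L) {
    if (!file.exists(meta)) {
      sono_stop("sonodct_metadata_error", sprintf("sidecar metadata file not found: %s", meta))
    }
    meta <- yaml::read_yaml(meta)
  }
  if (!is.list(meta)) {
    sono_stop("sonodct_metadata_error", "`meta` must be a list or a path to a YAML sidecar file")
  }
  required <- c("height", "width", "dtype")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    sono_stop(
      "sonodct_metadata_error",
      sprintf("sidecar metadata is missing required field(s): %s", paste(missing, collapse = ", "))
    )
  }
  if (!meta$dtype %in% names(.rf_dtypes)) {
    sono_stop(
      "sonodct_metadata_error",
      sprintf(
        "unsupported dtype '%s' (supported: %s)",
        meta$dtype, paste(names(.rf_dtypes), collapse = ", ")
      )
    )
  }
  meta$endian <- meta$endian %||% "little"
  if (!meta$endian %in% c("little", "big")) {
    sono_stop("sonodct_metadata_error", "endian must be 'little' or 'big'")
  }
  meta$offset <- meta$offset %||% 0
  meta$transducer_freq <- meta$transducer_freq %||% NULL
  meta
}

#' Read a raw RF scan from a flat binary file
#'
#' The scanner file format is an open convention: a flat binary array of
#' samples in row-major order (depth rows, lateral columns) plus a sidecar
#' metadata record declaring the geometry. The sidecar is a YAML file (or an
#' equivalent in-memory list) with fields:
#' \describe{
#'   \item{height, width}{image shape in pixels (required)}
#'   \item{dtype}{one of `int8`, `uint8`, `int16`, `uint16`, `int32`,
#'     `float32`, `float64` (required)}
#'   \item{endian}{`little` (default) or `big`}
#'   \item{offset}{device intensity offset, default 0}
#'   \item{transducer_freq}{probe frequency in MHz, optional}
#' }
#'
#' @param path Path to the raw binary file.
#' @param meta Sidecar metadata: a list, a path to a YAML file, or `NULL` to
#'   use `<path>.yml`.
#' @return An [rf_image()].
#' @export
read_rf <- function(path, meta = NULL) {
  if (!file.exists(path)) {
    sono_stop("sonodct_io_error", sprintf("RF file not found: %s", path))
  }
  meta <- .read_sidecar(meta %||% paste0(path, ".yml"))
  dt <- .rf_dtypes[[meta$dtype]]
  n <- as.integer(meta$height) * as.integer(meta$width)
  expected_bytes <- n * dt$size
  actual_bytes <- file.size(path)
  if (actual_bytes != expected_bytes) {
    sono_stop(
      "sonodct_format_error",
      sprintf(
        "RF file size mismatch for %s: expected %d bytes (%d x %d %s), found %d bytes",
        path, expected_bytes, meta$height, meta$width, meta$dtype, actual_bytes
      )
    )
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = meta$endian)
  samples <- matrix(as.numeric(vals), nrow = meta$height, ncol = meta$width, byrow = TRUE)
  rf_image(samples, offset = meta$offset, transducer_freq = meta$transducer_freq)
}

#' Write an RF image as flat binary plus YAML sidecar
#'
#' @param rf An [rf_image()].
#' @param path Output path for the binary payload; the sidecar is written to
#'   `<path>.yml`.
#' @param dtype Sample type to encode (see [read_rf()]); default `float64`
#'   round-trips any numeric matrix exactly.
#' @param endian Byte order, `little` (default) or `big`.
#' @return `path`, invisibly.
#' @export
write_rf <- function(rf, path, dtype = "float64", endian = "little") {
  stopifnot(inherits(rf, "rf_image"))
  if (!dtype %in% names(.rf_dtypes)) {
    sono_stop("sonodct_metadata_error", sprintf("unsupported dtype '%s'", dtype))
  }
  dt <- .rf_dtypes[[dtype]]
  vals <- as.vector(t(rf$samples))  # row-major
  if (dt$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = dt$size, endian = endian)
  meta <- list(
    height = rf$height, width = rf$width, dtype = dtype, endian = endian,
    offset = rf$offset
  )
  if (!is.null(rf$transducer_freq)) meta$transducer_freq <- rf$transducer_freq
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Load a B-mode image from a grayscale raster file (PNG or TIFF)
#'
#' Multi-channel images are collapsed to single-channel luminance using
#' Rec. 709 weights. Intensities are returned on the file's native integer
#' scale (0..255 for 8-bit, 0..65535 for 16-bit).
#'
#' @param path Path to a PNG or TIFF file.
#' @return A [bmode_image()].
#' @export
load_bmode <- function(path) {
  if (!file.exists(path)) {
    sono_stop("sonodct_io_error", sprintf("image file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path, info = TRUE),
      tif = ,
      tiff = tiff::readTIFF(path, info = TRUE),
      sono_stop("sonodct_io_error", sprintf("unsupported image extension '%s' (use PNG or TIFF)", ext))
    ),
    error = function(e) {
      if (inherits(e, "sonodct_error")) stop(e)
      sono_stop("sonodct_io_error", sprintf("failed to read %s: %s", path, conditionMessage(e)))
    }
  )
  # png attaches an "info" list; tiff attaches attributes directly
  info <- attr(img, "info")
  bits <- info$bit.depth %||% attr(img, "bits.per.sample") %||%
    info$bits.per.sample %||% 8
  scale <- 2^bits - 1
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    # Rec. 709 luminance for RGB(A); alpha ignored
    if (nch >= 3L) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  # drop reader-specific attributes so pixels are a plain numeric matrix
  px <- matrix(as.numeric(img) * scale, nrow(img), ncol(img))
  bmode_image(px, source_meta = list(path = path, bit_depth = bits))
}

#' Save a B-mode image as a grayscale raster file
#'
#' Pixels are clipped to `[0, 2^bits - 1]` and encoded at the requested bit
#' depth; values already on that integer scale round-trip exactly through
#' [load_bmode()]. PNG output is 8-bit (the limit of the PNG writer); 16-bit
#' output — needed for raw B-mode intensities, which routinely exceed 255 —
#' uses TIFF, so `bits = 16` requires a `.tif`/`.tiff` path.
#'
#' @param b A [bmode_image()].
#' @param path Output path: `.png` for 8-bit, `.tif`/`.tiff` for 8 or 16 bit.
#' @param bits Bit depth, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
save_bmode <- function(b, path, bits = 8) {
  stopifnot(inherits(b, "bmode_image"), bits %in% c(8, 16))
  ext <- tolower(tools::file_ext(path))
  scale <- 2^bits - 1
  px <- pmin(pmax(b$pixels, 0), scale) / scale
  if (ext == "png") {
    if (bits != 8) {
      sono_stop("sonodct_config_error",
                "PNG output is 8-bit only; use a .tif path for bits = 16")
    }
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = bits)
  } else {
    sono_stop("sonodct_io_error",
              sprintf("unsupported output extension '%s' (use PNG or TIFF)", ext))
  }
  invisible(path)
}

#' Render a B-mode image through a colormap
#'
#' Intensities are min-max normalized and mapped through the named colour
#' scheme; a constant image maps everywhere to the scale midpoint. The
#' mapping is monotone in intensity for monotone schemes such as `"gray"`.
#'
#' @param b A [bmode_image()].
#' @param scheme Colormap name: `"gray"` or any palette known to
#'   [grDevices::hcl.colors()] (e.g. `"viridis"`, `"inferno"`).
#' @param n Number of colour steps in the ramp (default 256).
#' @return An `height x width x 3` numeric array of RGB values in `[0, 1]`.
#' @export
render_colormap <- function(b, scheme = "gray", n = 256L) {
  stopifnot(inherits(b, "bmode_image"))
  pals <- grDevices::hcl.pals()
  hit <- pals[tolower(pals) == tolower(scheme)]   # hcl.pals() names are capitalized
  pal <- if (identical(scheme, "gray")) {
    grDevices::gray(seq(0, 1, length.out = n))
  } else if (length(hit) == 1L) {
    grDevices::hcl.colors(n, palette = hit)
  } else {
    sono_stop(
      "sonodct_config_error",
      sprintf("unknown colormap scheme '%s' (use 'gray' or a grDevices::hcl.pals() name)", scheme)
    )
  }
  rng <- range(b$pixels)
  norm <- if (rng[1] == rng[2]) {
    matrix(0.5, b$height, b$width)
  } else {
    (b$pixels - rng[1]) / (rng[2] - rng[1])
  }
  ramp <- grDevices::colorRamp(pal)
  rgb <- ramp(as.vector(norm)) / 255
  out <- array(0, dim = c(b$height, b$width, 3L))
  out[, , 1] <- rgb[, 1]
  out[, , 2] <- rgb[, 2]
  out[, , 3] <- rgb[, 3]
  out
}
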