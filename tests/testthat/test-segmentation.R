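# Otsu thresholding and block-wise segmentation.

test_that("otsu_threshold matches exhaustive between-class-variance search", {
  set.seed(61)
  cases <- list(
    c(rnorm(200, 0, 1), rnorm(200, 8, 1)),        # clean bimodal
    c(rnorm(300, 0, 2), rnorm(100, 5, 0.5)),      # unbalanced bimodal
    runif(250),                                   # uniform
    rlnorm(300),                                  # skewed
    1 + rnorm(100, sd = 1e-8)                     # near-degenerate
  )
  for (v in cases) {
    got <- otsu_threshold(v)
    ref <- otsu_exhaustive(v)
    expect_equal(as.numeric(got), ref$threshold, tolerance = 1e-9 * diff(range(v)))
    # tiny between-variances (near-degenerate inputs) cancel catastrophically
    # on the two computation routes, so the relative tolerance is looser there
    expect_equal(attr(got, "between_var"), ref$between_var,
                 tolerance = 1e-6)
  }
})

test_that("otsu_threshold is affine-equivariant", {
  set.seed(62)
  v <- c(rnorm(150, 0), rnorm(150, 6))
  t0 <- as.numeric(otsu_threshold(v))
  t1 <- as.numeric(otsu_threshold(3.5 * v + 11))
  expect_equal(t1, 3.5 * t0 + 11, tolerance = 1e-9)
})

test_that("otsu_threshold reports effectiveness and rejects bad input", {
  v <- c(rep(0, 50), rep(10, 50))
  got <- otsu_threshold(v)
  expect_gt(attr(got, "effectiveness"), 0.95)   # strongly bimodal
  expect_error(otsu_threshold(rep(1, 10)), class = "sonodct_degenerate_error")
  expect_error(otsu_threshold(3), class = "sonodct_input_error")
  expect_error(otsu_threshold(c(1, NA, 2)), class = "sonodct_numeric_error")
  expect_error(otsu_threshold(1:10, n_bins = 1L), class = "sonodct_config_error")
})

test_that("block_map enforces healthy <=> statistic > threshold", {
  stats <- matrix(c(1, 2, 3, 4), 2, 2)
  good <- matrix(c("suspicious", "suspicious", "healthy", "healthy"), 2, 2)
  m <- block_map(good, stats, threshold = 2.5, block_size = 4L)
  expect_s3_class(m, "block_map")
  bad <- matrix("healthy", 2, 2)
  expect_error(block_map(bad, stats, threshold = 2.5, block_size = 4L),
               class = "sonodct_input_error")
  expect_error(block_map(matrix("x", 2, 2), stats, 2.5, 4L),
               class = "sonodct_input_error")
})

test_that("segment recovers a block-aligned lesion exactly", {
  ph <- phantom_with_block_lesion(seed = 424, height = 512, width = 256,
                                  block_size = 32L, n_blocks_range = c(6L, 20L))
  m <- segment(ph$bmode, block_size = 32L)
  truth <- block_mask(ph$mask, 32L)
  pred <- m$labels == "suspicious"
  expect_equal(dim(pred), dim(truth))
  expect_gte(block_iou(pred, truth), 0.8)
  expect_true(is.finite(m$threshold))
  # lesion blocks score below healthy blocks in mean frequency
  expect_lt(mean(m$block_stats[truth]), mean(m$block_stats[!truth]))
})

test_that("a lesion-free phantom is declared healthy by the contrast gate", {
  ph <- generate_phantom(phantom_spec(height = 512, width = 256, seed = 77))
  expect_warning(m <- segment(ph$bmode, block_size = 32L),
                 "lesion-free")
  expect_true(all(m$labels == "healthy"))
  expect_identical(m$no_lesion_reason, "low_contrast")
  expect_identical(m$threshold, -Inf)
})

test_that("a constant image is handled as degenerate", {
  expect_warning(m <- segment(matrix(5, 64, 64), block_size = 32L),
                 "lesion-free")
  expect_identical(m$no_lesion_reason, "degenerate")
  expect_true(all(m$labels == "healthy"))
})

test_that("render_blockmap paints two tones at the cropped resolution", {
  stats <- matrix(c(1, 10), 1, 2)
  labels <- matrix(c("suspicious", "healthy"), 1, 2)
  m <- block_map(labels, stats, threshold = 5, block_size = 4L)
  img <- matrix(0, 5, 9)                  # crops to 4 x 8
  arr <- render_blockmap(m, img, healthy_tone = 0.9, suspicious_tone = 0.15)
  expect_equal(dim(arr), c(4L, 8L, 3L))
  expect_true(all(arr[1:4, 1:4, ] == 0.15))
  expect_true(all(arr[1:4, 5:8, ] == 0.9))
  expect_error(render_blockmap(m, matrix(0, 2, 2)),
               class = "sonodct_dimension_error")
})

test_that("blockmap_report tabulates blocks, areas, and bounding boxes", {
  stats <- matrix(c(1, 10, 10, 10), 2, 2)
  labels <- ifelse(stats > 5, "healthy", "suspicious")
  m <- block_map(labels, stats, threshold = 5, block_size = 4L)
  rep <- blockmap_report(m, pixel_spacing_cm = c(0.01, 0.02))
  expect_equal(rep$n_blocks, 4L)
  expect_equal(rep$suspicious_fraction, 0.25)
  expect_equal(rep$lesion_area_px, 16)
  expect_equal(rep$lesion_area_cm2, 16 * 0.01 * 0.02)
  b1 <- rep$blocks[rep$blocks$row == 1 & rep$blocks$col == 1, ]
  expect_equal(c(b1$row0, b1$row1, b1$col0, b1$col1), c(1, 4, 1, 4))
  expect_equal(b1$label, "suspicious")

  p <- tempfile(fileext = ".json")
  write_blockmap_report(rep, p, csv_path = tempfile(fileext = ".csv"))
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$threshold, 5)
  expect_equal(back$suspicious_fraction, 0.25)
  expect_equal(nrow(back$blocks), 4)
})
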