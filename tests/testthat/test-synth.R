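# Synthetic phantom generator and dataset machinery.

test_that("generate_phantom is deterministic and internally consistent", {
  spec <- phantom_spec(height = 128, width = 96, seed = 9,
                       lesions = list(lesion_spec("ellipse", center = c(80, 48),
                                                  size = c(30, 24), drop = 0.3)))
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$bmode$pixels, p2$bmode$pixels)
  expect_identical(p1$rf$samples, p2$rf$samples)

  # RF -> B-mode round trip is bit-exact at offset 0
  expect_identical(rf_to_bmode(p1$rf)$pixels, p1$bmode$pixels)
  expect_identical(p1$rf$offset, 0)
  expect_true(all(p1$bmode$pixels >= 0))
  expect_equal(dim(p1$mask), c(128L, 96L))
})

test_that("lesions are hypoechoic relative to their surroundings", {
  spec <- phantom_spec(height = 256, width = 128, seed = 10,
                       lesions = list(lesion_spec("rect", center = c(160, 64),
                                                  size = c(60, 60), drop = 0.25)))
  p <- generate_phantom(spec)
  inside <- mean(p$bmode$pixels[p$mask == 1])
  outside <- mean(p$bmode$pixels[p$mask == 0])
  expect_lt(inside, 0.5 * outside)
  # lesion pixel fraction matches the requested rectangle
  expect_equal(sum(p$mask), 61 * 61)     # inclusive half-width bounds
})

test_that("phantom speckle is multiplicative with the requested layer means", {
  spec <- phantom_spec(height = 300, width = 100, seed = 11,
                       layer_boundaries = c(1 / 3, 2 / 3),
                       layer_echogenicity = c(200, 100, 50))
  p <- generate_phantom(spec)
  expect_equal(mean(p$bmode$pixels[1:100, ]), 200, tolerance = 200 * 0.02)
  expect_equal(mean(p$bmode$pixels[101:200, ]), 100, tolerance = 100 * 0.02)
  expect_equal(mean(p$bmode$pixels[201:300, ]), 50, tolerance = 50 * 0.02)
})

test_that("spec validation rejects impossible phantoms", {
  expect_error(lesion_spec("rect", c(10, 10), size = c(2, 8)),
               class = "sonodct_spec_error")
  expect_error(lesion_spec("rect", c(10, 10), size = c(8, 8), drop = 1.2),
               class = "sonodct_spec_error")
  expect_error(
    phantom_spec(height = 64, width = 64,
                 lesions = list(lesion_spec("rect", c(60, 32), c(20, 10)))),
    class = "sonodct_spec_error"
  )
  overlapping <- list(lesion_spec("rect", c(50, 50), c(20, 20)),
                      lesion_spec("rect", c(55, 55), c(20, 20)))
  expect_error(generate_phantom(phantom_spec(height = 128, width = 128,
                                             lesions = overlapping)),
               class = "sonodct_spec_error")
  expect_error(phantom_spec(layer_boundaries = c(0.5),
                            layer_echogenicity = c(1, 2, 3)),
               class = "sonodct_spec_error")
})

test_that("block_mask applies the majority (>= 50%) rule", {
  mask <- matrix(0L, 8, 8)
  mask[1:4, 1:2] <- 1L                    # 8 of 16 pixels in block (1,1)
  mask[5:8, 5:5] <- 1L                    # 4 of 16 pixels in block (2,2)
  bm <- block_mask(mask, 4L)
  expect_identical(bm, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
})

test_that("phantom_with_block_lesion aligns the lesion to the block grid", {
  for (seed in c(3, 14)) {
    ph <- phantom_with_block_lesion(seed = seed, height = 512, width = 256,
                                    block_size = 32L, n_blocks_range = c(6L, 20L))
    truth <- block_mask(ph$mask, 32L)
    n_blocks <- sum(truth)
    expect_gte(n_blocks, 6L)
    expect_lte(n_blocks, 20L)
    # every truth block is fully covered: block pixel fractions are 0 or ~1
    grid <- partition_blocks(ph$mask, 32L)
    frac <- vapply(grid$blocks, mean, numeric(1))
    expect_true(all(frac < 0.05 | frac > 0.9))
  }
})

test_that("generate_dataset builds a reproducible labeled feature set", {
  g1 <- generate_dataset(3, seed = 8, height = 128, width = 96,
                         templates = small_templates(), keep_samples = FALSE)
  g2 <- generate_dataset(3, seed = 8, height = 128, width = 96,
                         templates = small_templates(), keep_samples = FALSE)
  expect_identical(g1$dataset$features, g2$dataset$features)
  expect_null(g1$samples)
  expect_equal(dim(g1$dataset$features), c(6L, 96L))
  expect_identical(g1$dataset$class_names, c("benign", "malignant"))
  expect_equal(nrow(g1$manifest), 6L)
  expect_equal(g1$manifest$label, rep(c("benign", "malignant"), each = 3))
  expect_true(all(g1$manifest$seed > 0 & g1$manifest$seed < 2^31))

  g3 <- generate_dataset(3, seed = 9, height = 128, width = 96,
                         templates = small_templates(), keep_samples = FALSE)
  expect_false(identical(g1$dataset$features, g3$dataset$features))
  expect_error(generate_dataset(0), class = "sonodct_spec_error")
})

test_that("write_phantom_set writes files that round-trip through the readers", {
  out <- file.path(tempdir(), "phantoms-test")
  manifest_path <- write_phantom_set(out, 1, seed = 15, height = 128, width = 96,
                                     templates = small_templates())
  man <- read.csv(manifest_path)
  expect_equal(nrow(man), 2L)
  expect_true(all(file.exists(man$rf_path, man$bmode_path, man$mask_path)))

  gen <- generate_dataset(1, seed = 15, height = 128, width = 96,
                          templates = small_templates())
  rf <- read_rf(man$rf_path[1])
  expect_identical(rf$samples, gen$samples[[1]]$rf$samples)
  b <- load_bmode(man$bmode_path[1])
  expect_lt(max(abs(b$pixels - gen$samples[[1]]$bmode$pixels)), 1)  # 16-bit truncation
  mask <- load_bmode(man$mask_path[1])
  expect_identical(mask$pixels / 255, gen$samples[[1]]$mask + 0)
  unlink(out, recursive = TRUE)
})
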