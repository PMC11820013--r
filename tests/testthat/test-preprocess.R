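test_that("tiling lays a full grid and drops partial border tiles", {
  img <- array(0.5, c(768, 1024, 3))  # height 768, width 1024
  cfg <- tiling_config(patch_size = 256, magnifications = "20x",
                       stride = 256)
  recs <- tile_slide(img, cfg)
  expect_equal(nrow(recs), 12)  # 4 x 3 grid
  expect_setequal(unique(recs$x), c(0, 256, 512, 768))
  expect_setequal(unique(recs$y), c(0, 256, 512))
  # exactly one tile for an exact-fit image
  one <- tile_slide(array(0.5, c(256, 256, 3)), cfg)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$x, one$y), c(0, 0))
  # too-small image errors
  expect_error(tile_slide(array(0.5, c(256, 255, 3)), cfg),
               "smaller than one patch")
})

test_that("two magnifications tile the downsampled pyramid consistently", {
  s <- simulate_slide(width = 1024, height = 512, n_tissue_blobs = 2,
                      blob_radius = c(60, 120), seed = 71)
  cfg <- tiling_config(patch_size = 128, magnifications = c("20x", "10x"),
                       stride = 128)
  recs <- tile_slide(s$image, cfg, base_magnification = "20x")
  r20 <- recs[recs$magnification == "20x", ]
  r10 <- recs[recs$magnification == "10x", ]
  expect_equal(nrow(r20), 8 * 4)
  expect_equal(nrow(r10), 4 * 2)
  # 10x coordinates are level-0 offsets covering twice the footprint
  expect_setequal(unique(r10$x), c(0, 256, 512, 768))
  expect_true(all(r10$size == 128))
})

test_that("tissue fraction recovers constructed ground truth", {
  white <- array(1, c(64, 64, 3))
  expect_equal(tissue_fraction(white), 0)
  pink <- array(rep(c(0.91, 0.28, 0.60), each = 64 * 64), c(64, 64, 3))
  expect_equal(tissue_fraction(pink), 1)
  # half saturated pink, half white, by construction
  half <- white
  half[, 1:32, 1] <- 0.91; half[, 1:32, 2] <- 0.28; half[, 1:32, 3] <- 0.60
  frac <- tissue_fraction(half)
  # independent per-pixel count of the constructed mask
  expect_equal(frac, sum(rep(c(TRUE, FALSE), each = 64 * 32)) / (64 * 64),
               tolerance = 0.02)
  expect_error(tissue_fraction(matrix(1, 4, 4)), "non-RGB")
})

test_that("tissue fraction depends on pixel content, not patch position", {
  s <- simulate_slide(width = 512, height = 256, n_tissue_blobs = 1,
                      blob_radius = c(60, 80), seed = 72)
  patchA <- s$image[1:128, 1:128, , drop = FALSE]
  thr <- 0.3
  expect_equal(tissue_fraction(patchA, thr), tissue_fraction(patchA, thr))
  # translating content: same pixels elsewhere give the same fraction
  img2 <- array(1, c(256, 512, 3))
  img2[129:256, 385:512, ] <- patchA
  patchB <- img2[129:256, 385:512, , drop = FALSE]
  expect_identical(tissue_fraction(patchB, thr),
                   tissue_fraction(patchA, thr))
})

test_that("per-patch fractions agree with the known mask within 0.02", {
  s <- simulate_slide(width = 512, height = 384, n_tissue_blobs = 3,
                      blob_radius = c(40, 90), seed = 73)
  cfg <- tiling_config(patch_size = 64, magnifications = "20x",
                       stride = 64)
  recs <- tile_slide(s$image, cfg)
  for (i in seq_len(nrow(recs))) {
    mfrac <- mean(s$mask[(recs$y[i] + 1):(recs$y[i] + 64),
                         (recs$x[i] + 1):(recs$x[i] + 64)])
    expect_lt(abs(recs$tissue_fraction[i] - mfrac), 0.02)
  }
})

test_that("patch filtering is a strict-less-than discard, order-preserving", {
  recs <- data.frame(slide_id = "s", x = c(0, 64, 128), y = 0, size = 64,
                     magnification = "20x",
                     tissue_fraction = c(0.20, 0.35, 0.50))
  kept <- filter_patches(recs, 0.35)
  expect_equal(kept$tissue_fraction, c(0.35, 0.50))  # boundary kept
  expect_equal(nrow(filter_patches(recs, 0)), 3)
  expect_equal(nrow(filter_patches(recs, 1)), 0)
  # subsequence + idempotence
  expect_identical(filter_patches(kept, 0.35), kept)
  expect_error(filter_patches(recs[, -6], 0.35), "tissue_fraction")
})

test_that("patch manifests round-trip through CSV", {
  s <- simulate_slide(width = 256, height = 256, n_tissue_blobs = 1,
                      blob_radius = c(50, 90), seed = 74)
  recs <- tile_slide(s$image, tiling_config(patch_size = 64,
                                            magnifications = "20x",
                                            stride = 64))
  f <- withr::local_tempfile(fileext = ".csv")
  write_patch_manifest(recs, f)
  back <- read_patch_manifest(f)
  expect_equal(back$x, recs$x)
  expect_equal(back$tissue_fraction, recs$tissue_fraction,
               tolerance = 1e-12)
})

test_that("slide images read from PNG with patches extractable", {
  s <- simulate_slide(width = 256, height = 128, n_tissue_blobs = 1,
                      blob_radius = c(30, 50), seed = 75)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(s$image, f)
  img <- read_slide_image(f)
  expect_equal(dim(img), c(128, 256, 3))
  expect_equal(img, s$image, tolerance = 1 / 255)
  recs <- tile_slide(img, tiling_config(patch_size = 64,
                                        magnifications = "20x",
                                        stride = 64))
  patches <- extract_patches(img, recs)
  expect_length(patches, nrow(recs))
  expect_equal(dim(patches[[1]]), c(64, 64, 3))
  expect_equal(patches[[2]], img[65:128, 1:64, , drop = FALSE])
  expect_error(read_slide_image("x.bmp"), "unsupported")
})
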