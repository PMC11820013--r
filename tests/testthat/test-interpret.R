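make_coords <- function(xs, ys, size = 4, mag = "20x") {
  data.frame(slide_id = "s", x = xs, y = ys, size = size,
             magnification = mag, tissue_fraction = 1)
}

test_that("activation maps are min-max normalized with a constant rule", {
  set.seed(101)
  p <- active_params(6, dim_model = 6, seed = 101)
  # identical instances -> identical raw scores -> all-zero map
  Xsame <- matrix(rep(rnorm(6), each = 5), 5, 6)
  m <- instance_activations(p, mil_bag(Xsame, 1))
  expect_equal(m$activations, rep(0, 5))
  # non-constant raw vectors normalize onto [0, 1] with endpoints hit
  found <- FALSE
  for (s in 1:5) {
    X <- matrix(rnorm(7 * 6), 7, 6)
    m <- instance_activations(p, mil_bag(X, 1))
    if (diff(range(m$raw)) > 1e-8) {
      found <- TRUE
      expect_equal(min(m$activations), 0)
      expect_equal(max(m$activations), 1)
    }
  }
  expect_true(found)
})

test_that("attribution is equivariant under instance reordering", {
  set.seed(102)
  p <- active_params(5, dim_model = 5, seed = 102)
  X <- matrix(rnorm(8 * 5), 8, 5)
  m <- instance_activations(p, mil_bag(X, 1))
  perm <- sample(8)
  mp <- instance_activations(p, mil_bag(X[perm, ], 1))
  expect_equal(mp$activations, m$activations[perm], tolerance = 1e-8)
})

test_that("attribution highlights witnesses on a trained model", {
  bags <- simulate_mil_bags(n_bags = 60, instances_per_bag = c(10, 20),
                            feature_dim = 16, witness_rate = 0.2,
                            effect_size = 3, signal_channels = 4,
                            seed = 103)
  fit <- camil(bags, epochs = 10, seed = 103)
  pos <- Filter(function(b) b$label == 1, bags)
  ok <- vapply(pos, function(b) {
    act <- instance_activations(fit, b)$activations
    il <- instance_labels(b)
    mean(act[il == 1]) > mean(act[il == 0])
  }, logical(1))
  expect_gt(mean(ok), 0.8)
  # non-finite parameters are rejected
  bad <- fit$params; bad$W_A[1] <- NaN
  expect_error(instance_activations(bad, bags[[1]]), "non-finite")
})

test_that("heatmaps paint each patch footprint at its activation color", {
  map <- structure(list(slide_id = "s", activations = c(0, 1),
                        raw = c(0, 2), prob = 0.9, layer = "attention",
                        coords = make_coords(c(0, 8), c(0, 4))),
                   class = "instance_activation_map")
  img <- render_heatmap(map, slide_dims = c(12, 8))
  act <- attr(img, "activation")
  expect_equal(dim(img), c(8, 12, 3))
  expect_equal(act[1, 1], 0)       # cool block at origin
  expect_equal(act[5, 9], 1)       # warm block at (8, 4)
  expect_true(is.na(act[1, 9]))    # background untouched
  cool <- camil:::heat_colormap(0); warm <- camil:::heat_colormap(1)
  expect_equal(as.numeric(img[1, 1, ]), as.numeric(cool))
  expect_equal(as.numeric(img[5, 9, ]), as.numeric(warm))
  # reprojection round-trip at patch centers
  expect_equal(as.numeric(img[2, 2, ]), as.numeric(cool))
  expect_equal(as.numeric(img[6, 10, ]), as.numeric(warm))
})

test_that("overlapping patches resolve by pixelwise maximum", {
  map <- structure(list(slide_id = "s", activations = c(0.2, 0.9),
                        raw = c(0.2, 0.9), prob = 0.5, layer = "attention",
                        coords = make_coords(c(0, 2), c(0, 0))),
                   class = "instance_activation_map")
  img <- render_heatmap(map, slide_dims = c(8, 4))
  act <- attr(img, "activation")
  # pixelwise-max oracle over the two 4x4 footprints
  oracle <- matrix(NA_real_, 4, 8)
  oracle[1:4, 1:4] <- 0.2
  oracle[1:4, 3:6] <- pmax(oracle[1:4, 3:6], 0.9, na.rm = TRUE)
  expect_equal(act, oracle)
  # out-of-bounds coordinates rejected
  bad <- map; bad$coords$x[2] <- 6
  expect_error(render_heatmap(bad, slide_dims = c(8, 4)), "outside")
})

test_that("heatmap files are written as PNG and CSV", {
  set.seed(104)
  p <- active_params(5, dim_model = 5, seed = 104)
  bag <- mil_bag(matrix(rnorm(4 * 5), 4, 5), 1,
                 coords = make_coords(c(0, 4, 0, 4), c(0, 0, 4, 4)))
  m <- instance_activations(p, bag)
  fp <- withr::local_tempfile(fileext = ".png")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_heatmap(m, c(8, 8), png_path = fp, csv_path = fc)
  expect_true(file.exists(fp))
  got <- utils::read.csv(fc)
  expect_equal(got$activation, m$activations, tolerance = 1e-6)
})
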