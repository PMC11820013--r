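#' Simulate MIL bags with a controlled witness rate and effect size
#'
#' Generates the statistical structure the model assumes: every instance
#' is a standard-Gaussian feature vector; in a positive bag,
#' `ceiling(witness_rate * N)` randomly placed "witness" instances get a
#' mean shift of `effect_size` added on the first `signal_channels`
#' channels. Negative bags contain no shifted instance, so bag labels obey
#' the MIL rule by construction. The default witness rate of 0.1 mirrors
#' the regime of sentinel-lymph-node slides, where tumor tissue typically
#' occupies under 10% of the positive slide — the regime that makes
#' bag-level learning hard.
#'
#' Ground-truth instance labels are attached to each bag but only
#' reachable via [instance_labels()]; no fitting code reads them.
#'
#' @param n_bags number of bags.
#' @param instances_per_bag length-2 integer range; each bag's N is drawn
#'   uniformly from it.
#' @param feature_dim channel count C (default 512).
#' @param witness_rate fraction of positive instances inside a positive
#'   bag, in (0, 1\]; default 0.1.
#' @param effect_size per-channel mean shift of witness instances
#'   (default 2).
#' @param signal_channels number of shifted channels k (default 8,
#'   capped at `feature_dim`).
#' @param positive_bag_fraction fraction of positive bags (default 0.5);
#'   the positive count is exact, `round(n_bags * fraction)`.
#' @param seed integer seed; the draw is fully deterministic in it.
#' @return list of [mil_bag()] objects, slide ids `synth_0001`, ...
#' @export
simulate_mil_bags <- function(n_bags = 200L,
                              instances_per_bag = c(20L, 60L),
                              feature_dim = 512L, witness_rate = 0.1,
                              effect_size = 2, signal_channels = 8L,
                              positive_bag_fraction = 0.5, seed = 1L) {
  stopifnot(n_bags >= 1L, length(instances_per_bag) == 2L,
            instances_per_bag[1] >= 1L,
            instances_per_bag[2] >= instances_per_bag[1],
            feature_dim >= 1L, effect_size >= 0)
  if (witness_rate <= 0 || witness_rate > 1) {
    stop("infeasible witness count: witness_rate must be in (0, 1]")
  }
  if (signal_channels > feature_dim) {
    stop("signal_channels exceeds feature_dim")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_pos <- round(n_bags * positive_bag_fraction)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n_bags - n_pos)))
  lapply(seq_len(n_bags), function(i) {
    n <- sample(seq(instances_per_bag[1], instances_per_bag[2]), 1L)
    X <- matrix(stats::rnorm(n * feature_dim), n, feature_dim)
    il <- integer(n)
    if (labels[i] == 1L) {
      n_wit <- as.integer(ceiling(witness_rate * n))
      wit <- sample.int(n, n_wit)
      X[wit, seq_len(signal_channels)] <-
        X[wit, seq_len(signal_channels)] + effect_size
      il[wit] <- 1L
    }
    mil_bag(X, label = labels[i],
            slide_id = sprintf("synth_%04d", i),
            instance_labels = il)
  })
}

#' Simulate a slide raster with a known tissue mask
#'
#' Draws saturated pink tissue blobs on a white background and returns the
#' RGB raster together with the exact pixel mask of tissue — the fixture
#' for testing tiling and tissue filtering against ground truth.
#'
#' @param width,height canvas size in pixels.
#' @param n_tissue_blobs number of circular blobs (0 gives an all-white
#'   slide).
#' @param blob_radius length-2 range of blob radii in pixels; blobs are
#'   placed so they fit inside the canvas.
#' @param tissue_color RGB triple in \[0, 1\] for tissue pixels (default a
#'   saturated pink reminiscent of eosin).
#' @param seed integer seed.
#' @return list with `image` (height x width x 3 array in \[0, 1\]),
#'   `mask` (logical height x width, TRUE on tissue), and `config`.
#' @export
simulate_slide <- function(width = 768L, height = 512L,
                           n_tissue_blobs = 3L, blob_radius = c(40L, 100L),
                           tissue_color = c(0.91, 0.28, 0.60), seed = 1L) {
  stopifnot(width >= 1L, height >= 1L, n_tissue_blobs >= 0L,
            blob_radius[1] >= 1L, blob_radius[2] >= blob_radius[1])
  if (2 * blob_radius[2] > min(width, height)) {
    stop("largest blob does not fit within the canvas")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  mask <- matrix(FALSE, height, width)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  for (b in seq_len(n_tissue_blobs)) {
    r <- stats::runif(1, blob_radius[1], blob_radius[2])
    cx <- stats::runif(1, r, width - r)
    cy <- stats::runif(1, r, height - r)
    mask <- mask | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  img <- array(1, dim = c(height, width, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- tissue_color[ch]
    img[, , ch] <- plane
  }
  list(image = img, mask = mask,
       config = list(width = width, height = height,
                     n_tissue_blobs = n_tissue_blobs,
                     blob_radius = blob_radius, seed = seed))
}
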