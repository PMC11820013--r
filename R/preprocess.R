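#' Tiling configuration
#'
#' @param patch_size patch side length in pixels at the extraction
#'   magnification (default 256).
#' @param magnifications magnifications to tile at, a subset of
#'   `c("20x", "10x")`.
#' @param min_tissue_fraction minimum tissue area per patch; patches with
#'   strictly less are discarded (default 0.35).
#' @param stride grid step in pixels; default equal to `patch_size`
#'   (non-overlapping tiles).
#' @return list of class `tiling_config`.
#' @export
tiling_config <- function(patch_size = 256L, magnifications = c("20x", "10x"),
                          min_tissue_fraction = 0.35, stride = patch_size) {
  stopifnot(patch_size >= 1L, stride >= 1L,
            min_tissue_fraction >= 0, min_tissue_fraction <= 1,
            all(magnifications %in% c("20x", "10x")),
            length(magnifications) >= 1L)
  structure(list(patch_size = as.integer(patch_size),
                 magnifications = magnifications,
                 min_tissue_fraction = min_tissue_fraction,
                 stride = as.integer(stride)),
            class = "tiling_config")
}

mag_value <- function(m) as.numeric(sub("x$", "", m))

#' Read a plain raster slide image
#'
#' Reads a PNG or (via the tiff package) TIFF image into a
#' height x width x 3 RGB array in \[0, 1\]. Grayscale images are
#' replicated to three channels; an alpha channel is dropped.
#'
#' @param path image file.
#' @return numeric array height x width x 3.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

## HSV saturation plane of an RGB array, as a height x width matrix.
saturation_plane <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("non-RGB input: expected a height x width x 3 array")
  }
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 1)
  matrix(hsv["s", ], nrow = dim(image)[1])
}

## Otsu threshold of a saturation plane; a (near-)constant plane has no
## two classes to separate, so fall back to 0.5 (tissue iff saturated).
otsu_saturation <- function(sat) {
  if (diff(range(sat)) < 1e-8) return(0.5)
  EBImage::otsu(sat, range = c(0, 1), levels = 256L)
}

#' Fraction of tissue pixels in a patch
#'
#' A pixel counts as tissue when its HSV saturation exceeds an Otsu
#' threshold — white/gray background has near-zero saturation while
#' stained tissue is strongly saturated. By default the threshold is
#' computed from the patch itself; pass the slide-level threshold (as
#' [tile_slide()] does) so all patches of a slide share one.
#'
#' @param patch height x width x 3 RGB array in \[0, 1\].
#' @param threshold optional saturation threshold in \[0, 1\]; computed by
#'   Otsu from the patch when `NULL`.
#' @return Fraction in \[0, 1\]. Deterministic in the pixel content only.
#' @export
tissue_fraction <- function(patch, threshold = NULL) {
  sat <- saturation_plane(patch)
  if (is.null(threshold)) threshold <- otsu_saturation(sat)
  mean(sat > threshold)
}

## 2x2-block (or f x f) mean downsampling; trailing rows/cols that do not
## fill a block are cropped.
downsample_image <- function(image, factor) {
  if (factor == 1) return(image)
  h <- (dim(image)[1] %/% factor) * factor
  w <- (dim(image)[2] %/% factor) * factor
  if (h < factor || w < factor) stop("image too small to downsample")
  out <- array(0, c(h %/% factor, w %/% factor, 3L))
  for (ch in 1:3) {
    plane <- image[seq_len(h), seq_len(w), ch]
    ## average factor x factor blocks
    m <- matrix(plane, nrow = factor)
    m <- colMeans(m)                             # h/f * w values
    m <- matrix(m, nrow = h %/% factor)          # rows pooled
    m2 <- matrix(t(m), nrow = factor)            # pool columns
    out[, , ch] <- t(matrix(colMeans(m2), nrow = w %/% factor))
  }
  out
}

#' Tile a slide into patch records
#'
#' Lays a regular grid of `patch_size` x `patch_size` tiles (step
#' `stride`) over the slide at each requested magnification and computes
#' each tile's tissue fraction against a per-slide, per-magnification Otsu
#' saturation threshold. Border tiles that do not fully fit are dropped;
#' coordinates are recorded as 0-based level-0 pixel offsets of the tile's
#' top-left corner (half-open extent `[x, x + size * scale)`).
#'
#' Magnifications below the base are obtained by block-mean downsampling
#' (20x -> 10x halves each dimension).
#'
#' @param image height x width x 3 RGB array at `base_magnification`.
#' @param cfg a [tiling_config()].
#' @param slide_id id recorded in the output.
#' @param base_magnification magnification of `image` (default "20x").
#' @return data.frame of patch records: slide_id, x, y, size,
#'   magnification, tissue_fraction. Unfiltered: apply
#'   [filter_patches()] for the tissue criterion.
#' @export
tile_slide <- function(image, cfg = tiling_config(), slide_id = "slide",
                       base_magnification = "20x") {
  stopifnot(inherits(cfg, "tiling_config"))
  base <- mag_value(base_magnification)
  out <- list()
  for (mag in cfg$magnifications) {
    f <- base / mag_value(mag)
    if (f < 1 || f != round(f)) {
      stop("magnification ", mag, " not reachable from base ",
           base_magnification)
    }
    im <- downsample_image(image, as.integer(f))
    h <- dim(im)[1]; w <- dim(im)[2]
    ps <- cfg$patch_size
    if (h < ps || w < ps) {
      stop("image smaller than one patch (", w, "x", h, " at ", mag,
           " vs patch ", ps, ")")
    }
    thr <- otsu_saturation(saturation_plane(im))
    xs <- seq(0L, w - ps, by = cfg$stride)
    ys <- seq(0L, h - ps, by = cfg$stride)
    sat <- saturation_plane(im)
    recs <- expand.grid(y = ys, x = xs)   # column-major order, x slowest
    tf <- vapply(seq_len(nrow(recs)), function(i) {
      x0 <- recs$x[i]; y0 <- recs$y[i]
      mean(sat[(y0 + 1):(y0 + ps), (x0 + 1):(x0 + ps)] > thr)
    }, numeric(1))
    out[[mag]] <- data.frame(slide_id = slide_id,
                             x = as.integer(recs$x * f),
                             y = as.integer(recs$y * f),
                             size = ps, magnification = mag,
                             tissue_fraction = tf,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Filter patch records by tissue fraction
#'
#' Keeps exactly the records whose tissue fraction is at least the
#' threshold — patches with strictly less tissue are discarded. Order is
#' preserved, so the output is a subsequence of the input and the
#' operation is idempotent.
#'
#' @param records data.frame from [tile_slide()] with a populated
#'   `tissue_fraction` column.
#' @param min_tissue_fraction threshold in \[0, 1\] (default 0.35).
#' @return Filtered data.frame.
#' @export
filter_patches <- function(records, min_tissue_fraction = 0.35) {
  if (!"tissue_fraction" %in% names(records)) {
    stop("records lack a tissue_fraction column")
  }
  records[records$tissue_fraction >= min_tissue_fraction, , drop = FALSE]
}

#' Extract patch rasters named by patch records
#'
#' @param image slide RGB array at `base_magnification`.
#' @param records patch records (rows of a [tile_slide()] data.frame).
#' @param base_magnification magnification of `image`.
#' @return list of patch arrays (size x size x 3), in record order.
#' @export
extract_patches <- function(image, records, base_magnification = "20x") {
  base <- mag_value(base_magnification)
  cache <- new.env()
  lapply(seq_len(nrow(records)), function(i) {
    mag <- records$magnification[i]
    f <- as.integer(base / mag_value(mag))
    key <- paste0("f", f)
    if (is.null(cache[[key]])) cache[[key]] <- downsample_image(image, f)
    im <- cache[[key]]
    x0 <- records$x[i] %/% f; y0 <- records$y[i] %/% f
    ps <- records$size[i]
    if (y0 + ps > dim(im)[1] || x0 + ps > dim(im)[2]) {
      stop("patch record ", i, " exceeds slide bounds")
    }
    im[(y0 + 1):(y0 + ps), (x0 + 1):(x0 + ps), , drop = FALSE]
  })
}

#' Write / read a patch manifest CSV
#'
#' @param records patch-record data.frame.
#' @param path CSV file path.
#' @return `path` invisibly; `read_patch_manifest()` returns the
#'   data.frame.
#' @export
write_patch_manifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_manifest
#' @export
read_patch_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
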