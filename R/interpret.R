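#' Gradient-based instance attribution
#'
#' Scores each instance's contribution to the bag logit in the Grad-CAM
#' spirit adapted to bag models: the gradient of the bag logit with
#' respect to the instance's embedding at `layer` is dotted with the
#' embedding itself, the positive part is kept, and the scores are
#' min–max normalized across the bag to \[0, 1\]. A constant raw vector
#' (e.g. a bag of identical instances) normalizes to all zeros.
#'
#' @param model a fitted [camil()] model (or a `camil_params` object).
#' @param bag a [mil_bag()]; its `coords`, when present, are carried into
#'   the result for heatmap reprojection.
#' @param layer which embedding to attribute at: the cascaded attention
#'   block's output (default), the encoder output, or the decoder output.
#' @return Object of class `instance_activation_map`: list with
#'   `slide_id`, `activations` (length N in \[0, 1\]), `raw` (unnormalized
#'   scores), `coords`.
#' @export
instance_activations <- function(model, bag,
                                 layer = c("attention", "encoder",
                                           "decoder")) {
  layer <- match.arg(layer)
  params <- if (inherits(model, "camil")) model$params else model
  if (!inherits(params, "camil_params")) stop("need a fitted model or camil_params")
  bag <- validate_bag(bag)
  bad <- !vapply(params[.trainable], function(a) all(is.finite(a)), logical(1))
  if (any(bad)) stop("non-finite model parameters: ",
                     paste(names(bad)[bad], collapse = ", "))
  fw <- camil_forward_cache(bag$X, params)
  bk <- camil_backward(params, fw$cache, dlogit = 1)
  emb <- switch(layer, attention = fw$cache$H, encoder = fw$cache$Xe,
                decoder = fw$cache$Hd)
  grad <- bk$taps[[layer]]
  raw <- pmax(rowSums(grad * emb), 0)
  rng <- range(raw)
  act <- if (diff(rng) < 1e-12) rep(0, length(raw)) else
    (raw - rng[1]) / diff(rng)
  structure(list(slide_id = bag$slide_id, activations = act, raw = raw,
                 prob = fw$prob, layer = layer, coords = bag$coords),
            class = "instance_activation_map")
}

#' @export
print.instance_activation_map <- function(x, ...) {
  cat("Instance activation map '", x$slide_id, "': ",
      length(x$activations), " instances at layer '", x$layer,
      "', bag prob ", sprintf("%.3f", x$prob), "\n", sep = "")
  invisible(x)
}

## blue -> cyan -> yellow -> red, the usual heatmap ramp (warm = high)
heat_colormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#2166FF", "#00E5FF", "#FFF200",
                                 "#FF1E00"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Reproject instance activations onto slide coordinates
#'
#' Paints each patch's footprint (its half-open level-0 extent, scaled by
#' `1/downsample`) with the colormap value of its activation — warm colors
#' mark instances driving the positive prediction, cool colors inert
#' ones. Where patches overlap, the pixelwise maximum activation wins.
#' Unpatched background is a neutral light gray.
#'
#' @param map an [instance_activations()] result whose `coords` are
#'   populated.
#' @param slide_dims integer c(width, height) of the slide at level 0.
#' @param downsample integer shrink factor for the rendered raster
#'   (default 1).
#' @param background RGB triple for unpatched pixels.
#' @return height x width x 3 RGB array (at the downsampled size), with
#'   the activation canvas attached as attribute `"activation"` (NA on
#'   background).
#' @export
render_heatmap <- function(map, slide_dims, downsample = 1L,
                           background = c(0.94, 0.94, 0.94)) {
  stopifnot(inherits(map, "instance_activation_map"))
  co <- map$coords
  if (is.null(co)) stop("activation map has no coordinates")
  W <- as.integer(slide_dims[1]); H <- as.integer(slide_dims[2])
  base_mag <- max(mag_value(co$magnification))
  scale <- base_mag / mag_value(co$magnification)  # footprint per record
  x1 <- co$x + co$size * scale; y1 <- co$y + co$size * scale
  if (any(co$x < 0 | co$y < 0 | x1 > W | y1 > H)) {
    stop("coords outside slide bounds")
  }
  w <- max(1L, W %/% downsample); h <- max(1L, H %/% downsample)
  canvas <- matrix(NA_real_, h, w)
  for (i in seq_len(nrow(co))) {
    xs <- max(1L, co$x[i] %/% downsample + 1L)
    ys <- max(1L, co$y[i] %/% downsample + 1L)
    xe <- min(w, as.integer(ceiling(x1[i] / downsample)))
    ye <- min(h, as.integer(ceiling(y1[i] / downsample)))
    block <- canvas[ys:ye, xs:xe]
    canvas[ys:ye, xs:xe] <- pmax(block, map$activations[i], na.rm = TRUE)
  }
  img <- array(rep(background, each = h * w), c(h, w, 3L))
  filled <- which(!is.na(canvas))
  if (length(filled)) {
    cols <- heat_colormap(canvas[filled])
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[filled] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  attr(img, "activation") <- canvas
  img
}

#' Write an activation map as PNG + CSV
#'
#' @param map an [instance_activations()] result.
#' @param slide_dims c(width, height) at level 0.
#' @param png_path,csv_path output files (`NULL` to skip either).
#' @param downsample shrink factor for the PNG.
#' @return Invisibly, the rendered raster.
#' @export
write_heatmap <- function(map, slide_dims, png_path = NULL,
                          csv_path = NULL, downsample = 1L) {
  img <- render_heatmap(map, slide_dims, downsample = downsample)
  if (!is.null(png_path)) png::writePNG(img, png_path)
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(slide_id = map$slide_id,
                                x = map$coords$x, y = map$coords$y,
                                activation = map$activations),
                     csv_path, row.names = FALSE)
  }
  invisible(img)
}
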