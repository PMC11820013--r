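#' Encoder specification
#'
#' Describes how patches are turned into fixed-length feature vectors.
#' The built-in `toy_histogram` encoder is deterministic and
#' download-free; a pretrained convolutional encoder (the usual choice for
#' real slides, producing 512-dimensional descriptors) can be plugged in
#' as `fn`, a function `(patch, output_dim) -> numeric vector`.
#'
#' @param name `"toy_histogram"` or `"custom"` (requires `fn`).
#' @param output_dim feature vector length (default 512).
#' @param normalize L2-normalize each feature vector (default FALSE).
#' @param fn custom encoder function for `name = "custom"`.
#' @return list of class `encoder_spec`.
#' @export
encoder_spec <- function(name = c("toy_histogram", "custom"),
                         output_dim = 512L, normalize = FALSE, fn = NULL) {
  name <- match.arg(name)
  stopifnot(output_dim >= 1L)
  if (name == "custom" && !is.function(fn)) {
    stop("custom encoder requires fn")
  }
  structure(list(name = name, output_dim = as.integer(output_dim),
                 normalize = isTRUE(normalize), fn = fn),
            class = "encoder_spec")
}

#' Deterministic histogram patch encoder
#'
#' Concatenates the per-channel intensity histograms of an RGB patch
#' (`output_dim / 3` equal-width bins per channel over \[0, 1\]) and
#' L1-normalizes the whole vector to sum to 1. Invariant to any pixel
#' permutation (mirroring, rotation) and to the patch's position on the
#' slide — a transparent stand-in for a learned encoder in tests.
#'
#' @param patch height x width x 3 RGB array in \[0, 1\].
#' @param output_dim total length; must be divisible by 3.
#' @return numeric vector of length `output_dim` summing to 1.
#' @export
toy_histogram_encoder <- function(patch, output_dim = 512L) {
  if (output_dim %% 3L != 0L) {
    stop("output_dim must be divisible by 3 (one histogram per channel)")
  }
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L) {
    stop("non-RGB patch")
  }
  nb <- output_dim %/% 3L
  breaks <- seq(0, 1, length.out = nb + 1L)
  v <- unlist(lapply(1:3, function(ch) {
    x <- pmin(pmax(as.vector(patch[, , ch]), 0), 1)
    tabulate(pmin(findInterval(x, breaks, all.inside = TRUE), nb), nb)
  }))
  v / sum(v)
}

#' Encode a list of patches into a feature matrix
#'
#' Applies the encoder described by `spec` to each patch. Deterministic:
#' two runs on the same input are bit-identical, and row i always encodes
#' patch i.
#'
#' @param patches list of same-sized RGB patch arrays (possibly empty).
#' @param spec an [encoder_spec()].
#' @return numeric matrix `length(patches)` x `spec$output_dim`.
#' @export
encode_patches <- function(patches, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (length(patches) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = spec$output_dim))
  }
  sizes <- vapply(patches, function(p) paste(dim(p), collapse = "x"),
                  character(1))
  if (length(unique(sizes)) != 1L) {
    stop("mixed patch sizes: ", paste(unique(sizes), collapse = ", "))
  }
  enc <- switch(spec$name,
                toy_histogram = function(p) toy_histogram_encoder(p, spec$output_dim),
                custom = function(p) spec$fn(p, spec$output_dim))
  X <- t(vapply(patches, enc, numeric(spec$output_dim)))
  if (!all(is.finite(X))) stop("encoder produced non-finite features")
  if (spec$normalize) {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- X / nrm
  }
  X
}
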