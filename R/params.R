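#' Initialize the model's learnable parameters
#'
#' Creates the full parameter set of the cascaded-attention MIL network:
#' input encoder (affine `dim_in -> dim_model` + ReLU), the three spatial
#' projections `W_A/W_B/W_D`, the two scalar residual gates `alpha` and
#' `beta` (both exactly 0 at initialization, so the attention block starts
#' as the identity), the fusion projection (only used by
#' `parallel_concat`), decoder (affine `dim_model -> dim_model` + ReLU),
#' the tanh attention-pooling scorer, and the sigmoid classifier head.
#'
#' Weight matrices use Glorot-uniform initialization; biases start at 0;
#' the classifier weights start at 0 so an untrained model outputs
#' probability exactly 0.5 for every bag.
#'
#' @param dim_in input channel count (feature dimension of the bags).
#' @param dim_model working width of the network. Defaults to `dim_in`
#'   (equal-dimensional encoding).
#' @param dim_hidden hidden width of the attention-pooling scorer.
#' @param fusion fusion mode of the attention block, see
#'   [cascaded_block()].
#' @param seed integer seed for the random initialization.
#' @return A `camil_params` object (a list of parameter arrays).
#' @export
camil_params <- function(dim_in, dim_model = dim_in, dim_hidden = 128L,
                         fusion = c("spatial_then_channel",
                                    "channel_then_spatial",
                                    "spatial_only", "channel_only",
                                    "parallel_concat"),
                         seed = 1L) {
  fusion <- match.arg(fusion)
  stopifnot(dim_in >= 1L, dim_model >= 1L, dim_hidden >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  glorot <- function(nr, nc) {
    l <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -l, l), nr, nc)
  }
  C <- as.integer(dim_model)
  p <- list(
    dim_in = as.integer(dim_in), dim_model = C,
    dim_hidden = as.integer(dim_hidden), fusion = fusion,
    W_enc = glorot(dim_in, C), b_enc = numeric(C),
    W_A = glorot(C, C), b_A = numeric(C),
    W_B = glorot(C, C), b_B = numeric(C),
    W_D = glorot(C, C), b_D = numeric(C),
    alpha = 0, beta = 0,
    W_fuse = glorot(2L * C, C), b_fuse = numeric(C),
    W_dec = glorot(C, C), b_dec = numeric(C),
    V_pool = glorot(dim_hidden, C), w_pool = numeric(dim_hidden),
    w_cls = numeric(C), b_cls = 0
  )
  p$w_pool <- stats::runif(dim_hidden, -sqrt(6 / (dim_hidden + 1)),
                           sqrt(6 / (dim_hidden + 1)))
  class(p) <- "camil_params"
  p
}

## names of the arrays that are trained (everything else is metadata)
.trainable <- c("W_enc", "b_enc", "W_A", "b_A", "W_B", "b_B", "W_D", "b_D",
                "alpha", "beta", "W_fuse", "b_fuse", "W_dec", "b_dec",
                "V_pool", "w_pool", "w_cls", "b_cls")

## Save/restore .Random.seed so parameter init does not disturb the
## caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.camil_params <- function(x, ...) {
  npar <- sum(vapply(.trainable, function(nm) length(x[[nm]]), numeric(1)))
  cat("camil parameters: dim_in=", x$dim_in, ", dim_model=", x$dim_model,
      ", fusion='", x$fusion, "', ", format(npar, big.mark = ","),
      " trainable values (alpha=", signif(x$alpha, 3),
      ", beta=", signif(x$beta, 3), ")\n", sep = "")
  invisible(x)
}
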