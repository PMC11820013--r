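## Full network forward pass with caching for backpropagation.
##
## Pipeline: encoder (affine + ReLU) -> cascaded attention block ->
## decoder (affine + ReLU) -> attention pooling -> sigmoid classifier.

relu <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

camil_forward_cache <- function(X, params) {
  if (ncol(X) != params$dim_in) {
    stop("channel mismatch: bag has ", ncol(X), " channels, model expects ",
         params$dim_in)
  }
  enc_pre <- sweep(X %*% params$W_enc, 2L, params$b_enc, "+")
  Xe <- relu(enc_pre)
  H <- cascaded_block(Xe, params)
  block_cache <- attr(H, "cache")
  attr(H, "cache") <- NULL
  dec_pre <- sweep(H %*% params$W_dec, 2L, params$b_dec, "+")
  Hd <- relu(dec_pre)
  pool <- attention_pool(Hd, params)
  logit <- sum(pool$bag_vector * params$w_cls) + params$b_cls
  list(prob = sigmoid(logit), logit = logit, weights = pool$weights,
       cache = list(X = X, enc_pre = enc_pre, Xe = Xe, H = H,
                    block = block_cache, dec_pre = dec_pre, Hd = Hd,
                    pool = pool$cache, z = pool$bag_vector, logit = logit))
}

#' Forward pass: bag-level prediction
#'
#' Runs a bag through the full network in inference mode and returns the
#' bag probability, its logit, and the attention-pooling weight assigned
#' to each instance (nonnegative, summing to 1). Deterministic: the same
#' bag and parameters always produce the same output, and the prediction
#' is invariant to reordering of the bag's instances.
#'
#' @param bag a [mil_bag()] (or a bare numeric matrix of instances).
#' @param params a [camil_params()] object.
#' @return list with elements `prob`, `logit`, `instance_weights`.
#' @export
camil_forward <- function(bag, params) {
  X <- if (inherits(bag, "mil_bag")) validate_bag(bag)$X else as.matrix(bag)
  fw <- camil_forward_cache(X, params)
  list(prob = fw$prob, logit = fw$logit, instance_weights = fw$weights)
}
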