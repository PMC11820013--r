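## Cascaded spatial -> channel attention over a bag's instance matrix.
##
## Conventions used throughout:
##  * X, E, G are N x C (rows = instances/patches, columns = channels).
##  * S is N x N with S[i, j] = s_ji, the influence of instance i on
##    instance j; every column of S sums to 1.
##  * Cmat is C x C with Cmat[i, j] = c_ji, the influence of channel i on
##    channel j; every column sums to 1.
##  * Both softmaxes are taken down columns and stabilized by per-column
##    max subtraction (exact, by shift invariance). Dot products are not
##    rescaled by 1/sqrt(C): the gated residual (alpha/beta init 0) keeps
##    the block well-behaved at the start of training.

#' Column-wise softmax with max-subtraction stabilization
#'
#' @param M numeric matrix of logits.
#' @return Matrix of the same shape whose columns each sum to 1.
#' @keywords internal
col_softmax <- function(M) {
  mx <- apply(M, 2L, max)
  Z <- exp(sweep(M, 2L, mx, "-"))
  sweep(Z, 2L, colSums(Z), "/")
}

#' Linear projections feeding the spatial attention stage
#'
#' Projects the instance matrix into three feature spaces: `A` and `B`
#' parameterize the instance-similarity logits, `D` carries the values
#' that get mixed across instances.
#'
#' @param X numeric N x C instance matrix.
#' @param params a `camil_params` object (or any list with `W_A`, `b_A`,
#'   `W_B`, `b_B`, `W_D`, `b_D`).
#' @return list with N x C matrices `A`, `B`, `D` where
#'   `A = X W_A + b_A` (bias broadcast across rows), likewise `B`, `D`.
#' @export
spatial_projections <- function(X, params) {
  affine <- function(W, b) {
    if (ncol(X) != nrow(W)) stop("dimension mismatch: X has ", ncol(X),
                                 " channels but projection expects ", nrow(W))
    sweep(X %*% W, 2L, b, "+")
  }
  list(A = affine(params$W_A, params$b_A),
       B = affine(params$W_B, params$b_B),
       D = affine(params$W_D, params$b_D))
}

#' Spatial (instance-to-instance) attention matrix
#'
#' `S[i, j]` is the softmax-normalized affinity `exp(A_i . B_j)` of
#' instance i toward instance j, normalized over i so that each column
#' sums to 1.
#'
#' @param A,B numeric N x C projection matrices from
#'   [spatial_projections()].
#' @return N x N column-stochastic matrix.
#' @export
spatial_attention_matrix <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("shape mismatch between A and B")
  col_softmax(A %*% t(B))   # logits M[i, j] = A_i . B_j
}

#' Apply spatial attention through the gated residual
#'
#' Each output row is the input row plus `alpha` times the
#' attention-weighted mixture of value rows:
#' `E_j = alpha * sum_i S[i, j] D_i + X_j`. With `alpha = 0` (its
#' initialization) the stage is exactly the identity.
#'
#' @param S N x N column-stochastic attention matrix.
#' @param D N x C value matrix.
#' @param X N x C input matrix (residual path).
#' @param alpha scalar residual gate.
#' @return N x C matrix `E`.
#' @export
apply_spatial_attention <- function(S, D, X, alpha) {
  if (nrow(S) != ncol(S) || nrow(S) != nrow(D) || !all(dim(D) == dim(X))) {
    stop("shape mismatch among S, D, X")
  }
  alpha * crossprod(S, D) + X
}

#' Channel attention matrix from the channel Gram matrix
#'
#' The logits are the Gram matrix of `E`'s columns (channel i dotted with
#' channel j); a softmax down each column yields `Cmat[i, j] = c_ji`, the
#' influence of channel i on channel j.
#'
#' @param E numeric N x C matrix.
#' @return C x C column-stochastic matrix.
#' @export
channel_attention_matrix <- function(E) {
  if (ncol(E) < 1L) stop("need at least one channel")
  col_softmax(crossprod(E))   # logits[i, j] = E[, i] . E[, j]
}

#' Apply channel attention through the gated residual
#'
#' Column j of the output is column j of `E` plus `beta` times the
#' attention-weighted mixture of all channels:
#' `G[, j] = beta * sum_i Cmat[i, j] E[, i] + E[, j]`. With `beta = 0`
#' (its initialization) the stage is exactly the identity.
#'
#' @param Cmat C x C column-stochastic channel attention matrix.
#' @param E N x C input matrix.
#' @param beta scalar residual gate.
#' @return N x C matrix `G`.
#' @export
apply_channel_attention <- function(Cmat, E, beta) {
  if (ncol(E) != nrow(Cmat) || nrow(Cmat) != ncol(Cmat)) {
    stop("shape mismatch between Cmat and E")
  }
  beta * E %*% Cmat + E
}

## One spatial stage with cache for backprop.
spatial_stage <- function(Z, params) {
  pr <- spatial_projections(Z, params)
  S <- spatial_attention_matrix(pr$A, pr$B)
  out <- apply_spatial_attention(S, pr$D, Z, params$alpha)
  list(out = out, cache = list(Z = Z, A = pr$A, B = pr$B, D = pr$D, S = S))
}

## One channel stage with cache.
channel_stage <- function(Z, params) {
  Cmat <- channel_attention_matrix(Z)
  out <- apply_channel_attention(Cmat, Z, params$beta)
  list(out = out, cache = list(Z = Z, Cmat = Cmat))
}

#' Cascaded attention block
#'
#' Composes the spatial and channel attention stages according to
#' `fusion`:
#' \describe{
#'   \item{`spatial_then_channel`}{(default) channel stage reads the
#'     spatial stage's output — the cascade order found best in ablation.}
#'   \item{`channel_then_spatial`}{reverse order; the channel stage reads
#'     the raw input.}
#'   \item{`spatial_only` / `channel_only`}{a single stage.}
#'   \item{`parallel_concat`}{both stages read the input independently;
#'     their outputs are concatenated along channels and linearly
#'     projected back to C.}
#' }
#' Because both residual gates initialize to zero, the whole block is the
#' identity map at initialization in every mode except `parallel_concat`
#' (whose learned output projection has no identity constraint).
#'
#' @param X numeric N x C matrix (encoded instances).
#' @param params a `camil_params` object.
#' @param fusion fusion mode; defaults to the mode stored in `params`.
#' @return N x C matrix `H` of refined instance features. The stage caches
#'   needed for backpropagation are attached as attribute `"cache"`.
#' @export
cascaded_block <- function(X, params, fusion = params$fusion) {
  fusion <- match.arg(fusion, c("spatial_then_channel",
                                "channel_then_spatial",
                                "spatial_only", "channel_only",
                                "parallel_concat"))
  cache <- list(fusion = fusion)
  if (fusion == "spatial_then_channel") {
    sp <- spatial_stage(X, params)
    ch <- channel_stage(sp$out, params)
    H <- ch$out
    cache$sp <- sp$cache; cache$ch <- ch$cache
  } else if (fusion == "channel_then_spatial") {
    ch <- channel_stage(X, params)
    sp <- spatial_stage(ch$out, params)
    H <- sp$out
    cache$sp <- sp$cache; cache$ch <- ch$cache
  } else if (fusion == "spatial_only") {
    sp <- spatial_stage(X, params)
    H <- sp$out
    cache$sp <- sp$cache
  } else if (fusion == "channel_only") {
    ch <- channel_stage(X, params)
    H <- ch$out
    cache$ch <- ch$cache
  } else { # parallel_concat
    sp <- spatial_stage(X, params)
    ch <- channel_stage(X, params)
    Hcat <- cbind(sp$out, ch$out)
    H <- sweep(Hcat %*% params$W_fuse, 2L, params$b_fuse, "+")
    cache$sp <- sp$cache; cache$ch <- ch$cache; cache$Hcat <- Hcat
  }
  attr(H, "cache") <- cache
  H
}

#' Attention pooling of instance features into a bag embedding
#'
#' Scores each instance with a two-layer tanh network
#' (`score_j = w . tanh(V h_j)`), softmax-normalizes the scores into
#' weights summing to one, and returns the weighted average of the
#' instance rows — the gateway from instance space to one bag-level
#' vector.
#'
#' @param H numeric N x C matrix of (refined) instance features.
#' @param params a `camil_params` object (uses `V_pool`, `w_pool`).
#' @return list with `bag_vector` (length C), `weights` (length N,
#'   nonnegative, summing to 1), and an internal `cache`.
#' @export
attention_pool <- function(H, params) {
  if (nrow(H) < 1L) stop("empty bag")
  Tm <- tanh(H %*% t(params$V_pool))            # N x hidden
  scores <- drop(Tm %*% params$w_pool)          # N
  scores <- scores - max(scores)
  w <- exp(scores); w <- w / sum(w)
  list(bag_vector = drop(crossprod(H, w)), weights = w,
       cache = list(H = H, Tm = Tm, w = w))
}
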